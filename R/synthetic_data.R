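#' Simulation configuration for im-SRT-like count data
#'
#' Parameters of the gamma-Poisson generator used to emulate the statistical
#' structure of imaging-based spatially resolved transcriptomics (im-SRT)
#' data: gene base expression levels drawn from a gamma distribution,
#' log-normal per-cell library factors, and subpopulation-enriched genes that
#' receive a multiplicative log-normal differential expression (DE) factor.
#'
#' Defaults target MERFISH-like data: a few hundred targeted genes, a couple
#' of thousand cells, roughly 70-90\% zero entries, and expected per-cell
#' totals around `exp(lib_location)` counts.
#'
#' @param n_genes number of gene species (>= 2).
#' @param n_cells number of cells (>= 2).
#' @param subpop_proportions named probability vector of subpopulation sizes;
#'   must sum to 1.
#' @param de_prob fraction of genes differentially expressed per
#'   subpopulation, in \[0, 1\].
#' @param de_fc_location,de_fc_scale meanlog / sdlog of the log-normal DE
#'   factor. The default location 1.0 gives a typical enrichment of
#'   about e ~ 2.7x.
#' @param mean_shape,mean_rate shape and rate of the gamma distribution of
#'   gene base means.
#' @param lib_location,lib_scale meanlog / sdlog of the log-normal per-cell
#'   library factor; `exp(lib_location)` is the median per-cell total count
#'   for a cell without extra DE inflation.
#' @param dropout logical; apply an additional logistic dropout stage
#'   (off by default, matching the analyses in this package).
#' @param dropout_mid,dropout_shape logistic dropout parameters on the
#'   log-mean scale (only used when `dropout = TRUE`).
#' @param seed integer master seed for the generator.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       n_cells = 2000L,
                       subpop_proportions = c(A = 0.5, B = 0.5),
                       de_prob = 0.1,
                       de_fc_location = 1.0,
                       de_fc_scale = 0.4,
                       mean_shape = 0.6,
                       mean_rate = 0.3,
                       lib_location = log(150),
                       lib_scale = 0.35,
                       dropout = FALSE,
                       dropout_mid = 0,
                       dropout_shape = -1,
                       seed = 1L) {
  if (n_genes < 2 || n_cells < 2) stop("n_genes and n_cells must both be >= 2")
  if (de_prob < 0 || de_prob > 1) stop("de_prob must be in [0, 1]")
  if (abs(sum(subpop_proportions) - 1) > 1e-9) {
    stop("subpop_proportions must sum to 1")
  }
  if (any(subpop_proportions < 0)) stop("subpop_proportions must be nonnegative")
  if (mean_shape <= 0 || mean_rate <= 0 || de_fc_scale <= 0 || lib_scale <= 0) {
    stop("shape/rate/scale parameters must be positive")
  }
  if (is.null(names(subpop_proportions))) {
    names(subpop_proportions) <- LETTERS[seq_along(subpop_proportions)]
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
      subpop_proportions = subpop_proportions, de_prob = de_prob,
      de_fc_location = de_fc_location, de_fc_scale = de_fc_scale,
      mean_shape = mean_shape, mean_rate = mean_rate,
      lib_location = lib_location, lib_scale = lib_scale,
      dropout = isTRUE(dropout), dropout_mid = dropout_mid,
      dropout_shape = dropout_shape, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate an im-SRT-like gene count matrix
#'
#' Gamma-Poisson generator: gene base means `m_g ~ Gamma(mean_shape,
#' mean_rate)` are rescaled to base proportions `m_g / sum(m)`; each cell
#' draws a library factor `L_i ~ LogNormal(lib_location, lib_scale)`; for
#' each subpopulation a `de_prob` fraction of genes receives a multiplicative
#' `LogNormal(de_fc_location, de_fc_scale)` DE factor. Counts are
#' `Poisson(L_i * de_factor_g(subpop(i)) * m_g / sum(m))`.
#'
#' Normalizing by the sum of base (not DE-adjusted) means makes the mean
#' fold change of a DE gene between subpopulations equal to its drawn factor,
#' and makes subpopulations carrying enriched genes detect proportionally
#' more total counts - the composition effect whose downstream consequences
#' this package measures.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (genes x cells integer matrix with
#'   gene/cell id dimnames), `cells` (data.frame with `cell_id`, `subpop`),
#'   `de_genes` (named list; per subpopulation a data.frame of `gene` and
#'   drawn `factor` - the simulation ground truth), and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  cell_ids <- sprintf("c%05d", seq_len(config$n_cells))
  subpops <- names(config$subpop_proportions)

  base_means <- with_seed(derive_seed(config$seed, "gene_means"), {
    stats::rgamma(config$n_genes, shape = config$mean_shape, rate = config$mean_rate)
  })
  base_prop <- base_means / sum(base_means)

  subpop <- with_seed(derive_seed(config$seed, "subpops"), {
    sample(subpops, config$n_cells, replace = TRUE,
           prob = config$subpop_proportions)
  })
  # guard: every subpopulation with positive proportion must be represented
  missing <- setdiff(subpops[config$subpop_proportions > 0], unique(subpop))
  if (length(missing)) {
    idx <- seq_along(missing)
    subpop[idx] <- missing
  }

  de <- with_seed(derive_seed(config$seed, "de_factors"), {
    lapply(stats::setNames(subpops, subpops), function(sp) {
      is_de <- stats::runif(config$n_genes) < config$de_prob
      fac <- rep(1, config$n_genes)
      fac[is_de] <- stats::rlnorm(sum(is_de), meanlog = config$de_fc_location,
                                  sdlog = config$de_fc_scale)
      list(factor = fac, genes = gene_ids[is_de])
    })
  })

  lib <- with_seed(derive_seed(config$seed, "lib_factors"), {
    stats::rlnorm(config$n_cells, meanlog = config$lib_location,
                  sdlog = config$lib_scale)
  })

  # expected counts per gene per cell
  lambda <- matrix(0, nrow = config$n_genes, ncol = config$n_cells)
  for (sp in subpops) {
    cols <- which(subpop == sp)
    if (!length(cols)) next
    mu_g <- base_prop * de[[sp]]$factor
    lambda[, cols] <- outer(mu_g, lib[cols])
  }

  counts <- with_seed(derive_seed(config$seed, "poisson"), {
    matrix(stats::rpois(length(lambda), lambda),
           nrow = config$n_genes, ncol = config$n_cells)
  })

  if (config$dropout) {
    counts <- with_seed(derive_seed(config$seed, "dropout"), {
      keep_p <- 1 - stats::plogis(config$dropout_shape *
                                    (log(lambda + 1e-12) - config$dropout_mid))
      keep <- matrix(stats::rbinom(length(counts), 1L, keep_p),
                     nrow = nrow(counts))
      counts * keep
    })
  }

  dimnames(counts) <- list(gene_ids, cell_ids)
  cells <- data.frame(cell_id = cell_ids, subpop = subpop,
                      stringsAsFactors = FALSE)
  de_genes <- lapply(de, function(d) {
    data.frame(gene = d$genes,
               factor = d$factor[match(d$genes, gene_ids)],
               stringsAsFactors = FALSE)
  })
  list(counts = counts, cells = cells, de_genes = de_genes, config = config)
}

#' Spatial layout: one axis-aligned rectangle per subpopulation
#'
#' @param blocks named list; for each subpopulation a numeric vector
#'   `c(xmin, xmax, ymin, ymax)` in micrometres. Blocks must have positive
#'   width and height.
#' @param jitter_sd Gaussian positional jitter (micrometres) added after the
#'   uniform draw inside the block.
#' @return an object of class `spatial_layout`.
#' @export
spatial_layout <- function(blocks, jitter_sd = 0) {
  stopifnot(is.list(blocks), !is.null(names(blocks)), jitter_sd >= 0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (length(b) != 4 || b[2] <= b[1] || b[4] <= b[3]) {
      stop("block for subpopulation '", nm,
           "' must be c(xmin, xmax, ymin, ymax) with positive extent")
    }
  }
  structure(list(blocks = blocks, jitter_sd = jitter_sd),
            class = "spatial_layout")
}

#' Assign spatial positions to cells
#'
#' Places each cell uniformly at random within its subpopulation's rectangle,
#' then adds isotropic Gaussian jitter. Coordinates are in micrometres.
#'
#' @param cells data.frame with `cell_id` and `subpop`.
#' @param layout a [spatial_layout()] with one block per subpopulation.
#' @param seed integer seed.
#' @return `cells` with numeric columns `x` and `y` added.
#' @export
assign_positions <- function(cells, layout, seed = 1L) {
  stopifnot(inherits(layout, "spatial_layout"))
  check_cells(cells)
  missing <- setdiff(unique(cells$subpop), names(layout$blocks))
  if (length(missing)) {
    stop("no spatial block for subpopulation(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(cells)
  with_seed(derive_seed(seed, "positions"), {
    x <- numeric(n)
    y <- numeric(n)
    for (sp in names(layout$blocks)) {
      idx <- which(cells$subpop == sp)
      if (!length(idx)) next
      b <- layout$blocks[[sp]]
      x[idx] <- stats::runif(length(idx), b[1], b[2])
      y[idx] <- stats::runif(length(idx), b[3], b[4])
    }
    if (layout$jitter_sd > 0) {
      x <- x + stats::rnorm(n, 0, layout$jitter_sd)
      y <- y + stats::rnorm(n, 0, layout$jitter_sd)
    }
    cells$x <- x
    cells$y <- y
    cells
  })
}

#' Z-position and cell volume configuration
#'
#' Defaults follow the partial-capture simulation this package reproduces:
#' two subpopulations at mean Z of 4.839 and 12 micrometres (SD 1.5), cell
#' volumes normal with mean 1000 and SD 2000 cubic micrometres, truncated to
#' positive values by rejection resampling.
#'
#' @param z_mean_by_subpop named numeric vector of mean Z positions (um).
#' @param z_sd SD of Z positions (um), > 0.
#' @param volume_mean,volume_sd mean and SD of cell volume (um^3);
#'   `volume_mean` must be positive.
#' @return an object of class `zvolume_config`.
#' @export
zvolume_config <- function(z_mean_by_subpop = c(A = 4.839, B = 12),
                           z_sd = 1.5,
                           volume_mean = 1000,
                           volume_sd = 2000) {
  stopifnot(z_sd > 0, volume_mean > 0, volume_sd >= 0)
  if (is.null(names(z_mean_by_subpop))) stop("z_mean_by_subpop must be named")
  structure(list(z_mean_by_subpop = z_mean_by_subpop, z_sd = z_sd,
                 volume_mean = volume_mean, volume_sd = volume_sd),
            class = "zvolume_config")
}

#' Assign Z positions and cell volumes
#'
#' Z positions are normal around each subpopulation's mean; volumes are
#' normal and rejection-resampled until strictly positive (a truncated
#' normal, preserving the configured location and scale intent while
#' enforcing physicality).
#'
#' @param cells data.frame with `cell_id` and `subpop`.
#' @param zv a [zvolume_config()].
#' @param seed integer seed.
#' @return `cells` with numeric columns `z_center` (um) and `volume` (um^3).
#' @export
assign_z_and_volume <- function(cells, zv = zvolume_config(), seed = 1L) {
  stopifnot(inherits(zv, "zvolume_config"))
  check_cells(cells)
  missing <- setdiff(unique(cells$subpop), names(zv$z_mean_by_subpop))
  if (length(missing)) {
    stop("no Z mean for subpopulation(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(cells)
  with_seed(derive_seed(seed, "z_volume"), {
    mu <- zv$z_mean_by_subpop[cells$subpop]
    cells$z_center <- stats::rnorm(n, mean = mu, sd = zv$z_sd)
    vol <- stats::rnorm(n, zv$volume_mean, zv$volume_sd)
    bad <- which(vol <= 0)
    while (length(bad)) {
      vol[bad] <- stats::rnorm(length(bad), zv$volume_mean, zv$volume_sd)
      bad <- which(vol <= 0)
    }
    cells$volume <- vol
    cells
  })
}

#' Radius of a sphere of given volume
#'
#' @param volume sphere volume (um^3), positive.
#' @return radius in micrometres: `(3 * volume / (4 * pi))^(1/3)`.
#' @export
sphere_radius <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (3 * volume / (4 * pi))^(1 / 3)
}
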