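# Orchestration: evaluate normalization methods across gene panels on one
# dataset, sweep panel sizes, and run the partial-volume capture study.

default_layout <- function(subpops, block = 500) {
  blocks <- lapply(seq_along(subpops), function(i) {
    c((i - 1) * block, i * block, 0, block)
  })
  names(blocks) <- subpops
  spatial_layout(blocks)
}

build_dataset <- function(config) {
  if (!is.null(config$counts)) {
    counts <- as_count_matrix(config$counts)
    cells <- align_cells(config$cells, counts)
    return(list(counts = counts, cells = cells, de_genes = NULL))
  }
  if (is.null(config$sim)) stop("config needs either counts/cells or sim")
  sim <- simulate_counts(config$sim)
  cells <- sim$cells
  layout <- config$layout %||%
    default_layout(names(config$sim$subpop_proportions))
  cells <- assign_positions(cells, layout, seed = config$sim$seed)
  zv <- config$zv %||% zvolume_config(
    z_mean_by_subpop = stats::setNames(
      seq(4.839, 12, length.out = length(unique(cells$subpop))),
      sort(unique(cells$subpop))))
  cells <- assign_z_and_volume(cells, zv, seed = config$sim$seed)
  list(counts = sim$counts, cells = cells, de_genes = sim$de_genes)
}

build_panels <- function(counts, cells, specs, methods, alpha, lfc_min,
                         seed) {
  pool <- NULL
  de_full <- NULL
  panels <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (inherits(sp, "gene_panel")) {
      panels[[length(panels) + 1L]] <- sp
      next
    }
    type <- sp$type %||% "full"
    pseed <- sp$seed %||% derive_seed(seed, paste0("panel", i))
    p <- switch(type,
      full = gene_panel(rownames(counts), provenance = "full"),
      random = sample_random_panel(rownames(counts), sp$size, seed = pseed),
      skewed = {
        if (is.null(pool)) {
          pool <- identify_de_pool(counts, cells,
                                   methods = intersect(methods,
                                     c("none", "library_size")),
                                   alpha = alpha, lfc_min = lfc_min)
        }
        sample_skewed_panel(pool[[sp$subpop]], sp$size, seed = pseed,
                            subpop = sp$subpop)
      },
      topk = {
        if (is.null(de_full)) {
          norm <- normalized_matrix(counts, cells, "library_size")
          de_full <- run_de(norm, cells)
        }
        top_k_panel(de_full, sp$subpop, sp$size)
      },
      stop("unknown panel type: ", type)
    )
    panels[[length(panels) + 1L]] <- p
  }
  names(panels) <- vapply(panels, function(p) p$provenance, character(1))
  if (anyDuplicated(names(panels))) {
    names(panels) <- make.unique(names(panels))
  }
  panels
}

#' Evaluate normalization methods against the full gene panel
#'
#' The core benchmarking loop: for each (panel, method) pair, counts are
#' subset to the panel, cells with zero panel counts are dropped (the same
#' retained-cell set is used for the paired full-panel run, so comparisons
#' are cell-matched), both runs are normalized, differential expression and
#' fold changes are computed, and concordance against the full-panel run is
#' quantified (scaling factor RMSE, per-gene correlation, FPR/FNR, SPR/SNR,
#' and optionally the spatially variable gene FNR).
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{sim}{a [sim_config()] to simulate data, or instead}
#'     \item{counts, cells}{an explicit dataset;}
#'     \item{layout, zv}{optional [spatial_layout()] / [zvolume_config()];}
#'     \item{panels}{list of [gene_panel()] objects or specs, each a list
#'       with `type` (`"skewed"`, `"random"`, `"topk"`, `"full"`), `subpop`,
#'       `size`, optional `seed`;}
#'     \item{methods}{normalization methods to evaluate (default
#'       `c("none", "library_size", "volume")`);}
#'     \item{alpha, lfc_min}{thresholds (defaults 0.05, 0.25);}
#'     \item{svg}{`NULL` to skip SVG analysis, or a list with `bin_size`,
#'       `n_perm`, `k`;}
#'     \item{seed}{master seed;}
#'     \item{out_dir}{optional output directory for CSVs and a manifest.}
#'   }
#' @return list with `report` (long data.frame: panel, method, metric,
#'   value), `details` (per panel x method: factors, DE tables, rate
#'   objects), `panels`, `data`, and `census` (dropped cells per panel).
#' @export
run_evaluation <- function(config) {
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  lfc_min <- config$lfc_min %||% 0.25
  methods <- config$methods %||% c("none", "library_size", "volume")
  data <- build_dataset(config)
  counts <- data$counts
  cells <- data$cells
  if (any(c("volume", "area") %in% methods) &&
      !any(c("volume", "area") %in% names(cells))) {
    stop("volume/area normalization requested but cells carry no volume")
  }
  specs <- config$panels %||% list(list(type = "full"))
  panels <- build_panels(counts, cells, specs, methods, alpha, lfc_min, seed)

  report <- list()
  details <- list()
  census <- list()
  for (pn in names(panels)) {
    panel <- panels[[pn]]
    counts_p_all <- subset_panel(counts, panel)
    keep <- colSums(counts_p_all) > 0 & colSums(counts) > 0
    census[[pn]] <- colnames(counts)[!keep]
    counts_p <- counts_p_all[, keep, drop = FALSE]
    counts_f <- counts[, keep, drop = FALSE]
    cells_r <- cells[match(colnames(counts_p), cells$cell_id), , drop = FALSE]
    for (m in methods) {
      res <- eval_pair(counts_p, counts_f, cells_r, panel, m,
                       alpha, lfc_min, config$svg, seed)
      details[[paste(pn, m, sep = "|")]] <- res
      add <- function(metric, value) {
        report[[length(report) + 1L]] <<- data.frame(
          panel = pn, method = m, metric = metric, value = value,
          stringsAsFactors = FALSE)
      }
      if (!is.null(res$sf_rmse)) add("sf_rmse", res$sf_rmse)
      add("median_gene_r", stats::median(res$per_gene_r, na.rm = TRUE))
      add("fpr", res$de_rates$fpr)
      add("fnr", res$de_rates$fnr)
      add("spr", res$fc_rates$spr)
      add("snr", res$fc_rates$snr)
      if (!is.null(res$svg_rates)) add("svg_fnr", res$svg_rates$fnr)
    }
  }
  report <- do.call(rbind, report)
  out <- list(report = report, details = details, panels = panels,
              data = data, census = census,
              config = list(seed = seed, alpha = alpha, lfc_min = lfc_min,
                            methods = methods))
  if (!is.null(config$out_dir)) write_evaluation(out, config$out_dir)
  out
}

eval_pair <- function(counts_p, counts_f, cells_r, panel, method,
                      alpha, lfc_min, svg_opts, seed) {
  norm_s <- normalized_matrix(counts_p, cells_r, method)
  norm_f <- normalized_matrix(counts_f, cells_r, method)
  fs <- attr(norm_s, "factors")
  ff <- attr(norm_f, "factors")
  sf_rmse <- if (!is.null(fs)) scaling_factor_rmse(fs, ff) else NULL
  per_gene_r <- per_gene_correlation(norm_s, norm_f)
  de_s <- run_de(norm_s, cells_r)
  # the full-panel run is normalized on all genes (that is where the panel
  # effect lives) but tested and BH-adjusted on the shared genes, so the
  # multiplicity family matches the skewed run; with panel-invariant
  # normalization the two runs are then identical, as they must be
  de_f <- run_de(norm_f[rownames(norm_s), , drop = FALSE], cells_r)
  de_rates <- de_error_rates(de_s, de_f, alpha = alpha)
  fc_rates <- fc_switch_rates(de_s, de_f)
  svg_rates <- NULL
  svg_s <- svg_f <- NULL
  if (!is.null(svg_opts)) {
    bin <- svg_opts$bin_size %||% 50
    np <- svg_opts$n_perm %||% 999
    k <- svg_opts$k %||% 6
    grid_s <- log_transform(rasterize(norm_s, cells_r, bin))
    grid_f <- log_transform(rasterize(norm_f, cells_r, bin))
    # restrict the full-panel grid to shared genes before testing so the BH
    # family matches the comparison set
    grid_f$values <- grid_f$values[rownames(grid_s$values), , drop = FALSE]
    svg_s <- run_svg(grid_s, n_perm = np, k = k, seed = seed)
    svg_f <- run_svg(grid_f, n_perm = np, k = k, seed = seed)
    svg_rates <- svg_fnr(svg_s, svg_f, alpha = alpha)
  }
  list(panel = panel$provenance, method = method,
       factors_skewed = fs, factors_full = ff, sf_rmse = sf_rmse,
       per_gene_r = per_gene_r, de_skewed = de_s, de_full = de_f,
       de_rates = de_rates, fc_rates = fc_rates,
       svg_skewed = svg_s, svg_full = svg_f, svg_rates = svg_rates)
}

write_evaluation <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "report.csv")
  utils::write.csv(out$report, p, row.names = FALSE)
  paths <- c(paths, p)
  for (key in names(out$details)) {
    d <- out$details[[key]]
    tag <- gsub("[^A-Za-z0-9_.-]", "_", key)
    if (!is.null(d$factors_skewed)) {
      p <- file.path(dir, paste0("factors_", tag, ".csv"))
      write_factors_csv(d$factors_skewed, d$panel, p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, paste0("de_", tag, ".csv"))
    utils::write.csv(d$de_skewed, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = out$config$seed, alpha = out$config$alpha,
    lfc_min = out$config$lfc_min, methods = out$config$methods,
    r_version = as.character(getRversion()),
    census = out$census,
    files = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Panel-size sweep: skew and concordance of top-k panels
#'
#' Emulates the single-cell RNA-seq experiment: simulate a full-transcriptome
#' -like dataset, rank genes for the target subpopulation by adjusted
#' p-value under library size normalization, build top-k panels across the
#' requested sizes (capped at the gene count), and report per size the panel
#' skew, the separation in unit-mean library-size factors between the target
#' subpopulation and the rest, and DE/fold-change concordance against the
#' full panel.
#'
#' @param sim a [sim_config()] describing the dataset (one simulation per
#'   seed).
#' @param target subpopulation the panels are skewed towards.
#' @param sizes panel sizes (default `c(50, 100, 500, 1000, 5000)`); values
#'   above the gene count are capped.
#' @param n_seeds number of independent replicate simulations (default 1).
#' @param alpha significance threshold (default 0.05).
#' @param seed master seed; replicate r uses a seed derived from it.
#' @return data.frame with one row per (seed, size): `seed_idx`, `size`,
#'   `skew`, `full_skew`, `factor_separation`, `fpr`, `fnr`, `spr`, `snr`.
#' @export
run_panel_size_sweep <- function(sim, target,
                                 sizes = c(50, 100, 500, 1000, 5000),
                                 n_seeds = 1, alpha = 0.05, seed = 1L) {
  sizes <- pmin(sizes, sim$n_genes)
  if (max(sizes) > sim$n_genes) stop("panel size exceeds gene count")
  rows <- list()
  for (r in seq_len(n_seeds)) {
    cfg <- sim
    cfg$seed <- derive_seed(seed, paste0("sweep_rep", r))
    dat <- simulate_counts(cfg)
    keep <- colSums(dat$counts) > 0
    counts <- dat$counts[, keep, drop = FALSE]
    cells <- dat$cells[match(colnames(counts), dat$cells$cell_id), ]
    norm_full <- normalized_matrix(counts, cells, "library_size")
    de_full <- run_de(norm_full, cells)
    full_skew <- compute_skew(counts, cells)$skew
    is_target <- cells$subpop == target
    for (k in unique(sizes)) {
      panel <- top_k_panel(de_full, target, k)
      counts_p <- subset_panel(counts, panel)
      keep_p <- colSums(counts_p) > 0
      cp <- counts_p[, keep_p, drop = FALSE]
      cf <- counts[, keep_p, drop = FALSE]
      cr <- cells[keep_p, , drop = FALSE]
      sk <- compute_skew(cp, cr)$skew
      f_s <- rescale_unit_mean(library_size_factors(cp))
      tgt <- cr$subpop == target
      sep <- mean(f_s[tgt]) - mean(f_s[!tgt])
      norm_s <- normalized_matrix(cp, cr, "library_size")
      norm_fm <- normalized_matrix(cf, cr, "library_size")
      de_s <- run_de(norm_s, cr)
      de_fm <- run_de(norm_fm[rownames(norm_s), , drop = FALSE], cr)
      der <- de_error_rates(de_s, de_fm, alpha = alpha)
      fcr <- fc_switch_rates(de_s, de_fm)
      rows[[length(rows) + 1L]] <- data.frame(
        seed_idx = r, size = k, skew = sk, full_skew = full_skew,
        factor_separation = sep, fpr = der$fpr, fnr = der$fnr,
        spr = fcr$spr, snr = fcr$snr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partial-volume capture study
#'
#' Simulates counts with Z positions and volumes, thins each cell's profile
#' by its captured volume fraction from the Z-stack geometry, then asks
#' whether normalization restores the separability of the subpopulations
#' that capture variation obscured. Separability is the mean silhouette
#' width of the subpopulation labels in 50-dimensional principal component
#' space of `log10(x + 1)` expression (genes centred and scaled).
#'
#' @param sim a [sim_config()]; two subpopulations with distinct Z means are
#'   simulated by default.
#' @param capture a [capture_config()].
#' @param zv a [zvolume_config()].
#' @param methods normalization methods compared (default
#'   `c("none", "library_size", "poscounts", "volume")`; `"volume"` uses the
#'   captured volume `volume * P_v`).
#' @param mode capture thinning mode, `"scale"` or `"binomial"`.
#' @param n_pcs number of principal components (default 50).
#' @return list with `separability` (data.frame: method,
#'   silhouette_captured, silhouette_truth), `capture` (per-cell group and
#'   fraction), and `cells`.
#' @export
run_capture_study <- function(sim = sim_config(),
                              capture = capture_config(),
                              zv = zvolume_config(),
                              methods = c("none", "library_size",
                                          "poscounts", "volume"),
                              mode = "scale",
                              n_pcs = 50) {
  dat <- simulate_counts(sim)
  cells <- assign_z_and_volume(dat$cells, zv, seed = sim$seed)
  r <- sphere_radius(cells$volume)
  cap <- classify_and_capture(cells$z_center, r, capture)
  cells$group <- cap$group
  cells$captured_fraction <- cap$captured_fraction
  cells$captured_volume <- cells$volume * cap$captured_fraction
  captured <- apply_capture(dat$counts, cap$captured_fraction, mode = mode,
                            seed = sim$seed)
  # cells with no captured volume (or no counts) carry no usable signal
  keep <- colSums(captured) > 0 & cells$captured_fraction > 0
  captured <- captured[, keep, drop = FALSE]
  truth <- dat$counts[, keep, drop = FALSE]
  cells_k <- cells[keep, , drop = FALSE]
  vol_cells <- data.frame(cell_id = cells_k$cell_id,
                          subpop = cells_k$subpop,
                          volume = cells_k$captured_volume)
  vol_cells_truth <- data.frame(cell_id = cells_k$cell_id,
                                subpop = cells_k$subpop,
                                volume = cells_k$volume)
  sep <- lapply(methods, function(m) {
    nc <- normalized_matrix(captured, vol_cells, m)
    nt <- normalized_matrix(truth, vol_cells_truth, m)
    data.frame(method = m,
               silhouette_captured = pca_silhouette(nc, cells_k$subpop,
                                                    n_pcs),
               silhouette_truth = pca_silhouette(nt, cells_k$subpop, n_pcs),
               stringsAsFactors = FALSE)
  })
  list(separability = do.call(rbind, sep),
       capture = data.frame(cell_id = cells$cell_id, group = cells$group,
                            captured_fraction = cells$captured_fraction,
                            captured_volume = cells$captured_volume),
       cells = cells)
}

# Mean silhouette width of labels in PCA space of log10(x + 1) expression.
pca_silhouette <- function(norm, labels, n_pcs = 50) {
  x <- log10(t(norm) + 1) # cells x genes
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1)
  pcs <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. = n_pcs)$x
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(pcs))
  mean(sil[, "sil_width"])
}
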