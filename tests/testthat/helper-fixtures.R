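# Fixtures are generated in code, once per test run, and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# tiny deterministic matrix: 3 genes x 2 cells, zero-free
toy_counts <- function() {
  matrix(c(2, 4, 6, 4, 8, 12), nrow = 3,
         dimnames = list(paste0("g", 1:3), c("c1", "c2")))
}

# two-subpopulation dataset of moderate size with positions and volumes,
# shared by panel / normalization / pipeline tests
two_pop_data <- function() {
  cached("two_pop", function() {
    cfg <- sim_config(n_genes = 200, n_cells = 500, de_prob = 0.2,
                      de_fc_location = 1.2, seed = 42L)
    dat <- simulate_counts(cfg)
    layout <- spatial_layout(list(A = c(0, 400, 0, 400),
                                  B = c(400, 800, 0, 400)))
    cells <- assign_positions(dat$cells, layout, seed = 42L)
    cells <- assign_z_and_volume(cells, zvolume_config(), seed = 42L)
    list(counts = dat$counts, cells = cells, de_genes = dat$de_genes,
         config = cfg)
  })
}

# A-skewed panel over the two_pop fixture, with its DE pool
two_pop_panel <- function(k = 20) {
  cached(paste0("two_pop_panel", k), function() {
    d <- two_pop_data()
    pool <- identify_de_pool(d$counts, d$cells,
                             methods = c("none", "library_size"))
    list(pool = pool,
         panel = sample_skewed_panel(pool$A, k, seed = 7L, subpop = "A"))
  })
}

# hand-built DE result tables for concordance tests
fake_de <- function(genes, region, p_adj, lfc,
                    lfc_flag = rep("ok", length(genes))) {
  data.frame(gene = genes, region = region, u_stat = NA_real_,
             p = p_adj, p_adj = p_adj, lfc = lfc, lfc_flag = lfc_flag,
             n_A = 10L, n_rest = 10L, stringsAsFactors = FALSE)
}

# raster grid with one synthetic cell per bin on an nx x ny lattice
lattice_grid <- function(values, nx, ny, bin_size = 50) {
  n <- nx * ny
  stopifnot(ncol(values) == n)
  cells <- data.frame(
    cell_id = colnames(values),
    subpop = "A",
    x = rep(seq_len(nx) - 0.5, times = ny) * bin_size,
    y = rep(seq_len(ny) - 0.5, each = nx) * bin_size)
  rasterize(values, cells, bin_size = bin_size)
}

# numerical integration oracle for the spherical cap fraction
cap_oracle <- function(r, h) {
  if (h == 0) return(0)
  stats::integrate(function(z) pi * (r^2 - z^2), lower = r - h, upper = r,
                   rel.tol = 1e-13)$value / (4 / 3 * pi * r^3)
}
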