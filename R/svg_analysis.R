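# Spatially variable gene (SVG) analysis: rasterize normalized expression
# onto a square-bin grid, then test spatial autocorrelation per gene with a
# permutation Moran's I on k-nearest-neighbour bin weights.

#' Rasterize normalized expression onto a square grid
#'
#' Cells are assigned to half-open square bins `[k*s, (k+1)*s)` by their x/y
#' position and each bin stores the arithmetic mean of normalized expression
#' per gene. Empty bins are absent.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param cells cell table with `cell_id`, `x`, `y` (micrometres).
#' @param bin_size bin edge length in micrometres (default 50).
#' @return an object of class `raster_grid`: list with `bins` (data.frame
#'   `bin_x`, `bin_y`, `n_cells`, bin-centre `x`, `y`), `values` (genes x
#'   bins matrix of means), and `bin_size`.
#' @export
rasterize <- function(norm, cells, bin_size = 50) {
  if (bin_size <= 0) stop("bin_size must be positive")
  cells <- align_cells(cells, norm)
  if (!all(c("x", "y") %in% names(cells))) stop("cells need x and y positions")
  bx <- floor(cells$x / bin_size)
  by <- floor(cells$y / bin_size)
  key <- paste(bx, by, sep = "_")
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  n_bins <- length(ukey)
  n_cells <- tabulate(idx, n_bins)
  # per-bin means: sum columns into bins, divide by occupancy
  sums <- matrix(0, nrow = nrow(norm), ncol = n_bins,
                 dimnames = list(rownames(norm), ukey))
  for (b in seq_len(n_bins)) {
    cols <- which(idx == b)
    sums[, b] <- if (length(cols) == 1L) norm[, cols] else
      rowSums(norm[, cols, drop = FALSE])
  }
  values <- sweep(sums, 2, n_cells, `/`)
  parts <- do.call(rbind, strsplit(ukey, "_", fixed = TRUE))
  bin_x <- as.numeric(parts[, 1])
  bin_y <- as.numeric(parts[, 2])
  bins <- data.frame(bin_x = bin_x, bin_y = bin_y, n_cells = n_cells,
                     x = (bin_x + 0.5) * bin_size,
                     y = (bin_y + 0.5) * bin_size)
  structure(list(bins = bins, values = values, bin_size = bin_size),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d bins of %g um, %d genes\n",
              nrow(x$bins), x$bin_size, nrow(x$values)))
  invisible(x)
}

#' Log10 transform of a raster grid
#'
#' @param grid a [rasterize()] result with nonnegative values.
#' @return the grid with `values` replaced by `log10(values + 1)`.
#' @export
log_transform <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  if (any(grid$values < 0)) stop("raster values must be nonnegative")
  grid$values <- log10(grid$values + 1)
  grid
}

# Row-standardized k-nearest-neighbour spatial weight matrix on bin centres.
knn_weights <- function(bins, k = 6) {
  n <- nrow(bins)
  if (n < 3) stop("need at least 3 bins")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(bins[, c("x", "y")]))
  diag(d) <- Inf
  i <- rep(seq_len(n), each = k)
  j <- as.vector(apply(d, 1, function(row) order(row)[seq_len(k)]))
  Matrix::sparseMatrix(i = i, j = j, x = 1 / k, dims = c(n, n))
}

# Moran's I with row-standardized weights (S0 = n): z' W z / z'z on the
# centred field.
moran_stat <- function(z, W) {
  z <- z - mean(z)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  sum(z * as.vector(W %*% z)) / denom
}

#' Permutation Moran's I test for one gene on a raster grid
#'
#' Computes Moran's I of the gene's binned values under row-standardized
#' k-nearest-neighbour weights and a one-sided permutation p-value
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm)`. The permutation seed is
#' derived from the seed and the gene id, so identical inputs give identical
#' p-values across panels and methods.
#'
#' @param grid a [rasterize()] (optionally [log_transform()]ed) grid with
#'   >= 3 bins.
#' @param gene gene id present in the grid.
#' @param n_perm number of permutations (default 999).
#' @param k number of nearest neighbours (default 6).
#' @param seed integer seed.
#' @return list with `gene`, `moran_i`, `p`, and `flag` (`"ok"` or
#'   `"zero_variance"`, in which case `moran_i` and `p` are NA).
#' @export
morans_i_test <- function(grid, gene, n_perm = 999, k = 6, seed = 1L) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!gene %in% rownames(grid$values)) stop("gene not in grid")
  W <- knn_weights(grid$bins, k)
  v <- grid$values[gene, ]
  res <- moran_perm_one(v, W, n_perm, derive_seed(seed, paste0("svg_", gene)))
  c(list(gene = gene), res)
}

moran_perm_one <- function(v, W, n_perm, seed) {
  if (stats::sd(v) == 0) {
    return(list(moran_i = NA_real_, p = NA_real_, flag = "zero_variance"))
  }
  z <- v - mean(v)
  denom <- sum(z^2)
  i_obs <- sum(z * as.vector(W %*% z)) / denom
  n <- length(z)
  perm <- with_seed(seed, {
    matrix(z[vapply(seq_len(n_perm), function(p) sample.int(n), integer(n))],
           nrow = n)
  })
  wp <- as.matrix(W %*% perm)
  i_perm <- colSums(perm * wp) / denom
  p <- (1 + sum(i_perm >= i_obs - 1e-12)) / (1 + n_perm)
  list(moran_i = i_obs, p = p, flag = "ok")
}

#' Spatially variable gene test over all genes of a raster grid
#'
#' Runs the permutation Moran's I test for every gene and adjusts p-values
#' across genes by Benjamini-Hochberg (zero-variance genes excluded from the
#' family and flagged).
#'
#' @inheritParams morans_i_test
#' @return data.frame with `gene`, `moran_i`, `p`, `p_adj`, `flag`.
#' @export
run_svg <- function(grid, n_perm = 999, k = 6, seed = 1L) {
  stopifnot(inherits(grid, "raster_grid"))
  W <- knn_weights(grid$bins, k)
  genes <- rownames(grid$values)
  rows <- lapply(genes, function(g) {
    res <- moran_perm_one(grid$values[g, ], W, n_perm,
                          derive_seed(seed, paste0("svg_", g)))
    data.frame(gene = g, moran_i = res$moran_i, p = res$p, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[, c("gene", "moran_i", "p", "p_adj", "flag")]
}

#' Spatially variable gene false negative rate between two runs
#'
#' Over genes shared by the two SVG result tables, with significance
#' `p_adj < alpha` and the full-panel run as ground truth:
#' `FNR = FN / (FN + TP)`. The false positive rate is reported only when
#' true negatives or false positives exist (spatially organized data often
#' has no non-significant genes on the full panel, leaving the FPR
#' undefined).
#'
#' @param skewed,full [run_svg()] tables.
#' @param alpha significance threshold (default 0.05).
#' @return list with `fnr`, `fpr` (NA when undefined) and `counts`.
#' @export
svg_fnr <- function(skewed, full, alpha = 0.05) {
  genes <- intersect(skewed$gene, full$gene)
  if (!length(genes)) stop("no shared genes")
  s <- skewed[match(genes, skewed$gene), ]
  f <- full[match(genes, full$gene), ]
  ok <- s$flag == "ok" & f$flag == "ok"
  sig_s <- s$p_adj[ok] < alpha
  sig_f <- f$p_adj[ok] < alpha
  fn <- sum(!sig_s & sig_f)
  tp <- sum(sig_s & sig_f)
  fp <- sum(sig_s & !sig_f)
  tn <- sum(!sig_s & !sig_f)
  list(fnr = rate(fn, fn + tp),
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       counts = c(FP = fp, FN = fn, TP = tp, TN = tn))
}
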