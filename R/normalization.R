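# Per-cell scaling factors and normalized expression.
#
# All factor functions return a named numeric vector (names = cell ids) with
# attributes `method` and `rescale`. Normalized expression is counts divided
# by the factor, so larger factors shrink a cell's profile.

new_factors <- function(x, method, rescale = "none") {
  stopifnot(all(x > 0), !is.null(names(x)))
  structure(x, method = method, rescale = rescale)
}

# DESeq2-style sparsity caveat: median-of-ratios factors collapse towards a
# degenerate value on very sparse data.
warn_degenerate <- function(f, method) {
  frac <- mean(abs(f) < 1e-6 | abs(f - 1) < 1e-6)
  if (frac > 0.5) {
    warning(sprintf(
      "%s: %.0f%% of scaling factors are within 1e-6 of 0 or 1; ",
      method, 100 * frac),
      "factors may be degenerate on sparse data", call. = FALSE)
  }
  invisible(f)
}

#' Drop cells with zero total counts
#'
#' Small panels can leave cells with no detected counts, for which no
#' count-based scaling factor exists. This filter removes them and reports a
#' census so that paired runs on other panels can be restricted to the same
#' retained cells.
#'
#' @param counts genes x cells matrix.
#' @return list with `counts` (retained columns) and `dropped` (character
#'   vector of removed cell ids).
#' @export
retain_nonzero_cells <- function(counts) {
  counts <- as_count_matrix(counts)
  tot <- colSums(counts)
  dropped <- colnames(counts)[tot <= 0]
  list(counts = counts[, tot > 0, drop = FALSE], dropped = dropped)
}

#' Library size scaling factors
#'
#' The factor for each cell is its total detected count over the genes in the
#' matrix (hence over the current gene panel).
#'
#' @param counts genes x cells matrix with positive column totals.
#' @return named numeric factor vector (method `"library_size"`).
#' @export
library_size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  f <- colSums(counts)
  if (any(f <= 0)) {
    stop("cells with zero total counts must be filtered before ",
         "library size factors (see retain_nonzero_cells)")
  }
  new_factors(f, "library_size")
}

#' Median-of-ratios (poscounts) scaling factors
#'
#' Zero-tolerant median-of-ratios size factors: for each gene the modified
#' geometric mean `m_g = exp(sum(log c_gi over positive c_gi) / n_cells)`
#' (zero for all-zero genes); the factor for cell i is the median over genes
#' with `m_g > 0` and `c_gi > 0` of `c_gi / m_g`. On zero-free data this is
#' the classic median-of-ratios estimator.
#'
#' @param counts genes x cells matrix.
#' @return named numeric factor vector (method `"poscounts"`).
#' @export
poscounts_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  n <- ncol(counts)
  logc <- log(counts)
  logc[!is.finite(logc)] <- 0 # zeros contribute nothing to the sum
  log_m <- rowSums(logc) / n
  m <- ifelse(rowSums(counts > 0) > 0, exp(log_m), 0)
  if (all(m == 0)) stop("no gene with a positive modified geometric mean")
  eligible <- m > 0
  f <- vapply(seq_len(n), function(i) {
    ci <- counts[, i]
    use <- eligible & ci > 0
    if (!any(use)) {
      stop("cell '", colnames(counts)[i],
           "' has no positive counts on eligible genes")
    }
    stats::median(ci[use] / m[use])
  }, numeric(1))
  names(f) <- colnames(counts)
  warn_degenerate(f, "poscounts")
  new_factors(f, "poscounts")
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Re-specified TMM with singleton pairing (the "wsp" variant) against a
#' reference cell. For cell i versus reference r, over genes positive in
#' both, M-values `log2(p_gi / p_gr)` and A-values `0.5 * log2(p_gi * p_gr)`
#' are computed on library-size-scaled proportions `p = c / N`, doubly
#' trimmed (`trim_m` on M, `trim_a` on A), and combined by a precision-
#' weighted mean with inverse approximate binomial variance weights
#' `1 / ((N_i - c_gi)/(N_i c_gi) + (N_r - c_gr)/(N_r c_gr))`. Cells sharing
#' no positive gene with the reference fall back to pairing their singleton
#' (positive in exactly one of the pair) genes by rank of magnitude. The
#' normalization factors f are rescaled to geometric mean 1.
#'
#' Two conventions for turning f into a scaling divisor are offered:
#' `"paper"` uses `1/f` directly (counts are multiplied by f, ignoring
#' library size), `"effective"` uses the normalized library size `N_i * f_i`.
#'
#' @param counts genes x cells matrix (>= 2 cells).
#' @param trim_m,trim_a two-sided trim fractions for M and A values.
#' @param reference reference cell id or index; `NULL` picks the cell whose
#'   upper-quartile scaled count is closest to the mean upper quartile.
#' @param convention `"paper"` (default) or `"effective"`.
#' @return named numeric factor vector (method `"tmm"`) with attribute
#'   `tmm_f` carrying the raw normalization factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        reference = NULL,
                        convention = c("paper", "effective")) {
  counts <- as_count_matrix(counts)
  convention <- match.arg(convention)
  n <- ncol(counts)
  if (n < 2) stop("TMM needs at least two cells")
  N <- colSums(counts)
  if (any(N <= 0)) stop("cells with zero totals must be filtered first")

  if (is.null(reference)) {
    q75 <- vapply(seq_len(n), function(i) {
      stats::quantile(counts[, i] / N[i], 0.75, names = FALSE)
    }, numeric(1))
    if (all(q75 == 0)) {
      ref <- 1L
    } else {
      ref <- which.min(abs(q75 - mean(q75)))
    }
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) stop("reference cell not found")
  } else {
    ref <- as.integer(reference)
  }

  cr <- counts[, ref]
  Nr <- N[ref]
  f <- vapply(seq_len(n), function(i) {
    if (i == ref) return(1)
    ci <- counts[, i]
    Ni <- N[i]
    both <- ci > 0 & cr > 0
    if (!any(both)) {
      # wsp singleton pairing: positive in exactly one cell of the pair,
      # ranked by magnitude and paired index-wise
      si <- sort(ci[ci > 0 & cr == 0], decreasing = TRUE)
      sr <- sort(cr[cr > 0 & ci == 0], decreasing = TRUE)
      m <- min(length(si), length(sr))
      if (m == 0) return(1)
      M <- log2((si[seq_len(m)] / Ni) / (sr[seq_len(m)] / Nr))
      return(2^mean(M))
    }
    pi_ <- ci[both] / Ni
    pr_ <- cr[both] / Nr
    M <- log2(pi_ / pr_)
    if (max(abs(M)) < 1e-6) return(1)
    A <- 0.5 * log2(pi_ * pr_)
    w <- 1 / ((Ni - ci[both]) / (Ni * ci[both]) +
                (Nr - cr[both]) / (Nr * cr[both]))
    ng <- length(M)
    loM <- floor(ng * trim_m) + 1
    hiM <- ng + 1 - loM
    loA <- floor(ng * trim_a) + 1
    hiA <- ng + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    val <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    if (!is.finite(val) || val <= 0) 1 else val
  }, numeric(1))

  f <- f / exp(mean(log(f))) # geometric mean 1
  sf <- if (convention == "paper") 1 / f else N * f
  names(sf) <- colnames(counts)
  out <- new_factors(sf, "tmm")
  attr(out, "tmm_f") <- stats::setNames(f, colnames(counts))
  attr(out, "convention") <- convention
  out
}

#' Cell volume (or area) scaling factors
#'
#' The factor is the measured cell volume (um^3) or area (um^2), independent
#' of detected counts and therefore identical for every gene panel over the
#' same cells.
#'
#' @param cells data.frame with `cell_id` and a `volume` (or `area`) column.
#' @param use `"volume"` or `"area"`.
#' @return named numeric factor vector (method `"volume"` or `"area"`).
#' @export
volume_factors <- function(cells, use = c("volume", "area")) {
  use <- match.arg(use)
  check_cells(cells)
  if (!use %in% names(cells)) stop("cells table has no '", use, "' column")
  v <- cells[[use]]
  if (any(is.na(v)) || any(v <= 0)) {
    stop("every retained cell needs a positive ", use)
  }
  new_factors(stats::setNames(as.numeric(v), cells$cell_id), use)
}

#' Unit scaling factors (no normalization)
#'
#' @param counts genes x cells matrix.
#' @return factor vector of ones (method `"none"`).
#' @export
none_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  new_factors(stats::setNames(rep(1, ncol(counts)), colnames(counts)), "none")
}

#' Normalize a count matrix by per-cell scaling factors
#'
#' @param counts genes x cells matrix.
#' @param factors named positive factor vector covering all cells of
#'   `counts`.
#' @return genes x cells matrix of `counts[g, i] / factors[i]`, with
#'   attribute `method` copied from the factors.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as_count_matrix(counts)
  if (is.null(names(factors))) stop("factors must be named by cell id")
  f <- factors[colnames(counts)]
  if (any(is.na(f))) stop("factors missing for some cells")
  if (any(f <= 0)) stop("scaling factors must be positive")
  out <- sweep(counts, 2, f, `/`)
  attr(out, "method") <- attr(factors, "method") %||% "custom"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic Pearson residual normalization
#'
#' Offset-model negative-binomial Pearson residuals, the analytic analogue
#' of scTransform's variance-stabilizing transform: expected counts
#' `mu_gi = rowsum_g * colsum_i / grand_total`, residuals
#' `(c_gi - mu_gi) / sqrt(mu_gi + mu_gi^2 / theta)`, clipped above at
#' `sqrt(n_cells)` and with negative residuals set to 0 so the output is a
#' nonnegative expression-like matrix. As `theta -> Inf` this reduces to
#' Poisson Pearson residuals.
#'
#' @param counts genes x cells matrix with positive grand total.
#' @param theta negative-binomial dispersion parameter (default 100).
#' @param clip upper clip value; default `sqrt(ncol(counts))`.
#' @return genes x cells nonnegative matrix (attribute `method =
#'   "pearson"`). All-zero genes get residual 0.
#' @export
pearson_residual_normalize <- function(counts, theta = 100, clip = NULL) {
  counts <- as_count_matrix(counts)
  if (theta <= 0) stop("theta must be positive")
  total <- sum(counts)
  if (total <= 0) stop("grand total of counts is zero")
  if (is.null(clip)) clip <- sqrt(ncol(counts))
  mu <- outer(rowSums(counts), colSums(counts)) / total
  denom <- sqrt(mu + mu^2 / theta)
  r <- (counts - mu) / denom
  r[denom == 0] <- 0 # all-zero gene or cell
  r[r > clip] <- clip
  r[r < 0] <- 0
  dimnames(r) <- dimnames(counts)
  attr(r, "method") <- "pearson"
  r
}

#' Rescale scaling factors to unit mean
#'
#' Divides factors by their arithmetic mean so that factor vectors computed
#' on panels of different sizes become comparable (removes the gross offset
#' between, say, 100-gene and 500-gene library sizes).
#'
#' @param factors named positive factor vector.
#' @return factors divided by `mean(factors)`; attribute `rescale` set to
#'   `"unit_mean"`.
#' @export
rescale_unit_mean <- function(factors) {
  if (!length(factors)) stop("empty factor vector")
  out <- factors / mean(factors)
  attributes(out) <- attributes(factors)
  attr(out, "rescale") <- "unit_mean"
  out
}

#' Compute normalized expression under a named method
#'
#' Dispatcher used by the panel and pipeline stages: computes the scaling
#' factors for `method` and returns the normalized matrix (with the factors
#' attached as attribute `factors`). `"pearson"` has no per-cell factor and
#' returns analytic Pearson residuals; `"none"` returns the counts unchanged
#' (unit factors).
#'
#' @param counts genes x cells matrix with positive column totals.
#' @param cells cell table (required for `"volume"`/`"area"`).
#' @param method one of `"none"`, `"library_size"`, `"poscounts"`, `"tmm"`,
#'   `"volume"`, `"area"`, `"pearson"`.
#' @param ... passed to the factor function (e.g. `theta` for `"pearson"`,
#'   `trim_m` for `"tmm"`).
#' @return normalized genes x cells matrix; attributes `method` and (except
#'   for `"pearson"`) `factors`.
#' @export
normalized_matrix <- function(counts, cells = NULL,
                              method = c("none", "library_size", "poscounts",
                                         "tmm", "volume", "area", "pearson"),
                              ...) {
  method <- match.arg(method)
  counts <- as_count_matrix(counts)
  if (method == "pearson") {
    return(pearson_residual_normalize(counts, ...))
  }
  f <- switch(method,
    none = none_factors(counts),
    library_size = library_size_factors(counts),
    poscounts = poscounts_factors(counts),
    tmm = tmm_factors(counts, ...),
    volume = {
      if (is.null(cells)) stop("volume normalization needs a cell table")
      volume_factors(align_cells(cells, counts), use = "volume")
    },
    area = {
      if (is.null(cells)) stop("area normalization needs a cell table")
      volume_factors(align_cells(cells, counts), use = "area")
    }
  )
  out <- normalize_counts(counts, f)
  attr(out, "factors") <- f
  out
}

#' Scaling factor methods with a per-cell factor
#'
#' @return character vector of method names usable with factor-based
#'   comparisons (excludes `"pearson"`, which has no per-cell factor).
#' @export
factor_methods <- function() {
  c("none", "library_size", "poscounts", "tmm", "volume", "area")
}
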