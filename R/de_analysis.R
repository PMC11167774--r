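# One-region-vs-rest differential expression on normalized expression.

# Midranks per gene plus the tie-correction term sum(t^3 - t) needed by the
# normal approximation of the rank-sum null variance.
rank_with_ties <- function(v) {
  r <- rank(v)
  tt <- rle(sort(v))$lengths
  list(ranks = r, tie_term = sum(tt^3 - tt))
}

# Exact one-sided (greater) rank-sum p by enumeration of all C(n, nA)
# assignments of the observed midranks to group A.
exact_ranksum_p <- function(ranks, idx_a) {
  n <- length(ranks)
  na <- length(idx_a)
  w_obs <- sum(ranks[idx_a])
  combs <- utils::combn(n, na)
  w_all <- colSums(matrix(ranks[combs], nrow = na))
  mean(w_all >= w_obs - 1e-9)
}

#' One-sided Wilcoxon rank-sum test of a region versus all other cells
#'
#' For each gene, tests whether normalized expression in the target
#' subpopulation is stochastically greater than in all remaining cells
#' (alternative = "greater"; panels are built from overexpressed genes, so
#' enrichment is the direction of interest). Ties are handled with midranks.
#' P-values use the tie-corrected, continuity-corrected normal approximation
#' when groups are large; for small problems (both groups below
#' `exact_threshold` and at most `exact_limit` enumerable assignments) the
#' exact permutation distribution of the rank sum is enumerated.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param cells cell table with `cell_id` and `subpop`.
#' @param subpop target subpopulation label.
#' @param exact `"auto"` (default), `"never"`, or `"always"` (errors if the
#'   enumeration is infeasible).
#' @param exact_threshold per-group size below which exact enumeration is
#'   attempted in auto mode (default 20).
#' @param exact_limit maximum number of enumerable assignments (default 2e5).
#' @return data.frame with `gene`, `u_stat` (Mann-Whitney U of the region),
#'   `p`, `n_A`, `n_rest`.
#' @export
wilcoxon_region_vs_rest <- function(norm, cells, subpop,
                                    exact = c("auto", "never", "always"),
                                    exact_threshold = 20,
                                    exact_limit = 2e5) {
  exact <- match.arg(exact)
  cells <- align_cells(cells, norm)
  idx_a <- which(cells$subpop == subpop)
  na <- length(idx_a)
  nb <- ncol(norm) - na
  if (na == 0 || nb == 0) {
    stop("both the region and the rest must be nonempty")
  }
  n <- na + nb
  n_comb <- choose(n, min(na, nb))
  do_exact <- switch(exact,
    never = FALSE,
    always = {
      if (n_comb > exact_limit) {
        stop("exact enumeration infeasible: choose(n, nA) = ", n_comb)
      }
      TRUE
    },
    auto = na < exact_threshold && nb < exact_threshold &&
      n_comb <= exact_limit
  )

  genes <- rownames(norm)
  p <- numeric(length(genes))
  u <- numeric(length(genes))
  for (g in seq_along(genes)) {
    rt <- rank_with_ties(norm[g, ])
    w <- sum(rt$ranks[idx_a])
    u[g] <- w - na * (na + 1) / 2
    if (do_exact) {
      p[g] <- exact_ranksum_p(rt$ranks, idx_a)
    } else {
      mu <- na * nb / 2
      sigma2 <- (na * nb / 12) *
        ((n + 1) - rt$tie_term / (n * (n - 1)))
      if (sigma2 <= 0) {
        p[g] <- 1 # all values tied: no evidence either way
      } else {
        z <- (u[g] - mu - 0.5) / sqrt(sigma2)
        p[g] <- stats::pnorm(z, lower.tail = FALSE)
      }
    }
  }
  data.frame(gene = genes, u_stat = u, p = p, n_A = na, n_rest = nb,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return monotone step-up adjusted values capped at 1.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Log2 fold change of a region versus all other cells
#'
#' Ratio of arithmetic means of normalized expression, no pseudocount.
#' Degenerate cases are flagged rather than patched: rest mean 0 with region
#' mean > 0 gives `Inf` (flag `"inf"`), region mean 0 with rest mean > 0
#' gives `-Inf` (flag `"ninf"`), both 0 gives `NaN` (flag `"undefined"`).
#' Flagged genes are excluded from switch-rate denominators downstream.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param cells cell table with `cell_id` and `subpop`.
#' @param subpop target subpopulation label.
#' @return data.frame with `gene`, `lfc`, `lfc_flag`.
#' @export
log2_fold_change <- function(norm, cells, subpop) {
  cells <- align_cells(cells, norm)
  in_a <- cells$subpop == subpop
  if (!any(in_a) || all(in_a)) {
    stop("both the region and the rest must be nonempty")
  }
  m_a <- rowMeans(norm[, in_a, drop = FALSE])
  m_r <- rowMeans(norm[, !in_a, drop = FALSE])
  lfc <- log2(m_a / m_r)
  flag <- rep("ok", length(lfc))
  flag[m_a > 0 & m_r == 0] <- "inf"
  flag[m_a == 0 & m_r > 0] <- "ninf"
  flag[m_a == 0 & m_r == 0] <- "undefined"
  data.frame(gene = rownames(norm), lfc = lfc, lfc_flag = flag,
             stringsAsFactors = FALSE)
}

#' Full differential expression table over all subpopulations
#'
#' Runs [wilcoxon_region_vs_rest()] and [log2_fold_change()] for every
#' subpopulation. By default the BH adjustment family is the set of genes
#' within one region-vs-rest comparison; `bh_family = "global"` adjusts one
#' family across all genes x regions instead.
#'
#' @param norm genes x cells normalized expression matrix.
#' @param cells cell table with `cell_id` and `subpop` (>= 2 subpopulations).
#' @param bh_family `"per_region"` (default) or `"global"`.
#' @param ... passed to [wilcoxon_region_vs_rest()].
#' @return data.frame with `gene`, `region`, `u_stat`, `p`, `p_adj`, `lfc`,
#'   `lfc_flag`, `n_A`, `n_rest`.
#' @export
run_de <- function(norm, cells, bh_family = c("per_region", "global"), ...) {
  bh_family <- match.arg(bh_family)
  cells <- align_cells(cells, norm)
  subpops <- sort(unique(cells$subpop))
  if (length(subpops) < 2) stop("need at least two subpopulations")
  parts <- lapply(subpops, function(sp) {
    w <- wilcoxon_region_vs_rest(norm, cells, sp, ...)
    fc <- log2_fold_change(norm, cells, sp)
    out <- data.frame(gene = w$gene, region = sp, u_stat = w$u_stat,
                      p = w$p, p_adj = NA_real_,
                      lfc = fc$lfc, lfc_flag = fc$lfc_flag,
                      n_A = w$n_A, n_rest = w$n_rest,
                      stringsAsFactors = FALSE)
    if (bh_family == "per_region") out$p_adj <- bh_adjust(out$p)
    out
  })
  de <- do.call(rbind, parts)
  rownames(de) <- NULL
  if (bh_family == "global") de$p_adj <- bh_adjust(de$p)
  de
}
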