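# Concordance between skewed-panel and full-panel results, taking the full
# panel as ground truth. Undefined rates (zero denominator) are reported as
# NA, never as 0: "no negatives existed" is not "no errors".

match_pairs <- function(skewed, full, cols) {
  key_s <- interaction(skewed$gene, skewed$region, drop = TRUE)
  key_f <- interaction(full$gene, full$region, drop = TRUE)
  shared <- intersect(levels(key_s), levels(key_f))
  if (!length(shared)) stop("no matched (gene, region) tests")
  s <- skewed[match(shared, key_s), cols, drop = FALSE]
  f <- full[match(shared, key_f), cols, drop = FALSE]
  list(s = s, f = f, keys = shared)
}

rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Differential expression error rates of a skewed panel against the full panel
#'
#' Tests are matched on (gene, region); only genes present in both result
#' tables are evaluated. Significance is `p_adj < alpha` in each run. With
#' the full panel as ground truth, `FPR = FP / (FP + TN)` and
#' `FNR = FN / (FN + TP)`.
#'
#' @param skewed,full [run_de()] tables from the skewed-panel and full-panel
#'   runs (same retained cells).
#' @param alpha significance threshold on adjusted p-values (default 0.05).
#' @return list with `fpr`, `fnr` (NA when the denominator is 0) and
#'   `counts` (named integer vector FP, FN, TP, TN).
#' @export
de_error_rates <- function(skewed, full, alpha = 0.05) {
  mp <- match_pairs(skewed, full, c("p_adj"))
  sig_s <- mp$s$p_adj < alpha
  sig_f <- mp$f$p_adj < alpha
  fp <- sum(sig_s & !sig_f)
  fn <- sum(!sig_s & sig_f)
  tp <- sum(sig_s & sig_f)
  tn <- sum(!sig_s & !sig_f)
  list(fpr = rate(fp, fp + tn), fnr = rate(fn, fn + tp),
       counts = c(FP = fp, FN = fn, TP = tp, TN = tn))
}

#' Fold change switch rates of a skewed panel against the full panel
#'
#' Comparisons are matched on (gene, region); pairs where either run flagged
#' the log2 fold change (infinite or undefined) are excluded. A fold change
#' of exactly 0 is treated as nonpositive. `SP` counts positive skewed-panel
#' fold changes whose full-panel counterpart is nonpositive; `SN` the
#' reverse; `TP`/`TN` are sign-concordant positives/nonpositives.
#' `SPR = SP / (SP + TN)`, `SNR = SN / (SN + TP)`.
#'
#' @param skewed,full [run_de()] tables.
#' @return list with `spr`, `snr` (NA when the denominator is 0), `counts`
#'   (SP, SN, TP, TN), and `switched` (data.frame of switched pairs with the
#'   full-panel fold change, for magnitude summaries).
#' @export
fc_switch_rates <- function(skewed, full) {
  mp <- match_pairs(skewed, full, c("lfc", "lfc_flag"))
  ok <- mp$s$lfc_flag == "ok" & mp$f$lfc_flag == "ok"
  ls <- mp$s$lfc[ok]
  lf <- mp$f$lfc[ok]
  pos_s <- ls > 0
  pos_f <- lf > 0
  sp <- sum(pos_s & !pos_f)
  sn <- sum(!pos_s & pos_f)
  tp <- sum(pos_s & pos_f)
  tn <- sum(!pos_s & !pos_f)
  switched <- data.frame(
    key = mp$keys[ok][xor(pos_s, pos_f)],
    lfc_skewed = ls[xor(pos_s, pos_f)],
    lfc_full = lf[xor(pos_s, pos_f)],
    stringsAsFactors = FALSE
  )
  list(spr = rate(sp, sp + tn), snr = rate(sn, sn + tp),
       counts = c(SP = sp, SN = sn, TP = tp, TN = tn),
       switched = switched)
}

#' Root mean squared error between two scaling factor vectors
#'
#' Factors are matched by cell id and (by default) rescaled to unit mean
#' first, removing the gross offset between panels of different sizes.
#'
#' @param sf_skewed,sf_full named factor vectors over the same retained
#'   cells.
#' @param scale `"unit_mean"` (default) or `"none"`.
#' @return the RMSE (a single number).
#' @export
scaling_factor_rmse <- function(sf_skewed, sf_full,
                                scale = c("unit_mean", "none")) {
  scale <- match.arg(scale)
  if (!setequal(names(sf_skewed), names(sf_full))) {
    stop("factor vectors cover different cells")
  }
  a <- as.numeric(sf_skewed)
  b <- as.numeric(sf_full[names(sf_skewed)])
  if (scale == "unit_mean") {
    a <- a / mean(a)
    b <- b / mean(b)
  }
  sqrt(mean((a - b)^2))
}

#' Per-gene Pearson correlation of normalized expression between two runs
#'
#' For each gene shared by the two normalized matrices, the Pearson
#' correlation of its values across the (matched) cells. Genes with zero
#' variance in either run get NA (undefined, excluded from summaries).
#'
#' @param norm_skewed,norm_full genes x cells normalized matrices over the
#'   same cells.
#' @return named numeric vector of correlations (NA = undefined).
#' @export
per_gene_correlation <- function(norm_skewed, norm_full) {
  if (ncol(norm_skewed) < 2) stop("need at least two cells")
  if (!setequal(colnames(norm_skewed), colnames(norm_full))) {
    stop("matrices cover different cells")
  }
  genes <- intersect(rownames(norm_skewed), rownames(norm_full))
  if (!length(genes)) stop("no shared genes")
  nf <- norm_full[genes, colnames(norm_skewed), drop = FALSE]
  ns <- norm_skewed[genes, , drop = FALSE]
  r <- vapply(genes, function(g) {
    x <- ns[g, ]
    y <- nf[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  r
}
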