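make_norm <- function(values_by_group, genes = 1) {
  # values_by_group: named list subpop -> numeric vector of cell values
  v <- unlist(values_by_group, use.names = FALSE)
  subpop <- rep(names(values_by_group), lengths(values_by_group))
  m <- matrix(rep(v, each = genes), nrow = genes, byrow = FALSE,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("c", seq_along(v))))
  list(norm = m,
       cells = data.frame(cell_id = colnames(m), subpop = subpop))
}

test_that("exact one-sided rank-sum p matches enumeration", {
  d <- make_norm(list(A = c(5, 6, 7), B = c(1, 2, 3)))
  res <- wilcoxon_region_vs_rest(d$norm, d$cells, "A", exact = "always")
  expect_equal(res$p, 1 / 20) # only 1 of C(6,3) assignments is as extreme
  # reversed groups: region smaller, p = 1 under "greater"
  res_b <- wilcoxon_region_vs_rest(d$norm, d$cells, "B", exact = "always")
  expect_equal(res_b$p, 1)
})

test_that("constant values give p = 1 under both code paths", {
  d <- make_norm(list(A = rep(2, 5), B = rep(2, 5)))
  expect_equal(wilcoxon_region_vs_rest(d$norm, d$cells, "A",
                                       exact = "always")$p, 1)
  expect_equal(wilcoxon_region_vs_rest(d$norm, d$cells, "A",
                                       exact = "never")$p, 1)
})

test_that("normal approximation tracks the exact enumeration on 8-vs-8 draws", {
  set.seed(21)
  for (i in 1:10) {
    # tie-free draws: the classical approximation-accuracy regime
    vals <- rnorm(16)
    d <- make_norm(list(A = vals[1:8], B = vals[9:16]))
    p_ex <- wilcoxon_region_vs_rest(d$norm, d$cells, "A", exact = "always")$p
    p_no <- wilcoxon_region_vs_rest(d$norm, d$cells, "A", exact = "never")$p
    expect_lt(abs(p_ex - p_no), 0.01)
  }
  for (i in 1:10) {
    # heavily tied counts: the midrank approximation is coarser but close
    vals <- rpois(16, 5)
    d <- make_norm(list(A = vals[1:8], B = vals[9:16]))
    p_ex <- wilcoxon_region_vs_rest(d$norm, d$cells, "A", exact = "always")$p
    p_no <- wilcoxon_region_vs_rest(d$norm, d$cells, "A", exact = "never")$p
    expect_lt(abs(p_ex - p_no), 0.05)
  }
})

test_that("rank-sum p is invariant to monotone transforms and common scaling", {
  set.seed(22)
  d <- make_norm(list(A = rnorm(30, 1), B = rnorm(40)))
  p0 <- wilcoxon_region_vs_rest(d$norm, d$cells, "A")$p
  p_exp <- wilcoxon_region_vs_rest(exp(d$norm), d$cells, "A")$p
  p_scaled <- wilcoxon_region_vs_rest(d$norm * 7.3, d$cells, "A")$p
  expect_equal(p0, p_exp)
  expect_equal(p0, p_scaled)
  expect_error(wilcoxon_region_vs_rest(d$norm, d$cells, "Z"), "nonempty")
})

test_that("bh_adjust implements step-up and matches stats::p.adjust", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
  set.seed(23)
  for (n in c(1, 5, 50, 500)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_equal(bh_adjust(c(0.2, NA, 0.01)),
               p.adjust(c(0.2, NA, 0.01), "BH", n = 2))
})

test_that("log2_fold_change uses the ratio of means and flags degenerate cases", {
  m <- rbind(g1 = c(4, 4, 1, 1),
             g2 = c(2, 2, 2, 2),
             g3 = c(1, 1, 4, 4),
             g4 = c(1, 1, 0, 0),
             g5 = c(0, 0, 0, 0),
             g6 = c(0, 0, 3, 3))
  colnames(m) <- paste0("c", 1:4)
  cells <- data.frame(cell_id = colnames(m),
                      subpop = c("A", "A", "B", "B"))
  fc <- log2_fold_change(m, cells, "A")
  expect_equal(fc$lfc[1:3], c(2, 0, -2))
  expect_equal(fc$lfc_flag, c("ok", "ok", "ok", "inf", "undefined", "ninf"))
  expect_equal(fc$lfc[4], Inf)
})

test_that("LFC is invariant to global rescaling of the normalized matrix", {
  d <- two_pop_data()
  norm <- normalize_counts(d$counts, library_size_factors(d$counts))
  a <- log2_fold_change(norm, d$cells, "A")
  b <- log2_fold_change(norm * 11, d$cells, "A")
  expect_equal(a$lfc, b$lfc)
})

test_that("run_de builds the full table, finds true DE genes, and is deterministic", {
  d <- two_pop_data()
  norm <- normalized_matrix(d$counts, d$cells, "library_size")
  de <- run_de(norm, d$cells)
  expect_setequal(unique(de$region), c("A", "B"))
  expect_equal(nrow(de), 2 * nrow(d$counts))
  expect_true(all(de$p_adj >= de$p - 1e-12, na.rm = TRUE))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_identical(de, run_de(norm, d$cells))

  # strongly enriched simulated genes are recovered
  strong <- d$de_genes$A$gene[d$de_genes$A$factor > 2.5]
  strong <- setdiff(strong, d$de_genes$B$gene)
  strong <- strong[rowMeans(d$counts[strong, , drop = FALSE]) > 0.3]
  hits <- de[de$region == "A" & de$gene %in% strong, ]
  expect_gt(mean(hits$p_adj < 0.05), 0.8)

  # global BH family is a single adjustment over genes x regions
  de_g <- run_de(norm, d$cells, bh_family = "global")
  expect_equal(de_g$p_adj, bh_adjust(de_g$p))
})
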