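test_that("library size factors are per-cell totals", {
  m <- matrix(c(1, 2, 3, 2, 2, 2), 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  f <- library_size_factors(m)
  expect_equal(as.numeric(f["c1"]), 6)
  expect_equal(as.numeric(f["c2"]), 6)
  norm <- normalize_counts(m, f)
  expect_equal(norm, m / 6, ignore_attr = TRUE)
  m0 <- m
  m0[, 2] <- 0
  expect_error(library_size_factors(m0), "zero total")
})

test_that("a subpop-enriched panel inflates that subpop's library factors", {
  # two genes: g1 enriched in A cells, g2 flat; panel = {g1}
  m <- rbind(g1 = c(30, 30, 10, 10), g2 = c(20, 20, 20, 20))
  colnames(m) <- paste0("c", 1:4) # c1, c2 in A
  full <- rescale_unit_mean(library_size_factors(m))
  panel <- rescale_unit_mean(library_size_factors(m["g1", , drop = FALSE]))
  gap_panel <- mean(panel[1:2]) - mean(panel[3:4])
  gap_full <- mean(full[1:2]) - mean(full[3:4])
  expect_gt(gap_panel, gap_full)
})

test_that("poscounts matches the median-of-ratios closed forms", {
  f <- poscounts_factors(toy_counts())
  expect_equal(as.numeric(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # zero-free columns (base, 2 x base) give factors in ratio 1:2
  base <- c(3, 7, 11, 2)
  m <- cbind(c1 = base, c2 = 2 * base)
  rownames(m) <- paste0("g", 1:4)
  f2 <- poscounts_factors(m)
  expect_equal(as.numeric(f2["c2"] / f2["c1"]), 2, tolerance = 1e-12)

  # single zero-free cell: factor 1
  s <- matrix(c(4, 9), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  expect_equal(as.numeric(suppressWarnings(poscounts_factors(s))), 1)

  # on zero-free data poscounts equals the classic median-of-ratios
  set.seed(31)
  zf <- matrix(rpois(60, 20) + 1, 10,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  classic <- apply(zf, 2, function(ci) {
    median(ci / exp(rowMeans(log(zf))))
  })
  expect_equal(as.numeric(poscounts_factors(zf)), unname(classic),
               tolerance = 1e-12)
})

test_that("poscounts and library size are scale-equivariant in one cell", {
  set.seed(5)
  m <- matrix(rpois(40, 15) + 1, 8,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  m2 <- m
  m2[, 3] <- m[, 3] * 4
  expect_equal(as.numeric(library_size_factors(m2)[3] /
                            library_size_factors(m)[3]), 4)
  # median-of-ratios equivariance is relative: scaling cell 3 by c scales its
  # factor relative to every other cell by c (the geometric means themselves
  # absorb c^(1/n))
  f_before <- poscounts_factors(m)
  f_after <- poscounts_factors(m2)
  expect_equal(as.numeric(f_after[3] / f_after[1]),
               4 * as.numeric(f_before[3] / f_before[1]), tolerance = 1e-12)
})

test_that("poscounts warns when factors collapse to a degenerate value", {
  m <- diag(4)
  dimnames(m) <- list(paste0("g", 1:4), paste0("c", 1:4))
  expect_warning(poscounts_factors(m), "degenerate")
})

test_that("TMM gives unit factors for proportional cells and geomean-1 f", {
  same <- cbind(c1 = c(5, 10, 15), c2 = c(5, 10, 15))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(as.numeric(tmm_factors(same)), c(1, 1))
  expect_equal(as.numeric(tmm_factors(toy_counts())), c(1, 1)) # c2 = 2*c1

  set.seed(8)
  m <- matrix(rpois(200, 8), 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  m <- m[, colSums(m) > 0]
  f <- attr(tmm_factors(m), "tmm_f")
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # effective convention recovers a global scaling through library size
  m2 <- m
  m2[, 2] <- m[, 2] * 3
  eff <- tmm_factors(m2, convention = "effective")
  expect_equal(as.numeric(eff[2] / eff[1]),
               as.numeric(colSums(m2)[2] / colSums(m2)[1] *
                            attr(eff, "tmm_f")[2] / attr(eff, "tmm_f")[1]))
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "two cells")
})

test_that("TMM singleton pairing handles zero-overlap cells", {
  # c2 shares no positive gene with the reference c1
  m <- rbind(g1 = c(10, 0), g2 = c(6, 0), g3 = c(0, 8), g4 = c(0, 2))
  colnames(m) <- c("c1", "c2")
  f <- tmm_factors(m, reference = "c1")
  expect_true(all(is.finite(f)) && all(f > 0))
})

test_that("volume factors are panel-independent and validated", {
  cells <- data.frame(cell_id = c("c1", "c2"), volume = c(10, 20),
                      area = c(4, 5))
  f <- volume_factors(cells)
  expect_equal(as.numeric(f), c(10, 20))
  expect_equal(as.numeric(volume_factors(cells, use = "area")), c(4, 5))
  # identical for any sub-panel of the same cells and hence identical
  # normalized values on shared genes
  m <- toy_counts()
  n_full <- normalize_counts(m, f)
  n_sub <- normalize_counts(m[1:2, ], f)
  expect_equal(n_sub, n_full[1:2, ], ignore_attr = TRUE)
  cells$volume[2] <- 0
  expect_error(volume_factors(cells), "positive volume")
})

test_that("normalize_counts divides by per-cell factors", {
  m <- toy_counts()
  expect_equal(normalize_counts(m, c(c1 = 1, c2 = 1)), m,
               ignore_attr = TRUE)
  expect_equal(as.numeric(normalize_counts(m, c(c1 = 2, c2 = 4))["g3", ]),
               c(3, 3))
  norm <- normalize_counts(m, library_size_factors(m))
  expect_equal(as.numeric(colSums(norm)), c(1, 1))
  expect_error(normalize_counts(m, c(c1 = 1, c2 = -1)), "positive")
  expect_error(normalize_counts(m, c(c1 = 1)), "missing")
})

test_that("pearson residuals: zero at the offset-model mean, nonnegative output", {
  # rank-one counts equal their row x column expectation exactly
  m <- outer(c(2, 4), c(3, 5))
  dimnames(m) <- list(c("g1", "g2"), c("c1", "c2"))
  r <- pearson_residual_normalize(m)
  expect_equal(unname(r), matrix(0, 2, 2), ignore_attr = TRUE)

  set.seed(12)
  big <- matrix(rpois(400, 3), 20,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:20)))
  out <- pearson_residual_normalize(big)
  expect_true(all(out >= 0))
  expect_true(all(out <= sqrt(20) + 1e-12))

  # theta -> Inf limit is the Poisson Pearson residual
  mu <- outer(rowSums(big), colSums(big)) / sum(big)
  pois <- (big - mu) / sqrt(mu)
  pois[pois < 0] <- 0
  nb <- pearson_residual_normalize(big, theta = 1e9, clip = Inf)
  expect_lt(max(abs(nb - pois)), 1e-6)
  expect_error(pearson_residual_normalize(big * 0), "grand total")
})

test_that("rescale_unit_mean rescales, preserves order, and is idempotent", {
  f <- c(c1 = 2, c2 = 4, c3 = 6)
  r <- rescale_unit_mean(f)
  expect_equal(as.numeric(r), c(0.5, 1.0, 1.5))
  expect_equal(mean(r), 1)
  expect_equal(as.numeric(rescale_unit_mean(r)), as.numeric(r))
  expect_identical(order(r), order(f))
  expect_error(rescale_unit_mean(numeric(0)), "empty")
})

test_that("normalized_matrix dispatches and attaches factors", {
  d <- two_pop_data()
  counts <- d$counts[, 1:50]
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0]
  cells <- d$cells[match(colnames(counts), d$cells$cell_id), ]
  for (m in c("none", "library_size", "poscounts", "tmm", "volume")) {
    nm <- normalized_matrix(counts, cells, m)
    expect_equal(attr(nm, "method"), m)
    expect_false(is.null(attr(nm, "factors")))
  }
  pr <- normalized_matrix(counts, cells, "pearson")
  expect_equal(attr(pr, "method"), "pearson")
  expect_error(normalized_matrix(counts, NULL, "volume"), "cell table")
})

test_that("retain_nonzero_cells drops and reports empty columns", {
  m <- toy_counts()
  m <- cbind(m, c3 = c(0, 0, 0))
  r <- retain_nonzero_cells(m)
  expect_equal(colnames(r$counts), c("c1", "c2"))
  expect_equal(r$dropped, "c3")
})
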