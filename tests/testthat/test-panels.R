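test_that("gene_panel validates and prints", {
  expect_error(gene_panel(c("a", "a")), "unique")
  expect_error(gene_panel(character(0)), "at least one")
  p <- gene_panel(c("a", "b"), provenance = "random", seed = 3L)
  expect_equal(p$size, 2L)
  expect_output(print(p), "2 genes")
})

test_that("skewed and random panels are seeded samples with size checks", {
  pool <- paste0("g", 1:10)
  expect_error(sample_skewed_panel(pool, 11), "smaller than panel size")
  p_all <- sample_skewed_panel(pool, 10, seed = 1L, subpop = "A")
  expect_setequal(p_all$gene_ids, pool) # |pool| = k: panel equals pool
  expect_equal(p_all$provenance, "skewed:A")
  p1 <- sample_skewed_panel(pool, 4, seed = 5L)
  p2 <- sample_skewed_panel(pool, 4, seed = 5L)
  expect_identical(p1$gene_ids, p2$gene_ids)

  universe <- paste0("g", 1:50)
  expect_equal(sort(sample_random_panel(universe, 50)$gene_ids),
               sort(universe))
  expect_error(sample_random_panel(universe, 51), "exceeds")
  r1 <- sample_random_panel(universe, 10, seed = 2L)
  expect_identical(r1$gene_ids, sample_random_panel(universe, 10,
                                                    seed = 2L)$gene_ids)
})

test_that("random panels carry the pool fraction in expectation", {
  universe <- paste0("g", 1:200)
  pool <- universe[1:40] # 20% of the universe
  k <- 50
  frac <- vapply(1:200, function(s) {
    mean(sample_random_panel(universe, k, seed = s)$gene_ids %in% pool)
  }, numeric(1))
  # hypergeometric: mean 0.2, var per draw ~ p(1-p)/k * fpc
  se <- sqrt(0.2 * 0.8 / k) / sqrt(200)
  expect_lt(abs(mean(frac) - 0.2), 4 * se)
})

test_that("top_k_panel ranks by adjusted p with deterministic tie-breaking", {
  de <- fake_de(genes = c("g1", "g2", "g3", "g4"), region = "A",
                p_adj = c(0.01, 0.001, 0.01, 0.5),
                lfc = c(0.3, 1.0, 0.9, 2.0))
  expect_equal(top_k_panel(de, "A", 1)$gene_ids, "g2")
  # tie between g1 and g3 broken by larger |lfc|
  expect_equal(top_k_panel(de, "A", 2)$gene_ids, c("g2", "g3"))
  # full tie falls back to lexical gene id
  de2 <- fake_de(genes = c("gb", "ga"), region = "A",
                 p_adj = c(0.1, 0.1), lfc = c(0.5, 0.5))
  expect_equal(top_k_panel(de2, "A", 1)$gene_ids, "ga")
  expect_error(top_k_panel(de, "A", 9), "exceeds")
  expect_error(top_k_panel(de, "Z", 1), "no DE results")
})

test_that("subset_panel restricts rows and validates membership", {
  m <- toy_counts()
  p <- gene_panel(c("g3", "g1"))
  expect_equal(rownames(subset_panel(m, p)), c("g3", "g1"))
  expect_error(subset_panel(m, gene_panel("nope")), "absent")
})

test_that("compute_skew matches hand computations", {
  # counts proportional to cell numbers: P = Q, skew 0
  m <- matrix(c(90, 10, 90, 10), 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  cells <- data.frame(cell_id = c("c1", "c2"), subpop = c("A", "B"))
  expect_equal(compute_skew(m, cells)$skew, 0)

  # count shares (0.9, 0.1) against cell shares (0.5, 0.5)
  m2 <- matrix(c(90, 10), 1, dimnames = list("g1", c("c1", "c2")))
  s <- compute_skew(m2, cells)
  expect_equal(s$skew, 0.9 * log(1.8) + 0.1 * log(0.2))
  expect_equal(s$skew, 0.3680642, tolerance = 1e-6)
  expect_equal(sum(s$p_counts), 1)
  expect_equal(sum(s$q_cells), 1)

  # single subpopulation: P = Q = 1
  one <- data.frame(cell_id = c("c1", "c2"), subpop = c("A", "A"))
  expect_equal(compute_skew(m2, one)$skew, 0)
  expect_error(compute_skew(m * 0, cells), "positive")
})

test_that("skew is nonnegative and zero only at P = Q", {
  set.seed(17)
  for (i in 1:20) {
    m <- matrix(rpois(80, 5), 8,
                dimnames = list(paste0("g", 1:8), paste0("c", 1:10)))
    cells <- data.frame(cell_id = colnames(m),
                        subpop = sample(c("A", "B", "C"), 10, replace = TRUE))
    if (length(unique(cells$subpop)) < 2 || sum(m) == 0) next
    s <- compute_skew(m, cells)
    expect_gte(s$skew, 0)
  }
})

test_that("identify_de_pool recovers simulated DE genes and skewed > random > full skew", {
  d <- two_pop_data()
  fix <- two_pop_panel()
  pool <- fix$pool
  expect_setequal(names(pool), c("A", "B"))
  # pools should be enriched for the simulated ground truth
  truth_a <- d$de_genes$A$gene[d$de_genes$A$factor > 1.5]
  expect_gt(length(intersect(pool$A, truth_a)) / length(truth_a), 0.5)

  skew_full <- compute_skew(d$counts, d$cells)$skew
  skew_skewed <- compute_skew(subset_panel(d$counts, fix$panel),
                              d$cells)$skew
  rnd <- sample_random_panel(rownames(d$counts), fix$panel$size, seed = 3L)
  skew_random <- compute_skew(subset_panel(d$counts, rnd), d$cells)$skew
  expect_gt(skew_skewed, skew_random)
  expect_gt(skew_skewed, 3 * skew_full)
  expect_lt(skew_random, skew_skewed / 2)
})

test_that("a gene significant under any single method enters the pool", {
  d <- two_pop_data()
  pool_both <- identify_de_pool(d$counts, d$cells,
                                methods = c("none", "library_size"))
  pool_none <- identify_de_pool(d$counts, d$cells, methods = "none")
  pool_lib <- identify_de_pool(d$counts, d$cells, methods = "library_size")
  expect_setequal(pool_both$A, union(pool_none$A, pool_lib$A))
})
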