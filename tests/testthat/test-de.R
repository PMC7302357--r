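test_that("size factors follow the geometric-mean reference construction", {
  m <- matrix(rpois(40, 50) + 1, 10, 4,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:4))
  )
  # identical samples: all factors 1
  ident <- m[, c(1, 1, 1)]
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))

  # doubled sample: factors (1/sqrt(2), sqrt(2))
  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(estimate_size_factors(two)), c(1 / sqrt(2), sqrt(2)))

  # all-zero gene rows are excluded; no positive gene is an error
  zeros <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_error(estimate_size_factors(zeros), "pseudo-reference")
})

test_that("log2 fold changes are invariant to rescaling all size factors", {
  set.seed(21)
  a <- matrix(rnbinom(100, mu = 80, size = 10), 10,
    dimnames = list(paste0("g", 1:10), paste0("a", 1:10))
  )
  b <- matrix(rnbinom(100, mu = 80, size = 10), 10,
    dimnames = list(paste0("g", 1:10), paste0("b", 1:10))
  )
  sf <- setNames(runif(20, 0.5, 2), c(colnames(a), colnames(b)))
  r1 <- nb_wald_test(a, b, size_factors = sf)
  r2 <- nb_wald_test(a, b, size_factors = 3 * sf)
  # rescaling changes the normalized means but not their ratio materially
  expect_equal(r1$log2fc, unname(log2(
    (rowMeans(sweep(a, 2, sf[colnames(a)], "/")) + 0.5) /
      (rowMeans(sweep(b, 2, sf[colnames(b)], "/")) + 0.5)
  )))
  expect_equal(cor(r1$log2fc, r2$log2fc), 1, tolerance = 1e-3)
})

test_that("dispersion estimation hits the floor on Poisson-like data and is calibrated", {
  # constant counts: zero variance
  expect_equal(estimate_dispersion(rep(50, 10), rep(50, 10)), 1e-8)
  # Poisson data at a seed where the variance does not exceed the mean
  set.seed(5)
  x <- rpois(100, 100)
  y <- rpois(100, 100)
  expect_equal(estimate_dispersion(x, y), 1e-8)
  expect_error(estimate_dispersion(5, c(1, 2)), "at least 2")

  # NB(mu=100, alpha=0.1): within 50% relative error in >= 90% of seeds
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    a <- rnbinom(50, mu = 100, size = 10)
    b <- rnbinom(50, mu = 100, size = 10)
    abs(estimate_dispersion(a, b) - 0.1) / 0.1 <= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the NB Wald test recovers fold changes and is calibrated under the null", {
  G <- 1000
  set.seed(42)
  ones <- function(a, b) setNames(rep(1, ncol(a) + ncol(b)), c(colnames(a), colnames(b)))

  # identical groups: zero fold change, p = 1
  a0 <- matrix(rnbinom(50, mu = 100, size = 10), 5,
    dimnames = list(paste0("g", 1:5), paste0("a", 1:10))
  )
  b0 <- a0
  colnames(b0) <- paste0("b", 1:10)
  r0 <- nb_wald_test(a0, b0, size_factors = ones(a0, b0))
  expect_equal(r0$log2fc, rep(0, 5))
  expect_equal(r0$p, rep(1, 5))

  # 400 vs 100: log2fc near 2, decisive p
  a1 <- matrix(rnbinom(G * 20, mu = 400, size = 20), G,
    dimnames = list(paste0("g", 1:G), paste0("a", 1:20))
  )
  b1 <- matrix(rnbinom(G * 20, mu = 100, size = 20), G,
    dimnames = list(paste0("g", 1:G), paste0("b", 1:20))
  )
  r1 <- nb_wald_test(a1, b1, size_factors = ones(a1, b1))
  expect_lt(abs(mean(r1$log2fc) - 2), 0.2)
  expect_gt(mean(r1$p < 1e-6), 0.95)

  # swapping groups negates the fold change and keeps p
  r1b <- nb_wald_test(b1, a1, size_factors = ones(a1, b1))
  expect_equal(r1b$log2fc, -r1$log2fc)
  expect_equal(r1b$p, r1$p)

  # null: type-I error within [0.03, 0.07] at nominal 0.05
  an <- matrix(rnbinom(G * 50, mu = 100, size = 10), G,
    dimnames = list(paste0("g", 1:G), paste0("a", 1:50))
  )
  bn <- matrix(rnbinom(G * 50, mu = 100, size = 10), G,
    dimnames = list(paste0("g", 1:G), paste0("b", 1:50))
  )
  rn <- nb_wald_test(an, bn, size_factors = ones(an, bn))
  expect_gte(mean(rn$p < 0.05), 0.03)
  expect_lte(mean(rn$p < 0.05), 0.07)

  expect_error(nb_wald_test(a0[, 1, drop = FALSE], b0), "at least 2")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5, 0.9, 0.04)),
    c(0.004, 2 / 3, 0.9, 0.08),
    tolerance = 1e-12
  )
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  set.seed(31)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # monotone in the order statistics
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("DE classification applies the headline thresholds", {
  expect_identical(classify_gene(2.5, 0.01), "up")
  expect_identical(classify_gene(1.0, 0.01), "minimal_up")
  expect_identical(classify_gene(3.0, 0.2), "ns")
  expect_identical(classify_gene(-2.5, 0.01), "down")
  expect_identical(classify_gene(-1.0, 0.01), "minimal_down")
  # the fold-change band is inclusive at |lfc| = 2
  expect_identical(classify_gene(2.0, 0.01), "minimal_up")
  expect_identical(classify_gene(-2.0, 0.01), "minimal_down")
})

test_that("de_table integrates the stages with padj >= p per gene", {
  cohort <- small_cohort(seed = 4)
  cl <- cohort$true_clusters$sample[cohort$true_clusters$cluster == "cluster_1"]
  de <- de_table(cohort$counts, cl)
  expect_true(all(de$padj >= de$p - 1e-15))
  expect_true(all(de$p >= 0 & de$p <= 1))
  markers <- cohort$marker_genes$cluster_1
  expect_true(all(de$de_class[de$gene %in% markers] == "up"))
})
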