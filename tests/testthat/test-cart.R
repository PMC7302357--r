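test_that("a separable pair is split once with perfect resubstitution", {
  expr <- matrix(c(rep(10, 5), rep(100, 5)),
    ncol = 1,
    dimnames = list(NULL, "CD48")
  )
  labels <- rep(c("low", "high"), each = 5)
  tree <- fit_cart(expr, labels, min_leaf = 1)
  expect_identical(extract_biomarkers(tree), "CD48")
  expect_equal(tree_accuracy(tree, expr, labels), 1)
  expect_equal(tree$root$threshold, 55) # midpoint between distinct values
})

test_that("a two-gene parity pattern needs depth 2", {
  expr <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1),
    ncol = 2,
    dimnames = list(NULL, c("gA", "gB"))
  )
  labels <- c("p", "q", "q", "p")
  deep <- fit_cart(expr, labels, min_leaf = 1, max_depth = 2)
  expect_equal(tree_accuracy(deep, expr, labels), 1)
  stump <- fit_cart(expr, labels, min_leaf = 1, max_depth = 1)
  expect_lte(tree_accuracy(stump, expr, labels), 0.75)
})

test_that("prediction routes at-or-above to the right and validates genes", {
  expr <- matrix(c(rep(0, 5), rep(10, 5)),
    ncol = 1,
    dimnames = list(NULL, "g1")
  )
  labels <- rep(c("a", "b"), each = 5)
  tree <- fit_cart(expr, labels, min_leaf = 1)
  thr <- tree$root$threshold
  expect_identical(predict(tree, c(g1 = thr)), "b")
  expect_identical(predict(tree, c(g1 = thr - 1e-9)), "a")
  expect_error(predict(tree, c(g2 = 1)), "lacks split gene")

  # a training sample from a pure leaf maps to that leaf's label
  expect_identical(predict(tree, expr), labels)
})

test_that("degenerate and structural cases behave as specified", {
  expr <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  # single class: trivial single-leaf tree with no biomarkers
  tree <- fit_cart(expr, rep("only", 10))
  expect_true(tree$root$leaf)
  expect_length(extract_biomarkers(tree), 0)
  expect_error(fit_cart(expr[0, , drop = FALSE], character(0)), "non-empty")

  # biomarker list is bounded by the internal node count
  set.seed(17)
  big <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("g", 1:6)))
  lab <- sample(c("a", "b", "c"), 100, replace = TRUE)
  t3 <- fit_cart(big, lab, min_leaf = 5, max_depth = 3)
  expect_lte(length(extract_biomarkers(t3)), 7)

  # training accuracy is non-decreasing in depth
  accs <- vapply(1:4, function(d) {
    tree_accuracy(fit_cart(big, lab, min_leaf = 5, max_depth = d), big, lab)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("accepted splits never increase weighted Gini impurity", {
  set.seed(23)
  expr <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("g", 1:3)))
  lab <- ifelse(expr[, 1] + rnorm(100, sd = 0.5) > 0, "a", "b")
  tree <- fit_cart(expr, lab)
  gini <- function(counts) 1 - sum((counts / sum(counts))^2)
  walk <- function(node) {
    if (node$leaf) {
      return(invisible())
    }
    parent <- gini(node$counts)
    child <- (sum(node$left$counts) * gini(node$left$counts) +
      sum(node$right$counts) * gini(node$right$counts)) / sum(node$counts)
    expect_lte(child, parent + 1e-12)
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
})

test_that("the fit is invariant to sample order", {
  set.seed(8)
  expr <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  lab <- rep(c("a", "b"), 25)
  expr[lab == "b", 2] <- expr[lab == "b", 2] + 2
  t1 <- fit_cart(expr, lab)
  perm <- sample(50)
  t2 <- fit_cart(expr[perm, ], lab[perm])
  expect_identical(tidy(t1), tidy(t2))
})

test_that("the fit agrees with rpart on clean two-class data", {
  skip_if_not_installed("rpart")
  set.seed(19)
  expr <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("g", 1:4)))
  lab <- rep(c("a", "b"), each = 50)
  expr[lab == "b", 3] <- expr[lab == "b", 3] + 3
  tree <- fit_cart(expr, lab)
  rp <- rpart::rpart(cl ~ .,
    data = data.frame(expr, cl = factor(lab)),
    method = "class", minbucket = 5, cp = 0
  )
  # same primary split gene, matching predictions
  expect_identical(tree$root$gene, as.character(rp$frame$var[1]))
  rp_pred <- as.character(predict(rp, data.frame(expr), type = "class"))
  expect_gte(mean(predict(tree, expr) == rp_pred), 0.98)
})

test_that("the cohort tree recovers planted structure with high held-out accuracy", {
  cohort <- small_cohort(seed = 4)
  truth <- cohort$true_clusters[cohort$true_clusters$cluster != "background", ]
  sf <- estimate_size_factors(cohort$counts)
  norm <- sweep(
    unclass(cohort$counts)[, truth$sample, drop = FALSE], 2,
    sf[truth$sample], "/"
  )
  expr <- t(norm)
  set.seed(4)
  holdout <- sample(nrow(expr), 15)
  tree <- fit_cart(expr[-holdout, ], truth$cluster[-holdout])
  expect_gte(
    mean(predict(tree, expr[holdout, ]) == truth$cluster[holdout]),
    0.9
  )
  # split genes come from the planted per-cluster signal
  planted <- unique(c(
    unlist(cohort$marker_genes),
    unlist(cohort$panel$steps), unlist(cohort$panel$checkpoint_genes),
    unlist(cohort$panel$decoy_genes)
  ))
  expect_true(all(extract_biomarkers(tree) %in% planted))
})
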