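test_that("exact 2xk p-values match hand enumeration and the classical test", {
  # two equiprobable tables under the margins
  expect_equal(fisher_exact_2xk(c(0, 1), c(1, 0)), 1)
  # hypergeometric enumeration over a = 0..5
  expect_equal(fisher_exact_2xk(c(5, 0), c(0, 5)), 2 / choose(10, 5))

  # reduces to the classical two-sided 2x2 Fisher test
  set.seed(9)
  for (i in 1:25) {
    a <- rpois(2, 8)
    b <- rpois(2, 8)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(
      fisher_exact_2xk(a, b),
      fisher.test(rbind(a, b))$p.value,
      tolerance = 1e-9
    )
  }
  # and agrees with the network-algorithm exact test at k = 3
  a <- c(2, 24, 2)
  b <- c(41, 211, 178)
  expect_equal(fisher_exact_2xk(a, b), fisher.test(rbind(a, b))$p.value,
    tolerance = 1e-7
  )

  expect_error(fisher_exact_2xk(c(1, 2), c(1.5, 2)), "integer")
  expect_error(fisher_exact_2xk(c(-1, 2), c(1, 2)), "integer")
  expect_error(fisher_exact_2xk(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("enumerated table probabilities sum to one", {
  for (m in list(c(5, 7), c(41, 211, 178), c(3, 4, 5, 6))) {
    n1 <- floor(sum(m) / 3)
    logp <- iema:::enumerate_tables(m, n1) - lchoose(sum(m), n1)
    expect_equal(sum(exp(logp)), 1, tolerance = 1e-9)
  }
})

test_that("p is invariant to category order permutation", {
  a <- c(2, 24, 2)
  b <- c(39, 187, 176)
  p0 <- fisher_exact_2xk(a, b)
  set.seed(2)
  for (i in 1:5) {
    o <- sample(3)
    expect_equal(fisher_exact_2xk(a[o], b[o]), p0, tolerance = 1e-12)
  }
})

test_that("cluster-vs-total association reproduces the reference p-values", {
  ref <- prad_iem_reference()
  # build a per-sample table matching the published Gleason contingency rows
  rows <- list()
  for (i in seq_len(nrow(ref$gleason))) {
    for (cat in c("le6", "eq7", "ge8")) {
      n <- ref$gleason[[cat]][i]
      if (n > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster = ref$gleason$cluster[i], gleason_cat = rep(cat, n)
        )
      }
    }
  }
  clin <- dplyr::bind_rows(rows)
  clin$sample <- sprintf("p%03d", seq_len(nrow(clin)))
  asg <- tibble::tibble(sample = clin$sample, cluster = clin$cluster)

  res <- associate_clusters(asg, clin, "gleason_cat", rest = "total")
  printed <- c(
    cluster_1 = 6.91e-1, cluster_2 = 3.52e-4, cluster_3 = 2.75e-2,
    cluster_4 = 4.24e-2, cluster_5 = 3.38e-1, cluster_6 = 1.26e-1,
    cluster_7 = 2.13e-4, cluster_8 = 6.12e-1
  )
  got <- setNames(res$p, res$cluster)[names(printed)]
  expect_equal(signif(unname(got), 3), unname(printed), tolerance = 2e-3)
  expect_setequal(
    res$cluster[res$significant],
    c("cluster_2", "cluster_3", "cluster_4", "cluster_7")
  )
})

test_that("all-zero categories are dropped before testing", {
  ref <- prad_iem_reference()
  rows <- list()
  for (i in seq_len(nrow(ref$tstage))) {
    for (cat in c("T1", "T2", "T3", "T4")) {
      n <- ref$tstage[[cat]][i]
      if (n > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster = ref$tstage$cluster[i], t_stage = rep(cat, n)
        )
      }
    }
  }
  clin <- dplyr::bind_rows(rows)
  clin$sample <- sprintf("q%03d", seq_len(nrow(clin)))
  asg <- tibble::tibble(sample = clin$sample, cluster = clin$cluster)
  res <- associate_clusters(asg, clin, "t_stage", rest = "total")
  # T1 never occurs and must not enter the enumeration
  expect_false(any(vapply(res$categories, function(x) "T1" %in% x, logical(1))))
  got <- setNames(res$p, res$cluster)
  expect_equal(signif(unname(got["cluster_3"]), 3), 1.93e-3, tolerance = 2e-3)
  expect_setequal(res$cluster[res$significant], "cluster_3")
})

test_that("missing values are excluded and counted", {
  asg <- tibble::tibble(
    sample = sprintf("s%02d", 1:40),
    cluster = rep(c("cluster_1", "cluster_2"), each = 20)
  )
  clin <- tibble::tibble(
    sample = asg$sample,
    gleason_cat = c(rep("eq7", 18), NA, "", rep(c("le6", "ge8"), 10))
  )
  res <- associate_clusters(asg, clin, "gleason_cat", rest = "others")
  expect_true(all(res$n_missing == 2))
  expect_equal(sum(res$n), 38)
  expect_error(
    associate_clusters(asg, clin, "nope"),
    "no column"
  )
})
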