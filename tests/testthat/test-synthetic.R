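test_that("the cohort is a deterministic function of its configuration", {
  c1 <- simulate_cohort(cohort_config(
    n_tumor = 40, n_normal = 6, n_genes = 120, n_clusters = 2,
    cluster_fracs = c(0.4, 0.3), marker_genes_per_cluster = 10, seed = 7
  ))
  c2 <- simulate_cohort(cohort_config(
    n_tumor = 40, n_normal = 6, n_genes = 120, n_clusters = 2,
    cluster_fracs = c(0.4, 0.3), marker_genes_per_cluster = 10, seed = 7
  ))
  expect_identical(unclass(c1$counts), unclass(c2$counts))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$fractions, c2$fractions)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_cohort(cohort_config(
    n_tumor = 10, n_normal = 4, n_genes = 120, n_clusters = 1,
    cluster_fracs = 0.5, marker_genes_per_cluster = 10, seed = 1
  )))
  expect_identical(rnorm(1), before)
})

test_that("planted layer effects reproduce the analytic NB mean ratio", {
  cfg <- cohort_config(
    n_tumor = 60, n_normal = 10, n_genes = 150, n_clusters = 1,
    cluster_fracs = 0.5, layer_effect = 3, nb_dispersion = 1e-8,
    marker_genes_per_cluster = 20, seed = 2
  )
  gen <- generate_counts(cfg)
  markers <- gen$marker_genes$cluster_1
  in_cluster <- gen$true_clusters$sample[gen$true_clusters$cluster == "cluster_1"]
  background <- gen$true_clusters$sample[gen$true_clusters$cluster == "background"]
  m <- unclass(gen$counts)
  ratio <- mean(m[markers, in_cluster]) / mean(m[markers, background])
  expect_lt(abs(ratio - 2^3) / 2^3, 0.10)
})

test_that("a null cohort yields no clusters in at least 9 of 10 seeds", {
  n_zero <- sum(vapply(1:10, function(s) {
    cohort <- simulate_cohort(cohort_config(
      n_tumor = 100, n_normal = 10, n_genes = 150, n_clusters = 2,
      cluster_fracs = c(0.3, 0.3), marker_genes_per_cluster = 15,
      layer_effect = 0, seed = s
    ))
    length(sequential_cluster(cohort$counts, plaid_params(seed = s))$clusters) == 0L
  }, logical(1)))
  expect_gte(n_zero, 9)
})

test_that("clinical generation respects the baseline and the enrichment", {
  truth <- tibble::tibble(
    sample = sprintf("t%03d", 1:400),
    cluster = rep(c("background", "cluster_1"), c(340, 60))
  )
  # null enrichment: frequencies within 3 sigma of the baseline simplex
  clin <- generate_clinical(truth, enrichment = list(), seed = 1)
  base <- c(le6 = 0.10, eq7 = 0.50, ge8 = 0.40)
  freq <- table(factor(clin$gleason_cat, levels = names(base))) / nrow(clin)
  sigma <- sqrt(base * (1 - base) / nrow(clin))
  expect_true(all(abs(freq - base) <= 3 * sigma))

  # strong enrichment closes the loop through the exact association test
  clin2 <- generate_clinical(truth,
    enrichment = list(cluster_1 = list(gleason_cat = c(ge8 = 20))), seed = 1
  )
  assoc <- associate_clusters(
    tibble::tibble(sample = truth$sample, cluster = truth$cluster),
    clin2, "gleason_cat",
    rest = "others"
  )
  expect_lt(assoc$p[assoc$cluster == "cluster_1"], 0.01)

  expect_error(
    generate_clinical(truth, enrichment = list(cluster_1 = list(gleason_cat = c(g10 = 2)))),
    "Unknown category"
  )
  expect_error(
    generate_clinical(truth, enrichment = list(nope = list(gleason_cat = c(ge8 = 2)))),
    "unknown cluster"
  )
})

test_that("fraction rows are Dirichlet with the requested shifts", {
  truth <- tibble::tibble(
    sample = sprintf("t%02d", 1:80),
    cluster = rep(c("background", "cluster_1"), each = 40)
  )
  # uniform concentrations: mean per column near 1/22 within 3 sigma
  fr <- generate_fractions(truth, base_concentration = 2, seed = 1)
  vals <- as.matrix(fr[, lm22_cell_types()])
  expect_true(all(abs(rowSums(vals) - 1) < 1e-9))
  col_means <- colMeans(vals)
  # Dirichlet(2,...,2) marginal variance, over n samples
  k <- 22
  v <- (2 * (2 * k - 2)) / ((2 * k)^2 * (2 * k + 1)) / nrow(fr)
  expect_true(all(abs(col_means - 1 / k) <= 3 * sqrt(v)))

  # x5 Treg concentration raises the cluster's mean Treg fraction in >= 95%
  # of seeds at n = 50 per group
  hits <- vapply(1:20, function(s) {
    tr2 <- tibble::tibble(
      sample = sprintf("t%02d", 1:100),
      cluster = rep(c("background", "cluster_1"), each = 50)
    )
    fr2 <- generate_fractions(
      tr2,
      shift_config = list(cluster_1 = c("T cells regulatory (Tregs)" = 5)),
      seed = s
    )
    treg <- fr2[["T cells regulatory (Tregs)"]]
    mean(treg[tr2$cluster == "cluster_1"]) > mean(treg[tr2$cluster == "background"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(
    generate_fractions(truth, shift_config = list(cluster_1 = c("Monocytes" = -1))),
    "positive"
  )
  expect_error(generate_fractions(truth, base_concentration = 0), "positive")
})

test_that("configuration invariants are enforced", {
  expect_error(
    cohort_config(n_clusters = 2, cluster_fracs = c(0.6, 0.6)),
    "at most 1"
  )
  expect_error(
    cohort_config(n_clusters = 2, cluster_fracs = c(0.9, 0.02)),
    "at least"
  )
  expect_error(cohort_config(n_clusters = 3, cluster_fracs = c(0.5, 0.3)), "one entry per")
  expect_error(cohort_config(nb_dispersion = 0))
})

test_that("write_cohort round-trips counts, clinical and fractions", {
  cohort <- simulate_cohort(cohort_config(
    n_tumor = 20, n_normal = 5, n_genes = 120, n_clusters = 1,
    cluster_fracs = 0.5, marker_genes_per_cluster = 10, seed = 9
  ))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_counts(
    file.path(dir, "counts.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    roles = file.path(dir, "sample_roles.tsv")
  )
  expect_identical(unclass(back), unclass(cohort$counts))
  expect_identical(sample_roles(back), sample_roles(cohort$counts))
  fr <- read_fractions(file.path(dir, "fractions.csv"))
  expect_equal(as.data.frame(fr), as.data.frame(cohort$fractions), tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(truth$seed, 9L)
})
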