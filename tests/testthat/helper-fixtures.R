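# Shared fixtures, built in code at test time.

# Small two-cluster cohort used by several integration tests.
small_cohort <- function(seed = 4) {
  simulate_cohort(cohort_config(
    n_tumor = 80, n_normal = 15, n_genes = 180,
    n_clusters = 2, cluster_fracs = c(0.4, 0.35),
    marker_genes_per_cluster = 18, seed = seed
  ))
}

# 20x20 noise matrix with a +5 block planted on rows/cols 1..5.
planted_block_matrix <- function(seed = 1, effect = 5) {
  set.seed(seed)
  Z <- matrix(rnorm(400, sd = 0.5), 20, 20,
    dimnames = list(paste0("g", 1:20), paste0("s", 1:20))
  )
  Z[1:5, 1:5] <- Z[1:5, 1:5] + effect
  Z
}

# Hand-built DE table: every gene ns except those passed as up-called.
fake_de <- function(up = character(0), genes = NULL, lfc = 3) {
  panel <- cancer_immunity_panel()
  genes <- genes %||% panel_genes(panel)
  tibble::tibble(
    gene = genes,
    base_mean = 100,
    log2fc = ifelse(genes %in% up, lfc, 0),
    se = 0.1,
    p = ifelse(genes %in% up, 1e-6, 0.9),
    padj = ifelse(genes %in% up, 1e-5, 0.95),
    de_class = ifelse(genes %in% up,
      ifelse(lfc > 2, "up", "minimal_up"), "ns"
    )
  )
}

# Exhaustive search for the contiguous rectangular block maximizing the
# constant-fit sum of squares mean(block)^2 * area. Independent oracle for
# the plaid layer fit on small instances.
best_constant_block <- function(Z) {
  n <- nrow(Z)
  m <- ncol(Z)
  S <- matrix(0, n + 1, m + 1)
  S[-1, -1] <- apply(apply(Z, 2, cumsum), 1, cumsum) |> t()
  best <- c(-1, 0, 0, 0, 0)
  for (i1 in 1:n) {
    for (i2 in i1:n) {
      for (j1 in 1:m) {
        for (j2 in j1:m) {
          tot <- S[i2 + 1, j2 + 1] - S[i1, j2 + 1] - S[i2 + 1, j1] + S[i1, j1]
          area <- (i2 - i1 + 1) * (j2 - j1 + 1)
          ss <- tot^2 / area
          if (ss > best[1]) best <- c(ss, i1, i2, j1, j2)
        }
      }
    }
  }
  best[2:5]
}

# Recovered cluster ids whose true counterpart carries a fraction shift.
map_shifted <- function(recovered, planted, asg) {
  ids <- vapply(asg$clusters, `[[`, character(1), "id")
  ids[recovered %in% planted]
}

# True cluster of every sample in a recovered cluster, by majority overlap.
majority_truth <- function(cluster_samples, truth) {
  names(which.max(table(truth$cluster[truth$sample %in% cluster_samples])))
}
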