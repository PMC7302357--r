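#' Median-of-ratios size factors
#'
#' Per-sample scale factors against a pseudo-reference of per-gene geometric
#' means; genes with any zero count are excluded from the reference. Each
#' sample's factor is the median across included genes of its count over the
#' reference.
#'
#' @param counts Gene-by-sample numeric matrix or [cohort_counts()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'   dimnames = list(paste0("g", 1:3), c("a", "b"))
#' )
#' estimate_size_factors(m) # sample b is at double depth
estimate_size_factors <- function(counts) {
  m <- unclass(counts)
  attr(m, "roles") <- NULL
  all_positive <- rowSums(m <= 0) == 0
  if (!any(all_positive)) {
    abort(paste(
      "No gene has all-positive counts across samples;",
      "cannot form the geometric-mean reference. Consider a pseudo-reference",
      "(e.g. adding a pseudo-count) before normalization."
    ))
  }
  lm <- log(m[all_positive, , drop = FALSE])
  ref <- rowMeans(lm) # log geometric mean
  sf <- apply(lm, 2, function(col) exp(median(col - ref)))
  setNames(sf, colnames(m))
}

#' Method-of-moments NB dispersion shared across two groups
#'
#' `alpha = max(floor, (pooled variance - pooled mean) / pooled mean^2)` on
#' normalized counts, where the pooled mean is the sample-size-weighted mean
#' of the group means and the pooled variance is the df-weighted within-group
#' variance. Poisson-like or constant data hit the floor.
#'
#' @param group_a,group_b Numeric vectors of normalized counts for one gene.
#' @param floor Lower bound on the estimate (default 1e-8).
#' @return Dispersion estimate `alpha >= floor`.
#' @export
estimate_dispersion <- function(group_a, group_b, floor = 1e-8) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) {
    abort("Both groups need at least 2 samples to estimate dispersion.")
  }
  pooled_mean <- (n_a * mean(group_a) + n_b * mean(group_b)) / (n_a + n_b)
  pooled_var <- ((n_a - 1) * var(group_a) + (n_b - 1) * var(group_b)) /
    (n_a + n_b - 2)
  if (pooled_mean <= 0) {
    return(floor)
  }
  max(floor, (pooled_var - pooled_mean) / pooled_mean^2)
}

#' Per-gene negative-binomial Wald test between two groups
#'
#' For each gene, normalized counts are compared between a cluster and a
#' reference group under a two-group NB model with a shared
#' method-of-moments dispersion. The log2 fold change uses a pseudo-count of
#' `eps` on the normalized scale; its standard error comes from the delta
#' method on the NB variance of each group mean; the p-value is the
#' two-sided normal tail of `log2fc / se`.
#'
#' @param cluster_counts,normal_counts Gene-by-sample count matrices for the
#'   two groups (same genes, both with at least 2 samples).
#' @param size_factors Named size factors covering every sample in both
#'   groups; defaults to factors estimated on the combined matrix.
#' @param eps Pseudo-count on the normalized scale (default 0.5).
#' @return A tibble: `gene`, `base_mean`, `log2fc`, `se`, `p`.
#' @export
nb_wald_test <- function(cluster_counts, normal_counts, size_factors = NULL,
                         eps = 0.5) {
  if (ncol(cluster_counts) < 2 || ncol(normal_counts) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  if (!identical(rownames(cluster_counts), rownames(normal_counts))) {
    abort("The two groups must cover the same genes in the same order.")
  }
  combined <- cbind(cluster_counts, normal_counts)
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(combined)
  }
  missing <- setdiff(colnames(combined), names(size_factors))
  if (length(missing) > 0) {
    abort(sprintf("No size factor for sample(s): %s.", paste(utils::head(missing, 5), collapse = ", ")))
  }
  a <- sweep(cluster_counts, 2, size_factors[colnames(cluster_counts)], "/")
  b <- sweep(normal_counts, 2, size_factors[colnames(normal_counts)], "/")
  n_a <- ncol(a)
  n_b <- ncol(b)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  var_a <- apply(a, 1, var)
  var_b <- apply(b, 1, var)
  pooled_mean <- (n_a * mean_a + n_b * mean_b) / (n_a + n_b)
  pooled_var <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / (n_a + n_b - 2)
  alpha <- pmax(1e-8, ifelse(pooled_mean > 0, (pooled_var - pooled_mean) / pooled_mean^2, 0))

  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  # delta method: Var(log2 (mean + eps)) = Var(mean) / ((mean + eps) ln 2)^2,
  # with NB variance of the group mean Var(mean) = (mu + alpha mu^2) / n
  v_a <- (mean_a + alpha * mean_a^2) / n_a / ((mean_a + eps) * log(2))^2
  v_b <- (mean_b + alpha * mean_b^2) / n_b / ((mean_b + eps) * log(2))^2
  se <- sqrt(v_a + v_b)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  tibble(
    gene = rownames(cluster_counts),
    base_mean = (n_a * mean_a + n_b * mean_b) / (n_a + n_b),
    log2fc = unname(log2fc),
    se = unname(se),
    p = unname(p)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; validates the inputs and delegates to
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.5, 0.9, 0.04))
bh_adjust <- function(p) {
  check_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Classify a gene's differential expression
#'
#' Differentially expressed genes have adjusted p below 0.05 and |log2 fold
#' change| above 2; significant genes inside the fold-change band are called
#' minimally differentially expressed (up or down by sign); everything else
#' is non-significant.
#'
#' @param log2fc Log2 fold change(s).
#' @param padj BH-adjusted p-value(s) in \[0, 1\].
#' @param padj_cutoff,lfc_cutoff Thresholds (defaults 0.05 and 2).
#' @return Character vector over
#'   `c("up", "down", "minimal_up", "minimal_down", "ns")`.
#' @export
#' @examples
#' classify_gene(c(2.5, 1.0, -3.0, 3.0), c(0.01, 0.01, 0.01, 0.2))
classify_gene <- function(log2fc, padj, padj_cutoff = 0.05, lfc_cutoff = 2) {
  check_prob(padj, "padj")
  dplyr::case_when(
    padj < padj_cutoff & log2fc > lfc_cutoff ~ "up",
    padj < padj_cutoff & log2fc < -lfc_cutoff ~ "down",
    padj < padj_cutoff & log2fc > 0 ~ "minimal_up",
    padj < padj_cutoff & log2fc < 0 ~ "minimal_down",
    TRUE ~ "ns"
  )
}

#' Cluster-versus-normal differential expression table
#'
#' Runs the NB Wald test of a cluster's samples against the pooled
#' adjacent-normal reference, adjusts p-values by Benjamini-Hochberg and
#' attaches the DE class.
#'
#' @param counts An [cohort_counts()] object.
#' @param cluster_samples Sample ids forming the cluster.
#' @param size_factors Optional named size factors (defaults to factors from
#'   the full matrix, so fold changes are comparable across clusters).
#' @param padj_cutoff,lfc_cutoff Classification thresholds.
#' @return A tibble of class `iema_de`: `gene`, `base_mean`, `log2fc`, `se`,
#'   `p`, `padj`, `de_class`.
#' @export
de_table <- function(counts, cluster_samples, size_factors = NULL,
                     padj_cutoff = 0.05, lfc_cutoff = 2) {
  stopifnot(inherits(counts, "iema_counts"))
  normals <- normal_samples(counts)
  if (length(normals) < 2) abort("Need at least 2 normal samples.")
  if (length(cluster_samples) < 2) abort("Need at least 2 cluster samples.")
  missing <- setdiff(cluster_samples, colnames(counts))
  if (length(missing) > 0) {
    abort(sprintf("Unknown cluster sample(s): %s.", paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- unclass(counts)
  attr(m, "roles") <- NULL
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  res <- nb_wald_test(
    m[, cluster_samples, drop = FALSE],
    m[, normals, drop = FALSE],
    size_factors = size_factors
  )
  res$padj <- bh_adjust(res$p)
  res$de_class <- classify_gene(res$log2fc, res$padj, padj_cutoff, lfc_cutoff)
  class(res) <- c("iema_de", class(res))
  res
}

#' @export
glance.iema_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$de_class == "up"),
    n_down = sum(x$de_class == "down"),
    n_minimal = sum(x$de_class %in% c("minimal_up", "minimal_down")),
    n_ns = sum(x$de_class == "ns")
  )
}

#' @export
autoplot.iema_de <- function(object, padj_cutoff = 0.05, lfc_cutoff = 2, ...) {
  df <- dplyr::mutate(as_tibble(object),
    neglog10_padj = -log10(pmax(.data$padj, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = .data$neglog10_padj, colour = .data$de_class
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(padj_cutoff), linetype = "dashed") +
    ggplot2::labs(
      x = "log2 fold change (cluster / normal)",
      y = "-log10 adjusted p", colour = "DE class"
    ) +
    ggplot2::theme_minimal()
}

#' Write a DE table as TSV
#'
#' @param de An `iema_de` tibble.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(as_tibble(de), path, progress = FALSE)
  invisible(path)
}
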