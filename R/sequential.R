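#' Sequential plaid clustering into disjoint patient clusters
#'
#' Runs plaid layer fitting repeatedly, removing each retained layer's
#' samples from the matrix, to produce discrete, non-overlapping patient
#' clusters. The loop stops when no layer is retained or when the next
#' layer's sample set is smaller than `min_frac` of the ORIGINAL sample
#' count. Genes are not removed between rounds, so a gene may define several
#' clusters. Remaining samples are reported as unclustered.
#'
#' @param x An [cohort_counts()] object (tumor samples are clustered after
#'   the median-of-ratios/log2/centering transform) or an already-transformed
#'   numeric matrix whose columns are all clustered.
#' @param params A [plaid_params()].
#' @param min_frac Stopping fraction of the original cohort (default 0.05).
#' @return An object of class `iema_assignment`: `clusters` (list of
#'   `id`/`samples`/`genes`/`layer_ss` in discovery order), `assignment`
#'   (tibble `sample`, `cluster` with `"unclustered"`), `unclustered`,
#'   `n_total`, `min_frac`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_tumor = 60, n_normal = 10, n_genes = 150, n_clusters = 2,
#'   cluster_fracs = c(0.45, 0.45), marker_genes_per_cluster = 15, seed = 3
#' ))
#' asg <- sequential_cluster(cohort$counts, plaid_params(seed = 3))
#' cluster_sizes(asg)
sequential_cluster <- function(x, params = plaid_params(), min_frac = 0.05) {
  if (min_frac <= 0 || min_frac >= 1) abort("`min_frac` must be in (0, 1).")
  if (inherits(x, "iema_counts")) {
    Z <- normalized_log_expression(x, samples = tumor_samples(x))
  } else if (is.matrix(x)) {
    Z <- x
  } else {
    abort("`x` must be an `iema_counts` object or a numeric matrix.")
  }
  if (ncol(Z) < 2) abort("Need at least 2 samples to cluster.")
  n_total <- ncol(Z)
  min_size <- ceiling(min_frac * n_total)
  all_samples <- colnames(Z)

  remaining <- Z
  clusters <- list()
  repeat {
    if (ncol(remaining) < max(2, min_size)) break
    layer <- fit_layer(remaining, params)
    if (length(layer$genes) == 0) break
    if (!layer_significance(layer, remaining, params)) break
    if (length(layer$samples) < min_size) break
    clusters[[length(clusters) + 1]] <- list(
      id = paste0("cluster_", length(clusters) + 1),
      samples = layer$samples,
      genes = layer$genes,
      layer_ss = layer$layer_ss
    )
    remaining <- remaining[, setdiff(colnames(remaining), layer$samples), drop = FALSE]
  }

  assigned <- setNames(rep("unclustered", n_total), all_samples)
  for (cl in clusters) assigned[cl$samples] <- cl$id
  structure(
    list(
      clusters = clusters,
      assignment = tibble(sample = all_samples, cluster = unname(assigned)),
      unclustered = all_samples[assigned == "unclustered"],
      n_total = n_total,
      min_frac = min_frac
    ),
    class = "iema_assignment"
  )
}

#' @export
print.iema_assignment <- function(x, ...) {
  cat(sprintf(
    "Sequential plaid clustering: %d cluster(s) over %d samples (%d unclustered)\n",
    length(x$clusters), x$n_total, length(x$unclustered)
  ))
  print(cluster_sizes(x))
  invisible(x)
}

#' Cluster size table under both denominators
#'
#' Reports each cluster's size as a percentage of the clustered patients and
#' of the original cohort (the two denominators differ once samples remain
#' unclustered).
#'
#' @param assignment An `iema_assignment`.
#' @return A tibble: `cluster`, `n_genes`, `n`, `pct_of_clustered`,
#'   `pct_of_total`.
#' @export
cluster_sizes <- function(assignment) {
  stopifnot(inherits(assignment, "iema_assignment"))
  n_clustered <- assignment$n_total - length(assignment$unclustered)
  tibble(
    cluster = map_chr(assignment$clusters, "id"),
    n_genes = map_int(assignment$clusters, ~ length(.x$genes)),
    n = map_int(assignment$clusters, ~ length(.x$samples)),
    pct_of_clustered = round(100 * .data$n / max(n_clustered, 1), 2),
    pct_of_total = round(100 * .data$n / assignment$n_total, 2)
  )
}

#' @export
tidy.iema_assignment <- function(x, ...) {
  x$assignment
}

#' @export
glance.iema_assignment <- function(x, ...) {
  n_clustered <- x$n_total - length(x$unclustered)
  tibble(
    n_clusters = length(x$clusters),
    n_total = x$n_total,
    n_clustered = n_clustered,
    n_unclustered = length(x$unclustered),
    pct_clustered = round(100 * n_clustered / x$n_total, 2),
    min_frac = x$min_frac
  )
}

# Accept either an iema_assignment or a bare sample/cluster data frame.
assignment_table <- function(assignment) {
  if (inherits(assignment, "iema_assignment")) {
    return(assignment$assignment)
  }
  if (is.data.frame(assignment) && all(c("sample", "cluster") %in% names(assignment))) {
    return(as_tibble(assignment[, c("sample", "cluster")]))
  }
  abort("`assignment` must be an `iema_assignment` or a sample/cluster data frame.")
}

#' @export
autoplot.iema_assignment <- function(object, ...) {
  sizes <- cluster_sizes(object)
  ggplot2::ggplot(sizes, ggplot2::aes(
    x = stats::reorder(.data$cluster, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Patients",
      title = "Cluster sizes from sequential plaid clustering",
      subtitle = sprintf(
        "%d of %d samples clustered (%.1f%%)",
        object$n_total - length(object$unclustered), object$n_total,
        100 * (object$n_total - length(object$unclustered)) / object$n_total
      )
    ) +
    ggplot2::theme_minimal()
}
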