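#' Exact test for a 2 x k contingency table
#'
#' Enumerates every 2 x k table with the observed row and column margins,
#' scores each by its multivariate hypergeometric probability, and returns
#' the two-sided p-value under the probability-ordering rule: the sum of the
#' probabilities of all tables at most as probable as the observed one (with
#' relative tolerance 1e-7 on the comparison). At k = 2 this is the
#' classical two-sided Fisher exact test.
#'
#' Categories whose total over both rows is zero are dropped before
#' enumeration.
#'
#' @param row_a,row_b Non-negative integer count vectors of equal length
#'   k >= 2 (e.g. one cluster's per-category counts and the comparison
#'   group's).
#' @return The exact p-value in (0, 1\].
#' @export
#' @examples
#' fisher_exact_2xk(c(5, 0), c(0, 5)) # 2 / choose(10, 5)
fisher_exact_2xk <- function(row_a, row_b) {
  if (length(row_a) != length(row_b) || length(row_a) < 2) {
    abort("`row_a` and `row_b` must have equal length k >= 2.")
  }
  counts <- c(row_a, row_b)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  keep <- (row_a + row_b) > 0
  row_a <- as.integer(row_a[keep])
  row_b <- as.integer(row_b[keep])
  k <- length(row_a)
  if (k < 2) {
    return(1)
  }
  if (sum(row_a) == 0 || sum(row_b) == 0) {
    return(1)
  }
  m <- row_a + row_b # column margins
  n1 <- sum(row_a) # first row margin
  N <- sum(m)

  log_obs <- sum(lchoose(m, row_a)) - lchoose(N, n1)

  # enumerate all first-row vectors a with sum(a) = n1, 0 <= a_j <= m_j,
  # carrying the accumulated log choose term
  log_probs <- enumerate_tables(m, n1) - lchoose(N, n1)
  total <- sum(exp(log_probs))
  p <- sum(exp(log_probs[log_probs <= log_obs + log(1 + 1e-7)]))
  # normalize against accumulated floating error in the enumeration
  min(1, p / total)
}

# Log sum-of-choose terms for every admissible first row; returns a numeric
# vector with one entry per table.
enumerate_tables <- function(m, n1) {
  k <- length(m)
  recurse <- function(j, remaining, acc) {
    if (j == k) {
      if (remaining <= m[k]) {
        return(acc + lchoose(m[k], remaining))
      }
      return(numeric(0))
    }
    lo <- max(0L, remaining - sum(m[(j + 1):k]))
    hi <- min(m[j], remaining)
    if (lo > hi) {
      return(numeric(0))
    }
    out <- vector("list", hi - lo + 1)
    for (a in lo:hi) {
      out[[a - lo + 1]] <- recurse(j + 1, remaining - a, acc + lchoose(m[j], a))
    }
    unlist(out)
  }
  recurse(1, n1, 0)
}

#' Cluster-versus-cohort clinical association tests
#'
#' For each cluster, builds the per-category counts of a categorical clinical
#' variable and tests them against the comparison row with
#' [fisher_exact_2xk()]. The default comparison row is the column total over
#' ALL clustered samples (the cluster included) — the construction that
#' compares a cluster's category distribution to the overall pattern;
#' `rest = "others"` instead compares against the other clustered samples
#' only. Samples with missing values are excluded and counted; categories
#' with zero total are dropped and recorded.
#'
#' @param assignment An `iema_assignment` from [sequential_cluster()] or a
#'   data frame with `sample` and `cluster` columns (unclustered samples
#'   labelled `"unclustered"` are ignored).
#' @param clinical Data frame with a `sample` column and the variable.
#' @param variable Name of the categorical clinical column.
#' @param rest `"total"` (default) or `"others"`.
#' @param alpha Significance level for flagging (default 0.05).
#' @return A tibble of class `iema_assoc`, one row per cluster: `cluster`,
#'   `variable`, `n`, `p`, `significant`, plus list columns `categories`,
#'   `cluster_counts`, `rest_counts`, and `n_missing`, `dropped`.
#' @export
associate_clusters <- function(assignment, clinical, variable,
                               rest = c("total", "others"), alpha = 0.05) {
  rest <- match.arg(rest)
  members <- assignment_table(assignment)
  members <- dplyr::filter(members, .data$cluster != "unclustered")
  if (!variable %in% names(clinical)) {
    abort(sprintf("Clinical table has no column '%s'.", variable))
  }
  df <- dplyr::left_join(members, clinical[, c("sample", variable)], by = "sample")
  vals <- df[[variable]]
  missing_mask <- is.na(vals) | (is.character(vals) & !nzchar(vals))
  n_missing_total <- sum(missing_mask)
  df <- df[!missing_mask, ]
  vals <- df[[variable]]
  cats <- if (is.factor(vals)) levels(vals) else sort(unique(as.character(vals)))
  tab <- table(factor(df$cluster), factor(as.character(vals), levels = cats))
  col_tot <- colSums(tab)
  dropped <- cats[col_tot == 0]
  keep <- cats[col_tot > 0]
  tab <- tab[, keep, drop = FALSE]
  col_tot <- col_tot[keep]

  clusters <- rownames(tab)
  if (rest == "others" && length(clusters) == 1) {
    abort("A single cluster holds all samples; there is no rest group.")
  }
  rows <- map(clusters, function(cl) {
    a <- as.integer(tab[cl, ])
    b <- if (rest == "total") as.integer(col_tot) else as.integer(col_tot - tab[cl, ])
    if (sum(b) == 0) abort(sprintf("Cluster '%s' contains all samples; empty rest.", cl))
    p <- fisher_exact_2xk(a, b)
    tibble(
      cluster = cl, variable = variable, n = sum(a),
      p = p, significant = p <= alpha,
      categories = list(keep),
      cluster_counts = list(setNames(a, keep)),
      rest_counts = list(setNames(b, keep)),
      n_missing = n_missing_total,
      dropped = list(dropped)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iema_assoc", class(out))
  out
}

#' @export
tidy.iema_assoc <- function(x, ...) {
  rows <- map(seq_len(nrow(x)), function(i) {
    cats <- x$categories[[i]]
    tibble(
      cluster = x$cluster[i],
      variable = x$variable[i],
      category = cats,
      cluster_count = as.integer(x$cluster_counts[[i]]),
      rest_count = as.integer(x$rest_counts[[i]]),
      pct_of_cluster = round(100 * as.integer(x$cluster_counts[[i]]) / x$n[i], 2),
      p = x$p[i],
      significant = x$significant[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
autoplot.iema_assoc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cluster, y = .data$pct_of_cluster, fill = .data$category
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "% of cluster",
      title = sprintf("Cluster composition by %s", df$variable[1])
    ) +
    ggplot2::theme_minimal()
}
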