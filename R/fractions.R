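#' The 22 LM22 immune cell types
#'
#' Column names of the LM22 leukocyte signature used by CIBERSORT-style
#' deconvolution output. Fraction tables consumed by this package use exactly
#' these columns.
#'
#' @return Character vector of length 22.
#' @export
lm22_cell_types <- function() {
  c(
    "B cells naive", "B cells memory", "Plasma cells",
    "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated",
    "Monocytes", "Macrophages M0", "Macrophages M1", "Macrophages M2",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated",
    "Eosinophils", "Neutrophils"
  )
}

#' Lymphocyte columns used for the aggregate lymphocyte fraction
#'
#' B cells, T cells and NK cells; plasma cells are excluded by default (they
#' are listed separately from B cells in LM22 and the lymphocyte aggregate is
#' defined over B, T and NK populations).
#'
#' @param include_plasma Also count the `Plasma cells` column.
#' @return Character vector of LM22 column names.
#' @export
lymphocyte_cell_types <- function(include_plasma = FALSE) {
  base <- c(
    "B cells naive", "B cells memory",
    "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated"
  )
  if (include_plasma) c(base[1:2], "Plasma cells", base[-(1:2)]) else base
}

check_fraction_table <- function(fractions) {
  if (!is.data.frame(fractions) || !"sample" %in% names(fractions)) {
    abort("`fractions` must be a data frame with a `sample` column.")
  }
  missing <- setdiff(lm22_cell_types(), names(fractions))
  if (length(missing) > 0) {
    abort(sprintf(
      "Fraction table is missing LM22 column(s): %s%s.",
      paste(utils::head(missing, 4), collapse = ", "),
      if (length(missing) > 4) ", ..." else ""
    ))
  }
  vals <- as.matrix(fractions[, lm22_cell_types()])
  if (any(vals < 0)) abort("Fractions must be non-negative.")
  sums <- rowSums(vals)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("Each fraction row must sum to 1 (tolerance 1e-6).")
  }
  invisible(fractions)
}

#' Total lymphocyte fraction per sample
#'
#' Sums the designated lymphocyte columns (B, T and NK populations) of a
#' CIBERSORT-style fraction table.
#'
#' @param fractions Data frame with a `sample` column and the 22 LM22 columns.
#' @param include_plasma Count plasma cells as lymphocytes (default `FALSE`).
#' @return A tibble with columns `sample` and `lymphocytes` (fraction in
#'   \[0, 1\]).
#' @export
total_lymphocytes <- function(fractions, include_plasma = FALSE) {
  check_fraction_table(fractions)
  cols <- lymphocyte_cell_types(include_plasma)
  tibble(
    sample = fractions$sample,
    lymphocytes = rowSums(as.matrix(fractions[, cols]))
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare one cell type's abundance between two groups
#'
#' Welch two-sample t-test on the fractions of a single cell type, with
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param group_a,group_b Numeric vectors of fractions (e.g. a cluster's
#'   samples and the normal samples). Both need at least 2 values and positive
#'   variance.
#' @return A one-row tibble: `t`, `p`, `stars`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
compare_cell_abundance <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    abort("Both groups have zero variance; the t-test is undefined.")
  }
  tt <- t.test(group_a, group_b)
  tibble(
    t = unname(tt$statistic),
    p = tt$p.value,
    stars = significance_stars(tt$p.value),
    mean_a = mean(group_a),
    mean_b = mean(group_b),
    n_a = length(group_a),
    n_b = length(group_b)
  )
}

#' Per-cluster immune composition summary
#'
#' For every cluster and cell type (the 22 LM22 columns plus the aggregate
#' `lymphocytes`), summarises mean, sd and n, and tests the cluster against
#' the reference samples with a Welch t-test. Mirrors the layout behind
#' violin-plot figures: one row per (cluster, cell type).
#'
#' @param fractions Fraction table (`sample` + LM22 columns).
#' @param assignment An `iema_assignment` from [sequential_cluster()], or a
#'   data frame with columns `sample` and `cluster`.
#' @param reference Sample ids of the reference group (e.g. adjacent normals).
#' @param include_plasma Passed to [total_lymphocytes()].
#' @return A tibble: `cluster`, `cell_type`, `mean`, `sd`, `n`, `t`, `p`,
#'   `stars`.
#' @export
summarize_composition <- function(fractions, assignment, reference,
                                  include_plasma = FALSE) {
  check_fraction_table(fractions)
  members <- assignment_table(assignment)
  members <- dplyr::filter(members, .data$cluster != "unclustered")
  lymph <- total_lymphocytes(fractions, include_plasma)
  aug <- dplyr::left_join(fractions, lymph, by = "sample")
  cell_cols <- c(lm22_cell_types(), "lymphocytes")
  ref_rows <- dplyr::filter(aug, .data$sample %in% reference)
  if (nrow(ref_rows) < 2) abort("Need at least 2 reference samples.")
  out <- list()
  for (cl in unique(members$cluster)) {
    ids <- members$sample[members$cluster == cl]
    rows <- dplyr::filter(aug, .data$sample %in% ids)
    if (nrow(rows) < 2) next
    for (cell in cell_cols) {
      a <- rows[[cell]]
      b <- ref_rows[[cell]]
      res <- if (var(a) == 0 && var(b) == 0) {
        tibble(t = NA_real_, p = NA_real_, stars = "")
      } else {
        compare_cell_abundance(a, b)[, c("t", "p", "stars")]
      }
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble(cluster = cl, cell_type = cell, mean = mean(a), sd = sd(a), n = length(a)),
        res
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Read a CIBERSORT-style fraction CSV
#'
#' First column is the sample id (any name); the 22 LM22 columns are required;
#' trailing statistic columns (`P-value`, `Correlation`, `RMSE`) are ignored.
#'
#' @param path CSV path.
#' @return A tibble with `sample` plus the 22 LM22 columns.
#' @export
read_fractions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample"
  df <- df[, c("sample", intersect(lm22_cell_types(), names(df)))]
  check_fraction_table(df)
  df
}

#' @rdname read_fractions
#' @param fractions Fraction table to write.
#' @export
write_fractions <- function(fractions, path) {
  check_fraction_table(fractions)
  readr::write_csv(fractions[, c("sample", lm22_cell_types())], path, progress = FALSE)
  invisible(path)
}
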