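#' Construct a gene-by-sample count container
#'
#' Bundles a non-negative integer expression matrix (genes in rows, samples in
#' columns) with a per-sample role label, `"tumor"` or `"normal"`. All
#' downstream stages (biclustering, differential expression, the pipeline)
#' consume this container.
#'
#' @param counts Numeric matrix of non-negative integers with gene symbols as
#'   row names and sample ids as column names.
#' @param roles Character vector of `"tumor"`/`"normal"`, one per sample,
#'   either named by sample id or in column order.
#' @return An object of class `iema_counts`: the matrix with a `roles`
#'   attribute.
#' @export
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:5))
#' )
#' cc <- cohort_counts(m, c("tumor", "tumor", "tumor", "normal", "normal"))
#' table(sample_roles(cc))
cohort_counts <- function(counts, roles) {
  check_count_matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene symbols as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Duplicate sample ids in `counts`.")
  }
  if (!is.null(names(roles))) {
    missing <- setdiff(colnames(counts), names(roles))
    if (length(missing) > 0) {
      abort(sprintf("No role given for samples: %s.", paste(utils::head(missing, 5), collapse = ", ")))
    }
    roles <- roles[colnames(counts)]
  }
  if (length(roles) != ncol(counts)) {
    abort("`roles` must have one entry per sample.")
  }
  roles <- as.character(roles)
  if (!all(roles %in% c("tumor", "normal"))) {
    abort("Roles must be 'tumor' or 'normal'.")
  }
  storage.mode(counts) <- "integer"
  structure(counts, roles = setNames(roles, colnames(counts)), class = c("iema_counts", "matrix"))
}

#' @rdname cohort_counts
#' @param x An `iema_counts` object.
#' @export
sample_roles <- function(x) {
  attr(x, "roles")
}

#' @rdname cohort_counts
#' @export
tumor_samples <- function(x) {
  names(sample_roles(x))[sample_roles(x) == "tumor"]
}

#' @rdname cohort_counts
#' @export
normal_samples <- function(x) {
  names(sample_roles(x))[sample_roles(x) == "normal"]
}

#' @export
print.iema_counts <- function(x, ...) {
  cat(sprintf(
    "Immune-gene count matrix: %d genes x %d samples (%d tumor, %d normal)\n",
    nrow(x), ncol(x), length(tumor_samples(x)), length(normal_samples(x))
  ))
  invisible(x)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and whose
#' header row holds sample ids. Sample roles come either from a two-column
#' sidecar TSV (`sample`, `role`) or from a `normal_prefix` naming convention
#' on the sample ids. Duplicate gene symbols are collapsed by summation with a
#' warning; if `gene_list` is given the matrix is restricted to those symbols
#' and missing ones are reported.
#'
#' @param path Path to the counts TSV.
#' @param gene_list Optional character vector of gene symbols, or path to a
#'   one-symbol-per-line text file, to restrict the matrix to.
#' @param roles Optional named character vector or path to a sidecar TSV with
#'   columns `sample` and `role`.
#' @param normal_prefix Prefix identifying normal samples when no `roles` are
#'   given (default `"normal"`).
#' @return An [cohort_counts()] object.
#' @export
read_counts <- function(path, gene_list = NULL, roles = NULL, normal_prefix = "normal") {
  df <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    name_repair = "minimal"
  )
  if (ncol(df) < 2) {
    abort("Counts file needs a gene column plus at least one sample column.")
  }
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    abort("Counts file contains non-numeric entries.")
  }
  if (anyDuplicated(colnames(mat))) {
    abort("Duplicate sample ids in counts file header.")
  }
  if (any(mat != round(mat), na.rm = TRUE)) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-integer count at gene '%s', sample '%s'.",
      genes[bad[1]], colnames(mat)[bad[2]]
    ))
  }
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Negative count at gene '%s', sample '%s'.",
      genes[bad[1]], colnames(mat)[bad[2]]
    ))
  }
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn(sprintf(
      "%d duplicate gene symbol(s) collapsed by sum: %s%s",
      length(dup), paste(utils::head(dup, 5), collapse = ", "),
      if (length(dup) > 5) ", ..." else ""
    ))
    mat <- rowsum(mat, group = genes)
  }
  if (!is.null(gene_list)) {
    if (is.character(gene_list) && length(gene_list) == 1 && file.exists(gene_list)) {
      gene_list <- readr::read_lines(gene_list)
      gene_list <- gene_list[nzchar(trimws(gene_list))]
    }
    present <- intersect(gene_list, rownames(mat))
    if (length(present) == 0) {
      abort("No genes in the counts file match the provided gene list.")
    }
    missing <- setdiff(gene_list, rownames(mat))
    if (length(missing) > 0) {
      warn(sprintf(
        "%d gene(s) from the list absent from the counts file: %s%s",
        length(missing), paste(utils::head(missing, 5), collapse = ", "),
        if (length(missing) > 5) ", ..." else ""
      ))
    }
    mat <- mat[present, , drop = FALSE]
  }
  if (is.null(roles)) {
    role_vec <- ifelse(startsWith(colnames(mat), normal_prefix), "normal", "tumor")
  } else if (is.character(roles) && length(roles) == 1 && file.exists(roles)) {
    rdf <- readr::read_tsv(roles, show_col_types = FALSE, progress = FALSE)
    role_vec <- setNames(as.character(rdf$role), rdf$sample)
  } else {
    role_vec <- roles
  }
  cohort_counts(mat, role_vec)
}

#' Write a count container to TSV
#'
#' Writes the matrix as genes x samples TSV (first column `gene`) plus an
#' optional sidecar TSV of sample roles.
#'
#' @param x An `iema_counts` object.
#' @param path Output TSV path.
#' @param roles_path Optional path for the `sample`/`role` sidecar.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, roles_path = NULL) {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(gene = rownames(x)), df)
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(roles_path)) {
    readr::write_tsv(
      tibble(sample = colnames(x), role = unname(sample_roles(x))),
      roles_path,
      progress = FALSE
    )
  }
  invisible(path)
}
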