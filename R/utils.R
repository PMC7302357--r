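#' Run code with a locally scoped RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' perturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' computed from the pair-counting contingency table.
#'
#' @param a,b Vectors of cluster labels (any type coercible to factor), equal
#'   length.
#' @return A number in \[-1, 1\]; 1 is identical partitions, 0 is the
#'   chance expectation.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# Shared input checks ---------------------------------------------------------

check_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort(sprintf("`%s` must be a numeric gene-by-sample matrix.", arg))
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg))
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` has a negative count at gene '%s', sample '%s'.", arg,
      rownames(counts)[bad[1]] %||% bad[1], colnames(counts)[bad[2]] %||% bad[2]
    ))
  }
  if (any(counts != round(counts))) {
    abort(sprintf("`%s` must contain integer counts.", arg))
  }
  invisible(counts)
}

check_prob <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", arg))
  }
  invisible(x)
}
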