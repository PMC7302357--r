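#' Parameters for plaid-model biclustering
#'
#' @param max_layers Cap on the number of fitted layers.
#' @param backfit_iters Backfitting sweeps per layer: each sweep runs the
#'   inner effect/membership updates and then prunes weak members.
#' @param inner_iters Effect/membership update iterations per sweep.
#' @param n_shuffles Row-wise permutations for the layer retention test.
#' @param row_release,col_release Pruning thresholds in \[0, 1\]: a member
#'   whose sum-of-squares contribution falls below this fraction of the mean
#'   member contribution is released.
#' @param seed Integer seed (drives the permutation test; the fit itself is
#'   deterministic).
#' @return A list of class `iema_plaid_params`.
#' @export
plaid_params <- function(max_layers = 10, backfit_iters = 3, inner_iters = 10,
                         n_shuffles = 3, row_release = 0.7, col_release = 0.7,
                         seed = 1L) {
  stopifnot(
    max_layers >= 1, backfit_iters >= 1, inner_iters >= 1, n_shuffles >= 1,
    row_release >= 0, row_release <= 1, col_release >= 0, col_release <= 1
  )
  structure(
    list(
      max_layers = as.integer(max_layers),
      backfit_iters = as.integer(backfit_iters),
      inner_iters = as.integer(inner_iters),
      n_shuffles = as.integer(n_shuffles),
      row_release = row_release, col_release = col_release,
      seed = as.integer(seed)
    ),
    class = "iema_plaid_params"
  )
}

#' Normalized, log-transformed, gene-centered expression
#'
#' The plaid input transform: per-sample median-of-ratios normalization,
#' `log2(x + 1)`, then gene-wise centering so layers model departures from
#' each gene's cohort mean.
#'
#' @param counts An [cohort_counts()] object or numeric count matrix.
#' @param samples Optional sample ids to restrict to (e.g. tumors only).
#' @param center Subtract each gene's row mean (default `TRUE`).
#' @return A numeric matrix, genes x samples.
#' @export
normalized_log_expression <- function(counts, samples = NULL, center = TRUE) {
  m <- unclass(counts)
  attr(m, "roles") <- NULL
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  sf <- tryCatch(estimate_size_factors(m), error = function(e) {
    rep(1, ncol(m))
  })
  norm <- sweep(m, 2, sf, "/")
  z <- log2(norm + 1)
  if (center) z <- z - rowMeans(z)
  z
}

empty_layer <- function() {
  structure(
    list(
      genes = character(0), samples = character(0),
      mu = 0, alpha = numeric(0), beta = numeric(0), layer_ss = 0
    ),
    class = "iema_layer"
  )
}

layer_theta <- function(layer) {
  outer(layer$alpha, layer$beta, `+`) + layer$mu
}

# Sum-of-squares reduction each row would contribute as a member, with its
# own least-squares row effect and the layer's current column effects.
# Positive means inclusion lowers the residual SS.
row_deltas <- function(Z, mu, beta, cols) {
  sub <- Z[, cols, drop = FALSE]
  alpha_all <- rowMeans(sub) - mu
  theta <- outer(alpha_all, beta, `+`) + mu
  list(delta = rowSums(2 * sub * theta - theta^2), alpha = alpha_all)
}

#' Fit one plaid layer to a residual matrix
#'
#' A layer is a gene set, a sample set and additive effects
#' `theta_ij = mu + alpha_i + beta_j` (row and column effects summing to zero
#' over members). Memberships are seeded from the top-quartile loadings of
#' the residual's leading singular vectors, then refined by alternating
#' least-squares effect estimates with inclusion updates (a gene or sample is
#' a member iff including it strictly reduces the residual sum of squares;
#' an exactly-zero change excludes). After each sweep's inner iterations,
#' members contributing less than the release fraction of the mean member
#' contribution are pruned. Layers that fall below 2 genes or 2 samples
#' collapse to the empty layer.
#'
#' @param Z Numeric residual matrix (genes x samples), finite entries, at
#'   least 2 x 2.
#' @param params A [plaid_params()].
#' @return A list of class `iema_layer`: `genes`, `samples`, `mu`, `alpha`,
#'   `beta` (named by member), `layer_ss` (sum of squared fitted effects over
#'   member cells).
#' @export
fit_layer <- function(Z, params = plaid_params()) {
  if (!is.matrix(Z) || nrow(Z) < 2 || ncol(Z) < 2) {
    abort("`Z` must be a matrix with at least 2 rows and 2 columns.")
  }
  if (anyNA(Z) || any(!is.finite(Z))) abort("`Z` has non-finite entries.")
  if (is.null(rownames(Z))) rownames(Z) <- paste0("g", seq_len(nrow(Z)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("s", seq_len(ncol(Z)))
  if (all(Z == 0)) {
    return(empty_layer())
  }

  sv <- svd(Z, nu = 1, nv = 1)
  u <- sv$u[, 1]
  v <- sv$v[, 1]
  # both orientations give a candidate high-mean block; keep the stronger
  init_for <- function(u, v) {
    rows <- which(u >= stats::quantile(u, 0.75))
    cols <- which(v >= stats::quantile(v, 0.75))
    list(rows = rows, cols = cols, score = sum(Z[rows, cols, drop = FALSE])^2)
  }
  cand <- list(init_for(u, v), init_for(-u, -v))
  best <- cand[[which.max(c(cand[[1]]$score, cand[[2]]$score))]]
  rows <- best$rows
  cols <- best$cols

  refit_effects <- function(rows, cols) {
    sub <- Z[rows, cols, drop = FALSE]
    mu <- mean(sub)
    list(
      mu = mu,
      alpha = rowMeans(sub) - mu,
      beta = colMeans(sub) - mu
    )
  }

  for (sweep in seq_len(params$backfit_iters)) {
    for (iter in seq_len(params$inner_iters)) {
      if (length(rows) < 2 || length(cols) < 2) {
        return(empty_layer())
      }
      # simultaneous membership update: both margins are scored against the
      # effects estimated from the pre-update memberships
      eff <- refit_effects(rows, cols)
      rd <- row_deltas(Z, eff$mu, eff$beta, cols)
      cd <- row_deltas(t(Z), eff$mu, eff$alpha, rows)
      new_rows <- which(rd$delta > 0)
      new_cols <- which(cd$delta > 0)
      if (length(new_rows) < 2 || length(new_cols) < 2) {
        return(empty_layer())
      }
      converged <- identical(new_rows, rows) && identical(new_cols, cols)
      rows <- new_rows
      cols <- new_cols
      if (converged) break
    }
    # release members that contribute little to the layer fit
    eff <- refit_effects(rows, cols)
    rd <- row_deltas(Z, eff$mu, eff$beta, cols)
    rc <- rd$delta[rows]
    rows <- rows[rc >= params$row_release * mean(rc)]
    if (length(rows) < 2) {
      return(empty_layer())
    }
    eff <- refit_effects(rows, cols)
    cd <- row_deltas(t(Z), eff$mu, eff$alpha, rows)
    cc <- cd$delta[cols]
    cols <- cols[cc >= params$col_release * mean(cc)]
    if (length(cols) < 2) {
      return(empty_layer())
    }
  }

  eff <- refit_effects(rows, cols)
  theta <- outer(eff$alpha, eff$beta, `+`) + eff$mu
  structure(
    list(
      genes = rownames(Z)[rows],
      samples = colnames(Z)[cols],
      mu = eff$mu,
      alpha = setNames(eff$alpha, rownames(Z)[rows]),
      beta = setNames(eff$beta, colnames(Z)[cols]),
      layer_ss = sum(theta^2)
    ),
    class = "iema_layer"
  )
}

#' @export
print.iema_layer <- function(x, ...) {
  if (length(x$genes) == 0) {
    cat("Empty plaid layer\n")
  } else {
    cat(sprintf(
      "Plaid layer: %d genes x %d samples, mu = %.3f, layer SS = %.1f\n",
      length(x$genes), length(x$samples), x$mu, x$layer_ss
    ))
  }
  invisible(x)
}

#' Permutation retention test for a fitted layer
#'
#' Refits a layer on `n_shuffles` independent row-wise permutations of the
#' matrix (each row's entries shuffled independently, seeded) and retains the
#' observed layer iff its sum of squares strictly exceeds the maximum
#' permuted layer sum of squares.
#'
#' @param layer An `iema_layer` fitted on `Z`.
#' @param Z The matrix the layer was fitted on.
#' @param params A [plaid_params()] (supplies `n_shuffles` and `seed`).
#' @return `TRUE` if the layer is retained.
#' @export
layer_significance <- function(layer, Z, params = plaid_params()) {
  if (params$n_shuffles < 1) abort("`n_shuffles` must be at least 1.")
  if (length(layer$genes) == 0 || layer$layer_ss <= 0) {
    return(FALSE)
  }
  perm_ss <- map_dbl(seq_len(params$n_shuffles), function(s) {
    Zp <- with_seed(params$seed + s, {
      t(apply(Z, 1, sample))
    })
    colnames(Zp) <- colnames(Z)
    fit_layer(Zp, params)$layer_ss
  })
  layer$layer_ss > max(perm_ss)
}

#' Fit a sequence of retained plaid layers
#'
#' Repeatedly fits a layer on the running residual (the matrix minus all
#' retained layers' fitted values), applies the permutation retention test,
#' subtracts the layer, and stops at `max_layers` or the first rejection.
#'
#' @inheritParams layer_significance
#' @return A list of class `iema_plaid`: `layers` (retained `iema_layer`s in
#'   fit order) and `residual` (final residual matrix).
#' @export
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(400, sd = 0.5), 20, 20)
#' Z[1:5, 1:5] <- Z[1:5, 1:5] + 5
#' fit <- fit_plaid(Z, plaid_params(n_shuffles = 2))
#' length(fit$layers)
fit_plaid <- function(Z, params = plaid_params()) {
  if (is.null(rownames(Z))) rownames(Z) <- paste0("g", seq_len(nrow(Z)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("s", seq_len(ncol(Z)))
  residual <- Z
  layers <- list()
  for (l in seq_len(params$max_layers)) {
    layer <- fit_layer(residual, params)
    if (length(layer$genes) == 0) break
    if (!layer_significance(layer, residual, params)) break
    ridx <- match(layer$genes, rownames(residual))
    cidx <- match(layer$samples, colnames(residual))
    residual[ridx, cidx] <- residual[ridx, cidx] - layer_theta(layer)
    layers[[length(layers) + 1]] <- layer
  }
  structure(list(layers = layers, residual = residual), class = "iema_plaid")
}

#' @export
print.iema_plaid <- function(x, ...) {
  cat(sprintf("Plaid fit: %d retained layer(s)\n", length(x$layers)))
  for (l in x$layers) print(l)
  invisible(x)
}

#' @export
tidy.iema_plaid <- function(x, ...) {
  if (length(x$layers) == 0) {
    return(tibble(
      layer = integer(0), n_genes = integer(0), n_samples = integer(0),
      mu = numeric(0), layer_ss = numeric(0)
    ))
  }
  tibble(
    layer = seq_along(x$layers),
    n_genes = map_int(x$layers, ~ length(.x$genes)),
    n_samples = map_int(x$layers, ~ length(.x$samples)),
    mu = map_dbl(x$layers, "mu"),
    layer_ss = map_dbl(x$layers, "layer_ss")
  )
}
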