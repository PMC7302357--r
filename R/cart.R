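#' Fit a classification tree predicting cluster membership
#'
#' Greedy binary recursive partitioning with the Gini impurity criterion.
#' Candidate thresholds are midpoints between consecutive sorted distinct
#' values of each gene; a sample routes left when its value is below the
#' threshold and right at-or-above. Splitting stops at node purity,
#' `min_leaf`, `max_depth`, or when the best sample-weighted impurity
#' decrease falls below `complexity`. At the default `complexity = 0` a
#' zero-decrease split is still accepted, so parity-style interactions
#' (where no single split improves impurity on its own) are resolved one
#' level deeper. Ties between equally good splits
#' break to the smallest gene index, then the smallest threshold, which
#' makes the fit invariant to sample order.
#'
#' @param expr Numeric matrix, samples x genes, with gene column names and
#'   no missing values.
#' @param labels Class label per sample (cluster ids).
#' @param min_leaf Minimum samples in a leaf (default 5).
#' @param max_depth Maximum tree depth, root = 0 (default 6).
#' @param complexity Minimum sample-weighted Gini decrease to accept a split
#'   (default 0).
#' @return An object of class `iema_tree`: `root` (nested node list),
#'   `classes`, `genes`, `params`, `n`.
#' @export
#' @examples
#' expr <- matrix(c(rep(10, 5), rep(100, 5)), ncol = 1,
#'   dimnames = list(NULL, "CD48")
#' )
#' tree <- fit_cart(expr, rep(c("a", "b"), each = 5), min_leaf = 1)
#' extract_biomarkers(tree)
fit_cart <- function(expr, labels, min_leaf = 5, max_depth = 6, complexity = 0) {
  if (!is.matrix(expr) || nrow(expr) == 0) {
    abort("`expr` must be a non-empty samples x genes matrix.")
  }
  if (anyNA(expr)) abort("`expr` must not contain missing values.")
  if (is.null(colnames(expr))) abort("`expr` needs gene column names.")
  if (length(labels) != nrow(expr)) {
    abort("`labels` must have one entry per sample (row of `expr`).")
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  n_class <- length(classes)

  gini <- function(counts) {
    n <- sum(counts)
    if (n == 0) {
      return(0)
    }
    1 - sum((counts / n)^2)
  }

  best_split <- function(idx) {
    counts <- tabulate(y[idx], n_class)
    n <- length(idx)
    parent <- gini(counts)
    best <- NULL
    for (g in seq_len(ncol(expr))) {
      v <- expr[idx, g]
      ord <- order(v)
      sv <- v[ord]
      sy <- y[idx][ord]
      distinct <- which(diff(sv) > 0)
      if (length(distinct) == 0) next
      left <- numeric(n_class)
      pos <- 1
      for (cut in distinct) {
        while (pos <= cut) {
          left[sy[pos]] <- left[sy[pos]] + 1
          pos <- pos + 1
        }
        nl <- cut
        nr <- n - cut
        if (nl < min_leaf || nr < min_leaf) next
        right <- counts - left
        dec <- parent - (nl * gini(left) + nr * gini(right)) / n
        thr <- (sv[cut] + sv[cut + 1]) / 2
        if (is.null(best) ||
          dec > best$dec + 1e-12 ||
          (abs(dec - best$dec) <= 1e-12 && (g < best$gene_idx ||
            (g == best$gene_idx && thr < best$threshold)))) {
          best <- list(gene_idx = g, threshold = thr, dec = dec)
        }
      }
    }
    best
  }

  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], n_class)
    node_label <- classes[which.max(counts)]
    leaf <- list(
      leaf = TRUE, label = node_label,
      counts = setNames(as.integer(counts), classes), n = length(idx)
    )
    if (length(unique(y[idx])) == 1 || depth >= max_depth ||
      length(idx) < 2 * min_leaf) {
      return(leaf)
    }
    sp <- best_split(idx)
    if (is.null(sp) || sp$dec < complexity) {
      return(leaf)
    }
    go_left <- expr[idx, sp$gene_idx] < sp$threshold
    list(
      leaf = FALSE,
      gene = colnames(expr)[sp$gene_idx],
      threshold = sp$threshold,
      decrease = sp$dec,
      counts = setNames(as.integer(counts), classes),
      n = length(idx),
      left = grow(idx[go_left], depth + 1),
      right = grow(idx[!go_left], depth + 1)
    )
  }

  structure(
    list(
      root = grow(seq_len(nrow(expr)), 0),
      classes = classes,
      genes = colnames(expr),
      params = list(min_leaf = min_leaf, max_depth = max_depth, complexity = complexity),
      n = nrow(expr)
    ),
    class = "iema_tree"
  )
}

#' Predict cluster labels from a fitted tree
#'
#' Routes each sample down the tree: below the threshold goes left,
#' at-or-above goes right.
#'
#' @param object An `iema_tree`.
#' @param newdata Numeric matrix (samples x genes) or named numeric vector
#'   for one sample; must provide every split gene.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.iema_tree <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  }
  needed <- extract_biomarkers(object)
  missing <- setdiff(needed, colnames(newdata))
  if (length(missing) > 0) {
    abort(sprintf("`newdata` lacks split gene(s): %s.", paste(missing, collapse = ", ")))
  }
  route <- function(node, x) {
    if (node$leaf) {
      return(node$label)
    }
    if (x[node$gene] < node$threshold) route(node$left, x) else route(node$right, x)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    route(object$root, newdata[i, ])
  }, character(1))
}

#' Distinct split genes in breadth-first order
#'
#' The tree's predictive biomarkers: the genes appearing at internal nodes,
#' deduplicated, in breadth-first node order.
#'
#' @param tree An `iema_tree`.
#' @return Character vector (empty for a single-leaf tree).
#' @export
extract_biomarkers <- function(tree) {
  stopifnot(inherits(tree, "iema_tree"))
  genes <- character(0)
  queue <- list(tree$root)
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    if (!node$leaf) {
      genes <- c(genes, node$gene)
      queue <- c(queue, list(node$left), list(node$right))
    }
  }
  unique(genes)
}

tree_nodes <- function(node, depth = 0, path = "root") {
  if (node$leaf) {
    return(tibble(
      path = path, depth = depth, leaf = TRUE,
      gene = NA_character_, threshold = NA_real_,
      label = node$label, n = node$n
    ))
  }
  dplyr::bind_rows(
    tibble(
      path = path, depth = depth, leaf = FALSE,
      gene = node$gene, threshold = node$threshold,
      label = NA_character_, n = node$n
    ),
    tree_nodes(node$left, depth + 1, paste0(path, ".L")),
    tree_nodes(node$right, depth + 1, paste0(path, ".R"))
  )
}

#' @export
tidy.iema_tree <- function(x, ...) {
  tree_nodes(x$root)
}

#' @export
glance.iema_tree <- function(x, ...) {
  nodes <- tree_nodes(x$root)
  tibble(
    n = x$n,
    n_classes = length(x$classes),
    n_leaves = sum(nodes$leaf),
    n_splits = sum(!nodes$leaf),
    depth = max(nodes$depth),
    n_biomarkers = length(extract_biomarkers(x))
  )
}

#' @export
print.iema_tree <- function(x, ...) {
  cat(sprintf(
    "Classification tree: %d samples, %d classes, %d split(s) on %d gene(s)\n",
    x$n, length(x$classes), sum(!tidy(x)$leaf), length(extract_biomarkers(x))
  ))
  render <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s-> %s (n=%d)\n", pad, node$label, node$n))
    } else {
      cat(sprintf("%s%s < %.4g ?\n", pad, node$gene, node$threshold))
      render(node$left, indent + 1)
      render(node$right, indent + 1)
    }
  }
  render(x$root, 0)
  invisible(x)
}

#' Resubstitution (or held-out) accuracy of a tree
#'
#' @param tree An `iema_tree`.
#' @param expr Samples x genes matrix.
#' @param labels True labels.
#' @return Fraction correctly classified.
#' @export
tree_accuracy <- function(tree, expr, labels) {
  mean(predict(tree, expr) == as.character(labels))
}

#' Serialize a tree to JSON
#'
#' @param tree An `iema_tree`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(
    list(
      classes = tree$classes, n = tree$n, params = tree$params,
      biomarkers = extract_biomarkers(tree), root = tree$root
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
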