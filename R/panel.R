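#' Cancer-immunity-cycle gene panel
#'
#' The panel maps each step of the cancer-immunity cycle (antigen release,
#' antigen presentation, T-cell priming/activation, trafficking, infiltration,
#' recognition, killing) to a gene set, and additionally lists checkpoint
#' genes (tolerance mechanisms: CTLA4, PD-1, PD-L1/2, TGF-beta), decoy
#' receptors (counterattack mechanisms: DcR3 = TNFRSF6B, TRAILR4 = TNFRSF10D)
#' and cytotoxic effector genes. The panel is data, not code: the default
#' ships as an editable JSON resource and any file in the same layout can be
#' supplied to [annotate_cluster()].
#'
#' @param path Path to a panel JSON file. Defaults to the panel bundled with
#'   the package.
#' @return An object of class `iema_panel`: a list with elements `steps`
#'   (named list of character vectors), `checkpoint_genes`, `decoy_genes`
#'   (named lists keyed by mechanism tag) and `effector_genes`.
#' @export
#' @examples
#' panel <- cancer_immunity_panel()
#' names(panel$steps)
cancer_immunity_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cancer_immunity_panel.json",
    package = "iema", mustWork = TRUE
  )
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel <- list(
    steps = lapply(raw$steps, as.character),
    checkpoint_genes = lapply(raw$checkpoint_genes, as.character),
    decoy_genes = lapply(raw$decoy_genes, as.character),
    effector_genes = as.character(raw$effector_genes)
  )
  required <- c(
    "antigen_release", "antigen_presentation", "priming_activation",
    "trafficking", "infiltration", "recognition", "killing"
  )
  missing <- setdiff(required, names(panel$steps))
  if (length(missing) > 0) {
    abort(sprintf(
      "Panel is missing required cycle steps: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(lengths(panel$steps) == 0)) {
    abort("Every cycle step must have at least one gene.")
  }
  tags <- c(names(panel$checkpoint_genes), names(panel$decoy_genes))
  if (anyDuplicated(tags)) {
    abort("Mechanism tags must be unique across checkpoint and decoy sets.")
  }
  structure(panel, class = "iema_panel")
}

#' @export
print.iema_panel <- function(x, ...) {
  cat("Cancer-immunity-cycle panel\n")
  cat(sprintf(
    "  %d cycle steps (%d genes), %d checkpoint mechanisms, %d decoy mechanisms\n",
    length(x$steps), length(unique(unlist(x$steps))),
    length(x$checkpoint_genes), length(x$decoy_genes)
  ))
  invisible(x)
}

#' All gene symbols referenced by a panel
#'
#' @param panel An `iema_panel`.
#' @return Character vector of unique gene symbols.
#' @export
panel_genes <- function(panel) {
  unique(c(
    unlist(panel$steps, use.names = FALSE),
    unlist(panel$checkpoint_genes, use.names = FALSE),
    unlist(panel$decoy_genes, use.names = FALSE),
    panel$effector_genes
  ))
}
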