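#' Call immune evasion mechanisms for one cluster
#'
#' Maps a cluster-versus-normal DE table onto the cancer-immunity-cycle
#' panel. A cycle step is *active* iff at least `min_step_genes` of its genes
#' are up-called (class `up` or `minimal_up`, adjusted p below `padj_cutoff`
#' and log2 fold change above `up_call_lfc`). Rules:
#'
#' * no step active: **ignorance** (the tumor raises no danger signal);
#' * some step active but antigen presentation inactive and killing or
#'   infiltration inactive: **impaired antigen presentation / low CTL
#'   activation**;
#' * each checkpoint gene set with an up-called gene adds its **tolerance**
#'   tag (CTLA4, PD-1, PD-L1/2, TGF-beta);
#' * each decoy-receptor set with an up-called gene adds its
#'   **counterattack** tag (DcR3, TRAILR4).
#'
#' Tolerance and counterattack tags combine freely with ignorance or
#' impaired antigen presentation; the latter two are mutually exclusive.
#' Panel genes absent from the DE table are treated as non-significant.
#'
#' The mechanism up-call threshold (`up_call_lfc = 1`) is deliberately looser
#' than the headline DE fold-change cutoff of 2: checkpoint transcripts are
#' low-abundance and a 2-fold increase is already biologically meaningful.
#' Both thresholds are exposed.
#'
#' @param de An `iema_de` tibble (from [de_table()]) for one cluster.
#' @param panel A [cancer_immunity_panel()].
#' @param min_step_genes Up-called genes needed to call a step active.
#' @param up_call_lfc Log2 fold-change threshold for mechanism evidence.
#' @param padj_cutoff Adjusted-p threshold for mechanism evidence.
#' @param cluster Optional cluster id recorded on the profile.
#' @return An object of class `iema_profile`: `cluster`, `mechanisms`
#'   (character vector of tags), `evidence` (tibble `mechanism`, `gene`,
#'   `log2fc`, `padj`, `de_class`), `active_steps`.
#' @export
annotate_cluster <- function(de, panel = cancer_immunity_panel(),
                             min_step_genes = 1, up_call_lfc = 1,
                             padj_cutoff = 0.05, cluster = NA_character_) {
  if (!is.data.frame(de) || nrow(de) == 0) {
    abort("`de` must be a non-empty DE table.")
  }
  stopifnot(all(c("gene", "log2fc", "padj", "de_class") %in% names(de)))

  up_called <- de$de_class %in% c("up", "minimal_up") &
    de$padj < padj_cutoff & de$log2fc > up_call_lfc
  up_genes <- de$gene[up_called]

  active_steps <- names(panel$steps)[
    map_lgl(panel$steps, ~ sum(.x %in% up_genes) >= min_step_genes)
  ]

  mechanisms <- character(0)
  evidence <- list()
  record <- function(mech, genes) {
    rows <- de[de$gene %in% genes, c("gene", "log2fc", "padj", "de_class")]
    evidence[[length(evidence) + 1]] <<- dplyr::bind_cols(
      tibble(mechanism = rep(mech, nrow(rows))), rows
    )
  }

  if (length(active_steps) == 0) {
    mechanisms <- "ignorance"
    evidence[[1]] <- tibble(
      mechanism = "ignorance", gene = NA_character_,
      log2fc = NA_real_, padj = NA_real_,
      de_class = "no cycle step active"
    )
  } else if (!("antigen_presentation" %in% active_steps) &&
    (!("killing" %in% active_steps) || !("infiltration" %in% active_steps))) {
    mechanisms <- "impaired_antigen_presentation"
    record(
      "impaired_antigen_presentation",
      intersect(unlist(panel$steps[active_steps]), up_genes)
    )
  }

  for (tag in names(panel$checkpoint_genes)) {
    hits <- intersect(panel$checkpoint_genes[[tag]], up_genes)
    if (length(hits) > 0) {
      mechanisms <- c(mechanisms, tag)
      record(tag, hits)
    }
  }
  for (tag in names(panel$decoy_genes)) {
    hits <- intersect(panel$decoy_genes[[tag]], up_genes)
    if (length(hits) > 0) {
      mechanisms <- c(mechanisms, tag)
      record(tag, hits)
    }
  }

  structure(
    list(
      cluster = cluster,
      mechanisms = mechanisms,
      evidence = dplyr::bind_rows(evidence),
      active_steps = active_steps
    ),
    class = "iema_profile"
  )
}

#' @export
print.iema_profile <- function(x, ...) {
  cat(sprintf(
    "IEM profile%s: %s\n",
    if (is.na(x$cluster)) "" else paste0(" for ", x$cluster),
    paste(x$mechanisms, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.iema_profile <- function(x, ...) {
  x$evidence
}

#' Prevalence of mechanism combinations across clusters
#'
#' For each queried mechanism set `M`, the prevalence is the summed size of
#' every cluster whose mechanism set contains all of `M`, divided by the
#' denominator (typically the number of clustered patients), as a
#' percentage.
#'
#' @param cluster_sizes Named integer vector: patients per cluster.
#' @param profiles Named list over the same clusters; each element either an
#'   `iema_profile` or a character vector of mechanism tags.
#' @param queries List of character vectors (mechanism sets to query); a
#'   single character vector is treated as one query. Defaults to every
#'   single mechanism observed.
#' @param denominator Patient count to divide by (default `sum(cluster_sizes)`).
#' @param digits Rounding for the percentage (default 2).
#' @return A tibble: `query` (label), `mechanisms` (list column),
#'   `n_patients`, `clusters`, `prevalence_pct`.
#' @export
#' @examples
#' sizes <- c(cluster_1 = 60, cluster_2 = 40)
#' profs <- list(
#'   cluster_1 = c("ignorance", "counterattack:DcR3"),
#'   cluster_2 = c("tolerance:CTLA4")
#' )
#' summarize_prevalence(sizes, profs, queries = list("ignorance"))
summarize_prevalence <- function(cluster_sizes, profiles, queries = NULL,
                                 denominator = NULL, digits = 2) {
  if (is.null(names(cluster_sizes))) abort("`cluster_sizes` must be named.")
  missing <- setdiff(names(cluster_sizes), names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("No profile for cluster(s): %s.", paste(missing, collapse = ", ")))
  }
  mech_sets <- map(profiles[names(cluster_sizes)], function(p) {
    if (inherits(p, "iema_profile")) p$mechanisms else as.character(p)
  })
  denominator <- denominator %||% sum(cluster_sizes)
  if (denominator < sum(cluster_sizes)) {
    abort("`denominator` must be at least the summed cluster sizes.")
  }
  if (is.null(queries)) {
    queries <- as.list(sort(unique(unlist(mech_sets))))
  }
  if (is.character(queries)) queries <- list(queries)
  rows <- map(queries, function(q) {
    carriers <- names(mech_sets)[map_lgl(mech_sets, ~ all(q %in% .x))]
    n <- sum(cluster_sizes[carriers])
    tibble(
      query = paste(q, collapse = " & "),
      mechanisms = list(q),
      n_patients = as.integer(n),
      clusters = paste(carriers, collapse = ","),
      prevalence_pct = round(100 * n / denominator, digits)
    )
  })
  dplyr::bind_rows(rows)
}

#' Mechanism-to-therapy lookup
#'
#' Suggested immunotherapy class for each evasion mechanism tag: cellular
#' vaccines for ignorance and impaired antigen presentation, the matching
#' checkpoint inhibitor for each tolerance tag, and decoy-receptor blockade
#' for counterattack tags.
#'
#' @return A tibble: `mechanism`, `suggested_therapy`.
#' @export
iem_therapy_lookup <- function() {
  tibble(
    mechanism = c(
      "ignorance", "impaired_antigen_presentation",
      "tolerance:CTLA4", "tolerance:PD-1", "tolerance:PD-L1/2",
      "tolerance:TGF-beta", "counterattack:DcR3", "counterattack:TRAILR4"
    ),
    suggested_therapy = c(
      "Sipuleucel-T / DC vaccines", "Sipuleucel-T / DC vaccines",
      "anti-CTLA4", "anti-PD-1", "anti-PD-L1",
      "anti-TGF-beta", "anti-DcR3", "anti-TRAILR4"
    )
  )
}

#' IEM profile report across clusters
#'
#' One row per (cluster, mechanism) with the suggested-therapy lookup
#' attached; suitable for writing as TSV.
#'
#' @param profiles Named list of `iema_profile`s (or mechanism character
#'   vectors).
#' @return A tibble: `cluster`, `mechanism`, `suggested_therapy`.
#' @export
iem_report <- function(profiles) {
  rows <- imap(profiles, function(p, cl) {
    mechs <- if (inherits(p, "iema_profile")) p$mechanisms else as.character(p)
    tibble(cluster = cl, mechanism = mechs)
  })
  dplyr::left_join(dplyr::bind_rows(rows), iem_therapy_lookup(), by = "mechanism")
}
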