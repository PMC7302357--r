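#' Pipeline configuration
#'
#' Collects input paths and stage parameters for [run_pipeline()]. Can also
#' be loaded from a YAML file with the same field names.
#'
#' @param counts Path to the counts TSV, or an [cohort_counts()] object.
#' @param gene_list Optional gene-list file (one symbol per line) or
#'   character vector.
#' @param roles Optional sample-role sidecar path or named vector (see
#'   [read_counts()]).
#' @param clinical Optional clinical TSV path or data frame
#'   (`sample`, `gleason_cat`, `t_stage`).
#' @param fractions Optional CIBERSORT-style fractions CSV path or data
#'   frame.
#' @param output_dir Directory for stage outputs (created if needed); `NULL`
#'   for in-memory results only.
#' @param panel_path Optional panel JSON (defaults to the bundled panel).
#' @param plaid A [plaid_params()] list.
#' @param min_frac Sequential-clustering stopping fraction (default 0.05).
#' @param de_padj,de_lfc DE classification thresholds (0.05, 2).
#' @param iem_up_lfc,iem_min_step_genes Mechanism-call thresholds (1, 1).
#' @param tree_min_leaf,tree_max_depth CART parameters (5, 6).
#' @param seed Integer seed used by every stochastic stage.
#' @return A list of class `iema_pipeline_config`.
#' @export
pipeline_config <- function(counts,
                            gene_list = NULL,
                            roles = NULL,
                            clinical = NULL,
                            fractions = NULL,
                            output_dir = NULL,
                            panel_path = NULL,
                            plaid = plaid_params(),
                            min_frac = 0.05,
                            de_padj = 0.05, de_lfc = 2,
                            iem_up_lfc = 1, iem_min_step_genes = 1,
                            tree_min_leaf = 5, tree_max_depth = 6,
                            seed = 1L) {
  if (is.character(counts) && !file.exists(counts)) {
    abort(sprintf("Counts file not found: %s", counts))
  }
  for (p in list(clinical, fractions, panel_path)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      abort(sprintf("Input file not found: %s", p))
    }
  }
  if (min_frac <= 0 || min_frac >= 1) abort("`min_frac` must be in (0, 1).")
  check_prob(de_padj, "de_padj")
  plaid$seed <- as.integer(seed)
  structure(
    list(
      counts = counts, gene_list = gene_list, roles = roles,
      clinical = clinical, fractions = fractions,
      output_dir = output_dir, panel_path = panel_path,
      plaid = plaid, min_frac = min_frac,
      de_padj = de_padj, de_lfc = de_lfc,
      iem_up_lfc = iem_up_lfc, iem_min_step_genes = iem_min_step_genes,
      tree_min_leaf = tree_min_leaf, tree_max_depth = tree_max_depth,
      seed = as.integer(seed)
    ),
    class = "iema_pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (plaid parameters under a `plaid:` block).
#' @return An `iema_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  plaid_args <- raw$plaid %||% list()
  raw$plaid <- do.call(plaid_params, plaid_args)
  do.call(pipeline_config, raw)
}

pipeline_inputs <- function(config) {
  counts <- if (inherits(config$counts, "iema_counts")) {
    config$counts
  } else {
    read_counts(config$counts, gene_list = config$gene_list, roles = config$roles)
  }
  clinical <- config$clinical
  if (is.character(clinical)) {
    clinical <- readr::read_tsv(clinical, show_col_types = FALSE, progress = FALSE)
  }
  fractions <- config$fractions
  if (is.character(fractions)) fractions <- read_fractions(fractions)
  list(
    counts = counts, clinical = clinical, fractions = fractions,
    panel = cancer_immunity_panel(config$panel_path)
  )
}

#' Run the full immune-evasion analysis pipeline
#'
#' Executes, in order: sequential plaid clustering of the tumor samples;
#' per-cluster NB Wald differential expression against the pooled adjacent
#' normals; evasion-mechanism annotation and mechanism-combination
#' prevalence; immune-composition summaries (if fractions are supplied);
#' clinical association tests (if a clinical table is supplied); and the
#' classification-tree biomarker selection over the clustered samples. The
#' whole run is deterministic for a fixed configuration seed. If
#' `output_dir` is set, every stage result is written (TSV/JSON) along with
#' a top-level `report.json`.
#'
#' @param config An `iema_pipeline_config`.
#' @return A list of class `iema_report`: `assignment`, `cluster_sizes`,
#'   `de` (named list of DE tibbles), `profiles`, `prevalence`,
#'   `composition`, `associations`, `tree`, `biomarkers`, `accuracy`,
#'   `seed`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(
#'   n_tumor = 60, n_normal = 10, n_genes = 150, n_clusters = 2,
#'   cluster_fracs = c(0.45, 0.45), marker_genes_per_cluster = 15, seed = 3
#' ))
#' report <- run_pipeline(pipeline_config(cohort$counts, seed = 3))
#' report$cluster_sizes
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "iema_pipeline_config"))
  inputs <- pipeline_inputs(config)
  counts <- inputs$counts
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  assignment <- stage("sequential_clustering", {
    sequential_cluster(counts, params = config$plaid, min_frac = config$min_frac)
  })
  sizes <- cluster_sizes(assignment)

  size_factors <- estimate_size_factors(counts)
  de_list <- stage("differential_expression", {
    setNames(
      map(assignment$clusters, function(cl) {
        de_table(counts, cl$samples,
          size_factors = size_factors,
          padj_cutoff = config$de_padj, lfc_cutoff = config$de_lfc
        )
      }),
      map_chr(assignment$clusters, "id")
    )
  })

  profiles <- stage("iem_annotation", {
    imap(de_list, function(de, id) {
      annotate_cluster(de, inputs$panel,
        min_step_genes = config$iem_min_step_genes,
        up_call_lfc = config$iem_up_lfc,
        padj_cutoff = config$de_padj, cluster = id
      )
    })
  })

  prevalence <- NULL
  if (length(profiles) > 0) {
    size_vec <- setNames(sizes$n, sizes$cluster)
    prevalence <- summarize_prevalence(size_vec, profiles)
  }

  composition <- NULL
  if (!is.null(inputs$fractions)) {
    composition <- stage("immune_composition", {
      summarize_composition(
        inputs$fractions, assignment,
        reference = normal_samples(counts)
      )
    })
  }

  associations <- NULL
  if (!is.null(inputs$clinical) && length(assignment$clusters) >= 1) {
    associations <- stage("clinical_association", {
      vars <- intersect(c("gleason_cat", "t_stage"), names(inputs$clinical))
      setNames(
        map(vars, ~ associate_clusters(assignment, inputs$clinical, .x)),
        vars
      )
    })
  }

  tree <- NULL
  biomarkers <- character(0)
  accuracy <- NA_real_
  if (length(assignment$clusters) >= 2) {
    tree <- stage("biomarker_tree", {
      clustered <- dplyr::filter(assignment$assignment, .data$cluster != "unclustered")
      norm <- sweep(
        unclass(counts)[, clustered$sample, drop = FALSE], 2,
        size_factors[clustered$sample], "/"
      )
      fit_cart(t(norm), clustered$cluster,
        min_leaf = config$tree_min_leaf, max_depth = config$tree_max_depth
      )
    })
    clustered <- dplyr::filter(assignment$assignment, .data$cluster != "unclustered")
    norm <- sweep(
      unclass(counts)[, clustered$sample, drop = FALSE], 2,
      size_factors[clustered$sample], "/"
    )
    biomarkers <- extract_biomarkers(tree)
    accuracy <- tree_accuracy(tree, t(norm), clustered$cluster)
  }

  report <- structure(
    list(
      assignment = assignment,
      cluster_sizes = sizes,
      de = de_list,
      profiles = profiles,
      prevalence = prevalence,
      composition = composition,
      associations = associations,
      tree = tree,
      biomarkers = biomarkers,
      accuracy = accuracy,
      seed = config$seed
    ),
    class = "iema_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.iema_report <- function(x, ...) {
  cat(sprintf(
    "IEM analysis report (seed %d): %d cluster(s), %d biomarker(s)\n",
    x$seed, length(x$assignment$clusters), length(x$biomarkers)
  ))
  print(x$cluster_sizes)
  invisible(x)
}

#' Write every stage output of a pipeline report
#'
#' Per-stage TSVs (assignment, cluster sizes, DE tables, IEM report,
#' prevalence, composition, associations, biomarkers), the tree JSON, and a
#' top-level `report.json` summarising cluster sizes under both
#' denominators, mechanisms per cluster, the prevalence table, association
#' p-values and the biomarker list.
#'
#' @param report An `iema_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$assignment$assignment,
    file.path(dir, "assignment.tsv"),
    progress = FALSE
  )
  readr::write_tsv(report$cluster_sizes, file.path(dir, "cluster_sizes.tsv"),
    progress = FALSE
  )
  for (id in names(report$de)) {
    write_de_table(report$de[[id]], file.path(dir, sprintf("de_%s.tsv", id)))
  }
  if (length(report$profiles) > 0) {
    readr::write_tsv(iem_report(report$profiles), file.path(dir, "iem_profiles.tsv"),
      progress = FALSE
    )
  }
  if (!is.null(report$prevalence)) {
    readr::write_tsv(
      dplyr::select(report$prevalence, -"mechanisms"),
      file.path(dir, "prevalence.tsv"),
      progress = FALSE
    )
  }
  if (!is.null(report$composition)) {
    readr::write_tsv(report$composition, file.path(dir, "immune_composition.tsv"),
      progress = FALSE
    )
  }
  if (!is.null(report$associations)) {
    for (v in names(report$associations)) {
      readr::write_tsv(tidy(report$associations[[v]]),
        file.path(dir, sprintf("association_%s.tsv", v)),
        progress = FALSE
      )
    }
  }
  if (!is.null(report$tree)) {
    write_tree(report$tree, file.path(dir, "tree.json"))
    readr::write_tsv(tibble(biomarker = report$biomarkers),
      file.path(dir, "biomarkers.tsv"),
      progress = FALSE
    )
  }
  json <- list(
    seed = report$seed,
    clusters = report$cluster_sizes,
    mechanisms = map(report$profiles, "mechanisms"),
    prevalence = if (!is.null(report$prevalence)) {
      dplyr::select(report$prevalence, -"mechanisms")
    },
    associations = if (!is.null(report$associations)) {
      map(report$associations, ~ .x[, c("cluster", "variable", "n", "p", "significant")])
    },
    biomarkers = report$biomarkers,
    tree_accuracy = report$accuracy
  )
  jsonlite::write_json(
    json[!map_lgl(json, is.null)],
    file.path(dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = 10
  )
  invisible(dir)
}
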