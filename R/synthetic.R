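#' Configuration for a synthetic immune-expression cohort
#'
#' Defines the generative model for a seeded synthetic cohort with planted
#' structure: negative-binomial counts whose log2 means are a per-gene
#' baseline plus additive plaid layers over cluster-specific gene blocks;
#' per-cluster immune-evasion patterns planted on the cancer-immunity panel
#' genes; cluster-enriched categorical clinical variables; and Dirichlet
#' immune-cell fractions with cluster-specific concentration shifts.
#'
#' The defaults describe a strong-signal recovery benchmark: 300 tumors and
#' 50 adjacent normals, 4 planted clusters holding 90% of tumors (10%
#' background), a 4-unit log2 layer effect and NB dispersion 0.05.
#'
#' @param n_tumor,n_normal Tumor / adjacent-normal sample counts.
#' @param n_genes Total immune genes (panel genes plus simulated filler).
#' @param n_clusters Number of planted clusters.
#' @param cluster_fracs Proportions of tumor samples per planted cluster;
#'   each at least `min_cluster_frac`, summing to at most 1. The remainder
#'   are background samples carrying baseline expression only.
#' @param base_log_mean_range Interval for the per-gene baseline log2 mean.
#' @param layer_effect Additive log2-scale effect of each planted layer.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param marker_genes_per_cluster Filler genes carrying each cluster's layer.
#' @param iem_truth Named list, one character vector of mechanism tags per
#'   cluster (names `cluster_1`, ...). Defaults to four distinct profiles.
#' @param clinical_enrichment Named list per cluster: named list per clinical
#'   variable of named category-odds multipliers.
#' @param fraction_shifts Named list per cluster of named Dirichlet
#'   concentration multipliers over the LM22 cell types.
#' @param min_cluster_frac Smallest admissible planted cluster fraction.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A list of class `iema_cohort_config`.
#' @export
cohort_config <- function(n_tumor = 300,
                          n_normal = 50,
                          n_genes = 300,
                          n_clusters = 4,
                          cluster_fracs = c(0.30, 0.25, 0.20, 0.15),
                          base_log_mean_range = c(3, 8),
                          layer_effect = 4,
                          nb_dispersion = 0.05,
                          marker_genes_per_cluster = 30,
                          iem_truth = NULL,
                          clinical_enrichment = NULL,
                          fraction_shifts = NULL,
                          min_cluster_frac = 0.05,
                          seed = 1L) {
  stopifnot(
    n_tumor >= 2, n_normal >= 2, n_genes >= 60, n_clusters >= 1,
    length(base_log_mean_range) == 2,
    base_log_mean_range[1] < base_log_mean_range[2],
    nb_dispersion > 0, marker_genes_per_cluster >= 2
  )
  if (length(cluster_fracs) != n_clusters) {
    abort("`cluster_fracs` must have one entry per planted cluster.")
  }
  if (any(cluster_fracs < min_cluster_frac)) {
    abort(sprintf("Every cluster fraction must be at least %g.", min_cluster_frac))
  }
  if (sum(cluster_fracs) > 1 + 1e-12) {
    abort("`cluster_fracs` must sum to at most 1.")
  }
  cl_names <- paste0("cluster_", seq_len(n_clusters))
  if (is.null(iem_truth)) {
    defaults <- list(
      c("ignorance", "counterattack:DcR3"),
      c(
        "impaired_antigen_presentation", "tolerance:CTLA4",
        "tolerance:PD-1", "counterattack:DcR3"
      ),
      c("ignorance", "tolerance:CTLA4"),
      c("ignorance")
    )
    iem_truth <- setNames(
      defaults[((seq_len(n_clusters) - 1) %% length(defaults)) + 1], cl_names
    )
  }
  if (!setequal(names(iem_truth), cl_names)) {
    abort("`iem_truth` must be named cluster_1 ... cluster_k.")
  }
  if (is.null(clinical_enrichment)) {
    clinical_enrichment <- list()
    if (n_clusters >= 2) {
      clinical_enrichment$cluster_2 <- list(gleason_cat = c(eq7 = 8))
    }
    if (n_clusters >= 3) {
      clinical_enrichment$cluster_3 <- list(
        gleason_cat = c(ge8 = 8), t_stage = c(T3 = 4)
      )
    }
  }
  if (is.null(fraction_shifts)) {
    fraction_shifts <- list()
    for (cl in cl_names) {
      if (any(startsWith(iem_truth[[cl]], "tolerance:"))) {
        fraction_shifts[[cl]] <- c(
          "T cells regulatory (Tregs)" = 3, "T cells CD8" = 2
        )
      }
    }
  }
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
      n_genes = as.integer(n_genes), n_clusters = as.integer(n_clusters),
      cluster_fracs = cluster_fracs,
      base_log_mean_range = base_log_mean_range,
      layer_effect = layer_effect, nb_dispersion = nb_dispersion,
      marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
      iem_truth = iem_truth,
      clinical_enrichment = clinical_enrichment,
      fraction_shifts = fraction_shifts,
      min_cluster_frac = min_cluster_frac,
      seed = as.integer(seed)
    ),
    class = "iema_cohort_config"
  )
}

# Baseline category frequencies for the clinical generator: Gleason grade
# categories (<=6, 7, >=8) and pathologic T stage. T1 is rare in surgical
# cohorts, hence its near-zero baseline.
clinical_baselines <- function() {
  list(
    gleason_cat = c(le6 = 0.10, eq7 = 0.50, ge8 = 0.40),
    t_stage = c(T1 = 0.02, T2 = 0.43, T3 = 0.52, T4 = 0.03)
  )
}

plan_gene_universe <- function(config, panel) {
  pg <- panel_genes(panel)
  n_filler <- config$n_genes - length(pg)
  need <- config$n_clusters * config$marker_genes_per_cluster
  if (n_filler < need + 10) {
    abort(sprintf(
      "n_genes = %d leaves %d filler genes but %d are needed for marker blocks.",
      config$n_genes, n_filler, need + 10
    ))
  }
  filler <- sprintf("IMMG%04d", seq_len(n_filler))
  list(genes = c(pg, filler), panel_genes = pg, filler = filler)
}

#' Generate planted NB counts and the true cluster labels
#'
#' Counts are NB via a gamma-Poisson mixture with mean
#' `2^(baseline + sum of planted layer effects)` and dispersion
#' `nb_dispersion`. Each planted cluster carries `+layer_effect` on its own
#' disjoint block of filler marker genes, plus the panel-gene pattern implied
#' by its planted evasion mechanisms (checkpoint / decoy upregulation, or
#' cycle-step activation for impaired antigen presentation). Background tumor
#' samples and all normal samples carry baseline expression only.
#'
#' @param config A [cohort_config()].
#' @param panel A [cancer_immunity_panel()]; defaults to the bundled panel.
#' @return A list: `counts` ([cohort_counts()]), `true_clusters` (tibble
#'   `sample`, `cluster` with `"background"` for unplanted tumors),
#'   `marker_genes` (named list per cluster).
#' @export
generate_counts <- function(config, panel = cancer_immunity_panel()) {
  stopifnot(inherits(config, "iema_cohort_config"))
  universe <- plan_gene_universe(config, panel)
  with_seed(config$seed, {
    genes <- universe$genes
    n_g <- length(genes)
    tumors <- sprintf("tumor_%03d", seq_len(config$n_tumor))
    normals <- sprintf("normal_%03d", seq_len(config$n_normal))
    samples <- c(tumors, normals)

    sizes <- floor(config$cluster_fracs * config$n_tumor)
    labels <- rep("background", config$n_tumor)
    order <- sample.int(config$n_tumor) # random placement of cluster members
    pos <- 1
    for (k in seq_len(config$n_clusters)) {
      idx <- order[pos:(pos + sizes[k] - 1)]
      labels[idx] <- paste0("cluster_", k)
      pos <- pos + sizes[k]
    }

    # disjoint marker blocks drawn from the filler genes
    filler_pool <- sample(universe$filler)
    marker_genes <- list()
    pos <- 1
    for (k in seq_len(config$n_clusters)) {
      marker_genes[[paste0("cluster_", k)]] <-
        filler_pool[pos:(pos + config$marker_genes_per_cluster - 1)]
      pos <- pos + config$marker_genes_per_cluster
    }

    baseline <- stats::runif(
      n_g, config$base_log_mean_range[1], config$base_log_mean_range[2]
    )
    log_mu <- matrix(baseline,
      nrow = n_g, ncol = length(samples),
      dimnames = list(genes, samples)
    )

    for (k in seq_len(config$n_clusters)) {
      cl <- paste0("cluster_", k)
      cols <- tumors[labels == cl]
      up_genes <- marker_genes[[cl]]
      for (mech in config$iem_truth[[cl]]) {
        if (mech %in% names(panel$checkpoint_genes)) {
          up_genes <- c(up_genes, panel$checkpoint_genes[[mech]])
        } else if (mech %in% names(panel$decoy_genes)) {
          up_genes <- c(up_genes, panel$decoy_genes[[mech]])
        } else if (mech == "impaired_antigen_presentation") {
          # some cycle steps fire while presentation and killing stay silent
          up_genes <- c(
            up_genes, panel$steps$trafficking, panel$steps$infiltration
          )
        } else if (mech != "ignorance") {
          abort(sprintf("Unknown planted mechanism '%s'.", mech))
        }
      }
      log_mu[unique(up_genes), cols] <- log_mu[unique(up_genes), cols] + config$layer_effect
    }

    mu <- 2^log_mu
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$nb_dispersion),
      nrow = n_g, dimnames = dimnames(mu)
    )
    list(
      counts = cohort_counts(
        counts,
        setNames(rep(c("tumor", "normal"), c(length(tumors), length(normals))), samples)
      ),
      true_clusters = tibble(sample = tumors, cluster = labels),
      marker_genes = marker_genes
    )
  })
}

#' Generate cluster-enriched categorical clinical data
#'
#' Each sample's category is drawn from the baseline simplex of its variable
#' after reweighting by the sample's cluster odds multipliers and
#' renormalizing. Background samples use the baseline.
#'
#' @param true_clusters Tibble `sample`, `cluster` (as from
#'   [generate_counts()]).
#' @param enrichment Named list per cluster: named list per variable of named
#'   category multipliers (all positive). Unknown cluster labels, variables
#'   or category keys raise errors.
#' @param seed Integer seed.
#' @return A tibble `sample`, `gleason_cat`, `t_stage`.
#' @export
generate_clinical <- function(true_clusters, enrichment = list(), seed = 1L) {
  baselines <- clinical_baselines()
  known_clusters <- unique(true_clusters$cluster)
  bad <- setdiff(names(enrichment), known_clusters)
  if (length(bad) > 0) {
    abort(sprintf("Enrichment for unknown cluster(s): %s.", paste(bad, collapse = ", ")))
  }
  for (cl in names(enrichment)) {
    bad_var <- setdiff(names(enrichment[[cl]]), names(baselines))
    if (length(bad_var) > 0) {
      abort(sprintf("Unknown clinical variable(s): %s.", paste(bad_var, collapse = ", ")))
    }
    for (v in names(enrichment[[cl]])) {
      mult <- enrichment[[cl]][[v]]
      bad_cat <- setdiff(names(mult), names(baselines[[v]]))
      if (length(bad_cat) > 0) {
        abort(sprintf(
          "Unknown category key(s) for %s: %s.", v, paste(bad_cat, collapse = ", ")
        ))
      }
      if (any(mult <= 0)) abort("Enrichment multipliers must be positive.")
    }
  }
  with_seed(seed, {
    draw <- function(cluster, variable) {
      p <- baselines[[variable]]
      mult <- enrichment[[cluster]][[variable]]
      if (!is.null(mult)) {
        p[names(mult)] <- p[names(mult)] * mult
      }
      p <- p / sum(p)
      sample(names(p), 1, prob = p)
    }
    tibble(
      sample = true_clusters$sample,
      gleason_cat = map_chr(true_clusters$cluster, draw, variable = "gleason_cat"),
      t_stage = map_chr(true_clusters$cluster, draw, variable = "t_stage")
    )
  })
}

#' Generate Dirichlet immune-cell fractions with cluster shifts
#'
#' Each sample's 22 LM22 fractions are Dirichlet with concentration
#' `base_concentration` elementwise-multiplied by its cluster's shift vector.
#' Rows sum to 1 by construction.
#'
#' @param true_clusters Tibble `sample`, `cluster`.
#' @param shift_config Named list per cluster of named positive concentration
#'   multipliers over LM22 cell-type names.
#' @param base_concentration Positive scalar or length-22 vector (default 2).
#' @param seed Integer seed.
#' @return A tibble `sample` plus the 22 LM22 columns.
#' @export
generate_fractions <- function(true_clusters, shift_config = list(),
                               base_concentration = 2, seed = 1L) {
  cells <- lm22_cell_types()
  if (any(base_concentration <= 0)) abort("Concentrations must be positive.")
  base <- rep_len(base_concentration, length(cells))
  names(base) <- cells
  for (cl in names(shift_config)) {
    mult <- shift_config[[cl]]
    bad <- setdiff(names(mult), cells)
    if (length(bad) > 0) {
      abort(sprintf("Unknown LM22 cell type(s): %s.", paste(bad, collapse = ", ")))
    }
    if (any(mult <= 0)) abort("Concentrations must be positive.")
  }
  with_seed(seed, {
    rows <- matrix(0, nrow(true_clusters), length(cells),
      dimnames = list(NULL, cells)
    )
    for (i in seq_len(nrow(true_clusters))) {
      conc <- base
      mult <- shift_config[[true_clusters$cluster[i]]]
      if (!is.null(mult)) conc[names(mult)] <- conc[names(mult)] * mult
      g <- rgamma(length(conc), shape = conc)
      rows[i, ] <- g / sum(g)
    }
    dplyr::bind_cols(tibble(sample = true_clusters$sample), as_tibble(rows))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_counts()], [generate_clinical()] (tumor samples; normals
#' have no clinical record) and [generate_fractions()] (all samples; normals
#' drawn at the base concentration) under sub-seeds derived from the
#' configuration seed.
#'
#' @param config A [cohort_config()].
#' @param panel A [cancer_immunity_panel()].
#' @return A list of class `iema_cohort`: `counts`, `true_clusters`,
#'   `true_iem`, `marker_genes`, `clinical`, `fractions`, `panel`, `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_tumor = 60, n_normal = 10, n_genes = 150,
#'   n_clusters = 2, cluster_fracs = c(0.4, 0.4),
#'   marker_genes_per_cluster = 15, seed = 7
#' ))
#' table(cohort$true_clusters$cluster)
simulate_cohort <- function(config = cohort_config(), panel = cancer_immunity_panel()) {
  gen <- generate_counts(config, panel)
  clinical <- generate_clinical(
    gen$true_clusters, config$clinical_enrichment,
    seed = config$seed + 1L
  )
  all_samples <- tibble(
    sample = colnames(gen$counts),
    cluster = c(
      gen$true_clusters$cluster,
      rep("normal", length(normal_samples(gen$counts)))
    )
  )
  fractions <- generate_fractions(
    all_samples, config$fraction_shifts,
    seed = config$seed + 2L
  )
  structure(
    list(
      counts = gen$counts,
      true_clusters = gen$true_clusters,
      true_iem = config$iem_truth,
      marker_genes = gen$marker_genes,
      clinical = clinical,
      fractions = fractions,
      panel = panel,
      config = config
    ),
    class = "iema_cohort"
  )
}

#' @export
print.iema_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic immune cohort: %d genes x %d samples, %d planted clusters (seed %d)\n",
    nrow(x$counts), ncol(x$counts), x$config$n_clusters, x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Counts TSV (plus sample-role sidecar), clinical TSV, fractions CSV in LM22
#' column order, and a truth JSON with the planted clusters, mechanisms and
#' marker genes.
#'
#' @param cohort An `iema_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(
    cohort$counts,
    file.path(dir, "counts.tsv"),
    roles_path = file.path(dir, "sample_roles.tsv")
  )
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  write_fractions(cohort$fractions, file.path(dir, "fractions.csv"))
  writeLines(rownames(cohort$counts), file.path(dir, "gene_list.txt"))
  truth <- list(
    true_clusters = setNames(
      as.list(cohort$true_clusters$cluster), cohort$true_clusters$sample
    ),
    true_iem = cohort$true_iem,
    marker_genes = cohort$marker_genes,
    seed = cohort$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
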