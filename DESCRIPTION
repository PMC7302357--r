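Package: iema
Title: Immune Evasion Mechanism Analysis for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumor cohorts by immune-gene expression and annotates each
    patient cluster with the immune evasion mechanisms it employs. Implements
    sequential plaid-model biclustering into disjoint patient clusters, per-cluster
    negative-binomial Wald differential expression against adjacent normal tissue,
    rule-based evasion-mechanism calls over the cancer-immunity cycle (ignorance,
    impaired antigen presentation, checkpoint tolerance, decoy-receptor
    counterattack), exact 2xk contingency tests for clinical association,
    immune-cell-fraction summaries from deconvolution output, and classification-tree
    biomarker selection. Ships a seeded synthetic cohort generator with planted
    cluster structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
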