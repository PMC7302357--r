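#' Reference immune-evasion stratification of the TCGA prostate cohort
#'
#' The published eight-cluster stratification of the TCGA prostate
#' adenocarcinoma cohort (498 tumors, of which 430 were clustered) that this
#' package's method family produces: per-cluster patient counts and gene-set
#' sizes, the evasion-mechanism set called for each cluster, and the
#' cluster-by-category contingency tables for Gleason score (<=6 / 7 / >=8)
#' and pathologic T stage (T1-T4). These tables serve as worked-example
#' inputs for [summarize_prevalence()] and [associate_clusters()]-style
#' contingency tests; the underlying expression data are not bundled.
#'
#' Note the T-stage table's published per-category totals (183/256/12) do not
#' equal its column sums over clusters (157/257/11); `tstage$total` reports
#' the column sums, and the discrepancy is preserved in
#' `tstage$printed_total`.
#'
#' @return A list:
#' \describe{
#'   \item{cluster_sizes}{named integer vector, patients per cluster (sums to 430).}
#'   \item{n_genes}{named integer vector, genes defining each cluster.}
#'   \item{cohort_size}{498, the original tumor count.}
#'   \item{mechanisms}{named list of mechanism tags per cluster.}
#'   \item{gleason}{tibble: `cluster`, `le6`, `eq7`, `ge8` counts.}
#'   \item{tstage}{tibble: `cluster`, `T1`, `T2`, `T3`, `T4` counts.}
#' }
#' @export
#' @examples
#' ref <- prad_iem_reference()
#' sum(ref$cluster_sizes)
prad_iem_reference <- function() {
  clusters <- paste0("cluster_", 1:8)
  list(
    cluster_sizes = setNames(
      c(129L, 44L, 52L, 56L, 43L, 49L, 28L, 29L), clusters
    ),
    n_genes = setNames(
      c(232L, 314L, 276L, 129L, 116L, 27L, 111L, 52L), clusters
    ),
    cohort_size = 498L,
    mechanisms = setNames(list(
      c("counterattack:DcR3", "ignorance"),
      c(
        "impaired_antigen_presentation", "tolerance:CTLA4",
        "tolerance:PD-1", "counterattack:DcR3"
      ),
      c("tolerance:CTLA4", "tolerance:PD-1", "ignorance"),
      c("tolerance:CTLA4", "ignorance"),
      c("ignorance"),
      c("tolerance:CTLA4", "counterattack:DcR3", "ignorance"),
      c("ignorance"),
      c("tolerance:CTLA4", "ignorance")
    ), clusters),
    gleason = tibble(
      cluster = clusters,
      le6 = c(11L, 4L, 3L, 1L, 7L, 9L, 2L, 4L),
      eq7 = c(59L, 34L, 17L, 24L, 19L, 19L, 24L, 15L),
      ge8 = c(59L, 6L, 32L, 31L, 17L, 21L, 2L, 10L)
    ),
    tstage = tibble(
      cluster = clusters,
      T1 = rep(0L, 8),
      T2 = c(51L, 23L, 9L, 16L, 19L, 16L, 15L, 8L),
      T3 = c(74L, 21L, 37L, 39L, 23L, 32L, 12L, 19L),
      T4 = c(2L, 0L, 5L, 1L, 1L, 0L, 1L, 1L)
    ),
    printed_tstage_total = c(T1 = 0L, T2 = 183L, T3 = 256L, T4 = 12L)
  )
}
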