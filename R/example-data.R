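#' Baseline counts from a published cN0 HNSCC training cohort
#'
#' Contingency counts of the clinical baseline characteristics of a
#' three-center head-and-neck squamous cell carcinoma cohort of clinically
#' node-negative patients (training split, n = 330), cross-tabulated against
#' pathological node status.  Shipped as a plain-text fixture; used by the
#' worked examples and the regression checks of the odds-ratio machinery.
#'
#' @return `hnsccBaselineCounts()`: data.frame with columns `variable`,
#'   `level`, `pn_neg`, `pn_pos`.
#' @examples
#' counts <- hnsccBaselineCounts()
#' sm <- subset(counts, variable == "smoking")
#' oddsRatio(sm$pn_pos[1], sm$pn_neg[1], sm$pn_pos[2], sm$pn_neg[2])
#' @export
hnsccBaselineCounts <- function() {
    read.csv(system.file("extdata", "hnscc_baseline_counts.csv",
                         package = "HabitatRadiomics"),
             stringsAsFactors = FALSE)
}

#' @rdname hnsccBaselineCounts
#' @return `hnsccCohortCounts()`: data.frame with columns `cohort`, `n`,
#'   `pn_pos` (occult-metastasis counts per cohort split).
#' @export
hnsccCohortCounts <- function() {
    read.csv(system.file("extdata", "hnscc_cohort_counts.csv",
                         package = "HabitatRadiomics"),
             stringsAsFactors = FALSE)
}
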