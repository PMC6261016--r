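# Cohort and condition filters applied to a DiagnosisMatrix before
# modelling. Each filter returns the filtered matrix plus a FilterReport so
# chained stages form an auditable manifest; no filter ever modifies a
# retained cell.

#' Remove patients with near-complete missingness
#'
#' Drops patients whose fraction of missing condition cells is greater than
#' or equal to \code{max_missing_fraction}. With the default 0.90 this is the
#' cohort rule "missing on at least 90% of the examined conditions".
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param max_missing_fraction proportion in (0, 1].
#' @return list(matrix, report).
#' @export
filterMissingPatients <- function(matrix, max_missing_fraction = 0.90) {
    stopifnot(is(matrix, "DiagnosisMatrix"),
              max_missing_fraction > 0, max_missing_fraction <= 1)
    M <- indicators(matrix)
    frac <- rowMeans(is.na(M))
    drop <- frac >= max_missing_fraction
    rep <- filterReport("filter_missing_patients", nrow(M), sum(!drop),
                        removed = rownames(M)[drop],
                        parameters = list(max_missing_fraction = max_missing_fraction))
    if (rep$n_after == 0) warning("all patients removed by missingness filter")
    list(matrix = matrix[!drop, ], report = rep)
}

#' Remove patients with no observed condition
#'
#' Drops patients whose observed cells are all 0 (patients with none of the
#' modelled conditions carry no information for the mixture model). Rows
#' consisting only of missing cells are likewise removed.
#'
#' @inheritParams filterMissingPatients
#' @return list(matrix, report).
#' @export
filterZeroConditionPatients <- function(matrix) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    M <- indicators(matrix)
    if (nrow(M) == 0) stop("empty matrix")
    any1 <- rowSums(M == 1, na.rm = TRUE) > 0
    rep <- filterReport("filter_zero_condition_patients", nrow(M), sum(any1),
                        removed = rownames(M)[!any1])
    list(matrix = matrix[any1, ], report = rep)
}

#' Drop skewed conditions by prevalence
#'
#' Removes condition columns whose prevalence among observed cells is
#' strictly below \code{min_prev} or strictly above \code{max_prev}
#' (prevalence of exactly 5\% or 95\% is retained under the default
#' "<5\% or >95\%" rule). High-prevalence columns are returned separately
#' for descriptive use.
#'
#' @inheritParams filterMissingPatients
#' @param min_prev,max_prev proportions, 0 <= min_prev < max_prev <= 1.
#' @return list(matrix, report, descriptive) where \code{descriptive} is the
#'   DiagnosisMatrix of dropped high-prevalence columns.
#' @export
filterConditionsByPrevalence <- function(matrix, min_prev = 0.05,
                                         max_prev = 0.95) {
    stopifnot(is(matrix, "DiagnosisMatrix"),
              min_prev >= 0, min_prev < max_prev, max_prev <= 1)
    prev <- conditionPrevalence(matrix)
    low <- prev < min_prev | is.nan(prev)
    high <- prev > max_prev
    keep <- !(low | high)
    if (!any(keep)) stop("all conditions dropped by prevalence filter; nothing to model")
    rep <- filterReport("filter_conditions_by_prevalence",
                        length(prev), sum(keep),
                        removed = names(prev)[!keep],
                        parameters = list(min_prev = min_prev,
                                          max_prev = max_prev))
    list(matrix = matrix[, keep], report = rep,
         descriptive = matrix[, high])
}

#' Simple random sample of patients
#'
#' Samples \code{round(fraction * n)} patients without replacement,
#' reproducibly for a given seed. Patient order of the retained rows follows
#' the input order. This mirrors downsampling a large eligible pool to a
#' computationally tractable analysis cohort.
#'
#' @inheritParams filterMissingPatients
#' @param fraction proportion in (0, 1].
#' @param seed integer seed.
#' @return list(matrix, report).
#' @export
samplePatients <- function(matrix, fraction, seed) {
    stopifnot(is(matrix, "DiagnosisMatrix"), fraction > 0, fraction <= 1)
    n <- dim(matrix)[1]
    size <- round(fraction * n)
    keep <- if (fraction == 1) seq_len(n) else {
        set.seed(.deriveSeed(seed, "sample_patients"))
        sort(sample.int(n, size))
    }
    removed <- setdiff(seq_len(n), keep)
    rep <- filterReport("sample_patients", n, length(keep),
                        removed = patientIDs(matrix)[removed],
                        parameters = list(fraction = fraction, seed = seed))
    list(matrix = matrix[keep, ], report = rep)
}
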