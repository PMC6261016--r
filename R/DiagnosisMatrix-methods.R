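#' Construct a DiagnosisMatrix
#'
#' @param indicators matrix or data.frame of 0/1/NA cells, patients in rows.
#' @param patientIDs,conditionNames optional dimnames; taken from
#'   \code{indicators} when absent.
#' @return A \code{\link{DiagnosisMatrix-class}} object.
#' @examples
#' m <- DiagnosisMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'     dimnames = list(c("P1", "P2"), c("htn", "dm"))))
#' indicators(m)
#' @export
DiagnosisMatrix <- function(indicators, patientIDs = NULL,
                            conditionNames = NULL) {
    m <- as.matrix(indicators)
    storage.mode(m) <- "double"
    if (!is.null(patientIDs)) rownames(m) <- patientIDs
    if (!is.null(conditionNames)) colnames(m) <- conditionNames
    new("DiagnosisMatrix", indicators = m)
}

#' @rdname accessors
#' @export
setMethod("indicators", "DiagnosisMatrix", function(x) x@indicators)

#' @rdname accessors
#' @export
setMethod("patientIDs", "DiagnosisMatrix",
          function(x) rownames(x@indicators))

#' @rdname accessors
#' @export
setMethod("conditionNames", "DiagnosisMatrix",
          function(x) colnames(x@indicators))

#' @describeIn DiagnosisMatrix-class patients x conditions dimensions.
#' @param x a DiagnosisMatrix.
#' @export
setMethod("dim", "DiagnosisMatrix", function(x) dim(x@indicators))

#' @describeIn DiagnosisMatrix-class subset patients (i) and/or
#'   conditions (j); always keeps the matrix structure.
#' @param i,j patient / condition indices (numeric, logical or names).
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "DiagnosisMatrix", function(x, i, j, ..., drop = FALSE) {
    m <- x@indicators
    if (!missing(i)) m <- m[i, , drop = FALSE]
    if (!missing(j)) m <- m[, j, drop = FALSE]
    new("DiagnosisMatrix", indicators = m)
})

setMethod("show", "DiagnosisMatrix", function(object) {
    m <- object@indicators
    nmiss <- sum(is.na(m))
    cat(sprintf("DiagnosisMatrix: %d patients x %d conditions (%d missing cells)\n",
                nrow(m), ncol(m), nmiss))
    if (ncol(m) > 0 && nrow(m) > 0) {
        prev <- round(100 * colMeans(m == 1, na.rm = TRUE), 1)
        shown <- utils::head(prev, 8)
        cat("  prevalence (%):",
            paste(sprintf("%s=%s", names(shown), shown), collapse = ", "),
            if (ncol(m) > 8) "..." else "", "\n")
    }
})

#' Per-condition sample prevalence
#'
#' Prevalence is the proportion of 1s among *observed* (non-missing) cells,
#' the convention used by the prevalence filter and by the Guttman item
#' ordering.
#'
#' @param x a DiagnosisMatrix.
#' @return Named numeric vector, one entry per condition (NaN for a
#'   condition with no observed cells).
#' @export
conditionPrevalence <- function(x) {
    stopifnot(is(x, "DiagnosisMatrix"))
    colMeans(indicators(x) == 1, na.rm = TRUE)
}
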