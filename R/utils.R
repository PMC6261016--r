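# Internal numerical helpers shared across modules.

# Numerically stable logistic; exact 0/1 in the tails instead of NaN.
.logistic <- function(x) {
    out <- numeric(length(x))
    pos <- x >= 0
    out[pos] <- 1 / (1 + exp(-x[pos]))
    ex <- exp(x[!pos])
    out[!pos] <- ex / (1 + ex)
    dim(out) <- dim(x)
    out
}

# log(1 + exp(x)) without overflow.
.log1pexp <- function(x) {
    out <- numeric(length(x))
    big <- x > 35
    out[big] <- x[big]
    out[!big] <- log1p(exp(x[!big]))
    dim(out) <- dim(x)
    out
}

# Gauss-Hermite nodes/weights rescaled for a standard normal density:
# integral f(t) dN(0,1)(t) ~ sum w_q f(z_q).
.ghNormal <- function(n) {
    gh <- pracma::gaussHermite(n)
    list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Deterministic stage seed derived from a global seed; stays well below 2^31.
.deriveSeed <- function(seed, stage) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.double(seed) * 7919 + offs) %% 2147483629)
}

# Collapse response rows (with NA) to unique patterns with counts.
# Returns list(X = unique pattern matrix, counts, index = pattern id per row).
.collapsePatterns <- function(X) {
    key <- apply(X, 1L, function(r) paste(ifelse(is.na(r), "m", r),
                                          collapse = ""))
    ids <- match(key, unique(key))
    keep <- !duplicated(ids)
    list(X = X[keep, , drop = FALSE],
         counts = as.numeric(tabulate(ids, max(ids))),
         index = ids)
}

# Descending-prevalence item order, ties broken alphabetically.
.prevalenceOrder <- function(X) {
    prev <- colMeans(X == 1, na.rm = TRUE)
    nms <- colnames(X)
    nms[order(-prev, nms)]
}

#' Build a filter report
#'
#' Every preprocessing and person-fit stage returns one of these records so
#' that chained stages form an auditable pipeline manifest: each report's
#' \code{n_after} equals \code{n_before - length(removed)}.
#'
#' @param stage label of the pipeline stage.
#' @param n_before,n_after entity counts before/after.
#' @param removed character vector of removed patient ids or condition names.
#' @param parameters named list of threshold values used.
#' @return A list with class \code{"FilterReport"}.
#' @export
filterReport <- function(stage, n_before, n_after, removed = character(),
                         parameters = list()) {
    stopifnot(n_after == n_before - length(removed))
    structure(list(stage = stage, n_before = n_before, n_after = n_after,
                   removed = as.character(removed), parameters = parameters),
              class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
    cat(sprintf("FilterReport [%s]: %d -> %d (removed %d)\n",
                x$stage, x$n_before, x$n_after, length(x$removed)))
    invisible(x)
}
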