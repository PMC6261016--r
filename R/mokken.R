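# Within-subgroup scaling diagnostics: Loevinger's H, restscore
# monotonicity, iterative item selection, and Guttman-error person fit.
#
# The cumulative ("Guttman") ordering places more prevalent conditions
# before rarer ones: a patient who has a rare condition but lacks a more
# common one commits a Guttman error. Loevinger's H for an item pair is
# 1 - F/E, the observed Guttman-error cell count F relative to its
# expectation E under marginal independence.

#' Cumulative item ordering by prevalence
#'
#' Items sorted by descending sample prevalence (observed cells only), ties
#' broken alphabetically. This is the ordering used for Guttman-error
#' counting.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @return Character vector of condition names.
#' @export
prevalenceOrder <- function(matrix) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    .prevalenceOrder(indicators(matrix))
}

#' Pairwise Loevinger H coefficients
#'
#' For items i (more prevalent) and j (less prevalent),
#' H_ij = 1 - F_ij / E_ij with F_ij the number of patients having j but not
#' i and E_ij = n * P(x_i = 0) * P(x_j = 1) from the marginals. Patients
#' missing either item are dropped pairwise. Pairs with a degenerate
#' marginal (E_ij = 0) are returned as NA and excluded from aggregates.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}} with >= 2 items and
#'   >= 2 patients.
#' @return Symmetric item x item matrix of H coefficients (NA diagonal).
#' @export
pairwiseH <- function(matrix) {
    fe <- .pairwiseFE(indicators(matrix))
    H <- 1 - fe$F / fe$E
    H[fe$E == 0] <- NA
    diag(H) <- NA
    H
}

# Observed (F) and expected (E) Guttman-error cell counts for all pairs.
# F[i,j] = F[j,i] = errors for the pair; stored symmetrically.
.pairwiseFE <- function(X) {
    I <- ncol(X)
    if (I < 2 || nrow(X) < 2) stop("need >= 2 items and >= 2 patients")
    Fm <- Em <- matrix(0, I, I, dimnames = list(colnames(X), colnames(X)))
    for (i in seq_len(I - 1)) for (j in (i + 1):I) {
        ok <- !is.na(X[, i]) & !is.na(X[, j])
        xi <- X[ok, i]; xj <- X[ok, j]
        n <- length(xi)
        if (n == 0) { Em[i, j] <- Em[j, i] <- 0; next }
        pi1 <- mean(xi); pj1 <- mean(xj)
        # the more prevalent item plays the "easier" role (ties: first)
        if (pi1 >= pj1) {
            f <- sum(xi == 0 & xj == 1)
            e <- n * (1 - pi1) * pj1
        } else {
            f <- sum(xj == 0 & xi == 1)
            e <- n * (1 - pj1) * pi1
        }
        Fm[i, j] <- Fm[j, i] <- f
        Em[i, j] <- Em[j, i] <- e
    }
    list(F = Fm, E = Em)
}

#' Item and scale Loevinger H
#'
#' H_item_j = 1 - sum_i F_ij / sum_i E_ij over partners i, and
#' H_scale = 1 - sum of all F / sum of all E. Conventional verdict bands:
#' a scale is acceptable from H >= 0.3, moderate from 0.4, strong from 0.5.
#'
#' @inheritParams pairwiseH
#' @return A \code{\link{ScaleResult-class}} (selection fields hold all
#'   items; see \code{\link{selectScaleItems}} for screening).
#' @export
scaleH <- function(matrix) {
    X <- indicators(matrix)
    fe <- .pairwiseFE(X)
    ok <- fe$E > 0
    Hpair <- 1 - fe$F / fe$E
    Hpair[!ok] <- NA
    diag(Hpair) <- NA
    sumF <- rowSums(fe$F * ok)
    sumE <- rowSums(fe$E * ok)
    Hitem <- ifelse(sumE > 0, 1 - sumF / sumE, NA_real_)
    names(Hitem) <- colnames(X)
    tot <- sum(fe$E[upper.tri(fe$E)][ok[upper.tri(ok)]])
    Hscale <- if (tot > 0)
        1 - sum(fe$F[upper.tri(fe$F)][ok[upper.tri(ok)]]) / tot
    else NA_real_
    new("ScaleResult",
        itemOrder = .prevalenceOrder(X),
        Hpair = Hpair, Hitem = Hitem, Hscale = Hscale,
        monotonicity = data.frame(),
        selectedItems = colnames(X),
        audit = data.frame(step = integer(), item = character(),
                           reason = character(), value = numeric(),
                           stringsAsFactors = FALSE))
}

setMethod("show", "ScaleResult", function(object) {
    cat(sprintf("ScaleResult: %d item(s) selected of %d, H_scale = %s\n",
                length(object@selectedItems), length(object@Hitem),
                format(round(object@Hscale, 3))))
})

#' @rdname accessors
#' @export
setMethod("selectedItems", "ScaleResult", function(x) x@selectedItems)

#' Restscore monotonicity check for one item
#'
#' Orders patients by restscore (number of *other* conditions present),
#' merges adjacent restscore groups smaller than \code{min_group_size}, and
#' tests every ordered pair of groups for a significant *decrease* in the
#' item's prevalence (one-sided two-proportion z-test at level
#' \code{alpha}). Under monotone homogeneity the trace line must be
#' non-decreasing, so any significant decrease is a violation.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param item condition name or index.
#' @param min_group_size minimum patients per restscore group (default 50).
#' @param alpha test level (default 0.05).
#' @return list: \code{verdict} ("ok", "violation" or "indeterminate"),
#'   \code{violations} (count of significant decreases), \code{groups}
#'   (data.frame restscore range, n, prevalence).
#' @export
checkMonotonicity <- function(matrix, item, min_group_size = 50,
                              alpha = 0.05) {
    X <- indicators(matrix)
    if (is.character(item)) {
        if (!item %in% colnames(X)) stop("unknown item: ", item)
        item <- match(item, colnames(X))
    }
    x <- X[, item]
    rest <- rowSums(X[, -item, drop = FALSE] == 1, na.rm = TRUE)
    keep <- !is.na(x)
    x <- x[keep]; rest <- rest[keep]
    lev <- sort(unique(rest))
    grp <- match(rest, lev)
    # merge adjacent groups (low to high) until each reaches min_group_size
    sizes <- tabulate(grp, length(lev))
    bounds <- list(); cur <- integer()
    for (g in seq_along(lev)) {
        cur <- c(cur, g)
        if (sum(sizes[cur]) >= min_group_size) { bounds <- c(bounds, list(cur)); cur <- integer() }
    }
    if (length(cur)) {
        if (length(bounds)) bounds[[length(bounds)]] <-
            c(bounds[[length(bounds)]], cur)
        else bounds <- list(cur)
    }
    gi <- integer(length(grp))
    for (b in seq_along(bounds)) gi[grp %in% bounds[[b]]] <- b
    G <- length(bounds)
    if (G < 2)
        return(list(verdict = "indeterminate", violations = NA_integer_,
                    groups = data.frame()))
    ng <- tabulate(gi, G)
    pg <- vapply(seq_len(G), function(g) mean(x[gi == g]), numeric(1))
    viol <- 0L
    for (g in seq_len(G - 1)) for (h in (g + 1):G) {
        # one-sided z-test for p_g > p_h (a decrease along the trace line)
        pp <- (pg[g] * ng[g] + pg[h] * ng[h]) / (ng[g] + ng[h])
        se <- sqrt(pp * (1 - pp) * (1 / ng[g] + 1 / ng[h]))
        if (se == 0) next
        z <- (pg[g] - pg[h]) / se
        if (stats::pnorm(z, lower.tail = FALSE) < alpha) viol <- viol + 1L
    }
    list(verdict = if (viol > 0) "violation" else "ok",
         violations = viol,
         groups = data.frame(
             restscore_min = vapply(bounds, function(b) lev[min(b)], numeric(1)),
             restscore_max = vapply(bounds, function(b) lev[max(b)], numeric(1)),
             n = ng, prevalence = pg))
}

#' Iterative Mokken item selection
#'
#' First removes monotonicity violators (re-checking after each removal),
#' then items with H_item below \code{H_min} (lowest first, recomputing the
#' coefficients after each removal). Errors if fewer than two items survive,
#' in which case the subgroup should be handled descriptively.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}} (>= 2 items).
#' @param H_min minimum acceptable item H (default 0.3, the conventional
#'   lower bound for a usable scale).
#' @param min_group_size,alpha monotonicity settings
#'   (\code{\link{checkMonotonicity}}).
#' @return A \code{\link{ScaleResult-class}} with the surviving items and an
#'   audit trail of removals.
#' @export
selectScaleItems <- function(matrix, H_min = 0.3, min_group_size = 50,
                             alpha = 0.05) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    cur <- matrix
    audit <- data.frame(step = integer(), item = character(),
                        reason = character(), value = numeric(),
                        stringsAsFactors = FALSE)
    step <- 0L
    monot_tab <- NULL
    repeat {  # monotonicity screening
        if (dim(cur)[2] < 2)
            stop("fewer than 2 items survive Mokken selection; handle this subgroup descriptively")
        checks <- lapply(conditionNames(cur), function(it)
            checkMonotonicity(cur, it, min_group_size, alpha))
        monot_tab <- data.frame(
            item = conditionNames(cur),
            violations = vapply(checks, function(k)
                as.integer(k$violations), integer(1)),
            verdict = vapply(checks, function(k) k$verdict, character(1)),
            stringsAsFactors = FALSE)
        bad <- which(monot_tab$verdict == "violation")
        if (!length(bad)) break
        worst <- bad[which.max(monot_tab$violations[bad])]
        step <- step + 1L
        audit <- rbind(audit, data.frame(
            step = step, item = monot_tab$item[worst],
            reason = "monotonicity violation",
            value = monot_tab$violations[worst]))
        cur <- cur[, setdiff(conditionNames(cur), monot_tab$item[worst])]
    }
    repeat {  # scalability screening
        if (dim(cur)[2] < 2)
            stop("fewer than 2 items survive Mokken selection; handle this subgroup descriptively")
        sr <- scaleH(cur)
        low <- which(!is.na(sr@Hitem) & sr@Hitem < H_min)
        if (!length(low)) {
            res <- sr
            break
        }
        worst <- low[which.min(sr@Hitem[low])]
        step <- step + 1L
        audit <- rbind(audit, data.frame(
            step = step, item = names(sr@Hitem)[worst],
            reason = sprintf("H_item < %g", H_min),
            value = unname(sr@Hitem[worst])))
        cur <- cur[, setdiff(conditionNames(cur), names(sr@Hitem)[worst])]
    }
    new("ScaleResult",
        itemOrder = res@itemOrder, Hpair = res@Hpair, Hitem = res@Hitem,
        Hscale = res@Hscale,
        monotonicity = monot_tab[monot_tab$item %in% conditionNames(cur), ],
        selectedItems = conditionNames(cur), audit = audit)
}

#' Count Guttman errors in one response pattern
#'
#' Number of ordered item pairs (i before j in the cumulative ordering) with
#' x_i = 0 and x_j = 1: the patient has the rarer condition but lacks the
#' more common one. Missing entries are skipped pairwise, so appending items
#' the patient is missing never changes the count.
#'
#' @param pattern binary vector (with optional NAs) aligned to
#'   \code{item_order}.
#' @param item_order optional explicit ordering (names or indices); by
#'   default the pattern is assumed already in cumulative (descending
#'   prevalence) order.
#' @return Non-negative integer, at most I*(I-1)/2.
#' @examples
#' guttmanErrors(c(htn = 0, chf = 1))  # has CHF but not HTN: 1 error
#' @export
guttmanErrors <- function(pattern, item_order = NULL) {
    x <- if (is.null(item_order)) pattern
         else pattern[item_order]
    obs <- which(!is.na(x))
    if (length(obs) < 2) return(0L)
    x <- x[obs]
    # errors = for each 1, the number of observed 0s before it
    zeros_before <- cumsum(x == 0)
    sum(zeros_before[x == 1])
}

#' Guttman-error person-fit filter
#'
#' Counts each patient's Guttman errors under the cumulative item ordering
#' and retains patients with at most \code{max_errors} (default 1: patients
#' with more than one error are classed as ill-fitting and excluded).
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param item_order explicit cumulative ordering (condition names); by
#'   default descending sample prevalence with alphabetical tie-break.
#' @param max_errors tolerated error count (default 1).
#' @return list: \code{matrix} (retained patients), \code{person_fit}
#'   (data.frame patient_id, guttman_errors, included), \code{report}
#'   (\code{\link{filterReport}} with the retained fraction).
#' @export
personFitFilter <- function(matrix, item_order = NULL, max_errors = 1) {
    stopifnot(is(matrix, "DiagnosisMatrix"), max_errors >= 0)
    X <- indicators(matrix)
    if (is.null(item_order)) item_order <- .prevalenceOrder(X)
    Xo <- X[, item_order, drop = FALSE]
    errs <- apply(Xo, 1, guttmanErrors)
    inc <- errs <= max_errors
    pf <- data.frame(patient_id = rownames(X), guttman_errors = errs,
                     included = inc, row.names = NULL,
                     stringsAsFactors = FALSE)
    rep <- filterReport("person_fit_filter", nrow(X), sum(inc),
                        removed = rownames(X)[!inc],
                        parameters = list(max_errors = max_errors,
                                          retained_fraction = mean(inc),
                                          item_order = item_order))
    list(matrix = matrix[inc, ], person_fit = pf, report = rep)
}
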