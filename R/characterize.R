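# Subgroup characterization on demographic/utilization covariates:
# dichotomization, model-based predicted probabilities with confidence
# intervals, Scheffe-corrected equivalence letters, and descriptive tables.

#' Dichotomize a categorical covariate
#'
#' Default rule \code{"modal_vs_rest"}: the most populated category maps to
#' 1 and every other category (including "unknown") to 0, the convention
#' used when finer categories are too sparse for modelling. An explicit
#' mapping (character vector of categories that map to 1) overrides the
#' rule; a modal tie is an error that requires one.
#'
#' @param raw vector/factor of categories.
#' @param rule \code{"modal_vs_rest"} or a character vector of positive
#'   categories.
#' @return Integer 0/1 vector (NAs preserved).
#' @examples
#' dichotomize(c("married", "divorced", "married", "single"))
#' dichotomize(c("65-74", "18-54", "85+"), rule = c("65-74", "75-84", "85+"))
#' @export
dichotomize <- function(raw, rule = "modal_vs_rest") {
    if (!length(raw)) stop("empty covariate column")
    x <- as.character(raw)
    if (length(rule) == 1 && rule == "modal_vs_rest") {
        tab <- sort(table(x), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2])
            stop("modal tie between categories '", names(tab)[1], "' and '",
                 names(tab)[2], "'; supply an explicit mapping")
        pos <- names(tab)[1]
    } else pos <- rule
    out <- as.integer(x %in% pos)
    out[is.na(raw)] <- NA_integer_
    out
}

#' Per-class predicted probability of a binary covariate
#'
#' Fits a multinomial logistic model for class membership with the covariate
#' as predictor and recovers, as model-based margins, each class's predicted
#' probability of the covariate's positive category. In this saturated
#' single-covariate case the margin equals the class-conditional sample
#' proportion exactly; confidence intervals use large-sample standard
#' errors on the logit scale, back-transformed. A class where the covariate
#' is constant (separation) is flagged and its interval widened to [0, 1].
#'
#' @param assignments integer/factor vector of modal class memberships.
#' @param covariate aligned binary (0/1) vector; NAs dropped pairwise.
#' @param alpha interval level parameter (default 0.05 for 95\% CIs).
#' @return data.frame: class, n, pp, lower, upper, se (delta-method SE on
#'   the probability scale), flag.
#' @export
fitCharacterization <- function(assignments, covariate, alpha = 0.05) {
    ok <- !is.na(assignments) & !is.na(covariate)
    cls <- as.integer(as.factor(assignments[ok]))
    lv <- sort(unique(as.integer(as.factor(assignments[ok]))))
    labels <- levels(as.factor(assignments[ok]))
    x <- covariate[ok]
    if (length(unique(cls)) < 2) stop("need >= 2 classes present")
    if (length(unique(x)) < 2)
        stop("covariate is constant; nothing to characterize")
    # class-membership model (margins recovered below via Bayes inversion)
    mfit <- nnet::multinom(factor(cls) ~ x, trace = FALSE,
                           maxit = 1000, reltol = 1e-13)
    pred <- stats::predict(mfit, newdata = data.frame(x = c(0, 1)),
                           type = "probs")
    if (is.null(dim(pred))) pred <- cbind(1 - pred, pred)  # K=2 case
    px <- mean(x)
    pclass <- pred[1, ] * (1 - px) + pred[2, ] * px
    pp <- pred[2, ] * px / pclass
    z <- stats::qnorm(1 - alpha / 2)
    out <- lapply(seq_along(lv), function(i) {
        nk <- sum(cls == lv[i])
        p <- pp[i]
        prop <- mean(x[cls == lv[i]])
        flag <- ""
        if (prop %in% c(0, 1)) p <- prop  # boundary MLE (separation)
        if (p <= 0 || p >= 1) {
            flag <- "degenerate (separation)"
            lo <- 0; hi <- 1; se <- NA_real_
        } else {
            se_logit <- 1 / sqrt(nk * p * (1 - p))
            lo <- stats::plogis(stats::qlogis(p) - z * se_logit)
            hi <- stats::plogis(stats::qlogis(p) + z * se_logit)
            se <- sqrt(p * (1 - p) / nk)
        }
        data.frame(class = labels[i], n = nk, pp = p, lower = lo,
                   upper = hi, se = se, flag = flag,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Scheffe-corrected equivalence letters across classes
#'
#' Tests all pairwise contrasts of per-class predicted probabilities with
#' the Scheffe critical value sqrt((K-1) * chi2_{K-1, 1-alpha}) applied to
#' the contrast z-statistics, then assigns compact letters so that classes
#' sharing a letter are pairwise non-significant after correction (standard
#' insert-absorb letter display; letters follow class order).
#'
#' @param pps data.frame from \code{\link{fitCharacterization}} (columns
#'   class, pp, se).
#' @param alpha familywise level (default 0.05).
#' @return The input data.frame with a \code{letters} column appended.
#' @export
scheffeGroups <- function(pps, alpha = 0.05) {
    K <- nrow(pps)
    if (K < 2) stop("need >= 2 classes")
    crit <- sqrt((K - 1) * stats::qchisq(1 - alpha, K - 1))
    nonsig <- matrix(TRUE, K, K)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        se2 <- pps$se[i]^2 + pps$se[j]^2
        zstat <- if (is.na(se2) || se2 == 0) {
            if (abs(pps$pp[i] - pps$pp[j]) < 1e-12) 0 else Inf
        } else abs(pps$pp[i] - pps$pp[j]) / sqrt(se2)
        nonsig[i, j] <- nonsig[j, i] <- zstat <= crit
    }
    pps$letters <- .letterDisplay(nonsig)
    pps
}

# Insert-absorb compact letter display over a symmetric non-significance
# relation; guarantees classes sharing a letter are pairwise non-significant.
.letterDisplay <- function(nonsig) {
    K <- nrow(nonsig)
    groups <- list(1L)
    for (k in 2:K) {
        placed <- FALSE
        for (g in seq_along(groups)) {
            if (all(nonsig[k, groups[[g]]])) {
                groups[[g]] <- c(groups[[g]], k)
                placed <- TRUE
            }
        }
        if (!placed) {
            # largest compatible subset of an existing group, plus k
            best <- integer()
            for (g in seq_along(groups)) {
                comp <- groups[[g]][nonsig[k, groups[[g]]]]
                if (length(comp) > length(best)) best <- comp
            }
            groups <- c(groups, list(sort(c(best, k))))
        }
    }
    # absorb groups contained in others
    keep <- rep(TRUE, length(groups))
    for (g in seq_along(groups)) for (h in seq_along(groups))
        if (g != h && keep[g] && keep[h] &&
            all(groups[[g]] %in% groups[[h]])) keep[g] <- FALSE
    groups <- groups[keep]
    # order groups by their first class, assign letters in class order
    groups <- groups[order(vapply(groups, min, integer(1)))]
    out <- character(K)
    for (g in seq_along(groups))
        out[groups[[g]]] <- paste0(out[groups[[g]]], LETTERS[g])
    out
}

#' Descriptive class-by-category table
#'
#' Per class and category of each categorical covariate: percentage and
#' count, formatted "19.3% (1,802)". Percentages within one covariate sum
#' to 100 (up to rounding) in every class. Empty classes are omitted with a
#' warning.
#'
#' @param assignments vector of modal class memberships.
#' @param covariates data.frame of raw categorical covariates aligned to
#'   \code{assignments}.
#' @return data.frame: class, variable, category, n, pct, label.
#' @export
descriptiveTable <- function(assignments, covariates) {
    stopifnot(nrow(covariates) == length(assignments))
    cls <- as.factor(assignments)
    empty <- levels(cls)[table(cls) == 0]
    if (length(empty))
        warning("empty class(es) omitted: ", paste(empty, collapse = ", "))
    rows <- list()
    for (v in names(covariates)) {
        x <- as.character(covariates[[v]])
        for (k in levels(cls)[table(cls) > 0]) {
            sel <- cls == k & !is.na(x)
            nk <- sum(sel)
            for (cat in sort(unique(x[!is.na(x)]))) {
                n <- sum(x[sel] == cat)
                pct <- 100 * n / nk
                rows[[length(rows) + 1L]] <- data.frame(
                    class = k, variable = v, category = cat, n = n,
                    pct = pct,
                    label = sprintf("%.1f%% (%s)", pct,
                                    format(n, big.mark = ",", trim = TRUE)),
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}

#' Characterize all covariates across classes
#'
#' Convenience wrapper running \code{\link{fitCharacterization}} and
#' \code{\link{scheffeGroups}} for every binary covariate column.
#'
#' @param assignments vector of modal class memberships.
#' @param covariates data.frame of binary covariates (a patient_id column,
#'   if present, is ignored).
#' @param alpha level for intervals and the Scheffe correction.
#' @return data.frame: covariate, class, n, pp, lower, upper, se, flag,
#'   letters.
#' @export
characterizeClasses <- function(assignments, covariates, alpha = 0.05) {
    cols <- setdiff(names(covariates), "patient_id")
    out <- lapply(cols, function(v) {
        res <- scheffeGroups(
            fitCharacterization(assignments, covariates[[v]], alpha), alpha)
        cbind(covariate = v, res, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
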