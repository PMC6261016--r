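# Subgroup-specific 1PL/2PL calibration on Mokken-selected items, model
# choice between them, and item-characteristic-curve profiles.
#
# Scale identification: the 1PL fixes the common discrimination (1.7 by
# default) and estimates the trait SD; the 2PL estimates item slopes and
# fixes the trait SD to 1. Both centre difficulties to sum zero and
# estimate the trait mean.

.subgroupConfig <- function(config = list()) {
    def <- list(max_iter = 500L, tol = 1e-6, quadrature = 21L, seed = 1L,
                n_starts = 1L)
    def[names(config)] <- config
    def
}

.fitSubgroup <- function(matrix, model_type, a, config) {
    cfg <- .subgroupConfig(config)
    dat <- .prepareResponseData(matrix)
    if (dat$n < 2) stop("insufficient data: need more than one patient")
    if (dat$I < 2) stop("need >= 2 items")
    if (dat$n < 50)
        warning("fewer than 50 patients; estimates may be unstable")
    const_col <- apply(dat$Robs == dat$X1, 2, all) |
        apply(dat$Robs == dat$X0, 2, all)
    if (any(const_col)) {
        warning("dropping all-identical response column(s): ",
                paste(dat$items[const_col], collapse = ", "))
        matrix <- matrix[, !const_col]
        dat <- .prepareResponseData(matrix)
        if (dat$I < 2) stop("need >= 2 informative items")
    }
    gh <- .ghNormal(cfg$quadrature)
    prev <- pmin(pmax(colSums(dat$X1 * dat$counts) /
                      pmax(colSums(dat$Robs * dat$counts), 1), 0.02), 0.98)
    est_slopes <- model_type == "2PL"
    st <- list(pi = 1,
               beta = rbind(-stats::qlogis(prev) / a),
               mu = 0, sigma = 1,
               slopes = rep(a, dat$I))
    m <- mean(st$beta[1, ]); st$beta[1, ] <- st$beta[1, ] - m; st$mu <- -m
    run <- .emRun(st, dat$X1, dat$X0, dat$Robs, dat$counts, gh,
                  est_slopes = est_slopes, est_sigma = !est_slopes,
                  max_iter = cfg$max_iter, tol = cfg$tol)
    if (!run$converged)
        warning(sprintf("%s EM did not converge in %d iterations",
                        model_type, cfg$max_iter))
    slopes <- run$state$slopes
    if (est_slopes && any(slopes <= 0.2 + 1e-6 | slopes >= 5 - 1e-6))
        warning("slope estimate(s) pinned at the [0.2, 5] boundary")
    I <- dat$I
    k <- if (est_slopes) (I - 1) + I + 2 else (I - 1) + 2
    fit <- modelFit(-2 * run$ll, k, dat$n)
    new("SubgroupIRTModel",
        modelType = model_type,
        itemNames = dat$items,
        difficulties = stats::setNames(run$state$beta[1, ], dat$items),
        discriminations = stats::setNames(slopes, dat$items),
        mu = run$state$mu[1], sigma = run$state$sigma[1],
        fit = fit,
        logLikTrace = run$trace,
        converged = run$converged,
        iterations = run$iterations)
}

#' Fit a subgroup 1PL (Rasch) model
#'
#' Marginal-maximum-likelihood EM with the common discrimination fixed at
#' \code{a} (1.7 = Rasch convention); difficulties are sum-zero and the
#' latent-trait mean and SD are estimated. Parameter count
#' k = (I - 1) + 2.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}} of the subgroup's
#'   fit-retained patients and Mokken-selected items (>= 2 items; a warning
#'   is issued below 50 patients).
#' @param a fixed common discrimination.
#' @param config list overriding \code{max_iter} (500), \code{tol} (1e-6),
#'   \code{quadrature} (21), \code{seed} (1).
#' @return A \code{\link{SubgroupIRTModel-class}}.
#' @export
fit1PL <- function(matrix, a = 1.7, config = list()) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    if (a <= 0) stop("discrimination 'a' must be positive")
    .fitSubgroup(matrix, "1PL", a, config)
}

#' Fit a subgroup 2PL model
#'
#' Estimates item-specific discriminations jointly with difficulties; the
#' trait SD is fixed to 1 for slope identifiability and slopes are bounded
#' to [0.2, 5] to prevent divergence (boundary-pinned slopes are flagged).
#' Parameter count k = (I - 1) + I + 2.
#'
#' @inheritParams fit1PL
#' @param start_a initial common slope value.
#' @return A \code{\link{SubgroupIRTModel-class}}.
#' @export
fit2PL <- function(matrix, start_a = 1.7, config = list()) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    .fitSubgroup(matrix, "2PL", start_a, config)
}

setMethod("show", "SubgroupIRTModel", function(object) {
    cat(sprintf("SubgroupIRTModel (%s): %d items, mu = %.3f, sigma = %.3f\n",
                object@modelType, length(object@itemNames),
                object@mu, object@sigma))
    show(object@fit)
})

#' @rdname accessors
#' @export
setMethod("difficulties", "SubgroupIRTModel",
          function(x) x@difficulties)
#' @rdname accessors
#' @export
setMethod("discrimination", "SubgroupIRTModel",
          function(x) x@discriminations)
#' @rdname accessors
#' @export
setMethod("bicOf", "SubgroupIRTModel", function(x) x@fit@BIC)

#' Choose between subgroup 1PL and 2PL calibrations
#'
#' Default criterion: lower BIC wins (the 2PL must buy its extra slope
#' parameters with likelihood). Also reported: the slope dispersion of the
#' 2PL (max/min ratio - the informal "are the separate slopes similar
#' enough" diagnostic) and the likelihood-ratio statistic.
#'
#' @param m1 a 1PL \code{\link{SubgroupIRTModel-class}}.
#' @param m2 a 2PL fit on the same items and patients.
#' @return list: \code{chosen} ("1PL"/"2PL"), \code{bic_1pl},
#'   \code{bic_2pl}, \code{slope_ratio}, \code{lr_stat}, \code{lr_df}.
#' @export
compare1PL2PL <- function(m1, m2) {
    stopifnot(is(m1, "SubgroupIRTModel"), is(m2, "SubgroupIRTModel"))
    if (!identical(m1@itemNames, m2@itemNames))
        stop("models were fitted on different items")
    if (m1@fit@n != m2@fit@n)
        stop("models were fitted on different patient counts")
    lr <- m1@fit@minus2LL - m2@fit@minus2LL
    list(chosen = if (bicOf(m2) < bicOf(m1)) "2PL" else "1PL",
         bic_1pl = bicOf(m1), bic_2pl = bicOf(m2),
         slope_ratio = max(m2@discriminations) / min(m2@discriminations),
         lr_stat = lr, lr_df = m2@fit@k - m1@fit@k)
}

#' Item characteristic curve profile
#'
#' Evaluates every item's response curve on a theta grid. Each item's
#' location (the theta at which the curve crosses probability 0.5) equals
#' its difficulty exactly; curves are non-decreasing in theta and bounded
#' in (0, 1). Suitable for plotting and for cross-subgroup location
#' comparison tables.
#'
#' @param model a \code{\link{SubgroupIRTModel-class}}.
#' @param theta_range length-2 interval (default c(-4, 4)).
#' @param n_points grid size (>= 2, default 101).
#' @return list: \code{theta} (grid), \code{curves} (grid x items
#'   probability matrix), \code{locations} (named vector, = difficulties).
#' @export
iccProfile <- function(model, theta_range = c(-4, 4), n_points = 101) {
    stopifnot(is(model, "SubgroupIRTModel"), n_points >= 2)
    grid <- seq(theta_range[1], theta_range[2], length.out = n_points)
    curves <- vapply(seq_along(model@itemNames), function(i)
        responseProbability(grid, model@difficulties[i],
                            model@discriminations[i]),
        numeric(n_points))
    colnames(curves) <- model@itemNames
    list(theta = grid, curves = curves, locations = model@difficulties)
}
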