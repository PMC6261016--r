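# Mixture-distribution Rasch estimation by marginal maximum likelihood.
#
# Model: person p in latent class c with trait theta has
#   P(x_pi = 1) = logistic(a * (theta - beta_ic)),   theta | c ~ N(mu_c, sigma_c^2),
# with class probabilities pi_c and a common discrimination a (1.7 by
# default, the Rasch convention). The marginal likelihood integrates theta
# by Gauss-Hermite quadrature and sums over classes; estimation is a
# generalized EM whose M-step runs coordinate Newton updates on the
# complete-data objective, which is jointly concave in (beta, mu, sigma,
# slopes) because all of them enter through a linear predictor. A
# step-halving guard makes the quadrature log-likelihood provably
# non-decreasing across iterations.

#' Item response probability
#'
#' \code{logistic(a * (theta - beta))}: the probability that a person at
#' complexity \code{theta} has a condition located at \code{beta}. At
#' \code{theta == beta} the probability is exactly 0.5 for any
#' discrimination. Numerically stable over the whole double range.
#'
#' @param theta person complexity (vectorized).
#' @param beta item location (vectorized).
#' @param a positive discrimination (default 1.7).
#' @return Probabilities in [0, 1].
#' @examples
#' responseProbability(0.8, 0.8)        # 0.5
#' responseProbability(log(3), 0, a = 1)  # 0.75
#' @export
responseProbability <- function(theta, beta, a = 1.7) {
    if (any(a <= 0)) stop("discrimination 'a' must be positive")
    .logistic(a * (theta - beta))
}

#' Probability of a full response pattern
#'
#' Product over observed items of \code{responseProbability} (for x_i = 1)
#' or its complement (x_i = 0); missing entries are skipped, so an
#' all-missing pattern has probability 1 (empty product).
#'
#' @param x binary vector with optional NAs.
#' @param theta scalar person complexity.
#' @param beta item location vector, same length as \code{x}.
#' @param a positive discrimination.
#' @return Probability in (0, 1].
#' @export
patternProbability <- function(x, theta, beta, a = 1.7) {
    if (length(x) != length(beta))
        stop("dimension error: x and beta must have the same length")
    obs <- !is.na(x)
    p <- responseProbability(theta, beta[obs], a)
    prod(ifelse(x[obs] == 1, p, 1 - p))
}

# --- internal engine -------------------------------------------------------

# Per-class pattern log-likelihood matrix (patterns x Q).
.classPatternLL <- function(X1, X0, beta_c, mu_c, sigma_c, slopes, z) {
    theta <- mu_c + sigma_c * z                       # Q
    eta <- slopes * outer(rep(1, length(beta_c)), theta) -
        slopes * beta_c                               # I x Q
    logp <- -.log1pexp(-eta)
    logq <- -.log1pexp(eta)
    X1 %*% logp + X0 %*% logq
}

.stateLogLik <- function(st, X1, X0, counts, gh) {
    C <- length(st$pi)
    npat <- nrow(X1)
    Q <- length(gh$z)
    A <- matrix(-Inf, npat, C * Q)
    for (c in seq_len(C)) {
        L <- .classPatternLL(X1, X0, st$beta[c, ], st$mu[c], st$sigma[c],
                             st$slopes, gh$z)
        A[, (c - 1) * Q + seq_len(Q)] <-
            sweep(L, 2, log(gh$w), `+`) + log(st$pi[c])
    }
    m <- apply(A, 1, max)
    llp <- m + log(rowSums(exp(A - m)))
    list(ll = sum(counts * llp), A = A, llp = llp)
}

# One GEM iteration; returns updated state.
.mStep <- function(st, R, X1, X0, Robs, counts, gh, est_slopes, est_sigma,
                   n_inner = 3L) {
    C <- length(st$pi)
    Q <- length(gh$z)
    n <- sum(counts)
    for (c in seq_len(C)) {
        rc <- R[, (c - 1) * Q + seq_len(Q), drop = FALSE]  # patterns x Q
        Nc <- crossprod(Robs, rc)                          # I x Q
        R1 <- crossprod(X1, rc)                            # I x Q
        sR1 <- rowSums(R1)
        for (it in seq_len(n_inner)) {
            theta <- st$mu[c] + st$sigma[c] * gh$z
            eta <- st$slopes * outer(st$beta[c, ] * 0 + 1, theta) -
                st$slopes * st$beta[c, ]
            P <- .logistic(eta)
            W <- Nc * P * (1 - P)
            # item locations
            g <- st$slopes * (rowSums(Nc * P) - sR1)
            h <- st$slopes^2 * rowSums(W) + 1e-10
            st$beta[c, ] <- pmin(pmax(
                st$beta[c, ] + pmin(pmax(g / h, -1), 1), -15), 15)
            # trait mean
            theta <- st$mu[c] + st$sigma[c] * gh$z
            eta <- st$slopes * outer(st$beta[c, ] * 0 + 1, theta) -
                st$slopes * st$beta[c, ]
            P <- .logistic(eta)
            W <- Nc * P * (1 - P)
            g <- sum(st$slopes * (R1 - Nc * P))
            h <- sum(st$slopes^2 * W) + 1e-10
            st$mu[c] <- st$mu[c] + pmin(pmax(g / h, -1), 1)
            if (est_sigma) {
                theta <- st$mu[c] + st$sigma[c] * gh$z
                eta <- st$slopes * outer(st$beta[c, ] * 0 + 1, theta) -
                    st$slopes * st$beta[c, ]
                P <- .logistic(eta)
                W <- Nc * P * (1 - P)
                zr <- matrix(gh$z, nrow(P), Q, byrow = TRUE)
                g <- sum(st$slopes * zr * (R1 - Nc * P))
                h <- sum(st$slopes^2 * zr^2 * W) + 1e-10
                st$sigma[c] <- pmin(pmax(
                    st$sigma[c] + pmin(pmax(g / h, -0.5), 0.5), 0.05), 10)
            }
            if (est_slopes) {
                theta <- st$mu[c] + st$sigma[c] * gh$z
                U <- outer(-st$beta[c, ], theta, `+`)   # theta_q - beta_i
                eta <- st$slopes * U
                P <- .logistic(eta)
                W <- Nc * P * (1 - P)
                g <- rowSums(U * (R1 - Nc * P))
                h <- rowSums(U^2 * W) + 1e-10
                st$slopes <- pmin(pmax(
                    st$slopes + pmin(pmax(g / h, -0.5), 0.5), 0.2), 5)
            }
        }
        # location identifiability: sum-zero difficulties per class
        m <- mean(st$beta[c, ])
        st$beta[c, ] <- st$beta[c, ] - m
        st$mu[c] <- st$mu[c] - m
    }
    st  # pi is updated by the caller from the responsibilities
}

# Interpolate between states (step-halving guard).
.blendState <- function(old, new, lambda) {
    st <- new
    st$pi <- old$pi + lambda * (new$pi - old$pi)
    st$pi <- st$pi / sum(st$pi)
    st$beta <- old$beta + lambda * (new$beta - old$beta)
    st$mu <- old$mu + lambda * (new$mu - old$mu)
    st$sigma <- pmax(old$sigma + lambda * (new$sigma - old$sigma), 0.05)
    st$slopes <- pmax(old$slopes + lambda * (new$slopes - old$slopes), 0.2)
    # re-center
    for (c in seq_along(st$mu)) {
        m <- mean(st$beta[c, ])
        st$beta[c, ] <- st$beta[c, ] - m
        st$mu[c] <- st$mu[c] - m
    }
    st
}

# Full EM run from one starting state.
.emRun <- function(st, X1, X0, Robs, counts, gh, est_slopes, est_sigma,
                   max_iter, tol) {
    n <- sum(counts)
    Q <- length(gh$z)
    C <- length(st$pi)
    cur <- .stateLogLik(st, X1, X0, counts, gh)
    trace <- cur$ll
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
        iter <- iter + 1L
        R <- exp(cur$A - cur$llp) * counts             # responsibilities
        new_st <- .mStep(st, R, X1, X0, Robs, counts, gh,
                         est_slopes, est_sigma)
        new_st$pi <- pmax(colSums(matrix(colSums(R), Q, C)), 1e-12)
        new_st$pi <- new_st$pi / sum(new_st$pi)
        new <- .stateLogLik(new_st, X1, X0, counts, gh)
        if (new$ll < cur$ll - 1e-9 * max(1, abs(cur$ll))) {
            lambda <- 0.5
            repeat {
                cand_st <- .blendState(st, new_st, lambda)
                cand <- .stateLogLik(cand_st, X1, X0, counts, gh)
                if (cand$ll >= cur$ll - 1e-12 * max(1, abs(cur$ll)) ||
                    lambda < 1e-4) break
                lambda <- lambda / 2
            }
            if (cand$ll < cur$ll) { converged <- TRUE; break }
            new_st <- cand_st; new <- cand
        }
        delta <- new$ll - cur$ll
        st <- new_st; cur <- new
        trace <- c(trace, cur$ll)
        if (abs(delta) < tol) { converged <- TRUE; break }
    }
    list(state = st, ll = cur$ll, trace = trace, converged = converged,
         iterations = iter)
}

.defaultMixtureConfig <- function(config = list()) {
    def <- list(n_starts = 10L, max_iter = 500L, tol = 1e-6,
                quadrature = 21L, seed = 1L)
    def[names(config)] <- config
    def
}

.prepareResponseData <- function(matrix) {
    X <- indicators(matrix)
    if (nrow(X) == 0 || ncol(X) == 0) stop("empty matrix")
    cp <- .collapsePatterns(X)
    Xu <- cp$X
    list(X1 = (!is.na(Xu) & Xu == 1) + 0,
         X0 = (!is.na(Xu) & Xu == 0) + 0,
         Robs = (!is.na(Xu)) + 0,
         counts = cp$counts, index = cp$index,
         n = nrow(X), I = ncol(X), items = colnames(X))
}

#' Fit a mixture-distribution Rasch model
#'
#' Marginal-maximum-likelihood EM with Gauss-Hermite quadrature and
#' class-specific normal latent traits. The best of \code{n_starts} random
#' initializations is kept; class labels are canonicalized by descending
#' mixing proportion and difficulties are sum-zero within each class.
#' Missing cells contribute nothing to person likelihoods.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param C number of latent classes (>= 1; must not exceed the number of
#'   distinct observed response patterns).
#' @param a common discrimination constant (default 1.7).
#' @param config list overriding any of: \code{n_starts} (10),
#'   \code{max_iter} (500), \code{tol} (1e-6, absolute log-likelihood
#'   change), \code{quadrature} (21 nodes), \code{seed} (1).
#' @return list with \code{model} (\code{\link{MixtureRaschModel-class}}),
#'   \code{fit} (\code{\link{ModelFit-class}}) and \code{assignments}
#'   (data.frame from \code{\link{assignClasses}}). Non-convergence within
#'   \code{max_iter} is flagged on the model, not an error.
#' @export
fitMixture <- function(matrix, C, a = 1.7, config = list()) {
    stopifnot(is(matrix, "DiagnosisMatrix"), C >= 1)
    if (a <= 0) stop("discrimination 'a' must be positive")
    cfg <- .defaultMixtureConfig(config)
    dat <- .prepareResponseData(matrix)
    if (C > length(dat$counts))
        stop(sprintf("C = %d exceeds the %d distinct observed response patterns",
                     C, length(dat$counts)))
    gh <- .ghNormal(cfg$quadrature)
    prev <- pmin(pmax(colSums(dat$X1 * dat$counts) /
                      pmax(colSums(dat$Robs * dat$counts), 1), 0.02), 0.98)
    beta0 <- -stats::qlogis(prev) / a
    set.seed(.deriveSeed(cfg$seed, "fit_mixture"))
    best <- NULL
    for (s in seq_len(cfg$n_starts)) {
        noise_sd <- if (s == 1 && C == 1) 0 else 0.5
        st <- list(
            pi = {p <- rep(1, C) + stats::runif(C, 0, 0.2); p / sum(p)},
            beta = t(vapply(seq_len(C), function(c)
                beta0 + stats::rnorm(dat$I, 0, noise_sd), numeric(dat$I))),
            mu = if (s == 1) rep(0, C) else stats::rnorm(C, 0, 0.3),
            sigma = rep(1, C),
            slopes = rep(a, dat$I))
        for (c in seq_len(C)) {
            m <- mean(st$beta[c, ]); st$beta[c, ] <- st$beta[c, ] - m
            st$mu[c] <- st$mu[c] - m
        }
        run <- .emRun(st, dat$X1, dat$X0, dat$Robs, dat$counts, gh,
                      est_slopes = FALSE, est_sigma = TRUE,
                      max_iter = cfg$max_iter, tol = cfg$tol)
        if (is.null(best) || run$ll > best$ll) best <- run
    }
    ord <- order(-best$state$pi)
    model <- new("MixtureRaschModel",
                 nClasses = as.integer(C),
                 mixing = best$state$pi[ord],
                 difficulties = {
                     d <- best$state$beta[ord, , drop = FALSE]
                     colnames(d) <- dat$items; d
                 },
                 traitMeans = best$state$mu[ord],
                 traitSDs = best$state$sigma[ord],
                 discrimination = a,
                 itemNames = dat$items,
                 logLik = best$ll,
                 logLikTrace = best$trace,
                 converged = best$converged,
                 iterations = best$iterations,
                 nStarts = as.integer(cfg$n_starts),
                 quadrature = as.integer(cfg$quadrature))
    if (!best$converged)
        warning(sprintf("EM did not converge in %d iterations (C = %d)",
                        cfg$max_iter, C))
    fit <- computeFit(model, matrix)
    list(model = model, fit = fit,
         assignments = assignClasses(model, matrix))
}

setMethod("show", "MixtureRaschModel", function(object) {
    cat(sprintf("MixtureRaschModel: %d class(es), %d items, a = %g\n",
                object@nClasses, length(object@itemNames),
                object@discrimination))
    cat("  mixing:", paste(round(object@mixing, 3), collapse = ", "), "\n")
    cat(sprintf("  logLik %.2f after %d iterations (%sconverged)\n",
                object@logLik, object@iterations,
                if (object@converged) "" else "NOT "))
})

#' @rdname accessors
#' @export
setMethod("mixingProportions", "MixtureRaschModel", function(x) x@mixing)
#' @rdname accessors
#' @export
setMethod("difficulties", "MixtureRaschModel", function(x) x@difficulties)
#' @rdname accessors
#' @export
setMethod("discrimination", "MixtureRaschModel", function(x) x@discrimination)
#' @rdname accessors
#' @export
setMethod("traitMeans", "MixtureRaschModel", function(x) x@traitMeans)
#' @rdname accessors
#' @export
setMethod("traitSDs", "MixtureRaschModel", function(x) x@traitSDs)

#' Marginal log-likelihood of a matrix under a fitted model
#'
#' sum_p log sum_c pi_c sum_q w_q P(x_p | theta_qc, beta_c, a) with
#' Gauss-Hermite nodes theta_qc transformed by (mu_c, sigma_c).
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}} (items must match the
#'   model's items).
#' @param model a \code{\link{MixtureRaschModel-class}}.
#' @param quadrature node count; defaults to the model's setting.
#' @return Scalar log-likelihood.
#' @export
marginalLogLik <- function(matrix, model, quadrature = NULL) {
    stopifnot(is(matrix, "DiagnosisMatrix"), is(model, "MixtureRaschModel"))
    if (!identical(conditionNames(matrix), model@itemNames))
        stop("matrix items do not match model items")
    if (is.null(quadrature)) quadrature <- model@quadrature
    if (quadrature < 5) stop("quadrature must be >= 5")
    dat <- .prepareResponseData(matrix)
    gh <- .ghNormal(quadrature)
    st <- list(pi = model@mixing, beta = unname(model@difficulties),
               mu = model@traitMeans, sigma = model@traitSDs,
               slopes = rep(model@discrimination, dat$I))
    .stateLogLik(st, dat$X1, dat$X0, dat$counts, gh)$ll
}

#' ModelFit constructor
#'
#' @param minus2LL -2 log marginal likelihood.
#' @param k free-parameter count.
#' @param n number of patients.
#' @return \code{\link{ModelFit-class}} with BIC = minus2LL + k * log(n).
#' @examples
#' bicOf(modelFit(200, 5, 100))  # 200 + 5*log(100)
#' @export
modelFit <- function(minus2LL, k, n) {
    new("ModelFit", minus2LL = minus2LL, k = k, n = n,
        BIC = minus2LL + k * log(n))
}

#' @rdname accessors
#' @export
setMethod("bicOf", "ModelFit", function(x) x@BIC)

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit: -2LL = %.2f, k = %g, n = %g, BIC = %.2f\n",
                object@minus2LL, object@k, object@n, object@BIC))
})

#' Likelihood-based fit of a mixture model
#'
#' By default the free-parameter count is k = C*(I-1) + (C-1) + 2C: sum-zero
#' difficulties per class, mixing proportions, and a trait mean and SD per
#' class. Software packages differ in their internal parameterizations, so
#' an explicit \code{k} may be supplied to reproduce a printed fit table
#' under another convention; BIC comparisons are valid within one
#' convention.
#'
#' @param model a \code{\link{MixtureRaschModel-class}}.
#' @param matrix the fitted \code{\link{DiagnosisMatrix-class}}.
#' @param k optional explicit parameter count.
#' @param quadrature optional node-count override.
#' @return A \code{\link{ModelFit-class}}.
#' @export
computeFit <- function(model, matrix, k = NULL, quadrature = NULL) {
    C <- model@nClasses
    I <- length(model@itemNames)
    if (is.null(k)) k <- C * (I - 1) + (C - 1) + 2 * C
    m2 <- -2 * marginalLogLik(matrix, model, quadrature)
    modelFit(m2, k, dim(matrix)[1])
}

#' Posterior class assignment and complexity estimation
#'
#' Posterior class probabilities are proportional to pi_c times the marginal
#' pattern likelihood under class c; every patient is assigned to the modal
#' class (ties broken toward the lowest class index and logged), making the
#' groups mutually exclusive and exhaustive. The complexity estimate theta
#' is the expected a-posteriori trait within the modal class.
#'
#' @param model a \code{\link{MixtureRaschModel-class}}.
#' @param matrix an item-aligned \code{\link{DiagnosisMatrix-class}}.
#' @return data.frame: patient_id, one posterior column per class
#'   (\code{prob.1} ... \code{prob.C}), \code{modal_class}, \code{theta}.
#' @export
assignClasses <- function(model, matrix) {
    stopifnot(is(model, "MixtureRaschModel"), is(matrix, "DiagnosisMatrix"))
    if (!identical(conditionNames(matrix), model@itemNames))
        stop("matrix items do not match model items")
    dat <- .prepareResponseData(matrix)
    gh <- .ghNormal(model@quadrature)
    C <- model@nClasses
    Q <- length(gh$z)
    npat <- nrow(dat$X1)
    logjoint <- matrix(NA_real_, npat, C)     # log pi_c + log m_c(x)
    eap <- matrix(NA_real_, npat, C)          # EAP theta per class
    for (c in seq_len(C)) {
        L <- .classPatternLL(dat$X1, dat$X0,
                             unname(model@difficulties)[c, ],
                             model@traitMeans[c], model@traitSDs[c],
                             rep(model@discrimination, dat$I), gh$z)
        Lw <- sweep(L, 2, log(gh$w), `+`)
        m <- apply(Lw, 1, max)
        wq <- exp(Lw - m)
        mc <- rowSums(wq)
        logjoint[, c] <- log(model@mixing[c]) + m + log(mc)
        theta_q <- model@traitMeans[c] + model@traitSDs[c] * gh$z
        eap[, c] <- as.vector(wq %*% theta_q) / mc
    }
    mrow <- apply(logjoint, 1, max)
    post <- exp(logjoint - mrow)
    post <- post / rowSums(post)
    modal <- max.col(post, ties.method = "first")
    ties <- apply(post, 1, function(p) sum(abs(p - max(p)) < 1e-12) > 1)
    if (any(ties[dat$index]))
        message(sprintf("%d patient(s) had tied posterior classes; assigned to the lowest class index",
                        sum(ties[dat$index])))
    idx <- dat$index
    out <- data.frame(patient_id = patientIDs(matrix),
                      stringsAsFactors = FALSE)
    for (c in seq_len(C)) out[[paste0("prob.", c)]] <- post[idx, c]
    out$modal_class <- modal[idx]
    out$theta <- eap[cbind(idx, modal[idx])]
    out
}

#' Fit a ladder of class counts and select by BIC
#'
#' Fits the mixture model for each class count in \code{C_range} and selects
#' the BIC-minimal count by default. Because the statistically optimal count
#' is not always the clinically preferred one, \code{override} lets the
#' caller pick a different count while the full fit table is still
#' reported. Individual fit failures are recorded and selection proceeds
#' over the successes.
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param C_range integer vector of class counts (default 1:7).
#' @param a common discrimination.
#' @param config estimation config (see \code{\link{fitMixture}}).
#' @param override optional class count to choose regardless of BIC.
#' @return list: \code{table} (data.frame C, minus2LL, k, BIC, converged,
#'   error), \code{chosen} (integer), \code{models} (per-C fit results).
#' @export
selectClasses <- function(matrix, C_range = 1:7, a = 1.7, config = list(),
                          override = NULL) {
    stopifnot(length(C_range) >= 1)
    fits <- vector("list", length(C_range))
    rows <- lapply(seq_along(C_range), function(i) {
        C <- C_range[i]
        res <- tryCatch(fitMixture(matrix, C, a = a, config = config),
                        error = function(e) e)
        fits[[i]] <<- res
        if (inherits(res, "error"))
            data.frame(C = C, minus2LL = NA, k = NA, BIC = NA,
                       converged = NA, error = conditionMessage(res))
        else
            data.frame(C = C, minus2LL = res$fit@minus2LL, k = res$fit@k,
                       BIC = res$fit@BIC, converged = res$model@converged,
                       error = NA_character_)
    })
    tab <- do.call(rbind, rows)
    if (all(!is.na(tab$error))) stop("all mixture fits failed")
    chosen <- if (!is.null(override)) {
        if (!override %in% C_range) stop("override outside C_range")
        as.integer(override)
    } else tab$C[which.min(tab$BIC)]
    names(fits) <- paste0("C", C_range)
    list(table = tab, chosen = chosen, models = fits)
}
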