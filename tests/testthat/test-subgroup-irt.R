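# Subgroup 1PL/2PL calibration, model choice and ICC profiles.

sim1pl <- function(n, beta, seed, a = 1.7) {
    spec <- cohortSpec(n_patients = n, difficulties = beta, seed = seed,
                       discrimination = a)
    generateCohort(spec)$matrix
}

test_that("1PL recovers difficulties and centres a symmetric item at 0", {
    beta <- c(-1.2, -0.6, 0, 0.3, 0.6, 0.9)
    errs <- vapply(1:5, function(s) {
        m <- fit1PL(sim1pl(2000, beta, seed = 600 + s))
        sqrt(mean((difficulties(m) - (beta - mean(beta)))^2))
    }, numeric(1))
    expect_lt(mean(errs), 0.15)
    # prevalence-0.5 item under a centred trait sits at location ~0
    m5 <- fit1PL(sim1pl(5000, c(0, -1, 1, 0.5, -0.5), seed = 77))
    expect_lt(abs(difficulties(m5)[1]), 0.1)
})

test_that("1PL fits are deterministic and flag degenerate inputs", {
    m <- sim1pl(400, c(-1, 0, 1), seed = 8)
    f1 <- fit1PL(m); f2 <- fit1PL(m)
    expect_identical(difficulties(f1), difficulties(f2))
    expect_identical(f1@fit@minus2LL, f2@fit@minus2LL)
    X <- indicators(m); X[, 2] <- 1
    expect_warning(fit1PL(DiagnosisMatrix(X)), "all-identical")
    expect_error(fit1PL(m[1, ]), "one patient")
    expect_warning(fit1PL(m[1:30, ]), "fewer than 50")
})

test_that("2PL recovers the slope rank order of heterogeneous items", {
    slopes <- c(0.8, 2.5, 1.0, 1.7)
    beta <- c(-0.5, 0, 0.5, 0)
    hits <- vapply(1:5, function(s) {
        set.seed(900 + s)
        n <- 4000
        theta <- rnorm(n)
        P <- plogis(t(slopes * (rep(1, 4) %o% theta - beta)))
        X <- (matrix(runif(n * 4), n, 4) < P) + 0
        dimnames(X) <- list(sprintf("P%04d", 1:n), paste0("it", 1:4))
        m2 <- fit2PL(DiagnosisMatrix(X))
        identical(order(discrimination(m2)), order(slopes))
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})

test_that("2PL on 1PL data returns near-constant slopes and loses to the
           1PL on BIC; equal-slope likelihoods agree", {
    m <- sim1pl(4000, c(-1, -0.3, 0.4, 1), seed = 31)
    f1 <- fit1PL(m)
    f2 <- fit2PL(m)
    expect_true(all(abs(discrimination(f2) - 1.7) < 0.4))
    cmp <- compare1PL2PL(f1, f2)
    expect_equal(cmp$chosen, "1PL")
    expect_gte(cmp$lr_stat, 0)
    expect_equal(cmp$lr_df, length(conditionNames(m)))
    # the 2PL likelihood surface contains the 1PL: evaluating the 2PL
    # engine at the 1PL's parameters reproduces its log-likelihood
    model <- new("MixtureRaschModel", nClasses = 1L, mixing = 1,
                 difficulties = rbind(unname(difficulties(f1))),
                 traitMeans = f1@mu, traitSDs = f1@sigma,
                 discrimination = 1.7, itemNames = f1@itemNames,
                 logLik = 0, logLikTrace = 0, converged = TRUE,
                 iterations = 0L, nStarts = 1L, quadrature = 21L)
    expect_lt(abs(marginalLogLik(m, model) - (-f1@fit@minus2LL / 2)), 1e-6)
})

test_that("strongly heterogeneous slopes make the 2PL win", {
    wins <- vapply(1:5, function(s) {
        set.seed(1200 + s)
        n <- 3000
        slopes <- c(0.4, 3.5, 0.4, 3.5, 1)
        beta <- c(-0.8, -0.4, 0, 0.4, 0.8)
        theta <- rnorm(n)
        P <- plogis(t(slopes * (rep(1, 5) %o% theta - beta)))
        X <- (matrix(runif(n * 5), n, 5) < P) + 0
        dimnames(X) <- list(sprintf("P%04d", 1:n), paste0("it", 1:5))
        m <- DiagnosisMatrix(X)
        cmp <- compare1PL2PL(fit1PL(m), fit2PL(m))
        cmp$chosen == "2PL" && cmp$slope_ratio > 2
    }, logical(1))
    expect_gte(mean(wins), 0.8)
})

test_that("ICC profiles cross 0.5 at the item location and agree with the
           scalar response probability", {
    m <- fit1PL(sim1pl(800, c(-1, 0, 1), seed = 55))
    icc <- iccProfile(m, theta_range = c(-6, 6), n_points = 201)
    expect_equal(unname(icc$locations), unname(difficulties(m)))
    for (i in seq_along(icc$locations)) {
        at_beta <- responseProbability(icc$locations[i], icc$locations[i],
                                       m@discriminations[i])
        expect_identical(at_beta, 0.5)
        expect_true(all(diff(icc$curves[, i]) > 0))
        expect_true(all(icc$curves[, i] > 0 & icc$curves[, i] < 1))
        expect_equal(icc$curves[, i],
                     responseProbability(icc$theta, icc$locations[i],
                                         m@discriminations[i]))
    }
    # logistic tail: theta = +6 with a = 1.7, beta = 0
    expect_gte(responseProbability(6, 0, 1.7), 0.9999)
})
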