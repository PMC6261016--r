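# Mixture-Rasch estimation: response model closed forms, likelihood
# oracles, EM behaviour, fit indices and posterior assignment.

test_that("response probability has its closed-form values and is stable", {
    expect_identical(responseProbability(0.8, 0.8, 1.7), 0.5)
    expect_identical(responseProbability(-3, -3, 0.3), 0.5)
    expect_equal(responseProbability(log(3), 0, a = 1), 0.75)
    expect_equal(responseProbability(700, 0, a = 1), 1)
    expect_equal(responseProbability(-700, 0, a = 1), 0)
    th <- seq(-3, 3, 0.5)
    expect_true(all(diff(responseProbability(th, 0.4)) > 0))
    expect_error(responseProbability(0, 0, a = 0), "positive")
})

test_that("pattern probability multiplies observed items and skips missing", {
    expect_equal(patternProbability(c(1, 0), 0, c(0, 0), a = 1), 0.25)
    expect_identical(patternProbability(c(NA, NA), 1.3, c(0, 2)), 1)
    # brute-force scalar oracle
    x <- c(1, 1, 0); beta <- c(0, 1, 2)
    manual <- prod(plogis(1.7 * (1 - beta[1:2]))) *
        (1 - plogis(1.7 * (1 - beta[3])))
    expect_equal(patternProbability(x, 1, beta, 1.7), manual)
    expect_error(patternProbability(c(1, 0), 0, c(0, 0, 0)), "dimension")
})

test_that("marginal likelihood matches dense-grid integration (C<=2, I<=3)", {
    set.seed(31)
    X <- rand_binary_matrix(8, 3, miss = 0.1)
    m <- DiagnosisMatrix(X)
    model <- new("MixtureRaschModel", nClasses = 2L,
                 mixing = c(0.6, 0.4),
                 difficulties = rbind(c(-0.5, 0.2, 0.3), c(0.8, -0.4, -0.4)),
                 traitMeans = c(-0.3, 0.5), traitSDs = c(0.8, 1.2),
                 discrimination = 1.7, itemNames = colnames(X),
                 logLik = 0, logLikTrace = 0, converged = TRUE,
                 iterations = 0L, nStarts = 1L, quadrature = 41L)
    got <- marginalLogLik(m, model)
    want <- oracle_marginal_loglik(X, model@mixing,
                                   unname(model@difficulties),
                                   model@traitMeans, model@traitSDs, 1.7)
    expect_lt(abs(got - want), 1e-6)
    # duplicating every patient doubles the log-likelihood exactly
    m2 <- DiagnosisMatrix(rbind(X, X), paste0("d", 1:16))
    expect_equal(marginalLogLik(m2, model), 2 * got)
})

test_that("degenerate single-item model has per-patient loglik ln(0.5)", {
    X <- matrix(c(1, 0, 1, 0), 4, 1,
                dimnames = list(paste0("P", 1:4), "only"))
    model <- new("MixtureRaschModel", nClasses = 1L, mixing = 1,
                 difficulties = matrix(0, 1, 1), traitMeans = 0,
                 traitSDs = 1e-8, discrimination = 1.7,
                 itemNames = "only", logLik = 0, logLikTrace = 0,
                 converged = TRUE, iterations = 0L, nStarts = 1L,
                 quadrature = 21L)
    expect_equal(marginalLogLik(DiagnosisMatrix(X), model), 4 * log(0.5),
                 tolerance = 1e-9)
})

test_that("EM increases the likelihood monotonically, is deterministic,
           and honours the identifiability constraints", {
    sim <- generateCohort(presetScenario("two_class_easy"), seed = 44)
    sub <- sim$matrix[1:1200, ]
    cfg <- list(n_starts = 2, max_iter = 150, tol = 1e-6, seed = 13)
    res <- fitMixture(sub, 2, config = cfg)
    expect_true(all(diff(res$model@logLikTrace) > -1e-8))
    expect_true(all(abs(rowSums(res$model@difficulties)) < 1e-8))
    expect_true(all(diff(res$model@mixing) <= 0))
    post <- as.matrix(res$assignments[, c("prob.1", "prob.2")])
    expect_equal(unname(rowSums(post)), rep(1, nrow(post)))
    res2 <- fitMixture(sub, 2, config = cfg)
    expect_identical(res$fit@minus2LL, res2$fit@minus2LL)
    expect_identical(res$model@difficulties, res2$model@difficulties)
})

test_that("single-class difficulties are recovered", {
    spec <- presetScenario("single_class")
    sim <- generateCohort(spec, seed = 61)
    res <- fitMixture(sim$matrix, 1, config = list(n_starts = 1, seed = 2))
    truth <- spec@difficulties[1, ] - mean(spec@difficulties[1, ])
    rmse <- sqrt(mean((res$model@difficulties[1, ] - truth)^2))
    expect_lt(rmse, 0.15)
})

test_that("C exceeding pattern diversity is an error", {
    X <- matrix(rep(c(1, 0), 6), 4, 3,
                dimnames = list(paste0("P", 1:4), paste0("c", 1:3)))
    expect_error(fitMixture(DiagnosisMatrix(X), 5), "distinct observed")
})

test_that("fit indices follow BIC arithmetic and the declared k formula", {
    expect_equal(bicOf(modelFit(200, 5, 100)), 200 + 5 * log(100))
    expect_equal(bicOf(modelFit(200, 0, 100)), 200)
    sim <- generateCohort(presetScenario("single_class"), seed = 3)
    res <- fitMixture(sim$matrix[1:300, ], 1,
                      config = list(n_starts = 1, seed = 1))
    # C=1, I=10: k = (I-1) + 0 + 2 = 11
    expect_equal(res$fit@k, 11)
    expect_equal(res$fit@n, 300)
    refit <- computeFit(res$model, sim$matrix[1:300, ], k = 99)
    expect_equal(refit@BIC, refit@minus2LL + 99 * log(300))
})

test_that("modal assignment breaks ties toward the lowest class and the
           selection override is honoured", {
    # two identical classes: posteriors tie at 0.5 for every pattern
    X <- rand_binary_matrix(10, 3)
    model <- new("MixtureRaschModel", nClasses = 2L, mixing = c(0.5, 0.5),
                 difficulties = matrix(0, 2, 3), traitMeans = c(0, 0),
                 traitSDs = c(1, 1), discrimination = 1.7,
                 itemNames = colnames(X), logLik = 0, logLikTrace = 0,
                 converged = TRUE, iterations = 0L, nStarts = 1L,
                 quadrature = 21L)
    expect_message(asg <- assignClasses(model, DiagnosisMatrix(X)), "tied")
    expect_true(all(asg$modal_class == 1))
    sim <- generateCohort(presetScenario("single_class"), seed = 9)
    sel <- selectClasses(sim$matrix[1:400, ], 1:2,
                         config = list(n_starts = 1, max_iter = 80,
                                       tol = 1e-5, seed = 4),
                         override = 2)
    expect_equal(sel$chosen, 2L)
    expect_equal(nrow(sel$table), 2)
    expect_true(all(is.finite(sel$table$BIC)))
})
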