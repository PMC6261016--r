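# The synthetic-cohort generator: determinism, distributional correctness,
# preset scenarios and the encounter round-trip.

test_that("generation is a pure function of spec and seed", {
    spec <- presetScenario("two_class_easy")
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(indicators(a$matrix), indicators(b$matrix))
    expect_identical(a$truth, b$truth)
    c <- generateCohort(spec, seed = 999)
    expect_false(identical(indicators(a$matrix), indicators(c$matrix)))
})

test_that("a symmetric single-class spec yields ~50% prevalence and
           extreme difficulties saturate prevalence", {
    spec <- cohortSpec(n_patients = 10000,
                       difficulties = rep(0, 4),
                       trait_sds = 1e-9, seed = 17)
    sim <- generateCohort(spec)
    prev <- conditionPrevalence(sim$matrix)
    expect_true(all(prev > 0.45 & prev < 0.55))
    spec2 <- cohortSpec(n_patients = 2000,
                        difficulties = c(-10, 0), seed = 18)
    sim2 <- generateCohort(spec2)
    expect_gt(conditionPrevalence(sim2$matrix)[1], 0.99)
})

test_that("marginal prevalence agrees with the quadrature expectation", {
    spec <- presetScenario("two_class_easy")
    spec@seed <- 71L
    sim <- generateCohort(spec)
    emp <- conditionPrevalence(sim$matrix)
    theo <- expectedPrevalence(spec)
    se <- sqrt(theo * (1 - theo) / spec@nPatients)
    expect_true(all(abs(emp - theo) < 3.5 * se))
})

test_that("invalid specs are rejected", {
    expect_error(cohortSpec(100, rep(0, 3), mixing = c(0.7, 0.2)),
                 "sum to 1")
    expect_error(cohortSpec(100, rep(0, 3), trait_sds = -1), "> 0")
    expect_error(generateCovariates(
        data.frame(patient_id = "P1", true_class = 1),
        presetScenario("single_class")), "no covariate")
})

test_that("covariates follow their class-conditional probabilities", {
    spec <- presetScenario("two_class_easy")
    spec@nPatients <- 9344L
    sim <- generateCohort(spec, seed = 23)
    cov <- generateCovariates(sim$truth, spec, seed = 23)
    p1 <- mean(cov$married[sim$truth$true_class == 1])
    expect_lt(abs(p1 - 0.19), 0.015)
    # degenerate probabilities are exact
    spec@covariateProbs <- list(always = c(1, 1), never = c(0, 0))
    cov2 <- generateCovariates(sim$truth, spec)
    expect_true(all(cov2$always == 1) && all(cov2$never == 0))
})

test_that("generated encounters rebuild the indicator matrix exactly", {
    dict <- list(a = c("303.*"), b = c("401.*", "402.1"), c = c("250.00"),
                 d = c("571.*"), e = c("309.81"))
    set.seed(5)
    for (rep in 1:3) {
        X <- rand_binary_matrix(20, 5)
        colnames(X) <- names(dict)
        m <- DiagnosisMatrix(X)
        enc <- generateEncounters(m, dict, seed = rep)
        if (sum(X) == 0) { expect_equal(nrow(enc), 0); next }
        rebuilt <- buildIndicatorMatrix(enc, dict)
        expect_equal(rebuilt[patientIDs(m)[rowSums(X) > 0], ] |> indicators(),
                     X[rowSums(X) > 0, , drop = FALSE])
    }
    # all-zero matrix -> no encounters
    z <- DiagnosisMatrix(matrix(0, 2, 5,
        dimnames = list(c("P1", "P2"), names(dict))))
    expect_equal(nrow(generateEncounters(z, dict)), 0)
})

test_that("preset scenarios have their declared structure", {
    expect_error(presetScenario("nope"), "valid names")
    s1 <- presetScenario("single_class")
    expect_equal(length(mixingProportions(s1)), 1)
    s2 <- presetScenario("two_class_easy")
    expect_equal(mixingProportions(s2), c(0.5, 0.5))
    d <- difficulties(s2)
    expect_gte(sum(abs(d[1, ] - d[2, ]) >= 2), ncol(d) / 2)
    gp <- presetScenario("guttman_perfect")
    expect_equal(gp@responseModel, "threshold")
})

test_that("paper_like marginals echo the published prevalence profile", {
    pl <- presetScenario("paper_like")
    expect_equal(length(mixingProportions(pl)), 6)
    expect_equal(length(conditionNames(pl)), 29)
    sim <- generateCohort(pl)
    prev <- conditionPrevalence(sim$matrix)
    expect_lt(abs(prev[["hypertension"]] - 0.72), 0.05)
    expect_lt(abs(prev[["chronic_pain"]] - 0.77), 0.05)
    expect_lt(abs(prev[["drug_abuse"]] - 0.20), 0.05)
})

test_that("guttman_perfect cohorts are error-free under prevalence order", {
    sim <- generateCohort(presetScenario("guttman_perfect"))
    ord <- prevalenceOrder(sim$matrix)
    X <- indicators(sim$matrix)[, ord]
    errs <- apply(X, 1, oracle_guttman)
    expect_true(all(errs == 0))
})
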