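# Mokken scaling diagnostics and Guttman person fit, verified against
# brute-force oracles.

test_that("pairwise H is 1 on perfect Guttman data and 0 on the classic
           2x2 counterexample", {
    # triangular (perfect cumulative) pattern matrix
    X <- matrix(0, 5, 4, dimnames = list(paste0("P", 1:5), paste0("c", 1:4)))
    for (i in 1:4) X[i:5, i] <- 1
    H <- pairwiseH(DiagnosisMatrix(X))
    expect_true(all(H[upper.tri(H)] == 1, na.rm = TRUE))
    # 4 patients, patterns (1,1),(1,0),(0,0),(0,1): F=1, E=1 -> H=0
    Y <- matrix(c(1, 1, 0, 0, 1, 0, 0, 1), 4, 2,
                dimnames = list(paste0("P", 1:4), c("i", "j")))
    expect_equal(pairwiseH(DiagnosisMatrix(Y))["i", "j"], 0)
    expect_equal(scaleH(DiagnosisMatrix(Y))@Hscale, 0)
})

test_that("independent items have H near zero", {
    set.seed(77)
    X <- rand_binary_matrix(10000, 2, p = c(0.5, 0.5))
    H <- pairwiseH(DiagnosisMatrix(X))
    expect_lt(abs(H[1, 2]), 0.05)
})

test_that("H coefficients match the brute-force oracle on random small
           matrices, including missing cells", {
    set.seed(88)
    for (r in 1:60) {
        n <- sample(2:6, 1); I <- sample(2:5, 1)
        X <- rand_binary_matrix(n, I, miss = ifelse(r %% 3 == 0, 0.2, 0))
        m <- DiagnosisMatrix(X)
        want <- oracle_H(X)
        got_pair <- pairwiseH(m)
        expect_equal(unname(got_pair), unname(want$Hpair), tolerance = 1e-12)
        sr <- scaleH(m)
        expect_equal(unname(sr@Hitem), want$Hitem, tolerance = 1e-12)
        expect_equal(sr@Hscale, want$Hscale, tolerance = 1e-12)
    }
})

test_that("guttman error counts match pair enumeration", {
    expect_equal(guttmanErrors(c(0, 1)), 1)       # has CHF, lacks HTN
    expect_equal(guttmanErrors(c(0, 0, 0)), 0)
    expect_equal(guttmanErrors(c(1, 1, 1)), 0)
    expect_equal(guttmanErrors(c(1, 0, 1, 0, 1)), 3)
    set.seed(99)
    for (r in 1:60) {
        x <- rbinom(sample(2:8, 1), 1, 0.5)
        if (r %% 4 == 0) x[sample(length(x), 1)] <- NA
        expect_equal(guttmanErrors(x), oracle_guttman(x))
    }
    # invariant to appending missing items
    x <- c(1, 0, 1)
    expect_equal(guttmanErrors(c(x, NA, NA)), guttmanErrors(x))
})

test_that("person-fit filter applies the more-than-one-error rule", {
    # items already in prevalence order c1 > c2 > c3 (forced by counts)
    X <- rbind(good = c(1, 1, 0), one = c(0, 1, 0), two = c(0, 0, 1),
               zero = c(0, 0, 0))
    X <- cbind(X, extra = c(1, 1, 0, 1))  # keeps prevalences distinct
    colnames(X) <- c("c1", "c2", "c3", "c0")
    m <- DiagnosisMatrix(X)
    res <- personFitFilter(m, max_errors = 1)
    errs <- setNames(res$person_fit$guttman_errors, res$person_fit$patient_id)
    ord <- prevalenceOrder(m)
    for (p in rownames(X))
        expect_equal(unname(errs[p]), oracle_guttman(X[p, ord]))
    expect_true(all(res$person_fit$included == (errs <= 1)))
    expect_equal(res$report$parameters$retained_fraction,
                 mean(errs <= 1))
    # boundary: exactly one error is retained
    expect_true(res$person_fit$included[res$person_fit$patient_id == "one"])
})

test_that("retained fraction under the error rule is stable across seeds
           for 1PL-generated data", {
    spec <- presetScenario("single_class")
    fracs <- vapply(1:4, function(s) {
        sim <- generateCohort(spec, seed = 500 + s)
        mean(personFitFilter(sim$matrix)$person_fit$included)
    }, numeric(1))
    expect_lt(max(fracs) - min(fracs), 0.06)
})

test_that("monotonicity check flags constructed violations only", {
    set.seed(202)
    sim <- generateCohort(presetScenario("single_class"), seed = 303)
    ok <- checkMonotonicity(sim$matrix, "cond05", min_group_size = 100)
    expect_equal(ok$verdict, "ok")
    # deliberately decreasing trace line: invert an item against restscore
    X <- indicators(sim$matrix)
    rest <- rowSums(X[, -5])
    X[, 5] <- as.numeric(rest <= stats::median(rest))
    bad <- checkMonotonicity(DiagnosisMatrix(X), 5, min_group_size = 100)
    expect_equal(bad$verdict, "violation")
    expect_gt(bad$violations, 0)
    # constant item: no violation
    X[, 5] <- 1
    X[1, 5] <- 0
    expect_equal(checkMonotonicity(DiagnosisMatrix(X), 5,
                                   min_group_size = 100)$verdict, "ok")
})

test_that("item selection removes a coin-flip intruder and keeps 1PL items", {
    set.seed(404)
    sim <- generateCohort(presetScenario("single_class"), seed = 404)
    X <- indicators(sim$matrix)
    X[, "cond06"] <- rbinom(nrow(X), 1, 0.5)  # independent intruder
    res <- selectScaleItems(DiagnosisMatrix(X), H_min = 0.3,
                            min_group_size = 100)
    expect_false("cond06" %in% selectedItems(res))
    expect_gt(length(selectedItems(res)), 5)
    expect_true("cond06" %in% res@audit$item)
    # all-1PL data: everything retained
    res2 <- selectScaleItems(sim$matrix, H_min = 0.3, min_group_size = 100)
    expect_equal(sort(selectedItems(res2)), sort(conditionNames(sim$matrix)))
})

test_that("selection errors when fewer than two items can scale", {
    set.seed(505)
    X <- cbind(a = rbinom(300, 1, 0.5), b = rbinom(300, 1, 0.5))
    rownames(X) <- paste0("P", 1:300)
    expect_error(selectScaleItems(DiagnosisMatrix(X), H_min = 0.3,
                                  min_group_size = 50),
                 "descriptive")
})
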