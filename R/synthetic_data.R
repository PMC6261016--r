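# Synthetic cohorts with known latent structure. The generator is the
# package's testing ground truth: every downstream stage (filters, mixture
# estimation, Mokken screening, subgroup calibration, characterization) is
# exercised against cohorts whose class memberships, traits and difficulties
# are known exactly.

#' Construct a CohortSpec
#'
#' @param n_patients cohort size.
#' @param condition_names item labels; defaults to cond01..condII.
#' @param mixing simplex of class proportions.
#' @param difficulties C x I matrix of class-specific item locations (logit
#'   scale); a plain vector is accepted when C = 1.
#' @param trait_means,trait_sds per-class latent-trait normal parameters.
#' @param discrimination common slope (default 1.7, the Rasch convention).
#' @param response_model "bernoulli" (default) or "threshold"
#'   (deterministic x_i = 1 iff theta >= beta_i; Guttman-perfect data).
#' @param covariate_probs named list of length-C class-specific Bernoulli
#'   probabilities for binary covariates.
#' @param seed integer default seed.
#' @return A \code{\link{CohortSpec-class}}.
#' @export
cohortSpec <- function(n_patients, difficulties, mixing = 1,
                       condition_names = NULL,
                       trait_means = NULL, trait_sds = NULL,
                       discrimination = 1.7,
                       response_model = "bernoulli",
                       covariate_probs = list(), seed = 1L) {
    if (is.vector(difficulties)) difficulties <- rbind(difficulties)
    C <- length(mixing)
    I <- ncol(difficulties)
    if (is.null(condition_names))
        condition_names <- sprintf("cond%02d", seq_len(I))
    if (is.null(trait_means)) trait_means <- rep(0, C)
    if (is.null(trait_sds)) trait_sds <- rep(1, C)
    dimnames(difficulties) <- NULL
    new("CohortSpec",
        nPatients = as.integer(n_patients),
        conditionNames = condition_names,
        mixing = as.numeric(mixing),
        difficulties = difficulties,
        traitMeans = as.numeric(trait_means),
        traitSDs = as.numeric(trait_sds),
        discrimination = as.numeric(discrimination),
        responseModel = response_model,
        covariateProbs = covariate_probs,
        seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec: %d patients, %d conditions, %d class(es), a=%g, %s responses\n",
                object@nPatients, length(object@conditionNames),
                length(object@mixing), object@discrimination,
                object@responseModel))
    cat("  mixing:", paste(round(object@mixing, 3), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("conditionNames", "CohortSpec", function(x) x@conditionNames)
#' @rdname accessors
#' @export
setMethod("mixingProportions", "CohortSpec", function(x) x@mixing)
#' @rdname accessors
#' @export
setMethod("difficulties", "CohortSpec", function(x) {
    d <- x@difficulties
    colnames(d) <- x@conditionNames
    d
})
#' @rdname accessors
#' @export
setMethod("discrimination", "CohortSpec", function(x) x@discrimination)
#' @rdname accessors
#' @export
setMethod("traitMeans", "CohortSpec", function(x) x@traitMeans)
#' @rdname accessors
#' @export
setMethod("traitSDs", "CohortSpec", function(x) x@traitSDs)

#' Generate a synthetic cohort
#'
#' For each patient: class ~ Categorical(mixing); theta ~ N(mu_c, sigma_c);
#' each indicator x_i ~ Bernoulli(logistic(a * (theta - beta_ic))) (or the
#' deterministic threshold x_i = 1 iff theta >= beta_ic under the
#' "threshold" response model). Fully deterministic given the spec's seed.
#'
#' @param spec a \code{\link{CohortSpec-class}}.
#' @param seed optional override of \code{spec@seed}.
#' @return list(matrix = DiagnosisMatrix, truth = data.frame(patient_id,
#'   true_class, true_theta), spec).
#' @export
generateCohort <- function(spec, seed = NULL) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    if (is.null(seed)) seed <- spec@seed
    set.seed(.deriveSeed(seed, "generate_cohort"))
    n <- spec@nPatients
    C <- length(spec@mixing)
    I <- length(spec@conditionNames)
    cls <- sample.int(C, n, replace = TRUE, prob = spec@mixing)
    theta <- stats::rnorm(n, spec@traitMeans[cls], spec@traitSDs[cls])
    eta <- spec@discrimination *
        (theta - spec@difficulties[cls, , drop = FALSE])
    X <- if (spec@responseModel == "threshold") {
        (theta >= spec@difficulties[cls, , drop = FALSE]) + 0
    } else {
        (matrix(stats::runif(n * I), n, I) < .logistic(eta)) + 0
    }
    ids <- sprintf("P%06d", seq_len(n))
    dimnames(X) <- list(ids, spec@conditionNames)
    list(matrix = DiagnosisMatrix(X),
         truth = data.frame(patient_id = ids, true_class = cls,
                            true_theta = theta, stringsAsFactors = FALSE),
         spec = spec)
}

#' Generate class-conditional binary covariates
#'
#' Each binary covariate is drawn Bernoulli with its class-specific
#' probability from \code{spec@covariateProbs}; used to emulate demographic
#' and utilization profiles that differ across latent subgroups.
#'
#' @param truth data.frame with patient_id and true_class (from
#'   \code{\link{generateCohort}}).
#' @param spec the \code{\link{CohortSpec-class}} used.
#' @param seed optional override of \code{spec@seed}.
#' @return data.frame: patient_id plus one 0/1 column per covariate.
#' @export
generateCovariates <- function(truth, spec, seed = NULL) {
    stopifnot(is(spec, "CohortSpec"))
    if (!length(spec@covariateProbs))
        stop("spec has no covariate probabilities")
    if (is.null(seed)) seed <- spec@seed
    set.seed(.deriveSeed(seed, "generate_covariates"))
    out <- data.frame(patient_id = truth$patient_id,
                      stringsAsFactors = FALSE)
    for (nm in names(spec@covariateProbs)) {
        p <- spec@covariateProbs[[nm]][truth$true_class]
        out[[nm]] <- stats::rbinom(nrow(truth), 1, p)
    }
    out
}

# Turn an ICD-9 pattern into one concrete valid code.
.concretizePattern <- function(pattern) {
    if (!grepl("\\*$", pattern)) return(pattern)
    pref <- sub("\\.?\\*$", "", pattern)
    if (.isValidICD9(pref)) return(pref)
    norm <- .normalizeICD9(pref)
    head_len <- if (startsWith(norm, "E")) 4L else 3L
    if (nchar(norm) < head_len)
        stop("pattern too short to concretize: ", pattern)
    head <- substr(norm, 1, head_len)
    tail <- substr(norm, head_len + 1, nchar(norm))
    if (nzchar(tail)) paste0(head, ".", tail) else head
}

#' Generate encounter records consistent with an indicator matrix
#'
#' Inverse of \code{\link{buildIndicatorMatrix}}: for every positive cell one
#' or more encounters are emitted with a concrete code drawn from the
#' condition's patterns, so rebuilding the indicator matrix from the
#' generated encounters recovers the input (restricted to observed cells).
#'
#' @param matrix a \code{\link{DiagnosisMatrix-class}}.
#' @param dictionary named pattern list covering every condition in the
#'   matrix.
#' @param seed integer seed.
#' @return Encounter data.frame (patient_id, icd9, setting).
#' @export
generateEncounters <- function(matrix, dictionary, seed = 1L) {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    .validateDictionary(dictionary)
    M <- indicators(matrix)
    missing_conds <- setdiff(colnames(M), names(dictionary))
    if (length(missing_conds))
        stop("conditions missing from dictionary: ",
             paste(missing_conds, collapse = ", "))
    set.seed(.deriveSeed(seed, "generate_encounters"))
    pos <- which(M == 1, arr.ind = TRUE)
    if (nrow(pos) == 0)
        return(data.frame(patient_id = character(), icd9 = character(),
                          setting = character(), stringsAsFactors = FALSE))
    reps <- 1L + stats::rbinom(nrow(pos), 1, 0.3)  # occasional duplicates
    rows <- rep(seq_len(nrow(pos)), reps)
    codes <- vapply(rows, function(r) {
        pats <- dictionary[[colnames(M)[pos[r, 2]]]]
        .concretizePattern(pats[sample.int(length(pats), 1)])
    }, character(1))
    out <- data.frame(
        patient_id = rownames(M)[pos[rows, 1]],
        icd9 = codes,
        setting = sample(c("inpatient", "outpatient", "community"),
                         length(rows), replace = TRUE),
        stringsAsFactors = FALSE)
    out[order(out$patient_id), , drop = FALSE]
}

#' Expected marginal item prevalence under a CohortSpec
#'
#' Computes sum_c pi_c E_theta[logistic(a (theta - beta_ic))] by
#' Gauss-Hermite quadrature; the Monte-Carlo prevalence of a generated
#' cohort converges to this value.
#'
#' @param spec a \code{\link{CohortSpec-class}}.
#' @param quadrature node count (default 61).
#' @return Named numeric vector of per-condition expected prevalences.
#' @export
expectedPrevalence <- function(spec, quadrature = 61) {
    gh <- .ghNormal(quadrature)
    C <- length(spec@mixing)
    I <- length(spec@conditionNames)
    prev <- numeric(I)
    for (c in seq_len(C)) {
        th <- spec@traitMeans[c] + spec@traitSDs[c] * gh$z
        P <- .logistic(spec@discrimination *
                       outer(th, spec@difficulties[c, ], `-`))
        prev <- prev + spec@mixing[c] * colSums(gh$w * P)
    }
    stats::setNames(prev, spec@conditionNames)
}

# Solve common base difficulties so that mixture marginal prevalences hit
# targets, given class-specific offsets (used by the paper_like preset).
.solveBaseDifficulties <- function(targets, offsets, mixing,
                                   trait_means, trait_sds, a) {
    vapply(seq_along(targets), function(i) {
        stats::uniroot(function(b) {
            spec_beta <- b + offsets[, i]
            gh <- .ghNormal(41)
            p <- 0
            for (c in seq_along(mixing)) {
                th <- trait_means[c] + trait_sds[c] * gh$z
                p <- p + mixing[c] *
                    sum(gh$w * .logistic(a * (th - spec_beta[c])))
            }
            p - targets[i]
        }, c(-12, 12), tol = 1e-9)$root
    }, numeric(1))
}

#' Preset simulation scenarios
#'
#' Fully specified cohort scenarios with pinned seeds:
#' \describe{
#'   \item{single_class}{C = 1, 10 items, n = 2,000; evenly spread
#'     difficulties. Baseline for difficulty-recovery checks.}
#'   \item{two_class_easy}{C = 2, equal mixing, n = 4,000, 10 items; the two
#'     class difficulty vectors are separated by 2.5 logits on half the
#'     items, so classes are well recoverable. Ships class-conditional
#'     covariate probabilities for characterization tests.}
#'   \item{paper_like}{C = 6, 29 chronic-condition items, n = 10,000; mixing
#'     proportions and marginal prevalences echo a large high-risk veteran
#'     cohort (e.g. hypertension 72\%, chronic pain 77\%, drug abuse 20\%),
#'     with class-specific signature conditions (substance use, mental
#'     health, diabetes, liver disease, two cancer profiles). Base
#'     difficulties are solved numerically so the mixture marginals hit the
#'     target prevalences.}
#'   \item{guttman_perfect}{C = 1, 8 items, n = 1,000, deterministic
#'     threshold responses: every patient's pattern is Guttman-consistent
#'     under prevalence ordering.}
#' }
#'
#' @param name one of the scenario names above.
#' @return A \code{\link{CohortSpec-class}}.
#' @export
presetScenario <- function(name = c("two_class_easy", "paper_like",
                                    "single_class", "guttman_perfect")) {
    name <- tryCatch(match.arg(name), error = function(e)
        stop("unknown scenario '", name[1],
             "'; valid names: two_class_easy, paper_like, single_class, guttman_perfect"))
    switch(name,
    single_class = cohortSpec(
        n_patients = 2000,
        difficulties = seq(-1.8, 1.8, length.out = 10),
        mixing = 1, seed = 101L),
    two_class_easy = {
        beta1 <- c(rep(-1.25, 5), rep(0.5, 5))
        beta2 <- c(rep(1.25, 5), rep(-0.5, 5))
        cohortSpec(
            n_patients = 4000,
            difficulties = rbind(beta1, beta2),
            mixing = c(0.5, 0.5),
            covariate_probs = list(
                married = c(0.19, 0.47),
                age65plus = c(0.20, 0.85),
                unemployed = c(0.22, 0.01),
                inpatient1plus = c(0.68, 0.65)),
            seed = 202L)
    },
    paper_like = .paperLikeSpec(),
    guttman_perfect = cohortSpec(
        n_patients = 1000,
        difficulties = seq(-2, 2, length.out = 8),
        mixing = 1, response_model = "threshold", seed = 404L))
}

# Six-class, 29-condition scenario mirroring the scale of a high-risk
# EHR cohort; marginal prevalences follow published condition frequencies.
.paperLikeSpec <- function() {
    conds <- c("depression", "anxiety", "ptsd", "bipolar", "psychosis",
               "drug_abuse", "alcohol_abuse", "nicotine_abuse",
               "hypertension", "coronary_artery_disease",
               "congestive_heart_failure", "cardiac_arrhythmias",
               "chronic_pulmonary_disease", "cerebrovascular_disease",
               "peripheral_vascular_disease", "clotting_disorders",
               "diabetes", "electrolyte_disorders", "thyroid_disorders",
               "chronic_renal_failure", "acute_renal_failure",
               "polyneuropathy", "liver_disease", "chronic_hepatitis",
               "chronic_arthritis", "chronic_pain", "weight_loss",
               "anemia", "malignant_neoplasm")
    targets <- c(0.40, 0.19, 0.22, 0.07, 0.09, 0.20, 0.18, 0.29, 0.72,
                 0.29, 0.21, 0.24, 0.33, 0.13, 0.17, 0.06, 0.43, 0.15,
                 0.11, 0.17, 0.10, 0.12, 0.13, 0.10, 0.47, 0.77, 0.07,
                 0.20, 0.22)
    mixing <- c(10579, 14649, 23691, 5826, 8629, 5026) / 68400
    C <- 6L
    offsets <- matrix(0, C, length(conds),
                      dimnames = list(NULL, conds))
    # class signatures: lower difficulty = condition easier to acquire
    offsets[1, c("drug_abuse", "alcohol_abuse")] <- -2.5
    offsets[1, c("liver_disease", "chronic_hepatitis")] <- -1
    offsets[2, c("depression", "anxiety", "ptsd")] <- -1.5
    offsets[2, "diabetes"] <- -0.5
    offsets[3, c("diabetes", "chronic_renal_failure")] <- -1.5
    offsets[3, "hypertension"] <- -1
    offsets[4, c("liver_disease", "chronic_hepatitis")] <- -3.5
    offsets[5, "malignant_neoplasm"] <- -2.5
    offsets[5, c("coronary_artery_disease",
                 "congestive_heart_failure")] <- -1
    offsets[6, "malignant_neoplasm"] <- -2.5
    offsets[6, c("depression", "hypertension")] <- -1
    base <- .solveBaseDifficulties(targets, offsets, mixing,
                                   trait_means = rep(0, C),
                                   trait_sds = rep(1, C), a = 1.7)
    beta <- sweep(offsets, 2, base, `+`)
    cohortSpec(
        n_patients = 10000,
        condition_names = conds,
        difficulties = unname(beta),
        mixing = mixing,
        covariate_probs = list(
            married = c(0.19, 0.37, 0.42, 0.30, 0.47, 0.38),
            male = c(0.92, 0.84, 0.97, 0.96, 0.98, 0.93),
            age65plus = c(0.20, 0.41, 0.73, 0.39, 0.85, 0.62),
            unemployed = c(0.22, 0.06, 0.01, 0.07, 0.003, 0.04)),
        seed = 303L)
}
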