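#' @import methods
NULL

#' DiagnosisMatrix: patients-by-conditions binary indicators
#'
#' Central data container of the package: a patients x conditions matrix of
#' binary chronic-condition indicators. Cells are 1 (condition present),
#' 0 (absent) or \code{NA} (presence/absence not recorded in the source
#' system). Missing cells can only enter through directly supplied matrices;
#' \code{\link{buildIndicatorMatrix}} never produces them, because absence of
#' a qualifying code is coded 0.
#'
#' @slot indicators numeric matrix, patients in rows (rownames = patient ids),
#'   conditions in columns (colnames = condition names); values in
#'   \{0, 1, NA\}.
#'
#' @seealso \code{\link{DiagnosisMatrix}} (constructor),
#'   \code{\link{indicators}}, \code{\link{patientIDs}},
#'   \code{\link{conditionNames}}
#' @export
setClass("DiagnosisMatrix", representation(indicators = "matrix"))

setValidity("DiagnosisMatrix", function(object) {
    m <- object@indicators
    msgs <- character()
    if (is.null(rownames(m)) && nrow(m) > 0)
        msgs <- c(msgs, "patient ids (rownames) are required")
    if (is.null(colnames(m)) && ncol(m) > 0)
        msgs <- c(msgs, "condition names (colnames) are required")
    if (nrow(m) > 0 && anyDuplicated(rownames(m)))
        msgs <- c(msgs, "duplicate patient ids")
    if (ncol(m) > 0 && anyDuplicated(colnames(m)))
        msgs <- c(msgs, "duplicate condition names")
    vals <- m[!is.na(m)]
    if (length(vals) && !all(vals %in% c(0, 1)))
        msgs <- c(msgs, "observed cells must be 0 or 1")
    if (length(msgs)) msgs else TRUE
})

#' CohortSpec: generative specification for a synthetic cohort
#'
#' Describes a mixture-distribution Rasch population: C latent classes with
#' mixing proportions, class-specific item difficulties on the logit scale,
#' class-specific normal latent-trait ("medical complexity") distributions, a
#' common discrimination constant, and optional class-conditional Bernoulli
#' probabilities for binary demographic/utilization covariates.
#'
#' @slot nPatients integer, cohort size.
#' @slot conditionNames character, item labels (length I).
#' @slot mixing numeric simplex of length C (all > 0, sums to 1).
#' @slot difficulties C x I numeric matrix of class-specific item locations
#'   (logit scale).
#' @slot traitMeans,traitSDs per-class latent-trait normal parameters
#'   (SDs > 0).
#' @slot discrimination positive common slope; 1.7 is the Rasch convention
#'   used throughout.
#' @slot responseModel \code{"bernoulli"} (stochastic responses) or
#'   \code{"threshold"} (deterministic x_i = 1 iff theta >= beta_i, which
#'   yields Guttman-perfect data within each class).
#' @slot covariateProbs named list; each element is a length-C vector of
#'   class-specific Bernoulli probabilities for one binary covariate.
#' @slot seed integer default seed for generation.
#' @export
setClass("CohortSpec", representation(
    nPatients = "integer",
    conditionNames = "character",
    mixing = "numeric",
    difficulties = "matrix",
    traitMeans = "numeric",
    traitSDs = "numeric",
    discrimination = "numeric",
    responseModel = "character",
    covariateProbs = "list",
    seed = "integer"
))

setValidity("CohortSpec", function(object) {
    msgs <- character()
    C <- length(object@mixing)
    I <- length(object@conditionNames)
    if (object@nPatients < 1) msgs <- c(msgs, "nPatients must be >= 1")
    if (I < 1) msgs <- c(msgs, "at least one condition is required")
    if (C < 1) msgs <- c(msgs, "at least one class is required")
    if (any(object@mixing <= 0) || abs(sum(object@mixing) - 1) > 1e-8)
        msgs <- c(msgs, "mixing proportions must be positive and sum to 1")
    if (!all(dim(object@difficulties) == c(C, I)))
        msgs <- c(msgs, "difficulties must be a C x I matrix")
    if (length(object@traitMeans) != C || length(object@traitSDs) != C)
        msgs <- c(msgs, "traitMeans/traitSDs must have one entry per class")
    if (any(object@traitSDs <= 0)) msgs <- c(msgs, "traitSDs must be > 0")
    if (length(object@discrimination) != 1 || object@discrimination <= 0)
        msgs <- c(msgs, "discrimination must be a single positive number")
    if (!object@responseModel %in% c("bernoulli", "threshold"))
        msgs <- c(msgs, "responseModel must be 'bernoulli' or 'threshold'")
    for (nm in names(object@covariateProbs)) {
        p <- object@covariateProbs[[nm]]
        if (length(p) != C || any(p < 0) || any(p > 1))
            msgs <- c(msgs, sprintf(
                "covariate '%s': need %d class probabilities in [0,1]", nm, C))
    }
    if (length(msgs)) msgs else TRUE
})

#' ModelFit: likelihood-based fit summary
#'
#' Holds -2 log marginal likelihood, the free-parameter count k, the sample
#' size n, and BIC = -2LL + k * log(n).
#'
#' @slot minus2LL,k,n,BIC numeric scalars.
#' @seealso \code{\link{modelFit}}, \code{\link{computeFit}}
#' @export
setClass("ModelFit", representation(
    minus2LL = "numeric", k = "numeric", n = "numeric", BIC = "numeric"))

setValidity("ModelFit", function(object) {
    if (abs(object@BIC - (object@minus2LL + object@k * log(object@n))) >
        1e-6 * max(1, abs(object@BIC)))
        "BIC must equal minus2LL + k*log(n)" else TRUE
})

#' MixtureRaschModel: fitted mixture-distribution Rasch model
#'
#' Parameters of the latent-class Rasch model: class mixing proportions,
#' class-specific item difficulties (sum-zero within each class), per-class
#' normal latent-trait parameters, and the common discrimination constant.
#' Classes are canonically ordered by descending mixing proportion.
#'
#' @slot nClasses integer C.
#' @slot mixing simplex of length C, descending.
#' @slot difficulties C x I matrix, each row sums to zero.
#' @slot traitMeans,traitSDs per-class latent-trait normal parameters.
#' @slot discrimination common slope (default 1.7).
#' @slot itemNames character of length I.
#' @slot logLik best achieved log marginal likelihood.
#' @slot logLikTrace per-iteration log-likelihood of the winning start
#'   (non-decreasing).
#' @slot converged logical; \code{FALSE} means the iteration cap was hit.
#' @slot iterations,nStarts,quadrature estimation metadata.
#' @export
setClass("MixtureRaschModel", representation(
    nClasses = "integer",
    mixing = "numeric",
    difficulties = "matrix",
    traitMeans = "numeric",
    traitSDs = "numeric",
    discrimination = "numeric",
    itemNames = "character",
    logLik = "numeric",
    logLikTrace = "numeric",
    converged = "logical",
    iterations = "integer",
    nStarts = "integer",
    quadrature = "integer"
))

setValidity("MixtureRaschModel", function(object) {
    msgs <- character()
    C <- object@nClasses
    if (length(object@mixing) != C ||
        abs(sum(object@mixing) - 1) > 1e-6)
        msgs <- c(msgs, "mixing must be a length-C simplex")
    if (is.unsorted(rev(object@mixing), strictly = FALSE))
        msgs <- c(msgs, "classes must be sorted by descending mixing proportion")
    if (nrow(object@difficulties) != C)
        msgs <- c(msgs, "difficulties must have C rows")
    if (ncol(object@difficulties) > 1 &&
        any(abs(rowSums(object@difficulties)) > 1e-6))
        msgs <- c(msgs, "difficulties must be sum-zero within each class")
    if (any(object@traitSDs <= 0)) msgs <- c(msgs, "traitSDs must be > 0")
    if (length(msgs)) msgs else TRUE
})

#' ScaleResult: Mokken scaling diagnostics for one item set
#'
#' @slot itemOrder items sorted by descending sample prevalence (ties
#'   alphabetical); the cumulative ordering used for Guttman errors.
#' @slot Hpair symmetric item x item Loevinger coefficients (NA where the
#'   expected error count is degenerate).
#' @slot Hitem,Hscale per-item and scale-level coefficients.
#' @slot monotonicity data.frame: item, violations (significant restscore
#'   decreases), verdict in \{"ok", "violation", "indeterminate"\}.
#' @slot selectedItems surviving items (subset of the input).
#' @slot audit data.frame log of removals (step, item, reason, value).
#' @export
setClass("ScaleResult", representation(
    itemOrder = "character",
    Hpair = "matrix",
    Hitem = "numeric",
    Hscale = "numeric",
    monotonicity = "data.frame",
    selectedItems = "character",
    audit = "data.frame"
))

#' SubgroupIRTModel: subgroup-specific 1PL or 2PL calibration
#'
#' @slot modelType "1PL" (common discrimination, fixed) or "2PL"
#'   (item-specific discriminations, trait SD fixed to 1).
#' @slot itemNames items calibrated.
#' @slot difficulties sum-zero item locations (logit scale).
#' @slot discriminations per-item slopes; all equal under 1PL.
#' @slot mu,sigma latent-trait normal parameters (sigma estimated under 1PL,
#'   fixed to 1 under 2PL).
#' @slot fit \code{\link{ModelFit-class}} of the calibration.
#' @slot logLikTrace,converged,iterations estimation metadata.
#' @export
setClass("SubgroupIRTModel", representation(
    modelType = "character",
    itemNames = "character",
    difficulties = "numeric",
    discriminations = "numeric",
    mu = "numeric",
    sigma = "numeric",
    fit = "ModelFit",
    logLikTrace = "numeric",
    converged = "logical",
    iterations = "integer"
))

setValidity("SubgroupIRTModel", function(object) {
    msgs <- character()
    I <- length(object@itemNames)
    if (length(object@difficulties) != I ||
        length(object@discriminations) != I)
        msgs <- c(msgs, "one difficulty and one discrimination per item")
    if (I > 1 && abs(sum(object@difficulties)) > 1e-6)
        msgs <- c(msgs, "difficulties must sum to zero")
    if (object@modelType == "1PL" &&
        length(unique(object@discriminations)) > 1)
        msgs <- c(msgs, "1PL requires a common discrimination")
    if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0")
    if (any(object@discriminations <= 0))
        msgs <- c(msgs, "discriminations must be > 0")
    if (length(msgs)) msgs else TRUE
})
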