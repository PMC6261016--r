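---
title: "Phenotyping comorbidity with mixture-distribution item response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping comorbidity with mixture-distribution item response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comirt)
```

## The model and its assumptions

`comirt` treats chronic-condition indicators the way educational measurement
treats test items. A patient's position on a latent "medical complexity"
continuum is θ; each condition *i* has a location β on the same continuum;
and the probability of carrying the condition is the two-parameter logistic

$$P(x_i = 1 \mid \theta) = \frac{1}{1 + e^{-a(\theta - \beta_i)}},$$

so a patient whose complexity equals a condition's location is exactly as
likely as not to have it. The discrimination $a$ is fixed at 1.7 under the
Rasch configuration, which makes the logistic closely track a probit scale
and is the convention used throughout the package's defaults.

Because comorbidity patterns differ qualitatively between subpopulations,
the population model is a *mixture*: latent class $c$ has its own item
locations $\beta_{ic}$, its own trait distribution
$\theta \mid c \sim N(\mu_c, \sigma_c^2)$, and mixing proportion $\pi_c$.
The marginal likelihood of a response vector is

$$p(\mathbf{x}) = \sum_c \pi_c \int
  \prod_i P(x_i \mid \theta, c)\, \phi_c(\theta)\, d\theta ,$$

with the integral evaluated by Gauss–Hermite quadrature (21 nodes by
default, transformed by $\mu_c$, $\sigma_c$). The model assumes
unidimensionality within class, local independence given $(\theta, c)$, and
monotone item response functions — exactly the assumptions the Mokken stage
later audits item by item within each discovered subgroup.

Key identifiability choices, applied consistently by the estimator and the
generator:

* item locations are centred to sum to zero within each class (the trait
  mean absorbs the shift);
* the mixture and 1PL stages fix $a$ and estimate $\sigma_c$; the 2PL stage
  estimates item slopes and fixes $\sigma = 1$;
* classes are reported in descending order of $\hat\pi_c$, which resolves
  label switching deterministically.

## Estimation

Estimation is marginal maximum likelihood by a generalized EM. The E-step
computes responsibilities over (class, quadrature node) pairs; the M-step
updates $\pi_c$ in closed form and takes coordinate Newton steps on the
expected complete-data log-likelihood for the item locations, trait means,
trait SDs and (in the 2PL) slopes. All of those parameters enter through a
linear predictor, so that objective is jointly concave and the Newton steps
are well behaved; steps are additionally clamped, and a step-halving guard
interpolates back toward the previous iterate in the rare case a step would
decrease the quadrature log-likelihood. The EM trace is therefore
non-decreasing by construction, which the test suite asserts on every fitted
trace rather than assuming.

Mixture likelihoods are multimodal, so `fitMixture()` keeps the best of
`n_starts` (default 10) random initializations; difficulties are initialized
from perturbed logit-prevalences. Convergence is declared when the absolute
log-likelihood change falls below `tol` (default 1e-6) within `max_iter`
(default 500) iterations; hitting the cap flags the model rather than
erroring. Duplicate response patterns are collapsed with counts before
estimation, which makes the cost depend on pattern diversity rather than raw
cohort size. Refits with the same seed and config are bit-identical.

Free-parameter counts for BIC are declared explicitly:
$k = C(I-1) + (C-1) + 2C$ for a $C$-class mixture on $I$ items,
$(I-1)+2$ for the subgroup 1PL and $(I-1)+I+2$ for the 2PL. Other software
uses different internal parameterizations, so `modelFit()`/`computeFit()`
accept an explicit $k$ when reproducing a fit table printed under another
convention; BIC comparisons are only meaningful within one convention.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `a` | 1.7 | common discrimination (logit scale); fixed under Rasch/1PL |
| `quadrature` | 21 | Gauss–Hermite nodes; raise (41–81) when comparing likelihoods to external integrations |
| `n_starts` | 10 | random EM restarts for mixtures |
| `tol`, `max_iter` | 1e-6, 500 | EM stopping rule |
| `min_prev`, `max_prev` | 0.05, 0.95 | subgroup prevalence screen; *strictly* outside drops, the boundary is retained |
| `H_min` | 0.3 | minimum item Loevinger H, the conventional lower bound for a usable scale |
| `min_group_size` | 50 | restscore group size for monotonicity trace lines |
| `max_errors` | 1 | Guttman errors tolerated per patient (more than one excludes) |
| `alpha` | 0.05 | level for monotonicity tests, CIs and the Scheffé correction |

## Mokken screening and person fit

Within each subgroup, `pairwiseH()` computes Loevinger coefficients from the
Guttman error cell: for the more prevalent item *i* and rarer item *j*,
$H_{ij} = 1 - F_{ij}/E_{ij}$ where $F_{ij}$ counts patients with $x_i = 0$
and $x_j = 1$ and $E_{ij} = n\,\hat P(x_i{=}0)\hat P(x_j{=}1)$. Item and
scale coefficients aggregate the F and E sums. This error-cell definition is
stated explicitly so the brute-force oracle in the test suite is
unambiguous; pairs with degenerate marginals are excluded from aggregates
rather than silently zeroed.

Monotonicity is checked on restscore trace lines: patients are grouped by
their count of *other* conditions (adjacent groups merged below
`min_group_size`), and every ordered pair of groups is tested for a
significant decrease in item prevalence with a one-sided two-proportion
z-test. Whether such screening should be significance-based or visual is a
judgment call; the package makes it significance-based with `alpha` and the
grouping exposed, because a reproducible pipeline needs a decision rule
rather than an inspection.

`selectScaleItems()` removes monotonicity violators first (worst first,
re-checking after each removal), then items with $H < H_{\min}$ (lowest
first, recomputing after each removal). Fewer than two survivors is an
error: a one-item scale is not a scale, and such subgroups should be
described, not calibrated.

Person fit counts Guttman errors against the subgroup's
descending-prevalence item ordering (ties broken alphabetically — the
ordering must be deterministic and the tie rule is otherwise arbitrary).
Patients with more than one error are excluded as ill-fitting before
calibration. Missing entries are skipped pairwise, so an error count never
increases when unobserved items are appended.

## Subgroup calibration and model choice

`fit1PL()`/`fit2PL()` reuse the single-class EM. The choice between them is
by BIC (`compare1PL2PL()`), with the 2PL's slope dispersion (max/min ratio)
and the likelihood-ratio statistic reported alongside so users who prefer an
informal "are the slopes similar enough" judgment can apply it; no
quantitative threshold for that judgment is imposed. 2PL slopes are bounded
to [0.2, 5] and boundary-pinned estimates are flagged — on small,
person-fit-filtered subgroups the selected patterns can be near-degenerate
and push slopes outward, which should be visible, not hidden.

`iccProfile()` evaluates the fitted curves on a θ grid; each item's
probability-0.5 crossing equals its location exactly, and cross-subgroup
location tables are how a condition can be shown to mark mild complexity in
one subgroup and extreme complexity in another.

## Characterization

`fitCharacterization()` fits a multinomial logistic model for class
membership on one binary covariate and inverts it to model-based margins:
the predicted probability of the covariate's positive category within each
class. In this saturated single-covariate case the margin equals the
class-conditional sample proportion (the test suite asserts equality to
floating tolerance), which keeps the predicted-probability table consistent
with the descriptive table. Confidence intervals use large-sample standard
errors on the logit scale, back-transformed; a class where the covariate is
constant is flagged and its interval widened to [0, 1]. Covariates are
modelled one at a time, matching how marginal profiles are usually
displayed; a joint adjusted model is a deliberate non-goal.

`scheffeGroups()` applies the Scheffé critical value
$\sqrt{(K-1)\chi^2_{K-1,1-\alpha}}$ to all pairwise contrast z-statistics
and assigns compact letters by the standard insert–absorb construction, so
classes sharing a letter are pairwise non-significant after correction. The
insert–absorb form was chosen over a transitive-closure grouping because
closure can chain significantly different classes into one letter when the
non-significance relation is intransitive.

Categorical covariates enter via `dichotomize()`: the most populated
category versus everything else (including "unknown", which folds into the
reference side), with explicit mappings for cases like age bands and a hard
error on modal ties.

## What the synthetic generator does and does not emulate

`generateCohort()` draws classes, traits and Bernoulli responses exactly
from the mixture-Rasch data-generating process, plus class-conditional
Bernoulli covariates. The presets pin every parameter and seed:
`single_class` (n = 2,000, 10 items) for difficulty recovery;
`two_class_easy` (n = 4,000, classes separated by 2.5 logits on half the
items) for assignment and selection recovery; `guttman_perfect`
(deterministic threshold responses) for person-fit edge cases; and
`paper_like` (n = 10,000, 6 classes, 29 conditions) whose mixing
proportions and marginal prevalences echo a large high-risk veteran cohort
— its base difficulties are solved numerically at construction so the
mixture marginals hit the target prevalences (e.g. hypertension 72%).

Because the generator *is* the model, passing recovery tests shows the
estimator and pipeline are correct and well calibrated under the model's
assumptions. It does not show that real EHR data satisfy those assumptions:
real diagnosis indicators carry coding artifacts, informative missingness,
correlated residuals (violating local independence) and drifting
prevalence, none of which are simulated. The covariate scheme in particular
is a testing harness, not a claim about how demographics relate to latent
classes in any real population. Retention rates under the Guttman rule also
depend strongly on scale length: with the presets' 10 roughly
equally-prevalent items, far fewer patients are Guttman-consistent than on
a short 4–6 item clinical scale, so the retained fraction is checked for
stability across seeds rather than against any particular level.

## Numerical choices and degenerate inputs

* Logistic evaluations use the stable `log1p(exp(·))` forms and survive
  |a(θ−β)| up to 700 without overflow; pattern probabilities of all-missing
  rows are 1 (empty product).
* Quadrature accuracy: 21 nodes suffice for estimation; likelihood
  comparisons against dense-grid integration are made at 41–81 nodes where
  1e-6 agreement is expected.
* Item locations are clamped to [−15, 15] and trait SDs to [0.05, 10]
  during EM; all-identical response columns are dropped with a warning
  before subgroup calibration (their locations are not identified).
* Posterior ties in modal assignment go to the lowest class index and are
  logged; `C` exceeding the number of distinct observed response patterns
  is an error.
* Prevalence filters use *observed* cells only, and rows with only missing
  cells count as zero-condition patients: they carry no modelling
  information.
* ICD-9 matching strips the decimal and compares string prefixes
  ("303.*" ⇒ prefix "303"), mirroring how comorbidity code families are
  specified without an external terminology service; dates are accepted
  but ignored unless a window is requested, since cohort-window extraction
  normally happens upstream.

## Pipeline reproducibility

`runPipeline()` derives a deterministic stage seed from the single global
seed and the stage name, so stages can be re-run in isolation while the
whole run stays a pure function of its config. Subgroup-local failures
(too few patients, unscalable items) quarantine that subgroup and the run
continues. The problem sizes used by the shipped tests — cohorts of
1,000–4,000 patients, 10–29 items, class ladders up to 4, and 20-replicate
recovery loops — were chosen as the smallest scales at which the recovery
and calibration properties are stable across seeds.

## Known limitations

* Polytomous items, covariate-dependent mixing, 3PL guessing parameters and
  standard errors for mixture parameters are out of scope.
* Mokken screening covers monotone homogeneity only; double monotonicity /
  invariant item ordering and multi-scale AISP partitioning are not
  implemented.
* The example condition dictionary shipped in `inst/extdata` is synthetic
  and illustrative; it is not a validated clinical code set.
* Model choice by BIC inherits BIC's large-n conservatism; with very large
  cohorts the override mechanism exists precisely because the BIC-minimal
  class count is not always the clinically interpretable one.
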