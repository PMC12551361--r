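---
title: "Methods: imputing dementia status and estimating birth-cohort effects"
author: "apcdem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputing dementia status and estimating birth-cohort effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcdem)
```

## The problem

Harmonized aging panels (HRS-, SHARE- and ELSA-style surveys) interview the
same people every two years but do not carry clinical dementia diagnoses.
Two methodological obstacles stand between such data and a statement like
"people born more recently have lower age-specific dementia prevalence":

1. **Measurement.** Dementia status must be imputed from what the surveys do
   measure — cognitive test scores (word recall, serial 7s, orientation),
   ADL/IADL limitation counts, demographics, and, for respondents too
   impaired to answer themselves, an informant questionnaire (IQCODE-style)
   completed by a proxy.
2. **Identification.** Age, calendar period and birth cohort are linearly
   dependent (age = year − birth year), so a regression with all three
   entered freely is rank deficient.  A measured period *proxy* — here the
   annual GDP growth rate of the respondent's country — replaces calendar
   time and breaks the collinearity while still absorbing period shocks such
   as recessions.

`apcdem` implements both stages plus a synthetic-data generator that makes
the whole pipeline testable by parameter recovery, since the real survey
micro-data are restricted-access.

## Stage 1: ordered-probit imputation of dementia status

Clinical adjudication in validation substudies distinguishes three ordered
states: dementia, cognitively impaired not demented (CIND), and normal.  We
model them with an ordered probit on a latent severity index,

$$P(\text{dementia} \mid x) = \Phi(\kappa_1 + x\beta), \qquad
  P(\text{dementia or CIND} \mid x) = \Phi(\kappa_2 + x\beta),
  \qquad \kappa_1 < \kappa_2 .$$

The orientation is chosen so that a *larger* fitted index $x\beta$ means a
*higher* dementia probability; this removes a sign ambiguity that ordered
models otherwise leave implicit.  Separate models are fitted for
self-respondents (test scores as features) and proxy respondents (informant
score as the cognitive feature), because the instruments differ.  Features
include between-wave *changes* in each cognitive instrument — a decline
carries information beyond the level — with a `first_wave` indicator where no
prior wave exists, and mean-imputation plus missingness indicators for
incomplete items.  The feature lists are configuration, so surveys lacking
an instrument simply drop it.

Estimation is quasi-Newton on the exact log-likelihood with analytic
gradients; the cutpoint order is enforced by optimizing
$\kappa_2 = \kappa_1 + e^g$, features are standardized internally for
conditioning, and three starts (frequency-based plus two jitters) guard
against local optima.  Non-convergence is reported, never silent, and
rank-deficient or separation-prone feature sets raise errors naming the
offending columns.

The fitted class probabilities are turned into a binary status either by
`argmax` or (default) by a cutoff on `p_dementia` chosen on the gold
calibration half to maximize binary accuracy over a 0.005-step grid, ties
going to the lower threshold.  **Validity** is the percentage of gold
*validation* person-waves whose predicted status matches the clinical label;
reporting it out of sample is a deliberate choice — an in-sample figure
would flatter the cutoff selection.

A single-hidden-layer perceptron (ReLU, softmax, cross-entropy, plain
mini-batch gradient descent, early stopping with best-epoch restoration)
re-implements the classifier as a robustness check with the same validity
definition.  Width 32 is the default; the architecture is deliberately
minimal so that training is deterministic under a fixed seed.

## Stage 2: cohort effects with a GDP period proxy

The cohort model is a binary-outcome regression of (imputed) dementia status
on age-group dummies (reference 71–75), cohort dummies (reference: the
survey's earliest cohort) and a period block:

$$\text{dementia}_{i,t} = \delta_0 + \lambda_1\,\text{agegroup}_{a,i,t}
  + \lambda_2\,\text{cohort}_{c,i} + \lambda_3\,\text{period}_{i,t}
  + u_i + \varepsilon_{i,t},$$

where the period block is either survey-year dummies or the single
`gdp_growth` column, and $u_i$ is a person-level normal random intercept.
`check_identifiability()` makes the APC problem concrete: with continuous
age, year and birth-year columns the design's null space is exactly
$(1, -1, 1)$, and the function reports it; the GDP-proxy design is full
rank.

### Fitting

The mixed model is fitted by maximizing the marginal likelihood with
**adaptive Gauss–Hermite quadrature** (default 9 nodes, configurable).
Nodes are centered per person at the posterior mode of $u_i$ with spread
from the curvature there; within each outer iteration the adapted grid is
held fixed so the objective is smooth with an exact analytic gradient, and
the grid is refreshed until the optimum is a fixed point.  This in-package
fitter exists because the pipeline's validation rests on hundreds of
Monte-Carlo refits and on cluster-robust inference: per-person score vectors
fall out of the quadrature directly, giving the clustered sandwich
covariance in both the mixed and fixed-effect paths.  The fitter is
cross-checked in the test suite against `lme4::glmer(nAGQ = 9)` on a shared
fixture (coefficients and intercept SD agree to ~0.02, with our fixed point
attaining at least as high a likelihood) and, for the no-RE path, against an
independent IRLS probit to 1e-6.

Conventions: probit link by default (coefficients live on the same
latent-normal scale as the generator and the classifier; logit is
available), 95% CIs are $\pm 1.96$ SE with two-sided normal p-values,
marked `**` below .01 and `*` below .05.  Cluster-robust covariances use
HC0 without a small-sample cluster adjustment, so with one observation per
cluster they coincide with the heteroskedasticity-robust covariance — the
large-sample survey convention.  Both the model-based and clustered
covariances are retained in the fit object because the literature mixes the
two; the clustered one is reported by default.

## The synthetic cohort generator

`sim_config()` + `simulate_panel()` generate panels whose latent cognition
is

$$c_{i,t} = \lambda_{\text{age}}(a_{i,t}) + \lambda_{\text{coh}}(c_i)
  + \gamma\, g_{k(i),t} + u_i + \varepsilon_{i,t},$$

with three-class truth assigned by two cutpoints (lower latent = worse;
dementia is the lowest category).  GDP growth is a stationary AR(1) per
country.  `degrade_to_observables()` then maps latent cognition to what a
survey sees: integer-rounded, range-truncated affine-plus-noise test scores
(recall 0–20, serial 7s 0–5, orientation 0–4), binomial ADL/IADL counts with
rates decreasing in cognition, a proxy flag whose probability rises as
cognition falls, and an informant score (1–5, decreasing in cognition) that
replaces the self tests for proxy person-waves.
`assign_gold_standard()` emulates a one-time clinical substudy: a simple
random sample of persons labeled at one observed wave, split 50/50 into
calibration and validation halves.

Default study conditions (chosen once, as a realistic regime for this kind
of panel, and not tuned thereafter): 10,000 persons, six biennial waves
2010–2020, births 1910–1948, age effects stepping −0.25 per five-year group,
cohort shifts rising to +0.55 for 1944–1948 (the scale of the gradients the
method is meant to detect), GDP loading 0.05 per percentage point,
person-intercept SD 0.5, occasion SD 1, cutpoints (−1.65, −0.65) placing
baseline prevalence near 5–7% at ages 71–75 and past 30% beyond 90, roughly
10% proxy person-waves, 10% gold fraction, and 5% per-wave attrition that is
independent of cognition by default (`attrition_latent_slope` exists to
exercise the mortality-selection caveat: panels under-count dementia when
the sickest die between waves).

What the generator does **not** emulate: survey weights, household
clustering, country heterogeneity beyond the GDP series, informative
non-response beyond the optional attrition link, and the true multivariate
distribution of real cognitive batteries (the affine-plus-noise score model
is a stand-in, not a claim about the surveys).  Passing tests therefore
demonstrate internal correctness and recoverability under a known
generating process — not that real-survey validity equals the synthetic
figure.

## Monte-Carlo validation design

The acceptance suite rests on parameter recovery under a reduced four-cohort
dialect (1929–1948 in five-year bins) with true dementia-scale cohort
effects $(0, -0.2, -0.3, -0.5)$ and GDP-driven period effects:

* sign and ordering of the cohort gradient recovered by the GDP-mode GLMM
  in at least 90% of 100 replicates at 10,000 persons;
* 95% CI coverage of the true coefficients within [90%, 99%] over 200
  replicates at 2,000 persons;
* sign concordance of year-dummy and GDP-proxy fits across 20 replicates
  (fixed-effects path, which is consistent for signs and keeps the
  comparison cheap);
* classifier validity at least 85% out of sample on the default regime,
  with the perceptron within 5 points of the ordered probit.

These problem sizes are scaled down from the surveys' hundreds of thousands
of person-waves; they were chosen so the whole suite completes on a desktop
while leaving the Monte-Carlo error far smaller than the margins being
asserted.  Replicate fits are warm-started at the generating values purely
as an optimization accelerator — the maximum-likelihood estimate does not
depend on the start, and the convergence criteria are unchanged.

## Numerical choices and edge cases

* Ordered-probit interval probabilities are computed with a tail-stable
  $\log(\Phi(a)-\Phi(b))$ (upper-tail differences flipped to lower-tail
  form) and floored at 1e-300.
* With only the two extreme classes present the model reduces to a binary
  probit with a single cutpoint; the fit then matches `glm`'s probit
  log-likelihood to 1e-6 and predicts zero CIND mass.
* Quadrature node count below ~5 is not recommended for person-intercept
  SDs approaching 1; the default 9 matches the accuracy of `glmer`'s AGQ
  on our fixtures.  The intercept-SD search is bounded away from zero at
  1e-6 on the log scale; truly zero variance collapses cleanly onto the
  GLM.
* Rounding of all printed percentages and coefficients is half-away-from-
  zero (one decimal for percentages, two for coefficients), which is the
  convention under which descriptive tables recompute exactly from their
  counts.
* Cohort bins are closed on both ends and must tile the covered years;
  birth years outside every bin and ages of 70 or below are excluded with
  logged counts, never silently.
* Cells (age group or cohort) with zero observations have their dummy
  dropped with a warning naming the cell.

## Known limitations

* The gold-standard emulation labels one wave per person; real clinical
  substudies have their own non-response and a time lag to the linked
  waves.
* Imputation error attenuates downstream cohort coefficients relative to
  fits on true status; the package reports what the data support and makes
  the attenuation visible in simulation by fitting both outcomes.
* The GLMM assumes a normal, exchangeable person intercept; no serial
  correlation within person beyond it.
* Survey weights and country fixed effects within pooled Europe are out of
  scope; country enters only through its GDP series.
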