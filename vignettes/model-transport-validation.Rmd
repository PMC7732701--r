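---
title: "Transporting an adolescent depression risk model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transporting an adolescent depression risk model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprisk)
```

## The problem

A risk model for adolescent depression is developed in one setting (a
low-prevalence birth cohort, about 3.1% developing depression) and is to be
used in another (a school survey cohort with follow-up prevalence around
11.8%). Transporting a clinical prediction model across settings raises two
separate questions: does it still *discriminate* (rank high-risk adolescents
above low-risk ones), and is it still *calibrated* (do predicted
probabilities match observed rates)? `deprisk` implements the full workflow:
coding raw survey answers into harmonized predictors, fitting a penalized
logistic model, and evaluating it under three updating regimes of increasing
aggressiveness — frozen coefficients (standard external validation), an
intercept update (recalibration-in-the-large), and a full refit.

## From survey items to predictors

Depression status at each wave follows the DSM-IV major-depression rule on
nine binary symptom items: positive when five or more items are endorsed
*and* at least one of the two core symptoms (depressed mood, anhedonia) is
among them (`classify_depression()`).

Seven predictors are harmonized across settings:

* `sex_female` — female indicator;
* `maltreatment` — ordered `none < probable < severe`: *severe* when the
  respondent reports "a lot" of domestic violence or physical abuse;
  *probable* when both are reported "a little", or the respondent does not
  live with a biological parent; everything else is *none*. The survey does
  not define the mixed case ("a little" on exactly one exposure while living
  with a parent); we code it conservatively as *none*, since only the severe
  and probable categories are defined positively;
* `school_failure` — ever repeated a class;
* `social_isolation` — zero close friends;
* `fights` — started a fight *and* hurt someone on purpose (a conjunction);
* `ran_away` — ran away from home for many days;
* `drug_use` — any use ("a little" or "a lot") of alcohol, cigarettes, or
  marijuana.

Records with a missing value in any coding input are excluded
(complete-case) with an audited count; no imputation is attempted because
the workflow this emulates reported none. The analysis sample is then
selected by an inclusive baseline age window (default 14–16) and exclusion
of adolescents already depressed at baseline; `select_analysis_sample()`
returns the filtered cohort together with a `selection_flow` audit of the
counts at each stage.

## The risk model

The model is logistic with an L2 (ridge) penalty on the slopes only:

$$\hat\beta = \arg\max_\beta \; \ell(\beta) - \frac{\lambda}{2}\sum_{j\ge1}\beta_j^2,$$

with the intercept unpenalized, fitted by Newton iteration with
step-halving (`fit_penalized()`, convergence tolerance 1e-8 on the
coefficient change, at most 100 iterations). λ is an absolute penalty, not
scaled per observation; `penalty = 0` reduces to ordinary maximum
likelihood, which the test suite verifies against a brute-force likelihood
grid and `stats::glm`, and the penalized path against `glmnet` at matched
scaling. At `penalty = 0` separated data are detected and reported with
advice to use a positive penalty. The original tuning procedure behind the
transported model is not recorded, so the default is 10-fold
cross-validated deviance over a small grid (`cv_penalty()`, stratified
folds, fixed seed), with an explicit `penalty` override.

Maltreatment enters the design as two dummies (reference `none`) rather
than a linear score: the three levels are defined qualitatively and there
is no reason to force equal spacing. Rebuilding the model on a predictor
subset (`rebuild_without_predictors()`) is a genuine refit on the retained
columns, not deletion of coefficients — the two are only equivalent when
predictors are independent, which real data are not.

## The performance panel

For predicted probabilities $p_i$ and linear predictor $\mathrm{lp}_i$:

* **Brier score** $\frac1n\sum (p_i - y_i)^2$; 0 is perfect, and the
  constant predictor at the event rate scores $\bar p(1-\bar p)$.
* **AUC** by the rank formula, equal to the pairwise concordance
  probability with ties counting one-half. The confidence interval is a
  stratified percentile bootstrap (cases and non-cases resampled
  separately, default B = 2000, fixed seed). The variant of
  "bootstrap-corrected" interval used in the original work is not recorded;
  the stratified percentile form was chosen because it is simple, never
  leaves a resample with one class, and is reproducible under a seed.
* **Calibration-in-the-large (CITL)**: the intercept $a$ of the offset
  logistic fit $\mathrm{logit}\,P(y{=}1) = a + \mathrm{offset}(\mathrm{lp})$.
  Defining CITL on the logit scale (rather than as a probability-scale
  difference) makes "CITL = 0 after an intercept update" an exact identity
  and matches standard recalibration practice; the probability-scale
  difference is exposed as a secondary field.
* **Calibration slope**: $b$ from
  $\mathrm{logit}\,P(y{=}1) = a + b\,\mathrm{lp}$; 1 is ideal, below 1
  indicates over-extreme (overfitted) predictions.
* **Unreliability test**: the likelihood-ratio statistic comparing the free
  recalibration model $(a, b)$ against the fixed $(0, 1)$ model, referred
  to a χ² distribution with 2 degrees of freedom. A likelihood-ratio form
  was chosen over Wald/score because it is exact about the two nested fits
  actually performed.
* **Flexible calibration curve**: a local-linear loess smooth
  (span 0.75, 100-point grid restricted to the observed probability range)
  with 95% pointwise bands from the smoother's standard errors, plus decile
  group points. Above 10,000 observations the smoother is fitted on an
  evenly thinned (by sorted probability) subset, which bounds the memory of
  the standard-error computation without materially changing the curve.
  The bands are *pointwise*: their errors are correlated along the grid, so
  the fraction of grid points covering the ideal line fluctuates between
  single draws even for a perfectly calibrated model; the stable property
  (and the one tested) is the average coverage over replicates.
* **Wilson score interval** for prevalences.

## The three regimes

`validate_all()` runs, on one identical validation set with one shared
bootstrap seed (so regime comparisons are paired):

1. **standard** — coefficients and intercept frozen;
2. **adjusted** — intercept shifted by the CITL estimated on the validation
   data; slopes untouched. Discrimination is computed on the *unadjusted*
   scores: a monotone intercept shift cannot change the risk ranking, so the
   adjusted regime's AUC equals the standard regime's exactly, and computing
   it that way avoids spurious floating-point tie churn when distinct
   predictor patterns have coincidentally equal coefficient sums;
3. **refitted** — all coefficients re-estimated on the validation data.
   The default is unpenalized maximum likelihood, under which the in-sample
   CITL is 0 and the slope is 1 by the score equations; a `penalty`
   argument supports a shrunken refit, since published refits do not always
   display the exact in-sample identities.

`validation_table()` assembles the four-row metric panel (Brier, AUC with
CI, CITL, slope) across regimes, formatted to 2 decimals with the unrounded
values attached. `sensitivity_by_age()` repeats the whole triple after
re-selecting the sample for each baseline age window (defaults 15–15 and
11–17 alongside the main 14–16 window).

## The synthetic cohort generator

No individual-level data from either setting are distributable, so the
package ships a generator that emulates the *statistical structure* the
analysis assumes and makes every stage testable.

* **Marginals.** Predictors are drawn independently with defaults matching
  the school-survey setting: 49.4% female, school failure 25.8%, fights
  3.9%, drug use 6.0%, social isolation 4.4%, ran away 2.3%, maltreatment
  probable 18.4% / severe 6.7%. Independence is a modelling choice forced
  by the absence of any published joint distribution; real survey
  predictors are correlated (e.g. fighting and substance use), so
  generator-based results say nothing about performance under predictor
  correlation.
* **Outcome model.** `depressed_followup ~ Bernoulli(plogis(c* + k·xβ +
  drift))`, with the intercept `c*` solved so that the *population* mean
  probability equals the target prevalence (11.8% validation, 3.1%
  development). Because the predictor space is finite (192 cells for the
  seven predictors), the expectation is computed exactly by cell
  enumeration and the root found by bisection to 1e-6 — deterministic,
  with no Monte-Carlo error. The shrinkage factor `k` and intercept
  `drift` let tests inject known miscalibration;
  `inject_miscalibration()` applies the same transform on the model side,
  and validating the transformed model on data from the original recovers
  slope ≈ 1/k and CITL ≈ −drift.
* **Generating coefficients.** The transported model's original
  coefficients were never published, so the defaults (log-odds 0.62 female,
  0.35/0.90 maltreatment probable/severe, 0.55 school failure, 0.60
  isolation, 0.50 fights, 0.70 ran away, 0.55 drug use) were fixed once as
  plausible moderate risk-factor effects; at the default marginals they
  give an AUC in the low 0.6s, the discrimination range typical of
  questionnaire-based adolescent risk scores. They are study conditions,
  not tuning knobs.
* **Raw survey fixture.** `generate_raw_survey(lagos_raw_spec())` emits
  item-level records whose selection flow is exact by construction: 3171
  followed up → 2321 aged 14–16 → 393 of those baseline-depressed → 1928
  final (976 male / 952 female). The seed only shuffles record order and
  item-level realizations. Symptom vectors are drawn conditional on the
  intended depression status (so reclassification reproduces the status by
  construction), and raw answers are drawn uniformly over representations
  consistent with the coded value, so recoding round-trips exactly.
  Coded cohorts from `generate_coded_cohort()` represent the
  *analysis-ready* population (baseline-depressed rate 0 by default); the
  raw fixture owns the selection flow.

## Problem sizes and numerical choices

The test suite and acceptance script use: exhaustive enumeration for the
512 symptom profiles and 18 maltreatment combinations; n = 50,000 draws for
the definition anchors (true-model slope, chance AUC) and n = 100,000 for
parameter recovery (slope within ±0.1 of 1/k for k ∈ {0.5, 0.8, 2}, CITL
within ±0.05 of −drift); 1000 null simulations at n = 2000 for the
unreliability test's type-I error; and cohorts of 2,500–30,000 for the
regime properties. These sizes keep Monte-Carlo error comfortably below
the asserted tolerances. Ties in the AUC are handled by average ranks;
bisection and Newton tolerances are stated above; degenerate inputs
(single-class outcomes, zero-variance linear predictors, empty selections,
all-predictors-dropped rebuilds) raise informative errors or warnings
rather than propagating nonsense.

## Known limitations

* Independent predictors and a correctly specified logistic outcome model
  make the generator an easy case: passing parameter-recovery tests shows
  the estimators are implemented correctly, not that the model transports
  well to real populations.
* The generator does not emulate school-level clustering, nonresponse, or
  measurement differences between self-report and clinical interview — all
  of which plausibly drive real-world miscalibration.
* The four predictors unavailable at validation are simulated generically;
  their real distributions are unknown here.
* The flexible calibration curve's bands are pointwise, not simultaneous.
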