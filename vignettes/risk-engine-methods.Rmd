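---
title: "Methods: a four-state progression model for risk-based retinopathy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-state progression model for risk-based retinopathy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

## The problem

Diabetic eye screening programmes photograph the retina at (roughly) fixed
intervals and refer anyone found with sight-threatening features. A blanket
annual interval spends most of its episodes on people at very low risk while
still missing some fast progressors. `retscreen` implements a risk
calculation engine for individualised intervals: it models progression
through four per-person retinopathy states —

1. no retinopathy,
2. non-referable retinopathy in one eye,
3. non-referable retinopathy in both eyes,
4. referable retinopathy (screen-positive, absorbing),

— predicts each person's probability of reaching state 4 within 6, 12 and
24 months, and allocates the longest interval whose predicted risk does not
exceed an agreed threshold (2.5% by default).

## The model

Progression is a continuous-time Markov process on the four states with the
permitted instantaneous moves 1↔2, 2→3, 3→2, 2→4 and 3→4. Each intensity is
log-linear in five clinical covariates:

\[
\log \lambda_{ij} = \beta^0_{ij} + \sum_C \beta^C_{ij}\,(x_C - \bar x_C),
\]

with \(C\) ranging over age at diagnosis (years), duration of known diabetes
(years), HbA1c (mmol/mol), total cholesterol (mmol/l) and systolic blood
pressure (mmHg). Centering constants \(\bar x_C\) are the cohort means at
first screening and are stored in the fitted model, so
\(\exp(\beta^C_{ij})\) is always the per-unit hazard ratio and
\(\exp(\beta^0_{ij})\) the baseline intensity of a person at cohort-mean
covariates. The intensities populate a generator \(Q\) whose rows sum to
zero, with row 4 identically zero (screen-positive is absorbing for
allocation purposes).

Progression risk is not constant in time since first screen: transitions are
more likely early. This is captured by a Weibull operational-time
transformation \(u = t^\alpha\) with a single shared shape \(\alpha\)
(default 0.9, estimated from data when fitting): the process is an ordinary
homogeneous Markov chain on the \(u\) clock, so

\[
P(t_1, t_2) = \exp\!\big(Q\,(t_2^\alpha - t_1^\alpha)\big),
\]

which reduces to \(P(t) = \exp(Q t^\alpha)\) from baseline. Operational time
accumulates from the subject's first screening episode; a per-interval reset
would make the interval probabilities depend on an arbitrary visit schedule,
which breaks the Markov property on the \(u\) clock, so accumulation is the
implemented convention (the prediction engine, by contrast, deliberately
restarts the clock at the prediction episode, because a new prediction is
made each time fresh clinical information arrives).

### Interval censoring

Screening data are panel data: the state is known only at visit times, never
the moment of transition. The likelihood therefore multiplies interval
probabilities: for a subject observed in states \(s_0, s_1, \dots\) at times
\(t_0 < t_1 < \dots\),

\[
\ell = \sum_k \log P_{s_{k-1}, s_k}(t_{k-1}, t_k),
\]

with \(Q\) rebuilt from the covariates recorded at each interval's left
endpoint (covariates are treated as piecewise constant between episodes).
Arrival in state 4 needs no special casing — its probability is the
\((s, 4)\) entry of the interval matrix, integrating over all unobserved
paths and transition times. Observed jumps such as 1→3 across an interval
are legal: they pass through state 2 between visits.

## Fitting

`fit_mle()` maximises the panel likelihood by L-BFGS-B with analytic
gradients. The gradient of each interval probability is obtained from the
eigendecomposition of \(Q\) (the divided-difference formula
\(\partial P = V (F \circ (V^{-1} \partial Q\, V)) V^{-1}\)); a
scaling-and-squaring fallback with finite differences covers near-defective
generators (reciprocal condition number of the eigenvector matrix below
1e-10). Numerical choices that matter:

* Covariate columns are standardised internally (coefficients are returned
  per unit); without this, the mix of scales (mmHg vs mmol/l) conditions the
  problem badly enough to slow convergence several-fold.
* Intensities are floored at 1e-12 per year, and the log intensities are
  bounded below at −25, so a transition with no observed events settles at
  an effectively-zero rate rather than diverging.
* An interval probability below 1e-20 — possible only through floored
  (structurally forbidden) paths — is treated as impossible: the likelihood
  is \(-\infty\) and the offending subject and interval are reported.
* \(\alpha\) is estimated on the log scale within (0, 2]; convergence uses
  the optimiser's default gradient and relative-change tolerances
  (`factr = 1e7`, `pgtol = 1e-5`, overridable via `control`).

Standard errors come from the inverse observed information (`optimHess` on
the analytic gradient). `aicc()` uses the subject count as \(n\): subjects,
not episodes, are the independent units of a panel.

### Covariate selection

`select_covariates()` follows a ranked nested procedure: fit the full model
with all candidates, rank candidates by their joint Wald statistic (the
quadratic form over the candidate's six transition coefficients), then fit
the nested sequence baseline → +1st → +2nd → … and choose the smallest
AICc. Ranking from the joint full model is the default; one-at-a-time
marginal ranking is available (`marginal = TRUE`). The reported "% explained
likelihood" is defined as
\(100 (\ell_k - \ell_{\text{base}}) / (\ell_{\text{full}} - \ell_{\text{base}})\)
against the state-only baseline model and the all-candidates full model;
this anchoring (0% at baseline, 100% at full) is a documented
interpretation — other anchorings are possible and no equivalence to any
published table is claimed.

## Missing covariates

Two regimes, matching the two uses of the model:

* **Fitting** uses chained-equations multiple imputation
  (`multiple_impute()`, default \(m = 10\)): each incomplete covariate is
  regressed on the other four plus observed state and episode time, and its
  gaps are filled with posterior-predictive draws (residual variance from a
  scaled chi-square, coefficients from their multivariate normal, then
  observation noise), with 5 burn-in cycles. Covariates below 80%
  completeness are refused — exclude them from the model instead. Fits on
  the \(m\) copies can be pooled by Rubin's rules (`pool_fits()`); for
  predictions the \(m\) predicted probabilities are averaged instead,
  because the probability is the decision quantity.
* **Prediction** must work on a single new observation, so it uses worst-case
  single imputation: missing values are replaced by the covariate's 75th
  percentile among non-missing baseline values (linear interpolation between
  order statistics — the convention is pinned for reproducibility), giving a
  deliberately pessimistic risk. The percentiles are stored inside the model
  file so a deployed model is self-contained.

## Interval allocation

`predict_risk()` returns \(P_{s,4}(0, h)\) at each candidate horizon with
the clock restarted at the prediction episode; `allocate_interval()` returns
the longest horizon whose risk does not exceed the threshold, treating a
risk exactly at the threshold as acceptable, and falls back to the shortest
offered interval (6 months) when even that exceeds the threshold. Risks are
non-decreasing in the horizon because state 4 is absorbing, and lowering the
threshold can only shorten intervals.

## Validation and policy accounting

`screening_outcomes()` reduces a panel to per-subject outcome records. The
event time of a screen positive is the midpoint of the interval between the
last negative and first positive screen — the transition time itself is
censored; in simulation studies the exact hidden time can be substituted.
On these records:

* `concordance_index()` — pairwise concordance with ties counting one half;
  a pair is comparable when one subject's event precedes the other's event
  or falls within the other's follow-up.
* `horizon_discrimination()` — cases had events by the horizon, controls
  were event-free through it; AUC by rank comparison, sensitivity and
  specificity from classifying risk above the threshold as positive.
* `kfold_validate()` — subject-level folds (default 4) stratified by
  baseline state to stabilise the event count per fold (plain random
  splitting is recovered by removing the stratification, but the stratified
  default is deliberate: with a few hundred events, an unlucky split
  otherwise starves a fold); each fold is scored on predictions from a model
  fitted without it, pooled before scoring.
* `bootstrap_optimism()` — subject-level bootstrap (default \(B = 200\),
  floor 50): optimism is the mean of (metric of the resample fit on the
  resample) − (same fit on the original data); corrected = apparent −
  optimism.
* `episode_accounting()` — people allocated 6/12/24 months attend 4/2/1
  episodes over two years; the annual reference is 2 per person. A screen
  positive is correctly allocated if the (midpoint) event time is at or
  after the allocated date; a screen negative only by the maximal interval,
  with under-24-months follow-up excluded. Under a blanket annual policy no
  screen negative can be correctly allocated, which is the structural
  baseline the individualised policy is compared against.

## The cohort simulator

`simulate_cohort()` is first-class, tested code: it generates panel data
with exactly the structure the model assumes, so every downstream claim can
be checked against a known truth.

* The chain is simulated **exactly** in operational time by competing
  exponential clocks (inverse transform \(t = u^{1/\alpha}\)), not by Euler
  stepping — the simulator is therefore a valid generative oracle for the
  likelihood.
* The default truth is `reference_model()`: per-unit hazard ratios and
  1-year baseline transition probabilities representative of an established
  UK screening cohort, with baseline intensities obtained by
  `calibrate_baseline_intensities()` (principal matrix logarithm of a
  completed probability matrix, projected to the permitted sparsity, then
  least-squares refinement; achieved residual below 1e-10).
* Visit schedule: 5 visits, gaps Normal(1.0, 0.15²) years truncated at
  0.25 — annual screening with realistic jitter. Observation is panel-style:
  states are recorded at visits only and the record stops at the first
  observed screen positive.
* Covariates are drawn once per subject at baseline from a truncated
  multivariate normal (means 55 y, 8 y, 58 mmol/mol, 4.9 mmol/l, 134 mmHg;
  SDs 12, 5.5, 14, 1.1, 16; mild positive correlations, e.g. 0.2 between
  duration and HbA1c). These are plausible diabetes-population values chosen
  once for realism; no claim is made that they match any particular
  programme, and all are config-overridable.
* Baseline states are drawn from (0.60, 0.25, 0.15) over states 1–3 — a
  screening population dominated by no-retinopathy.
* Missingness is MCAR per covariate cell, capped at 0.2 in keeping with the
  80%-completeness rule.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: grading misclassification (the model has no
hidden-Markov layer), eye-level disease, informative visit schedules,
covariate drift within follow-up, and informative missingness (a MAR stress
mode for the imputation module is the natural extension). Real-data
performance claims require external validation.

## Problem sizes used by the test and acceptance runs

Chosen as the package's own study conditions: parameter recovery uses 10
replicate cohorts of 2,000 subjects with 5 annual visits (50 replicates is
the appropriate nightly setting); at 10 replicates a per-coefficient
coverage check is statistically meaningless, so Wald 95% CI coverage is
pooled over all coefficient–replicate pairs. Monte-Carlo agreement of
observed 1-year transition fractions with \(\exp(Q)\) uses 50,000 subjects
per starting state at baseline covariates, compared on the six permitted
transitions. Cross-validated discrimination uses a 2,000-subject cohort with
fourfold splitting.

```{r example, eval = FALSE}
# end-to-end sketch
d <- simulate_cohort(sim_config(n_subjects = 2000, miss_rate = 0.05, seed = 1))
imp <- multiple_impute(d, m = 10, seed = 1)
fit <- fit_mle(imp$datasets[[1]], dr_covariates())
fit$model$percentile75 <- worst_case_reference(d)
pred <- predict_cohort(fit$model, d, threshold = 0.025)
table(pred$interval_months)
```

## Known limitations

The shape parameter is shared across all six transitions; transition-specific
shapes would need many more events. Covariates enter all six transitions
whenever active — per-transition subsets are not searched. The likelihood
treats covariates as constant within an interval at their left-endpoint
value; rapidly changing HbA1c between visits is smoothed over. Disease
duration is fixed at its baseline value by default (`baseline_duration =
FALSE` updates it per episode, but then duration and the time scale are
partially confounded). Fits with very sparse transitions (under a handful of
events on a move) return that intercept at its floor with unavailable
standard errors rather than failing.
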