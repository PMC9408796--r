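---
title: "Modelling three-wave GHQ-12 panels with ghqwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling three-wave GHQ-12 panels with ghqwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ghqwave analyses short ordinal-questionnaire panels — the motivating design is
a travel-study cohort answering the 12-item General Health Questionnaire
(GHQ-12) at three waves: before a trip (wave 0), at return (wave 1), and one
month later (wave 2). This vignette is the package's methods account: the
model, its assumptions, the tunable parameters, the synthetic-data generator,
and the numerical and design choices a maintainer would want written down.

## The model

Each item response is an ordered category $y \in \{0,1,2,3\}$. The package
fits a multilevel regression formulation of the Graded Response Model of item
response theory. Latent distress for person $p$ at a person-wave enters the
linear predictor

$$\eta_{pi} = \theta_p + \sum_{j=1}^{J} \beta_j x_{jpi},$$

with $\theta_p$ the person-specific mental distress and $x_j$ the design
covariates (wave dummies with wave 0 as reference, an indicator for sex
category 2 with category 1 — men — as reference, standardized age, seasonal
terms, diarrhoea flags, and optionally wave-by-season interactions). Item
responses follow a cumulative-logit link with item discrimination $a_i$ and
ordered thresholds $\tau_{ik}$:

$$\Pr(y \le k) = \operatorname{logit}^{-1}\!\big(a_i(\tau_{ik} - \eta)\big),
\qquad a_i = \exp(\mathrm{log\_disc}_i).$$

Discriminations are modelled on the log scale so they are always positive,
and with this parameterization a negative wave coefficient means *less*
distress at that wave. The model ladder is:

* **m1** — thresholds shared across items, plus a bivariate item-level random
  effect: a threshold shift and a log-discrimination deviation with estimated
  SDs and correlation (3 + 2 threshold-structure parameters);
* **m3** — fully item-specific thresholds ($3 \times 12$ parameters);
* **m4** — m3 plus time-of-year and diarrhoea covariates;
* **m5** — m4 plus wave-by-season interaction terms.

The "model 2" of the ladder is m1 refitted on multiply imputed data via
`fit_pooled()`.

**Identification.** The person effect is fixed to $\theta_p \sim N(0, 1)$
(`person_sd` in `model_spec()`), so the latent scale is carried by the
discriminations. This is an interpretive choice: the analysis this package
implements reports a discrimination intercept but no person-SD, which is
consistent with a unit-variance person effect.

**Seasonality.** Time of year is encoded as
$\cos(2\pi t/360)$ and $\sin(2\pi t/360)$ where $t$ counts days since
2018-08-12 (the first trip-return date of the emulated cohort). The 360-day
period is the annual cycle; writing the period as 360 days rather than 365
changes the phase by under a week across the study window and keeps the
angular arithmetic in round numbers. Whether the seasonal-interaction model
should carry both sine and cosine interactions is genuinely open (only the
cosine interaction is typically interpretable as "pre- versus post-November
trips"); `model_spec("m5", sine_interactions = FALSE)` keeps the
cosine-only form, and the default includes all four interaction columns.

**Priors** (weakly informative, fixed in the JAGS code and stated here
because the original analysis software's defaults are not documented):
regression coefficients $N(0, 5)$; thresholds and the log-discrimination
intercept Student-t(3, 0, 2.5); random-effect SDs half-Student-t(3, 0, 2.5);
the item random-effect correlation uniform on $(-1, 1)$. With hundreds to
thousands of item responses these priors are dominated by the likelihood for
every structural parameter; the sensitivity that remains is in the item
random-effect SDs at small item counts.

**Sampling.** Posterior draws come from MCMC via JAGS (rjags). Defaults are
4 chains, 1000 warmup and 1000 retained iterations; the simulation studies in
the test suite use reduced profiles (2 chains, 150–300 warmup, 100–300
retained) chosen as the package's desk-scale test sizes. Convergence is gated
on rank-normalized split-chain $\widehat{R} < 1.05$ for every monitored
parameter — the gate is strict, and a fit failing it is *flagged*, never
silently returned as converged. Effective sample sizes come from coda.

## The synthetic-data generator

The raw study data are not deposited, so the generator is the package's
test bed. Its defaults emulate the printed study conditions:

| quantity | default | origin |
|---|---|---|
| persons | 174 | cohort size |
| men | 27% | printed marginal |
| age | Uniform(18, 65) | printed range; uniform approximately matches the printed SD 16.49 without inventing a shape |
| items × waves | 12 × 3 | instrument and design |
| trip-return dates | 16 equally spaced, 2018-08-12 – 2019-03-10 | printed count and endpoints |
| diarrhoea during / after | 71% / 13% | printed marginals |
| coverage per wave | 98% / 76% / 72% | printed item-response counts |
| partial responders | ≤ 2 | printed attrition description |
| item parameters | thresholds (−1.54, 2.73, 6.23), disc intercept −0.06, sd(disc) 0.32, sd(thr) 1.29, cor 0.35 | the shared-threshold model's reported posterior means |
| wave effects | −0.63 (wave 1), −0.21 (wave 2) | the covariate model's reported posterior means |

Attrition deletes whole person-waves (missingness in the emulated study was
almost entirely person-level), with at most `max_partial_responders` persons
receiving item-level deletion to absorb sub-person remainders; after that
budget is spent, targets are matched to the nearest whole person. The default
mechanism is missing-completely-at-random; an `"mnar"` mode (deletion odds
increasing with the person-wave's distress) exists for imputation stress
tests. The diarrhoea flags are drawn independently of each other and of
$\theta$ — the source tables give only marginals, so independence is an
assumption, flagged as such; a `diarrhoea_joint` hook lets users inject
dependence.

What the generator does *not* emulate: the joint covariate distribution
beyond printed marginals, informative missingness (by default), item-wording
effects, and any dependence of diarrhoea on distress. Passing tests therefore
demonstrate that the machinery recovers what it assumes — not that the
substantive findings would replicate on the real cohort.

## Scoring and classical tests

Both scoring systems are implemented: the 0–36 Likert sum of raw categories
and the 0–12 interpreted (0-0-1-1) score, with caseness defined as
interpreted score ≥ 3. Scoring is complete-case: a person-wave missing any
item yields missing scores, matching the convention in which per-wave
respondent counts fall below the cohort size; no proration rule is invented.
Display percentages round half-up; raw proportions are kept in the machine
output. The printed 0–36 "Range" column of such tables is ambiguous between
theoretical and observed ranges; the summary object reports the theoretical
range in print and keeps observed min/max available from the data.

The "complete-data linear model" across waves is read as a one-way
fixed-effects ANOVA on person-wave sums treating person-waves as independent
(the printed denominator degrees of freedom equal the summed per-wave
respondent counts minus three, which supports this reading). Paired
two-sided t-tests compare waves on the Likert sum by default — the wording
"sum score" points to the 0–36 sum — with `use = "interpreted_score"` as the
alternative; no multiplicity correction is applied, as none is reported in
the original analysis.

## Imputation

`pmm_chained_impute()` implements multiple imputation by chained equations
with predictive mean matching, operating at the item level in wide format
(one column per wave-item cell) — the analysis imputed item responses rather
than sums, so that is the default here. Donor pool size is 5 (the
conventional default), sweeps default to 10, and the per-imputation
between-dataset variability comes from bootstrap-parameter PMM (the
regression used to predict the missing rows is fitted on a bootstrap
resample of the observed rows). Imputed values are always observed donor
categories. Covariates (the diarrhoea flags, sex, age) are treated as fully
observed and are not imputed. Pooling concatenates per-dataset posterior
draws with equal weight, the mixture representation of the
multiple-imputation posterior; convergence is assessed per dataset.

## Model comparison

PSIS-LOO is implemented in-package: importance ratios per observation are
tail-smoothed with a generalized-Pareto fit (the Zhang–Stephens
empirical-Bayes estimator, tail size $\lceil \min(0.2S, 3\sqrt{S}) \rceil$),
and the Pareto shape $k$ is reported per observation with a warning when any
$k > 0.7$. The LOO observation unit is one item response
(person-wave-item), matching the likelihood's factorization. The sign
convention of `compare_models()` is stated in its output documentation:
`delta_looic = looic(a) − looic(b)`, positive when `a` is the worse model.
The implementation is validated against exact closed-form leave-one-out on a
conjugate normal toy.

## Reporting

`predict_wave_sums()` is the posterior-predictive check in sum-score units:
for each draw, item responses are simulated for the observed person-waves
(complete-case person-waves by default, mirroring the observed-summary
convention; `mode = "all_items"` predicts every item) and averaged within
wave. `seasonal_effect_curve()` evaluates, per unique trip-return date, the
posterior of the wave's total coefficient — main effect plus interaction
terms times the date's cosine/sine — summarized by the posterior mean and an
equal-tailed 95% interval (the interval type is a choice; equal-tailed
quantiles are used throughout). The canonical artifact is the numeric
per-date table; `autoplot()` renders figures from it.

## Numerical notes and degenerate inputs

* Category probabilities are successive differences of logistic cumulative
  probabilities; they telescope to 1 exactly, and log-likelihoods floor the
  probability at `1e-300` before taking logs.
* Items with a single observed category are allowed (thresholds then mostly
  prior-driven) and trigger a warning.
* Constant data make the wave ANOVA error explicitly rather than return an
  undefined F; identical paired vectors return $t = 0, p = 1$.
* A PSIS input in which all draws agree is rejected as degenerate.
* All randomness flows through explicit seeds (`withr::with_seed`); the
  generator derives per-stage streams from the config seed, and each JAGS
  chain gets a deterministic RNG seed, so identical configs are
  byte-identical.

## Test problem sizes

The simulation studies in the test suite are run at reduced, fixed sizes
chosen once as the package's desk-scale profile: parameter recovery uses 10
replicate cohorts of 90 persons × 12 items × 3 waves at the study's coverage
rates (2 chains, 200 warmup, 350 retained draws); the model-preference
experiment uses 20 replicates of 40 persons × 6 items with balanced base
thresholds and strongly item-specific threshold spacing, so that all
thresholds are data-informed and the experiment has power to detect the
structure it tests; the imputation robustness check uses one 90-person
cohort with 3 imputations. The acceptance script runs the full pipeline at
the emulated study scale (174 × 12 × 3).

## Known limitations

* JAGS's Gibbs/slice sampling mixes more slowly than Hamiltonian Monte Carlo
  on the correlated threshold/discrimination posterior; the discrimination
  intercept is the slowest-mixing parameter, and short-profile fits can fail
  the $\widehat{R}$ gate (they are then flagged, and downstream reporting
  refuses them unless forced).
* The person trait is wave-constant; a person-wave random effect (local
  dependence across items within a visit) is not modelled.
* The generator's attrition is person-wave-granular by design; arbitrary
  item-level missingness patterns beyond the small partial-responder budget
  are out of scope.
* LOOIC differences on small cohorts carry large standard errors; the
  package reports SEs from pointwise differences and leaves interpretation
  to the user.
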