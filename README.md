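# ghqwave

Bayesian graded-response modelling of longitudinal GHQ-12 well-being panels.

`ghqwave` is for epidemiologists and psychometricians analysing short ordinal
questionnaire panels — specifically a three-wave travel-study design in which
participants answer the 12-item General Health Questionnaire (GHQ-12, four
ordered categories per item) before a trip (wave 0), at return (wave 1), and
one month after (wave 2), with wave-structured attrition. Because such cohort
data are rarely shareable, the package pairs the analysis machinery with a
synthetic-cohort generator that emulates the study's printed marginals, so
every stage is testable end to end.

## The model

Responses follow a multilevel regression formulation of the Graded Response
Model. Latent distress enters the linear predictor

$$\eta_{pi} = \theta_p + \sum_{j=1}^{J}\beta_j x_{jpi}, \qquad
\theta_p \sim N(0, 1),$$

and each item's ordered response obeys a cumulative-logit link with
log-scale discrimination and ordered thresholds,

$$\Pr(y \le k) = \operatorname{logit}^{-1}\!\big(e^{d_i}(\tau_{ik} - \eta)\big).$$

The model ladder: **m1** shares thresholds across items with correlated
item-level random effects (threshold shift, log-discrimination); **m3** uses
fully item-specific thresholds; **m4** adds time-of-year
($\cos 2\pi t/360$, $\sin 2\pi t/360$) and travellers'-diarrhoea covariates;
**m5** adds wave-by-season interactions. A multiply imputed refit of m1
(chained equations with predictive mean matching) probes attrition bias.
Models are compared by PSIS-LOO (LOOIC), and posterior-predictive checks are
reported in GHQ-12 sum-score units. Sampling is MCMC via JAGS with a strict
rank-normalized split-$\widehat{R} < 1.05$ convergence gate.

## Worked example

```r
library(ghqwave)

study <- simulate_ghq_study(cohort_config(n_persons = 40, seed = 3))
descriptive_summary(study$responses, study$persons)
#> Cohort characteristics
#>   N (total)                   40
#>   Men                          9   23%
#>   Diarrhoea during trip       30   75%
#>   Diarrhoea after trip         5   13%
#>   Age mean (sd) [range]     39.7 (12.2) [19-61]
#> Per wave
#>   wave 0:  470 item responses ( 98%), cases 3/39 (8%), Likert sum 7.59 (3.45)
#>   wave 1:  365 item responses ( 76%), cases 0/30 (0%), Likert sum 6.30 (3.11)
#>   wave 2:  348 item responses ( 73%), cases 2/29 (7%), Likert sum 7.76 (3.31)
```

Coverage tracks the configured 98/76/72% targets; cases are person-waves with
interpreted (0-0-1-1) score ≥ 3, and distress dips at wave 1 because the
generator's default wave effects are negative on the latent scale. Classical
tests and a model fit:

```r
sc <- score_ghq(study$responses)
wave_tests(sc)
#> # A tibble: 4 × 7
#>   comparison     statistic   df1   df2 p_value mean_diff n_pairs
#> 1 wave_anova         1.78      2    95  0.174     NA          NA
#> 2 wave1_vs_wave0    -2.50     29    NA  0.0182    -1.07       30
#> 3 wave2_vs_wave0     0.418    27    NA  0.679      0.179      28
#> 4 wave2_vs_wave1     2.00     20    NA  0.0596     1.19       21

fit <- fit_grm(study$responses, study$persons, spec = model_spec("m1"),
               chains = 2, warmup = 200, iter = 200, seed = 1)
tidy(fit)          # posterior means, SDs, 95% credible intervals
grm_loo(fit)       # PSIS-LOO: elpd, looic, Pareto-k diagnostics
predict_wave_sums(fit, force = TRUE)  # observed vs predicted wave sums
```

At this toy scale the wave-1 drop is visible (paired p ≈ 0.02) while the
short two-chain run is honestly flagged `converged: FALSE`; production runs
use the 4-chain, 1000-draw default. `run_pipeline()` chains all stages
(simulate/load → score → tests → fits → LOO → imputation → reports) and
writes every artifact plus a JSON manifest recording config hash and seeds.

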