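Package: ghqwave
Title: Bayesian Graded-Response Modelling of Longitudinal GHQ-12 Well-Being Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation, scoring and Bayesian multilevel analysis of three-wave
    General Health Questionnaire (GHQ-12) panel data. Provides a synthetic cohort
    generator emulating a longitudinal travel study with wave-structured attrition,
    both GHQ-12 scoring systems with caseness classification, classical wave
    comparisons, a multilevel graded-response (ordinal IRT) model with covariate
    regression on the latent distress trait sampled by MCMC via JAGS, multiple
    imputation by chained equations with predictive mean matching, Pareto-smoothed
    importance-sampling leave-one-out model comparison (LOOIC), posterior-predictive
    checks in sum-score units, and seasonal (cyclic) effect curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
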