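# Independent oracle implementations: deliberately share no code with the
# package (own logistic, explicit loops, textbook formulas).

ilogit_ref <- function(x) 1 / (1 + exp(-x))

# Category probability by brute-force differences of the cumulative curve.
grm_prob_ref <- function(y, eta, log_disc, tau) {
  a <- exp(log_disc)
  cum <- function(k) {
    if (k < 0) return(0)
    if (k >= length(tau)) return(1)
    ilogit_ref(a * (tau[k + 1] - eta))
  }
  cum(y) - cum(y - 1)
}

# Explicit-loop log-likelihood over a long response table.
loglik_ref <- function(responses, design, params) {
  total <- 0
  for (r in seq_len(nrow(responses))) {
    y <- responses$response[r]
    if (is.na(y)) next
    drow <- design[design$person_id == responses$person_id[r] &
                     design$wave == responses$wave[r], ]
    eta <- params$theta[[as.character(responses$person_id[r])]]
    for (nm in names(params$beta)) eta <- eta + params$beta[[nm]] * drow[[nm]]
    it <- responses$item[r]
    total <- total + log(grm_prob_ref(y, eta, params$log_disc[it],
                                      params$thresholds[it, ]))
  }
  total
}

# Textbook one-way ANOVA from explicit sums of squares.
anova_ref <- function(values, groups) {
  g <- split(values, groups)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- n - length(g)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Textbook paired t from the mean/SD of the differences.
paired_t_ref <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# Small default study used by several test files.
tiny_study <- function(n_persons = 20, n_items = 4, seed = 42,
                       effects = c(wave1 = -0.6, wave2 = -0.2),
                       coverage = c(1, 1, 1)) {
  simulate_ghq_study(cohort_config(
    n_persons = n_persons, n_items = n_items, seed = seed,
    true_effects = effects, coverage_targets = coverage
  ))
}

# Random parameter set for a toy problem (used by likelihood oracle checks).
random_toy <- function(seed) {
  withr::with_seed(seed, {
    np <- sample(2:4, 1)
    ni <- sample(2:3, 1)
    nw <- sample(2:3, 1)
    persons <- tibble::tibble(
      person_id = seq_len(np),
      sex = stats::rbinom(np, 1, 0.5),
      age = stats::runif(np, 20, 60),
      diarrhoea_trip = stats::rbinom(np, 1, 0.5),
      diarrhoea_after = stats::rbinom(np, 1, 0.5),
      t_days = sample(0:210, np, replace = TRUE)
    )
    responses <- tidyr::crossing(person_id = seq_len(np), wave = 0:(nw - 1),
                                 item = seq_len(ni)) |>
      dplyr::mutate(response = sample(0:3, dplyr::n(), replace = TRUE))
    covs <- c("sex2", "age_z", "wave1", "cos_t")
    design <- build_design(persons, n_waves = nw, covariates = covs)
    params <- list(
      beta = stats::setNames(stats::rnorm(length(covs), 0, 0.5), covs),
      theta = stats::setNames(stats::rnorm(np), as.character(seq_len(np))),
      log_disc = stats::rnorm(ni, 0, 0.3),
      thresholds = t(apply(matrix(stats::rnorm(ni * 3, 0, 2), ni, 3), 1, sort))
    )
    list(responses = responses, design = design, params = params)
  })
}
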