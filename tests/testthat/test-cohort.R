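test_that("generate_cohort reproduces the configured marginals deterministically", {
  cfg <- cohort_config(n_persons = 174, frac_men = 0.27, seed = 1)
  p1 <- generate_cohort(cfg)
  p2 <- generate_cohort(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 174)
  # men count is a binomial draw around 0.27 * 174 = 47
  lims <- stats::qbinom(c(0.0005, 0.9995), 174, 0.27)
  expect_gte(sum(p1$sex == 1), lims[1])
  expect_lte(sum(p1$sex == 1), lims[2])
  expect_gte(min(p1$age), 18)
  expect_lte(max(p1$age), 65)
  expect_equal(mean(p1$age_z), 0, tolerance = 1e-12)
  expect_true(all(p1$t_days >= 0))
  expect_true(all(p1$trip_return_date %in% cfg$trip_return_dates))
  expect_length(unique(cfg$trip_return_dates), 16)
})

test_that("cohort_config validates its invariants", {
  expect_error(cohort_config(frac_men = 1.2), class = "ghqwave_error")
  expect_error(cohort_config(trip_return_dates = as.Date(character())),
               class = "ghqwave_error")
  expect_error(cohort_config(coverage_targets = c(1, 1)), class = "ghqwave_error")
  expect_error(cohort_config(age_range = c(65, 18)), class = "ghqwave_error")
  expect_error(cohort_config(n_items = 1), class = "ghqwave_error")
})

test_that("item parameters honour the bivariate random-effect structure", {
  # zero-variance degenerate: all items identical, thresholds = shared
  it0 <- draw_item_parameters(n_items = 5, re_sd_disc = 0, re_sd_thr = 0,
                              seed = 1)
  expect_true(all(it0$log_disc == it0$log_disc[1]))
  expect_equal(unname(as.matrix(it0[, c("tau_1", "tau_2", "tau_3")])[3, ]),
               c(-1.54, 2.73, 6.23))
  # ordering always preserved, with and without scatter
  for (s in 1:10) {
    it <- draw_item_parameters(n_items = 8, threshold_scatter_sd = s %% 3,
                               seed = s)
    tau <- as.matrix(it[, c("tau_1", "tau_2", "tau_3")])
    expect_true(all(apply(tau, 1, function(r) all(diff(r) > 0))))
  }
  # Monte-Carlo: empirical SD of log_disc near the generating value
  big <- draw_item_parameters(n_items = 10000, re_sd_disc = 0.32, seed = 2)
  se <- 0.32 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sd(big$log_disc) - 0.32), 3 * se)
  expect_error(draw_item_parameters(shared_thresholds = c(1, 1, 2)),
               class = "ghqwave_error")
  expect_error(draw_item_parameters(re_cor = 1.5), class = "ghqwave_error")
})

test_that("simulated responses follow the closed-form category probabilities", {
  # single person replicated 10000 times at a fixed (eta, item)
  persons <- tibble::tibble(person_id = 1:10000, sex = 0, age = 40,
                            t_days = 0, diarrhoea_trip = 0, diarrhoea_after = 0)
  items <- draw_item_parameters(n_items = 1, shared_thresholds = c(-1, 0.5, 2),
                                disc_intercept = 0.2, re_sd_disc = 0,
                                re_sd_thr = 0, seed = 1)
  resp <- simulate_item_responses(persons, items, effects = c(wave1 = 0),
                                  person_sd = 0, n_waves = 1, seed = 9)
  freq <- tabulate(resp$response + 1L, nbins = 4) / nrow(resp)
  p <- grm_category_probs(0, 0.2, c(-1, 0.5, 2))[1, ]
  mc_se <- sqrt(p * (1 - p) / nrow(resp))
  expect_true(all(abs(freq - p) < 3 * mc_se))

  # determinism and limit behaviour
  r1 <- simulate_item_responses(persons[1:50, ], items,
                                effects = c(wave1 = 0), seed = 4)
  r2 <- simulate_item_responses(persons[1:50, ], items,
                                effects = c(wave1 = 0), seed = 4)
  expect_identical(r1, r2)
  huge <- draw_item_parameters(n_items = 1, shared_thresholds = c(5, 6, 7),
                               disc_intercept = log(1e6), re_sd_disc = 0,
                               re_sd_thr = 0, seed = 1)
  r3 <- simulate_item_responses(persons[1:100, ], huge,
                                effects = c(wave1 = 0), person_sd = 0, seed = 5)
  expect_true(all(r3$response == 0))
  expect_error(
    simulate_item_responses(persons[1:5, ], items, effects = c(nope = 1)),
    class = "ghqwave_error"
  )
})

test_that("attrition hits coverage targets at person-wave granularity", {
  study <- tiny_study(n_persons = 174, n_items = 12, seed = 11)
  full <- study$responses_complete
  out <- apply_attrition(full, c(0.98, 0.76, 0.72),
                         max_partial_responders = 2, seed = 3)
  tot <- 174 * 12
  counts <- table(factor(out$wave, levels = 0:2))
  targets <- round(c(0.98, 0.76, 0.72) * tot)
  expect_true(all(abs(as.integer(counts) - targets) <= 12))
  # at most 2 persons partially observed in any wave
  partial <- out |>
    dplyr::summarise(k = dplyr::n(), .by = c("person_id", "wave")) |>
    dplyr::filter(k > 0, k < 12)
  expect_lte(nrow(partial), 2)
  # deletion only: surviving records keep their values
  joined <- dplyr::inner_join(out, full, by = c("person_id", "wave", "item"))
  expect_equal(joined$response.x, joined$response.y)
  # trivial targets
  expect_identical(apply_attrition(full, c(1, 1, 1), seed = 1), full)
  gone <- apply_attrition(full, c(1, 0, 1), seed = 1)
  expect_equal(sum(gone$wave == 1), 0)
  expect_error(apply_attrition(full, c(1, 2, 1)), class = "ghqwave_error")
})

test_that("null generator yields homogeneous category distributions across waves", {
  rejected <- 0
  for (s in 1:50) {
    persons <- generate_cohort(cohort_config(n_persons = 30, n_items = 4,
                                             seed = s))
    items <- draw_item_parameters(n_items = 4, re_sd_disc = 0, re_sd_thr = 0,
                                  shared_thresholds = c(-1, 0.5, 2), seed = 1)
    resp <- simulate_item_responses(persons, items,
                                    effects = c(wave1 = 0, wave2 = 0),
                                    person_sd = 0, n_waves = 3, seed = s + 100)
    tab <- table(resp$wave, resp$response)
    p <- suppressWarnings(stats::chisq.test(tab))$p.value
    if (p < 0.01) rejected <- rejected + 1
  }
  expect_lte(rejected, 2)
})

test_that("the full generator pipeline is deterministic given config + seed", {
  s1 <- simulate_ghq_study(cohort_config(n_persons = 25, n_items = 5, seed = 8))
  s2 <- simulate_ghq_study(cohort_config(n_persons = 25, n_items = 5, seed = 8))
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$persons, s2$persons)
})
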