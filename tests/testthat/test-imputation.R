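structural_draws_of <- function(fit, term) {
  idx <- match(sub("^b_", "", term), fit$spec$covariates)
  fit$draws$beta[, idx]
}

test_that("complete data pass through imputation unchanged", {
  study <- tiny_study(n_persons = 10, n_items = 3, seed = 4)
  imp <- pmm_chained_impute(study$responses_complete, study$persons,
                            imputation_config(m = 3, seed = 1),
                            n_items = 3, n_waves = 3)
  expect_length(imp$datasets, 3)
  for (d in imp$datasets) {
    j <- dplyr::inner_join(d, study$responses_complete,
                           by = c("person_id", "wave", "item"))
    expect_equal(j$response.x, j$response.y)
  }
})

test_that("a forced donor pool yields the only possible value", {
  # item 2's observed values are all category 2, so every imputation of its
  # missing cells must be 2
  resp <- tidyr::crossing(person_id = 1:12, wave = 0:1, item = 1:2) |>
    dplyr::mutate(response = ifelse(.data$item == 1,
                                    rep_len(0:3, dplyr::n()), 2L))
  resp$response[resp$item == 2 & resp$person_id <= 3] <- NA
  persons <- tibble::tibble(person_id = 1:12, sex = rep_len(0:1, 12),
                            age = 20 + 1:12, t_days = 30,
                            diarrhoea_trip = 0L, diarrhoea_after = 0L)
  imp <- pmm_chained_impute(resp, persons, imputation_config(m = 4, seed = 2),
                            n_items = 2, n_waves = 2)
  for (d in imp$datasets) {
    expect_true(all(d$response[d$item == 2] == 2L))
    expect_false(anyNA(d$response))
    expect_true(all(d$response %in% 0:3))
  }
})

test_that("observed cells are never altered and draw counts pool correctly", {
  study <- tiny_study(n_persons = 14, n_items = 3, seed = 9,
                      coverage = c(0.95, 0.7, 0.7))
  imp <- pmm_chained_impute(study$responses, study$persons,
                            imputation_config(m = 2, seed = 3),
                            n_items = 3, n_waves = 3)
  obs <- study$responses |> dplyr::filter(!is.na(.data$response))
  for (d in imp$datasets) {
    j <- dplyr::inner_join(d, obs, by = c("person_id", "wave", "item"))
    expect_equal(j$response.x, j$response.y)
  }
  # determinism
  imp2 <- pmm_chained_impute(study$responses, study$persons,
                             imputation_config(m = 2, seed = 3),
                             n_items = 3, n_waves = 3)
  expect_identical(imp$datasets, imp2$datasets)
  # column with zero observed values is rejected
  none <- study$responses |> dplyr::filter(!(.data$item == 1 & .data$wave == 0))
  expect_error(pmm_chained_impute(none, study$persons,
                                  imputation_config(m = 1),
                                  n_items = 3, n_waves = 3),
               class = "ghqwave_error")
})

test_that("with m = 1 the pooled fit reduces to a single fit_grm call", {
  study <- tiny_study(n_persons = 12, n_items = 3, seed = 15,
                      coverage = c(1, 0.8, 0.8))
  imp <- pmm_chained_impute(study$responses, study$persons,
                            imputation_config(m = 1, seed = 1),
                            n_items = 3, n_waves = 3)
  spec <- model_spec("m1", covariates = c("wave1", "wave2"))
  pooled <- fit_pooled(imp, study$persons, spec = spec,
                       chains = 2, warmup = 150, iter = 100, seed = 7)
  single <- fit_grm(imp$datasets[[1]], study$persons, spec = spec,
                    chains = 2, warmup = 150, iter = 100, seed = 7)
  expect_equal(pooled$pooled$b_wave1, structural_draws_of(single, "b_wave1"))
  expect_equal(nrow(tidy(pooled)), nrow(tidy(single)))
  # pooled draw count = m x per-dataset retained draws
  imp3 <- pmm_chained_impute(study$responses, study$persons,
                             imputation_config(m = 3, seed = 1),
                             n_items = 3, n_waves = 3)
  pooled3 <- fit_pooled(imp3, study$persons, spec = spec,
                        chains = 2, warmup = 150, iter = 100, seed = 7)
  expect_equal(length(pooled3$pooled$b_wave1), 3 * 2 * 100)
  expect_type(pooled3$converged, "logical")
})

test_that("imputed categories track the generator's distribution under MCAR", {
  study <- simulate_ghq_study(cohort_config(
    n_persons = 500, n_items = 6, seed = 20,
    coverage_targets = c(0.98, 0.76, 0.72), max_partial_responders = 2
  ))
  imp <- pmm_chained_impute(study$responses, study$persons,
                            imputation_config(m = 20, max_iterations = 5,
                                              seed = 5),
                            n_items = 6, n_waves = 3)
  truth <- study$responses_complete |>
    dplyr::anti_join(study$responses, by = c("person_id", "wave", "item"))
  imputed <- purrr::map_dfr(imp$datasets, function(d) {
    dplyr::semi_join(d, truth, by = c("person_id", "wave", "item"))
  })
  p_true <- tabulate(truth$response + 1L, 4) / nrow(truth)
  p_imp <- tabulate(imputed$response + 1L, 4) / nrow(imputed)
  tvd <- sum(abs(p_true - p_imp)) / 2
  expect_lt(tvd, 0.1)
})

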