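# One small converged-ish fit shared by the reporting tests.
reporting_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      study <- tiny_study(n_persons = 24, n_items = 4, seed = 17,
                          effects = c(wave1 = -0.7, wave2 = -0.2))
      fit <<- fit_grm(study$responses, study$persons,
                      spec = model_spec("m3",
                                        covariates = c("wave1", "wave2")),
                      chains = 2, warmup = 300, iter = 300, seed = 4)
    }
    fit
  }
})

test_that("seasonal curve identities hold exactly", {
  draws <- data.frame(wave1 = rnorm(200, -0.6, 0.1),
                      wave1_cos = rnorm(200, 0.3, 0.05),
                      wave1_sin = rnorm(200, -0.2, 0.05),
                      wave2 = rnorm(200, -0.2, 0.1))
  # zero interactions: flat curve at the main effect for every date
  flat <- seasonal_curve_points(draws["wave2"], t_days = c(0, 45, 180, 300),
                                wave = 2)
  expect_equal(flat$estimate, rep(mean(draws$wave2), 4), tolerance = 1e-12)
  expect_equal(flat$conf.low, rep(flat$conf.low[1], 4), tolerance = 1e-12)
  # at t = 0: total = wave + wave_cos exactly, per draw
  at0 <- seasonal_curve_points(draws, t_days = 0, wave = 1)
  expect_equal(at0$estimate, mean(draws$wave1 + draws$wave1_cos),
               tolerance = 1e-12)
  # 360-day periodicity
  a <- seasonal_curve_points(draws, t_days = 33, wave = 1)
  b <- seasonal_curve_points(draws, t_days = 33 + 360, wave = 1)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
  expect_equal(a$conf.low, b$conf.low, tolerance = 1e-9)
  expect_error(seasonal_curve_points(draws["wave2"], 0, wave = 1),
               class = "ghqwave_error")
})

test_that("credible intervals nest with the nominal level", {
  draws <- data.frame(wave1 = rnorm(500, -0.5, 0.2),
                      wave1_cos = rnorm(500, 0.2, 0.1))
  lv <- lapply(c(0.5, 0.8, 0.95), function(l) {
    seasonal_curve_points(draws, t_days = 120, wave = 1, level = l)
  })
  for (i in 1:2) {
    expect_lt(lv[[i + 1]]$conf.low, lv[[i]]$conf.low)
    expect_gt(lv[[i + 1]]$conf.high, lv[[i]]$conf.high)
    expect_true(lv[[i]]$conf.low < lv[[i]]$estimate &
                  lv[[i]]$estimate < lv[[i]]$conf.high)
  }
})

test_that("the fitted seasonal curve needs interaction terms and plots", {
  fit <- reporting_fit()
  expect_error(seasonal_effect_curve(fit), class = "ghqwave_error")
  study <- tiny_study(n_persons = 20, n_items = 3, seed = 23)
  fit5 <- fit_grm(study$responses, study$persons, spec = model_spec("m5"),
                  chains = 2, warmup = 200, iter = 150, seed = 5)
  curve <- seasonal_effect_curve(fit5)
  expect_s3_class(curve, "ghq_seasonal_curve")
  expect_equal(sort(unique(curve$wave)), c(1, 2))
  # one entry per unique trip-return date and wave
  n_dates <- length(unique(fit5$persons$trip_return_date))
  expect_equal(nrow(curve), 2 * n_dates)
  expect_true(all(curve$conf.low <= curve$estimate &
                    curve$estimate <= curve$conf.high))
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
})

test_that("posterior-predictive wave sums are calibrated on the generator", {
  fit <- reporting_fit()
  pred <- predict_wave_sums(fit, force = TRUE, seed = 2)
  n_items <- length(fit$item_levels)
  expect_true(all(pred$predicted_mean >= 0 &
                    pred$predicted_mean <= 3 * n_items))
  expect_true(all(pred$predicted_sd >= 0))
  # the observed mean should sit well inside the predictive distribution
  gap <- abs(pred$observed_mean - pred$predicted_mean)
  expect_true(all(gap < 4 * pred$predicted_mean_sd))
  # determinism given seed
  pred2 <- predict_wave_sums(fit, force = TRUE, seed = 2)
  expect_equal(pred$predicted_mean, pred2$predicted_mean)
  p <- autoplot(pred)
  expect_s3_class(p, "ggplot")
})

test_that("prediction refuses a non-converged fit unless forced", {
  fit <- reporting_fit()
  fit_bad <- fit
  fit_bad$converged <- FALSE
  expect_error(predict_wave_sums(fit_bad), class = "ghqwave_error")
  expect_s3_class(predict_wave_sums(fit_bad, force = TRUE),
                  "ghq_wave_prediction")
})

test_that("package probabilities agree with an independent implementation", {
  withr::with_seed(41, {
    for (i in 1:30) {
      eta <- rnorm(1, 0, 2)
      ld <- rnorm(1, 0, 0.4)
      tau <- sort(rnorm(3, 0.5, 1.5))
      p <- grm_category_probs(eta, ld, tau)[1, ]
      ref <- vapply(0:3, grm_prob_ref, numeric(1), eta = eta, log_disc = ld,
                    tau = tau)
      expect_equal(unname(p), ref, tolerance = 1e-12)
    }
  })
})
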