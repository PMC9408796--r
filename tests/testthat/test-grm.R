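test_that("category probabilities match direct evaluation of the logistic", {
  p <- grm_category_probs(0, 0, c(-1, 0, 1))[1, ]
  ref <- c(ilogit_ref(-1), 0.5 - ilogit_ref(-1), ilogit_ref(1) - 0.5,
           1 - ilogit_ref(1))
  expect_equal(unname(p), ref, tolerance = 1e-12)
  expect_equal(unname(p), c(0.26894, 0.23106, 0.23106, 0.26894),
               tolerance = 1e-4)
  # eta at a threshold: cumulative probability exactly one half
  p2 <- grm_category_probs(0.7, 0.3, c(-2, 0.7, 3))[1, ]
  expect_equal(unname(p2[1] + p2[2]), 0.5, tolerance = 1e-12)
  expect_error(grm_category_probs(0, 0, c(1, 1, 2)), class = "ghqwave_error")
})

test_that("probabilities normalize and are monotone in the latent trait", {
  withr::with_seed(31, {
    for (i in 1:25) {
      eta <- stats::rnorm(7, 0, 3)
      tau <- sort(stats::rnorm(3, 0, 2))
      ld <- stats::rnorm(1, 0, 0.5)
      p <- grm_category_probs(eta, ld, tau)
      expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
      expect_true(all(p >= -1e-15))
      # P(y >= k) strictly increasing in eta for every k >= 1
      es <- seq(-4, 4, length.out = 30)
      ps <- grm_category_probs(es, ld, tau)
      for (k in 2:4) {
        upper <- rowSums(ps[, k:4, drop = FALSE])
        expect_true(all(diff(upper) > 0))
      }
    }
  })
})

test_that("log-likelihood equals the explicit-loop oracle on toy problems", {
  for (s in 1:10) {
    toy <- random_toy(s)
    got <- grm_loglik(toy$responses, toy$design, toy$params)
    ref <- loglik_ref(toy$responses, toy$design, toy$params)
    expect_equal(got$total, ref, tolerance = 1e-12)
    expect_equal(sum(got$pointwise$log_lik), got$total, tolerance = 1e-12)
  }
  # single observation and additivity
  toy <- random_toy(77)
  one <- toy$responses[3, ]
  got1 <- grm_loglik(one, toy$design, toy$params)
  drow <- toy$design[toy$design$person_id == one$person_id &
                       toy$design$wave == one$wave, ]
  eta <- toy$params$theta[[as.character(one$person_id)]] +
    sum(unlist(toy$params$beta) * unlist(drow[names(toy$params$beta)]))
  pk <- grm_category_probs(eta, toy$params$log_disc[one$item],
                           toy$params$thresholds[one$item, ])[1, one$response + 1]
  expect_equal(got1$total, unname(log(pk)), tolerance = 1e-12)
  both <- grm_loglik(dplyr::bind_rows(toy$responses, toy$responses),
                     toy$design, toy$params)
  expect_equal(both$total, 2 * grm_loglik(toy$responses, toy$design,
                                          toy$params)$total, tolerance = 1e-12)
  # missing responses contribute nothing
  withna <- toy$responses
  withna$response[1:3] <- NA
  expect_equal(grm_loglik(withna, toy$design, toy$params)$total,
               grm_loglik(toy$responses[-(1:3), ], toy$design,
                          toy$params)$total, tolerance = 1e-12)
  bad <- toy$responses
  bad$response[1] <- 5L
  expect_error(grm_loglik(bad, toy$design, toy$params), class = "ghqwave_error")
})

test_that("rank-normalized split R-hat behaves at its reference points", {
  withr::with_seed(5, {
    # independent same-distribution chains: R-hat close to 1
    m <- matrix(stats::rnorm(4000), 1000, 4)
    expect_gt(split_rhat(m), 0.99)
    expect_lt(split_rhat(m), 1.02)
    # grossly separated chains (rank normalization bounds the statistic,
    # but far above any reasonable gate)
    m2 <- cbind(stats::rnorm(500), stats::rnorm(500, 100))
    expect_gt(split_rhat(m2), 1.5)
    # within-chain drift is caught by splitting
    m3 <- cbind(c(stats::rnorm(250), stats::rnorm(250, 5)),
                c(stats::rnorm(250), stats::rnorm(250, 5)))
    expect_gt(split_rhat(m3), 1.5)
    expect_true(is.na(split_rhat(matrix(1, 100, 2))))
  })
})

test_that("the convergence gate is strict at 1.05", {
  diag <- tibble::tibble(parameter = c("a", "b", "c"),
                         rhat = c(1.00, 1.049, NA))
  expect_true(check_convergence(diag)$pass)
  diag$rhat[2] <- 1.051
  res <- check_convergence(diag)
  expect_false(res$pass)
  expect_equal(res$offending$parameter, "b")
  # exactly at the gate fails (strict inequality)
  expect_false(check_convergence(tibble::tibble(parameter = "a",
                                                rhat = 1.05))$pass)
  # single chain: R-hat undefined
  fake <- structure(list(meta = list(chains = 1)), class = "grm_fit")
  expect_error(check_convergence(fake), class = "ghqwave_error")
})

test_that("fit_grm returns a complete posterior contract on a small cohort", {
  study <- tiny_study(n_persons = 18, n_items = 4, seed = 2,
                      effects = c(wave1 = -0.8, wave2 = -0.2))
  fit <- fit_grm(study$responses, study$persons,
                 spec = model_spec("m1", covariates = c("wave1", "wave2")),
                 chains = 2, warmup = 200, iter = 200, seed = 1)
  expect_s3_class(fit, "grm_fit")
  # every monitored parameter carries an R-hat and an ESS
  expect_true(all(c("beta[1]", "theta[1]", "disc[1]", "tau[1,1]", "sd_thr",
                    "cor_dt") %in% fit$diagnostics$parameter))
  expect_true(all(is.finite(fit$diagnostics$ess)))
  expect_equal(dim(fit$draws$beta), c(400, 2))
  expect_equal(dim(fit$draws$tau), c(400, 4, 3))
  # thresholds ordered in every draw
  expect_true(all(apply(fit$draws$tau, c(1, 2), function(r) all(diff(r) > 0))))
  td <- tidy(fit)
  expect_true(all(c("b_wave1", "sd_thr", "cor_dt", "tau0_2") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(study$responses))
  expect_type(gl$converged, "logical")
  # item-specific variant drops the shared-threshold components
  fit3 <- fit_grm(study$responses, study$persons,
                  spec = model_spec("m3", covariates = c("wave1", "wave2")),
                  chains = 2, warmup = 200, iter = 200, seed = 1)
  expect_false(any(grepl("sd_thr|cor_dt", tidy(fit3)$term)))
  expect_error(fit_grm(study$responses[study$responses$item == 1, ],
                       study$persons, model_spec("m1")),
               class = "ghqwave_error")
})

test_that("a never-observed covariate keeps its prior", {
  study <- tiny_study(n_persons = 12, n_items = 3, seed = 6,
                      effects = c(wave1 = -0.5, wave2 = 0))
  persons <- study$persons
  persons$diarrhoea_after <- 0L # identically zero column
  fit <- fit_grm(study$responses, persons,
                 spec = model_spec("m3",
                                   covariates = c("wave1", "wave2",
                                                  "diarrhoea_after")),
                 chains = 2, warmup = 300, iter = 1500, seed = 3)
  b <- fit$draws$beta[, 3]
  # prior is Normal(0, 5): mean near 0, SD within 20%
  expect_lt(abs(mean(b)), 3 * 5 / sqrt(length(b)))
  expect_gt(sd(b), 4)
  expect_lt(sd(b), 6)
})
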