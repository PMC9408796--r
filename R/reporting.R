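#' Posterior-predictive wave means of the GHQ-12 sum score
#'
#' For each retained posterior draw, simulates item responses for the observed
#' person-waves from the fitted graded-response model (reusing
#' the model's category probabilities), forms Likert sums, and averages within
#' wave. Reported per wave: the observed mean/SD, the posterior mean of the
#' predicted wave mean (`predicted_mean`) and its posterior SD
#' (`predicted_mean_sd`), and the posterior mean of the across-person SD of
#' predicted sums (`predicted_sd`). This is the sum-score posterior-predictive
#' check: a well-specified model puts the observed wave means well inside the
#' predictive distribution.
#'
#' @param fit A converged [fit_grm()] result.
#' @param mode `"complete_case"` (default) predicts sums only for person-waves
#'   whose items were all observed, mirroring the observed-summary convention;
#'   `"all_items"` predicts every item for every observed person-wave.
#' @param max_draws Cap on posterior draws used (evenly subsampled).
#' @param force Set `TRUE` to predict from a non-converged fit.
#' @param seed Seed for the predictive simulation.
#' @return A `ghq_wave_prediction` tibble: `wave`, `n_person_waves`,
#'   `observed_mean`, `observed_sd`, `predicted_mean`, `predicted_mean_sd`,
#'   `predicted_sd`.
#' @export
predict_wave_sums <- function(fit, mode = c("complete_case", "all_items"),
                              max_draws = 500L, force = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (!fit$converged && !force) {
    abort("Fit is not converged; pass force = TRUE to predict anyway.",
          class = "ghqwave_error")
  }
  n_items <- length(fit$item_levels)
  scored <- score_ghq(fit$responses, n_items = n_items)
  pw <- if (mode == "complete_case") {
    scored |> dplyr::filter(!is.na(.data$likert_sum))
  } else {
    scored
  }
  if (nrow(pw) == 0) abort("No person-waves to predict.", class = "ghqwave_error")
  design <- fit$design
  X <- as.matrix(design[, fit$spec$covariates, drop = FALSE])
  pid <- match(design$person_id, fit$person_levels)
  row_id <- match(paste(pw$person_id, pw$wave),
                  paste(design$person_id, design$wave))
  S_all <- attr(fit$draws, "n_draws")
  use <- unique(round(seq(1, S_all, length.out = min(max_draws, S_all))))
  K1 <- dim(fit$draws$tau)[3]
  cells_item <- rep(seq_len(n_items), times = nrow(pw))
  cells_row <- rep(row_id, each = n_items)
  cells_pw <- rep(seq_len(nrow(pw)), each = n_items)
  waves <- sort(unique(pw$wave))
  mean_draws <- matrix(NA_real_, length(use), length(waves))
  sd_draws <- matrix(NA_real_, length(use), length(waves))
  with_seed_maybe(seed, {
    for (si in seq_along(use)) {
      s <- use[si]
      eta_pw <- fit$draws$theta[s, pid] + as.vector(X %*% fit$draws$beta[s, ])
      eta <- eta_pw[cells_row]
      a <- fit$draws$disc[s, cells_item]
      tau_s <- matrix(fit$draws$tau[s, , ], ncol = K1)
      u <- runif(length(eta))
      y <- integer(length(eta))
      for (k in seq_len(K1)) {
        y <- y + as.integer(u > plogis(a * (tau_s[cells_item, k] - eta)))
      }
      sums <- rowsum(y, cells_pw)[, 1]
      for (wi in seq_along(waves)) {
        sel <- pw$wave == waves[wi]
        mean_draws[si, wi] <- mean(sums[sel])
        sd_draws[si, wi] <- sd(sums[sel])
      }
    }
  })
  out <- pw |>
    dplyr::summarise(
      n_person_waves = dplyr::n(),
      observed_mean = mean(.data$likert_sum),
      observed_sd = sd(.data$likert_sum),
      .by = "wave"
    ) |>
    dplyr::arrange(.data$wave) |>
    dplyr::mutate(
      predicted_mean = colMeans(mean_draws),
      predicted_mean_sd = apply(mean_draws, 2, sd),
      predicted_sd = colMeans(sd_draws)
    )
  class(out) <- c("ghq_wave_prediction", class(out))
  out
}

#' Seasonal total-effect curve from posterior draws
#'
#' Workhorse behind [seasonal_effect_curve()]: given named coefficient draws,
#' computes per trip-return time the posterior of the wave's total coefficient
#' \deqn{\beta_{wave} + \beta_{wave \times cos} \cos(2\pi t/360) +
#'       \beta_{wave \times sin} \sin(2\pi t/360)}
#' (absent interaction columns contribute zero) and summarizes it by the
#' posterior mean and a central credible interval.
#'
#' @param beta_draws Matrix or data frame of posterior draws with columns named
#'   `wave{w}`, and optionally `wave{w}_cos`, `wave{w}_sin`.
#' @param t_days Integer days since 2018-08-12, one per evaluation point.
#' @param wave Which wave's coefficient to total (1 or 2).
#' @param level Credible level (equal-tailed).
#' @return Tibble: `wave`, `t_days`, `estimate`, `conf.low`, `conf.high`.
#' @export
seasonal_curve_points <- function(beta_draws, t_days, wave, level = 0.95) {
  beta_draws <- as.data.frame(beta_draws)
  main <- paste0("wave", wave)
  if (!main %in% names(beta_draws)) {
    abort(sprintf("`beta_draws` lacks the %s column.", main),
          class = "ghqwave_error")
  }
  b <- beta_draws[[main]]
  bc <- beta_draws[[paste0(main, "_cos")]] %||% rep(0, length(b))
  bs <- beta_draws[[paste0(main, "_sin")]] %||% rep(0, length(b))
  a <- (1 - level) / 2
  purrr::map_dfr(t_days, function(t) {
    ang <- 2 * pi * t / 360
    tot <- b + bc * cos(ang) + bs * sin(ang)
    tibble::tibble(wave = wave, t_days = t, estimate = mean(tot),
                   conf.low = unname(quantile(tot, a)),
                   conf.high = unname(quantile(tot, 1 - a)))
  })
}

#' Posterior wave-effect curves over trip-return dates
#'
#' For each unique trip-return date, sums the wave main effect and its
#' seasonal interaction terms per posterior draw and reports the posterior
#' mean with a central 95% credible interval -- the "how did the time of the
#' trip shape the wave effect" curve. Requires a fit whose design includes the
#' wave-by-season interaction columns (variant `m5`).
#'
#' @param fit A [fit_grm()] result with interaction terms.
#' @param dates Evaluation dates (default: the unique trip-return dates of the
#'   fitted persons table).
#' @param waves Waves to evaluate (default `c(1, 2)`).
#' @param level Credible level.
#' @return A `ghq_seasonal_curve` tibble: `wave`, `trip_return_date`,
#'   `t_days`, `estimate`, `conf.low`, `conf.high`.
#' @export
seasonal_effect_curve <- function(fit, dates = NULL, waves = c(1L, 2L),
                                  level = 0.95) {
  covs <- fit$spec$covariates
  if (!any(grepl("_cos$|_sin$", covs))) {
    abort("The fitted model has no wave-by-season interaction terms.",
          class = "ghqwave_error")
  }
  if (is.null(dates)) {
    dates <- sort(unique(as.Date(fit$persons$trip_return_date)))
  }
  t_days <- as.integer(as.Date(dates) - ghq_epoch())
  beta_draws <- as.data.frame(fit$draws$beta)
  names(beta_draws) <- covs
  out <- purrr::map_dfr(waves, function(w) {
    seasonal_curve_points(beta_draws, t_days, w, level = level) |>
      dplyr::mutate(trip_return_date = as.Date(dates), .after = "wave")
  })
  class(out) <- c("ghq_seasonal_curve", class(out))
  out
}

#' Plot a seasonal effect curve
#'
#' Points are posterior means per trip-return date, vertical lines the
#' credible intervals, one panel per wave; the dashed line marks no effect.
#'
#' @param object A `ghq_seasonal_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ghq_seasonal_curve
#' @export
autoplot.ghq_seasonal_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trip_return_date,
                                       y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$conf.low,
                                         ymax = .data$conf.high)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~wave, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Trip-return date",
                  y = "Total wave coefficient (latent distress scale)") +
    ggplot2::theme_minimal()
}

#' Plot observed versus posterior-predicted wave sums
#'
#' @param object A `ghq_wave_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ghq_wave_prediction
#' @export
autoplot.ghq_wave_prediction <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("wave", "observed_mean", "predicted_mean")],
    -"wave", names_to = "series", values_to = "mean_sum"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$wave), y = .data$mean_sum,
                                  colour = .data$series, group = .data$series)) +
    ggplot2::geom_errorbar(
      data = tibble::as_tibble(object),
      mapping = ggplot2::aes(
        x = factor(.data$wave),
        ymin = .data$predicted_mean - 2 * .data$predicted_mean_sd,
        ymax = .data$predicted_mean + 2 * .data$predicted_mean_sd
      ),
      inherit.aes = FALSE, width = 0.15, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wave", y = "Mean GHQ-12 sum (0-36)", colour = NULL) +
    ggplot2::theme_minimal()
}
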