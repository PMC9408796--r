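#' Configuration for a synthetic GHQ-12 travel cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate the
#' study cohort the package is designed around: 174 travellers (27% men, ages
#' 18--65), 12 GHQ-12 items observed at three waves (before the trip, at return,
#' one month after), 16 equally spaced trip-return dates from 2018-08-12 to
#' 2019-03-10, travellers' diarrhoea in 71% during and 13% after the trip, and
#' per-wave item-response coverage of 98% / 76% / 72% with missingness almost
#' entirely at the person-wave level (at most 2 partially observed responders).
#'
#' @param n_persons Number of travellers.
#' @param frac_men Proportion of men (sex is coded 1 = man, 0 = woman).
#' @param age_range Two-element numeric, minimum and maximum age in years; ages
#'   are drawn uniformly on this range and standardized into `age_z`.
#' @param n_items Number of ordinal items (4 categories each, coded 0--3).
#' @param n_waves Number of measurement waves, coded `0:(n_waves - 1)`.
#' @param trip_return_dates Vector of `Date`s travellers can return on.
#' @param date_weights Optional per-date assignment weights (default uniform).
#' @param diarrhoea_trip_rate,diarrhoea_after_rate Bernoulli rates for the
#'   during-trip and after-trip diarrhoea flags (drawn independently).
#' @param true_effects Named numeric vector of latent-scale regression
#'   coefficients used when simulating responses; names must be design columns
#'   understood by [build_design()]. The default carries wave effects
#'   (wave 1 \eqn{-0.63}, wave 2 \eqn{-0.21}), small sex/age effects, a seasonal
#'   cosine/sine pair and the two diarrhoea effects.
#' @param person_sd Standard deviation of the person-level latent distress
#'   \eqn{\theta_p} (default 1, the model's identification convention).
#' @param coverage_targets Per-wave proportion of item responses observed after
#'   attrition; length `n_waves`.
#' @param max_partial_responders Maximum number of persons allowed to have
#'   item-level (partial) missingness; all other attrition deletes whole
#'   person-waves.
#' @param attrition_mechanism `"mcar"` (default) deletes person-waves completely
#'   at random; `"mnar"` makes deletion probability increase with the
#'   person-wave's distress (for imputation stress tests).
#' @param mnar_strength Log-odds slope of deletion on the standardized
#'   person-wave interpreted score when `attrition_mechanism = "mnar"`.
#' @param diarrhoea_joint Optional hook: a function `f(persons)` returning the
#'   persons table with modified diarrhoea flags, applied after the independent
#'   draws, so dependence between the flags (or with covariates) can be
#'   injected. Default `NULL` keeps the flags independent.
#' @param seed Integer seed; every generator stage derives its own stream from
#'   it, so a config is fully reproducible.
#' @return A `ghq_cohort_config` list.
#' @seealso [generate_cohort()], [simulate_ghq_study()]
#' @export
cohort_config <- function(n_persons = 174L,
                          frac_men = 0.27,
                          age_range = c(18, 65),
                          n_items = 12L,
                          n_waves = 3L,
                          trip_return_dates = default_trip_dates(),
                          date_weights = NULL,
                          diarrhoea_trip_rate = 0.71,
                          diarrhoea_after_rate = 0.13,
                          true_effects = default_true_effects(),
                          person_sd = 1,
                          coverage_targets = c(0.98, 0.76, 0.72),
                          max_partial_responders = 2L,
                          attrition_mechanism = c("mcar", "mnar"),
                          mnar_strength = 1,
                          diarrhoea_joint = NULL,
                          seed = 1L) {
  assert_prop(frac_men, "frac_men")
  assert_prop(diarrhoea_trip_rate, "diarrhoea_trip_rate")
  assert_prop(diarrhoea_after_rate, "diarrhoea_after_rate")
  assert_prop(coverage_targets, "coverage_targets")
  if (n_items < 2) abort("`n_items` must be >= 2.", class = "ghqwave_error")
  if (n_waves < 2) abort("`n_waves` must be >= 2.", class = "ghqwave_error")
  if (length(coverage_targets) != n_waves) {
    abort("`coverage_targets` must have one entry per wave.", class = "ghqwave_error")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("`age_range` must be (min, max) with min < max.", class = "ghqwave_error")
  }
  if (length(trip_return_dates) == 0) {
    abort("`trip_return_dates` must be non-empty.", class = "ghqwave_error")
  }
  trip_return_dates <- as.Date(trip_return_dates)
  if (!is.null(date_weights) && length(date_weights) != length(trip_return_dates)) {
    abort("`date_weights` must match `trip_return_dates` in length.",
          class = "ghqwave_error")
  }
  structure(
    list(
      n_persons = as.integer(n_persons), frac_men = frac_men,
      age_range = as.numeric(age_range), n_items = as.integer(n_items),
      n_waves = as.integer(n_waves), trip_return_dates = trip_return_dates,
      date_weights = date_weights, diarrhoea_trip_rate = diarrhoea_trip_rate,
      diarrhoea_after_rate = diarrhoea_after_rate, true_effects = true_effects,
      person_sd = person_sd, coverage_targets = coverage_targets,
      max_partial_responders = as.integer(max_partial_responders),
      attrition_mechanism = match.arg(attrition_mechanism),
      mnar_strength = mnar_strength, diarrhoea_joint = diarrhoea_joint,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "ghq_cohort_config"
  )
}

#' @export
print.ghq_cohort_config <- function(x, ...) {
  cat("<ghq_cohort_config>\n")
  cat(sprintf("  %d persons, %d items x %d waves, seed %s\n",
              x$n_persons, x$n_items, x$n_waves,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  coverage targets: %s; attrition: %s\n",
              paste(x$coverage_targets, collapse = "/"), x$attrition_mechanism))
  invisible(x)
}

# 16 equally spaced return dates spanning the emulated study window.
default_trip_dates <- function() {
  seq(as.Date("2018-08-12"), as.Date("2019-03-10"), length.out = 16)
}

default_true_effects <- function() {
  c(sex2 = -0.06, age_z = -0.05, wave1 = -0.63, wave2 = -0.21,
    cos_t = 0.01, sin_t = -0.18, diarrhoea_trip = -0.24, diarrhoea_after = 0.53)
}

#' Generate a person-level covariate table
#'
#' Draws the person table of a synthetic cohort: sex (Bernoulli at
#' `frac_men`), age (uniform on `age_range`, standardized into `age_z`),
#' trip-return date (sampled from the configured list), and the two diarrhoea
#' flags (independent Bernoulli unless a `diarrhoea_joint` hook is configured).
#' `t_days` counts days since 2018-08-12, the first return date of the emulated
#' study.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per person: `person_id`, `sex` (1 = man),
#'   `age`, `age_z`, `trip_return_date`, `t_days`, `diarrhoea_trip`,
#'   `diarrhoea_after`.
#' @examples
#' persons <- generate_cohort(cohort_config(n_persons = 20, seed = 1))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ghq_cohort_config"))
  n <- config$n_persons
  persons <- with_seed_maybe(config$seed, {
    age <- runif(n, config$age_range[1], config$age_range[2])
    dates <- sample(config$trip_return_dates, n, replace = TRUE,
                    prob = config$date_weights)
    tibble::tibble(
      person_id = seq_len(n),
      sex = rbinom(n, 1L, config$frac_men),
      age = age,
      age_z = as.numeric(scale(age)),
      trip_return_date = dates,
      t_days = as.integer(dates - ghq_epoch()),
      diarrhoea_trip = rbinom(n, 1L, config$diarrhoea_trip_rate),
      diarrhoea_after = rbinom(n, 1L, config$diarrhoea_after_rate)
    )
  })
  if (!is.null(config$diarrhoea_joint)) persons <- config$diarrhoea_joint(persons)
  persons
}

#' Draw item parameters for the graded-response generator
#'
#' Per-item log-discriminations and threshold shifts are drawn from a bivariate
#' normal with the given standard deviations and correlation; each item's
#' thresholds are the shared base thresholds plus its scalar shift. With
#' `threshold_scatter_sd > 0` an extra independent per-threshold jitter is
#' added (and thresholds re-sorted), producing genuinely item-specific spacing
#' that a shared-threshold model cannot absorb.
#'
#' Defaults mirror the emulated study's fitted shared-threshold model:
#' base thresholds (\eqn{-1.54, 2.73, 6.23}), discrimination intercept
#' \eqn{-0.06} (log scale), sd(disc) 0.32, sd(threshold) 1.29, correlation 0.35.
#'
#' @param n_items Number of items.
#' @param shared_thresholds Strictly increasing base thresholds (K-1 values).
#' @param disc_intercept Log-scale discrimination intercept.
#' @param re_sd_disc,re_sd_thr SDs of the log-discrimination and threshold-shift
#'   item random effects.
#' @param re_cor Correlation between the two item random effects, in [-1, 1].
#' @param threshold_scatter_sd SD of independent per-threshold jitter
#'   (default 0: pure shift, shared spacing).
#' @param seed Integer seed or `NULL`.
#' @return A `ghq_item_params` tibble: `item`, `log_disc`, `threshold_shift`,
#'   `tau_1` ... `tau_{K-1}`, with the generating constants as attributes.
#' @export
draw_item_parameters <- function(n_items = 12L,
                                 shared_thresholds = c(-1.54, 2.73, 6.23),
                                 disc_intercept = -0.06,
                                 re_sd_disc = 0.32,
                                 re_sd_thr = 1.29,
                                 re_cor = 0.35,
                                 threshold_scatter_sd = 0,
                                 seed = NULL) {
  if (any(diff(shared_thresholds) <= 0)) {
    abort("`shared_thresholds` must be strictly increasing.", class = "ghqwave_error")
  }
  if (abs(re_cor) > 1) abort("`re_cor` must lie in [-1, 1].", class = "ghqwave_error")
  if (re_sd_disc < 0 || re_sd_thr < 0 || threshold_scatter_sd < 0) {
    abort("Random-effect SDs must be non-negative.", class = "ghqwave_error")
  }
  K1 <- length(shared_thresholds)
  out <- with_seed_maybe(seed, {
    z1 <- rnorm(n_items)
    z2 <- rnorm(n_items)
    disc_dev <- re_sd_disc * z1
    shift <- re_sd_thr * (re_cor * z1 + sqrt(1 - re_cor^2) * z2)
    tau <- outer(shift, rep(1, K1)) +
      matrix(shared_thresholds, n_items, K1, byrow = TRUE)
    if (threshold_scatter_sd > 0) {
      tau <- tau + matrix(rnorm(n_items * K1, 0, threshold_scatter_sd), n_items, K1)
      tau <- t(apply(tau, 1, sort))
    }
    colnames(tau) <- paste0("tau_", seq_len(K1))
    tibble::as_tibble(cbind(
      tibble::tibble(item = seq_len(n_items),
                     log_disc = disc_intercept + disc_dev,
                     threshold_shift = shift),
      tibble::as_tibble(tau)
    ))
  })
  structure(out,
            class = c("ghq_item_params", class(out)),
            shared_thresholds = shared_thresholds,
            disc_intercept = disc_intercept,
            re_sd_disc = re_sd_disc, re_sd_thr = re_sd_thr, re_cor = re_cor,
            threshold_scatter_sd = threshold_scatter_sd)
}

item_threshold_matrix <- function(items) {
  as.matrix(items[, grep("^tau_", names(items)), drop = FALSE])
}

#' Simulate complete ordinal item responses from the graded-response model
#'
#' For each person a latent distress \eqn{\theta_p \sim N(0, \mathrm{person\_sd}^2)}
#' is drawn once; the person-wave linear predictor is
#' \eqn{\eta = \theta_p + \sum_j \beta_j x_j} with the design built by
#' [build_design()] from the names of `effects`; each item response is then
#' drawn from the cumulative-logit graded-response category probabilities
#' ([grm_category_probs()]). The returned table is complete (no missing cells);
#' attrition is imposed separately by [apply_attrition()].
#'
#' @param persons Person table from [generate_cohort()].
#' @param items Item parameters from [draw_item_parameters()].
#' @param effects Named latent-scale coefficients; names must be design columns
#'   known to [build_design()].
#' @param person_sd SD of the person latent trait.
#' @param n_waves Number of waves.
#' @param seed Integer seed or `NULL`.
#' @return A response tibble: `person_id`, `wave`, `item`, `response` (0--3).
#' @export
simulate_item_responses <- function(persons, items,
                                    effects = default_true_effects(),
                                    person_sd = 1, n_waves = 3L, seed = NULL) {
  design <- build_design(persons, n_waves = n_waves, covariates = names(effects))
  X <- as.matrix(design[, names(effects), drop = FALSE])
  tau <- item_threshold_matrix(items)
  n_items <- nrow(items)
  with_seed_maybe(seed, {
    theta <- rnorm(nrow(persons), 0, person_sd)
    names(theta) <- as.character(persons$person_id)
    eta_pw <- theta[as.character(design$person_id)] +
      as.vector(X %*% as.numeric(effects))
    grid <- tidyr::crossing(
      pw = seq_len(nrow(design)),
      item = seq_len(n_items)
    )
    eta <- eta_pw[grid$pw]
    a <- exp(items$log_disc[grid$item])
    # cumulative P(y <= k); category from one uniform per cell
    u <- runif(nrow(grid))
    y <- integer(nrow(grid))
    for (k in seq_len(ncol(tau))) {
      y <- y + as.integer(u > plogis(a * (tau[grid$item, k] - eta)))
    }
    tibble::tibble(
      person_id = design$person_id[grid$pw],
      wave = design$wave[grid$pw],
      item = grid$item,
      response = y
    ) |> dplyr::arrange(.data$person_id, .data$wave, .data$item)
  })
}

#' Impose wave-structured attrition on a complete response table
#'
#' Deletes records so each wave's item-response coverage is as close as
#' achievable to its target. Missingness is imposed primarily by deleting
#' entire person-waves (the study's observed pattern); at most
#' `max_partial_responders` persons (across all waves) receive item-level
#' partial deletion to absorb sub-person remainders, after which targets are
#' matched to the nearest whole person. Observed values are never altered,
#' only removed.
#'
#' @param responses Complete response table (from [simulate_item_responses()]).
#' @param coverage_targets Per-wave proportion of item responses to retain.
#' @param max_partial_responders Persons allowed item-level deletion.
#' @param seed Integer seed or `NULL`.
#' @param mechanism `"mcar"` (uniform deletion) or `"mnar"` (deletion odds
#'   increase with the person-wave's interpreted distress score).
#' @param mnar_strength Log-odds slope for the `"mnar"` mechanism.
#' @return The response tibble with deleted records removed.
#' @export
apply_attrition <- function(responses, coverage_targets,
                            max_partial_responders = 2L, seed = NULL,
                            mechanism = c("mcar", "mnar"), mnar_strength = 1) {
  mechanism <- match.arg(mechanism)
  assert_prop(coverage_targets, "coverage_targets")
  waves <- sort(unique(responses$wave))
  if (length(coverage_targets) != length(waves)) {
    abort("`coverage_targets` must have one entry per wave present.",
          class = "ghqwave_error")
  }
  n_items <- length(unique(responses$item))
  with_seed_maybe(seed, {
    partial_left <- max_partial_responders
    keep <- rep(TRUE, nrow(responses))
    for (wi in seq_along(waves)) {
      w <- waves[wi]
      idx <- which(responses$wave == w)
      persons_w <- unique(responses$person_id[idx])
      total <- length(idx)
      deficit <- total - round_half_up(coverage_targets[wi] * total)
      if (deficit <= 0) next
      n_whole <- deficit %/% n_items
      rem <- deficit - n_whole * n_items
      if (rem > 0 && partial_left <= 0) {
        # no partial budget left: match to the nearest whole person
        n_whole <- as.integer(round_half_up(deficit / n_items))
        rem <- 0L
      }
      prob <- NULL
      if (mechanism == "mnar") {
        sc <- responses[idx, ] |>
          dplyr::summarise(s = sum(.data$response >= 2), .by = "person_id")
        z <- as.numeric(scale(sc$s))
        z[is.na(z)] <- 0
        prob <- plogis(mnar_strength * z)[match(persons_w, sc$person_id)]
      }
      n_pick <- min(n_whole + (rem > 0), length(persons_w))
      drop_persons <- sample(persons_w, n_pick, prob = prob)
      if (rem > 0 && n_pick == n_whole + 1) {
        part <- drop_persons[n_pick]
        drop_persons <- drop_persons[-n_pick]
        part_idx <- idx[responses$person_id[idx] == part]
        keep[sample(part_idx, rem)] <- FALSE
        partial_left <- partial_left - 1L
      }
      keep[idx[responses$person_id[idx] %in% drop_persons]] <- FALSE
    }
    responses[keep, ]
  })
}

#' Simulate a full synthetic study (cohort, items, responses, attrition)
#'
#' Convenience wrapper running the whole generator pipeline under seeds derived
#' from `config$seed` (cohort, items, responses and attrition each get their
#' own stream). With the default configuration the result emulates the
#' three-wave travel study the package is designed around.
#'
#' @param config A [cohort_config()].
#' @param items Optional pre-drawn [draw_item_parameters()] table; drawn with
#'   defaults when `NULL`.
#' @return A `ghq_study` list: `config`, `persons`, `items`,
#'   `responses_complete` (pre-attrition), `responses` (post-attrition), and
#'   `theta` (the true person latent values, kept for recovery checks).
#' @examples
#' \donttest{
#' study <- simulate_ghq_study(cohort_config(n_persons = 30, seed = 7))
#' }
#' @export
simulate_ghq_study <- function(config, items = NULL) {
  stopifnot(inherits(config, "ghq_cohort_config"))
  s <- config$seed
  sub <- function(k) if (is.null(s)) NULL else s + k
  persons <- generate_cohort(config)
  if (is.null(items)) {
    items <- draw_item_parameters(n_items = config$n_items, seed = sub(1L))
  }
  complete <- simulate_item_responses(
    persons, items, effects = config$true_effects,
    person_sd = config$person_sd, n_waves = config$n_waves, seed = sub(2L)
  )
  observed <- apply_attrition(
    complete, config$coverage_targets,
    max_partial_responders = config$max_partial_responders, seed = sub(3L),
    mechanism = config$attrition_mechanism, mnar_strength = config$mnar_strength
  )
  structure(
    list(config = config, persons = persons, items = items,
         responses_complete = complete, responses = observed),
    class = "ghq_study"
  )
}

#' @export
print.ghq_study <- function(x, ...) {
  cat("<ghq_study>\n")
  cat(sprintf("  %d persons, %d items, %d waves\n", x$config$n_persons,
              x$config$n_items, x$config$n_waves))
  cov <- x$responses |>
    dplyr::summarise(n = dplyr::n(), .by = "wave") |>
    dplyr::arrange(.data$wave)
  tot <- x$config$n_persons * x$config$n_items
  cat(sprintf("  observed item responses per wave: %s (of %d)\n",
              paste(cov$n, collapse = ", "), tot))
  invisible(x)
}
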