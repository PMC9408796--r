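canonical_covariates <- function() {
  c("sex2", "age_z", "wave1", "wave2", "cos_t", "sin_t",
    "diarrhoea_trip", "diarrhoea_after",
    "wave1_cos", "wave1_sin", "wave2_cos", "wave2_sin")
}

#' Specify a graded-response model variant
#'
#' The model ladder mirrors the analysis the package implements:
#' * `m1` -- shared ordinal thresholds plus correlated item random effects
#'   (threshold shift and log-discrimination), covariates sex, standardized
#'   age and wave dummies;
#' * `m3` -- fully item-specific thresholds, same covariates;
#' * `m4` -- `m3` plus time-of-year (`cos_t`, `sin_t`) and the two diarrhoea
#'   flags;
#' * `m5` -- `m4` plus wave-by-season interactions (`wave1_cos`, `wave1_sin`,
#'   `wave2_cos`, `wave2_sin`).
#'
#' (The "model 2" of the ladder is the multiply imputed refit of `m1`; see
#' [fit_pooled()].)
#'
#' @param variant One of `"m1"`, `"m3"`, `"m4"`, `"m5"`.
#' @param covariates Optional explicit design-column selection overriding the
#'   variant's default (must be canonical names, see [build_design()]).
#' @param sine_interactions For `m5`: also include the wave-by-sine columns
#'   (default `TRUE`); `FALSE` keeps only the cosine interactions.
#' @param person_sd Fixed SD of the person latent trait (identification
#'   convention; default 1).
#' @return A `ghq_model_spec` list.
#' @export
model_spec <- function(variant = c("m1", "m3", "m4", "m5"),
                       covariates = NULL, sine_interactions = TRUE,
                       person_sd = 1) {
  variant <- match.arg(variant)
  base <- c("sex2", "age_z", "wave1", "wave2")
  m4 <- c(base, "cos_t", "sin_t", "diarrhoea_trip", "diarrhoea_after")
  if (is.null(covariates)) {
    covariates <- switch(variant,
      m1 = base, m3 = base, m4 = m4,
      m5 = c(m4, if (sine_interactions) c("wave1_cos", "wave1_sin",
                                          "wave2_cos", "wave2_sin")
                 else c("wave1_cos", "wave2_cos"))
    )
  }
  unknown <- setdiff(covariates, canonical_covariates())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown covariate(s): %s", paste(unknown, collapse = ", ")),
          class = "ghqwave_error")
  }
  structure(
    list(variant = variant, covariates = covariates,
         item_specific_thresholds = variant != "m1",
         person_sd = person_sd),
    class = "ghq_model_spec"
  )
}

#' @export
print.ghq_model_spec <- function(x, ...) {
  cat(sprintf("<ghq_model_spec %s> thresholds: %s\n  covariates: %s\n",
              x$variant,
              if (x$item_specific_thresholds) "item-specific"
              else "shared + item random effects",
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

#' Build the person-wave design matrix
#'
#' One row per person and wave, with the canonical covariate encodings:
#' `sex2` (indicator of sex category 2, women; men are the reference),
#' `age_z` (age standardized against the sample mean/SD), `wave1`/`wave2`
#' dummies (wave 0 is the reference), the annual-cycle terms
#' `cos_t = cos(2*pi*t/360)` and `sin_t = sin(2*pi*t/360)` where `t` is days
#' since 2018-08-12, the diarrhoea flags, and the wave-by-season interaction
#' products.
#'
#' @param persons Person table (needs `person_id`, `sex`, `age`,
#'   `trip_return_date` or `t_days`, `diarrhoea_trip`, `diarrhoea_after` as
#'   required by the selected covariates).
#' @param n_waves Number of waves (rows are `wave = 0:(n_waves-1)`).
#' @param covariates Character vector of canonical design columns to keep.
#' @param origin Date from which `t` is counted.
#' @return Tibble `person_id`, `wave`, then the requested covariate columns.
#' @export
build_design <- function(persons, n_waves = 3L,
                         covariates = model_spec("m4")$covariates,
                         origin = ghq_epoch()) {
  unknown <- setdiff(covariates, canonical_covariates())
  if (length(unknown) > 0) {
    abort(sprintf("Unknown covariate(s): %s", paste(unknown, collapse = ", ")),
          class = "ghqwave_error")
  }
  d <- tidyr::crossing(person_id = persons$person_id,
                       wave = 0:(n_waves - 1L)) |>
    dplyr::left_join(persons, by = "person_id")
  if (!"t_days" %in% names(d) && "trip_return_date" %in% names(d)) {
    d$t_days <- as.integer(as.Date(d$trip_return_date) - origin)
  }
  needs_t <- any(covariates %in% c("cos_t", "sin_t", "wave1_cos", "wave1_sin",
                                   "wave2_cos", "wave2_sin"))
  if (needs_t) {
    if (!"t_days" %in% names(d)) {
      abort("Seasonal covariates need `trip_return_date` or `t_days`.",
            class = "ghqwave_error")
    }
    if (any(d$t_days < 0)) {
      abort(sprintf("Trip-return dates before %s are not allowed.",
                    format(origin)), class = "ghqwave_error")
    }
  }
  ang <- if (needs_t) 2 * pi * d$t_days / 360 else rep(NA_real_, nrow(d))
  full <- d |>
    dplyr::mutate(
      sex2 = if ("sex" %in% names(d)) as.numeric(.data$sex == 0) else NA_real_,
      age_z = if ("age" %in% names(d))
        (.data$age - mean(persons$age)) / sd(persons$age) else NA_real_,
      wave1 = as.numeric(.data$wave == 1),
      wave2 = as.numeric(.data$wave == 2),
      cos_t = cos(ang),
      sin_t = sin(ang),
      wave1_cos = .data$wave1 * cos(ang),
      wave1_sin = .data$wave1 * sin(ang),
      wave2_cos = .data$wave2 * cos(ang),
      wave2_sin = .data$wave2 * sin(ang)
    )
  missing_cov <- covariates[vapply(covariates, function(cv) {
    !cv %in% names(full) || anyNA(full[[cv]])
  }, logical(1))]
  if (length(missing_cov) > 0) {
    abort(sprintf("Covariate(s) not computable from `persons`: %s",
                  paste(missing_cov, collapse = ", ")),
          class = "ghqwave_error")
  }
  out <- full |> dplyr::select("person_id", "wave", dplyr::all_of(covariates))
  attr(out, "covariates") <- covariates
  out
}
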