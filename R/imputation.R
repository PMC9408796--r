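#' Configuration for multiple imputation
#'
#' @param m Number of imputed datasets (the analysis default is 100; simulation
#'   profiles use fewer).
#' @param pmm_donors Predictive-mean-matching donor-pool size (default 5).
#' @param max_iterations Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed; imputation `d` runs under `seed + d - 1`.
#' @return A `ghq_imputation_config` list.
#' @export
imputation_config <- function(m = 100L, pmm_donors = 5L, max_iterations = 10L,
                              seed = 1L) {
  if (m < 1) abort("`m` must be >= 1.", class = "ghqwave_error")
  if (pmm_donors < 1) abort("`pmm_donors` must be >= 1.", class = "ghqwave_error")
  structure(list(m = as.integer(m), pmm_donors = as.integer(pmm_donors),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "ghq_imputation_config")
}

responses_to_wide <- function(responses, persons, n_items, n_waves) {
  grid <- tidyr::crossing(person_id = persons$person_id,
                          wave = 0:(n_waves - 1L), item = seq_len(n_items))
  grid |>
    dplyr::left_join(responses, by = c("person_id", "wave", "item")) |>
    dplyr::mutate(col = sprintf("w%d_i%d", .data$wave, .data$item)) |>
    dplyr::select("person_id", "col", "response") |>
    tidyr::pivot_wider(names_from = "col", values_from = "response")
}

wide_to_long <- function(wide) {
  wide |>
    tidyr::pivot_longer(-"person_id", names_to = "col", values_to = "response") |>
    tidyr::extract("col", c("wave", "item"), "w(\\d+)_i(\\d+)", convert = TRUE) |>
    dplyr::arrange(.data$person_id, .data$wave, .data$item)
}

# One PMM draw for the missing cells of column `target` given completed data.
# Bootstrap-parameter PMM: coefficients for the missing rows come from a fit
# on a bootstrap resample of the observed rows, so imputations vary between
# datasets; donors are the `k` observed rows with closest predicted means.
pmm_impute_column <- function(df, target, obs_rows, k) {
  rhs <- setdiff(names(df), target)
  f <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", target))
  fit_obs <- suppressWarnings(stats::lm(f, data = df[obs_rows, ]))
  boot <- sample(obs_rows, length(obs_rows), replace = TRUE)
  fit_boot <- suppressWarnings(stats::lm(f, data = df[boot, ]))
  pred_obs <- suppressWarnings(unname(stats::predict(fit_obs, df[obs_rows, ])))
  mis_rows <- setdiff(seq_len(nrow(df)), obs_rows)
  pred_mis <- suppressWarnings(unname(stats::predict(fit_boot, df[mis_rows, ])))
  y_obs <- df[[target]][obs_rows]
  vapply(pred_mis, function(pm) {
    pool <- order(abs(pred_obs - pm))[seq_len(min(k, length(pred_obs)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Imputes missing item responses at the item level in wide format (one column
#' per wave-item cell), using fully observed person covariates (sex, age,
#' seasonal terms, diarrhoea flags) plus all other item columns as predictors.
#' Each sweep visits incomplete columns in order of increasing missingness and
#' replaces each missing cell with an observed donor value whose predicted
#' mean is among the `pmm_donors` closest -- imputed values are therefore
#' always members of the observed category set. Observed cells are never
#' altered. Deterministic given the config seed.
#'
#' @param responses Long response tibble with attrition (absent or `NA` cells
#'   are treated as missing).
#' @param persons Person covariate table (must be fully observed).
#' @param config An [imputation_config()].
#' @param n_items,n_waves Dimensions of the full response grid.
#' @return A `ghq_imputations` object: `datasets` (list of `m` complete long
#'   response tibbles), `config`, and the missingness map.
#' @export
pmm_chained_impute <- function(responses, persons, config = imputation_config(),
                               n_items = 12L, n_waves = 3L) {
  stopifnot(inherits(config, "ghq_imputation_config"))
  wide <- responses_to_wide(responses, persons, n_items, n_waves)
  item_cols <- setdiff(names(wide), "person_id")
  n_obs_col <- vapply(wide[item_cols], function(x) sum(!is.na(x)), integer(1))
  if (any(n_obs_col == 0)) {
    abort(sprintf("Column(s) with zero observed values: %s",
                  paste(item_cols[n_obs_col == 0], collapse = ", ")),
          class = "ghqwave_error")
  }
  covars <- persons[match(wide$person_id, persons$person_id), , drop = FALSE]
  aux <- list()
  if ("sex" %in% names(covars)) aux$sex <- covars$sex
  if ("age" %in% names(covars)) aux$age_z <- as.numeric(scale(covars$age))
  if ("t_days" %in% names(covars)) {
    aux$cos_t <- cos(2 * pi * covars$t_days / 360)
    aux$sin_t <- sin(2 * pi * covars$t_days / 360)
  }
  for (fl in c("diarrhoea_trip", "diarrhoea_after")) {
    if (fl %in% names(covars)) aux[[fl]] <- covars[[fl]]
  }
  aux <- tibble::as_tibble(aux)
  aux <- aux[, vapply(aux, function(x) !anyNA(x) && var(x) > 0, logical(1)),
             drop = FALSE]
  miss_map <- is.na(wide[item_cols])
  # visit order: least missing first
  visit <- item_cols[order(colSums(miss_map))]
  visit <- visit[colSums(miss_map)[order(colSums(miss_map))] > 0]
  datasets <- lapply(seq_len(config$m), function(d) {
    with_seed_maybe(config$seed + d - 1L, {
      filled <- wide
      for (cl in visit) {
        nas <- which(is.na(filled[[cl]]))
        filled[[cl]][nas] <- sample(filled[[cl]][-nas], length(nas),
                                    replace = TRUE)
      }
      df <- dplyr::bind_cols(filled[item_cols], aux)
      if (length(visit) > 0) {
        for (sweep in seq_len(config$max_iterations)) {
          for (cl in visit) {
            obs_rows <- which(!miss_map[, cl])
            df[[cl]][miss_map[, cl]] <-
              pmm_impute_column(df, cl, obs_rows, config$pmm_donors)
          }
        }
      }
      out <- dplyr::bind_cols(wide["person_id"], df[item_cols])
      wide_to_long(out)
    })
  })
  structure(list(datasets = datasets, config = config,
                 n_items = n_items, n_waves = n_waves,
                 n_missing = sum(miss_map)),
            class = "ghq_imputations")
}

#' @export
print.ghq_imputations <- function(x, ...) {
  cat(sprintf("<ghq_imputations> m = %d completed datasets, %d imputed cells each\n",
              x$config$m, x$n_missing))
  invisible(x)
}

#' Fit the graded-response model to every imputed dataset and pool
#'
#' Runs [fit_grm()] on each completed dataset and pools the posteriors by
#' concatenating draws with equal weight (the mixture representation of the
#' multiple-imputation posterior). Convergence is assessed per dataset; the
#' pooled result is flagged non-converged if any per-dataset fit fails the
#' R-hat gate.
#'
#' @param imputations A [pmm_chained_impute()] result (or a plain list of
#'   complete long response tibbles).
#' @param persons Person covariate table.
#' @param spec A [model_spec()].
#' @param chains,warmup,iter Per-dataset sampler settings (reduced by default:
#'   with many datasets the pooled draw count grows as `m * chains * iter`).
#' @param seed Integer seed; dataset `d` is fitted under `seed + d - 1`.
#' @param quiet Suppress JAGS output.
#' @return A `grm_pooled_fit`: per-dataset `fits`, pooled structural draws,
#'   `converged` flag.
#' @export
fit_pooled <- function(imputations, persons, spec = model_spec("m1"),
                       chains = 2L, warmup = 500L, iter = 500L,
                       seed = 1L, quiet = TRUE) {
  datasets <- if (inherits(imputations, "ghq_imputations"))
    imputations$datasets else imputations
  fits <- lapply(seq_along(datasets), function(d) {
    fit_grm(datasets[[d]], persons, spec = spec, chains = chains,
            warmup = warmup, iter = iter, seed = seed + d - 1L, quiet = quiet)
  })
  pooled <- purrr::reduce(lapply(fits, structural_draws),
                          function(a, b) purrr::map2(a, b, c))
  structure(
    list(fits = fits, pooled = pooled, m = length(datasets), spec = spec,
         converged = all(vapply(fits, `[[`, logical(1), "converged"))),
    class = "grm_pooled_fit"
  )
}

#' @export
print.grm_pooled_fit <- function(x, ...) {
  cat(sprintf("<grm_pooled_fit %s> m = %d datasets, converged: %s\n",
              x$spec$variant, x$m, x$converged))
  print(tidy(x), n = 15)
  invisible(x)
}

#' @rdname tidy.grm_fit
#' @method tidy grm_pooled_fit
#' @export
tidy.grm_pooled_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  purrr::map_dfr(names(x$pooled), function(nm) {
    v <- x$pooled[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' @rdname glance.grm_fit
#' @method glance grm_pooled_fit
#' @export
glance.grm_pooled_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant, m = x$m,
    draws = length(x$pooled[[1]]),
    converged = x$converged
  )
}
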