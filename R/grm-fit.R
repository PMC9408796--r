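#' Fit the Bayesian multilevel graded-response model
#'
#' Fits the selected model variant (see [model_spec()]) by MCMC with JAGS:
#' person-wave latent distress \eqn{\eta = \theta_p + \sum_j \beta_j x_j},
#' person trait \eqn{\theta_p \sim N(0, \mathrm{person\_sd}^2)} (fixed for
#' identification, so scale is carried by the item discriminations), a
#' cumulative-logit link with exponentiated log-scale discriminations, and
#' either shared thresholds with correlated item random effects (`m1`) or
#' item-specific ordered thresholds (`m3`/`m4`/`m5`).
#'
#' Default sampler settings are 4 chains with 1000 warmup and 1000 retained
#' iterations each; reduced profiles (2 chains, a few hundred iterations) are
#' appropriate for simulation studies. After sampling, every monitored
#' parameter gets a rank-normalized split R-hat and an effective sample size;
#' the fit is flagged (never silently accepted) when any R-hat reaches 1.05.
#' Items with a single observed category are permitted -- their thresholds are
#' then informed mostly by the prior -- and trigger a warning.
#'
#' @param responses Long response tibble; `NA` responses are dropped.
#' @param persons Person covariate table.
#' @param spec A [model_spec()].
#' @param chains,warmup,iter MCMC chains, warmup (adaptation + burn-in) and
#'   retained iterations per chain.
#' @param seed Integer seed (drives each chain's RNG deterministically).
#' @param quiet Suppress JAGS progress output.
#' @return A `grm_fit` object: posterior arrays (`beta`, `theta`, `tau`,
#'   `disc`, variance components), a `diagnostics` tibble (parameter, rhat,
#'   ess), `converged` flag, and the data/design used.
#' @seealso [check_convergence()], [tidy.grm_fit()], [grm_loo()]
#' @export
fit_grm <- function(responses, persons, spec = model_spec("m1"),
                    chains = 4L, warmup = 1000L, iter = 1000L,
                    seed = 1L, quiet = TRUE) {
  stopifnot(inherits(spec, "ghq_model_spec"))
  obs <- responses |> dplyr::filter(!is.na(.data$response))
  if (any(!obs$response %in% 0:3)) {
    abort("Responses must be categories 0..3.", class = "ghqwave_error")
  }
  person_levels <- persons$person_id
  item_levels <- sort(unique(obs$item))
  if (length(person_levels) < 2 || length(item_levels) < 2) {
    abort("Need at least 2 persons and 2 items.", class = "ghqwave_error")
  }
  K <- 4L
  single_cat <- obs |>
    dplyr::summarise(k = dplyr::n_distinct(.data$response), .by = "item") |>
    dplyr::filter(.data$k == 1)
  if (nrow(single_cat) > 0) {
    warn(sprintf("Item(s) %s have a single observed category; their thresholds are prior-driven.",
                 paste(single_cat$item, collapse = ", ")))
  }
  n_waves <- max(obs$wave) + 1L
  design <- build_design(persons, n_waves = n_waves, covariates = spec$covariates)
  dat <- jags_data(obs, design, spec, person_levels, item_levels, K)
  dat <- dat[!vapply(dat, is.null, logical(1))]
  code <- if (spec$item_specific_thresholds) jags_model_item_specific()
          else jags_model_m1()
  inits <- jags_inits(spec, chains, seed, length(item_levels), K)
  monitors <- c("beta", "theta", "tau", "disc", "disc_int", "sd_disc",
                if (!spec$item_specific_thresholds) c("tau0", "sd_thr", "cor_dt"))
  n_adapt <- max(100L, ceiling(warmup / 2))
  n_burn <- max(0L, warmup - n_adapt)
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                            n.chains = chains, n.adapt = n_adapt, quiet = quiet)
    if (n_burn > 0) stats::update(jm, n.iter = n_burn, progress.bar = "none")
    rjags::coda.samples(jm, variable.names = monitors, n.iter = iter,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  draws <- parse_draws(samples)
  diagnostics <- if (chains >= 2) mcmc_diagnostics(samples) else
    tibble::tibble(parameter = character(), rhat = numeric(), ess = numeric())
  converged <- chains >= 2 &&
    check_convergence(diagnostics, rhat_max = 1.05)$pass
  structure(
    list(
      spec = spec, draws = draws, samples = samples,
      diagnostics = diagnostics, converged = converged,
      responses = obs, persons = persons, design = design,
      person_levels = person_levels, item_levels = item_levels,
      meta = list(chains = chains, warmup = warmup, iter = iter, seed = seed,
                  n_obs = nrow(obs))
    ),
    class = "grm_fit"
  )
}

# Reshape an mcmc.list into named arrays [draw, ...dims] with chains stacked
# along the draw dimension (chain-major).
parse_draws <- function(samples) {
  mats <- lapply(samples, as.matrix)
  big <- do.call(rbind, mats)
  vn <- colnames(big)
  base <- sub("\\[.*$", "", vn)
  out <- list()
  for (nm in unique(base)) {
    cols <- which(base == nm)
    idx_txt <- sub("^.*\\[", "", sub("\\]$", "", vn[cols]))
    if (identical(idx_txt[1], vn[cols][1])) { # scalar
      out[[nm]] <- as.numeric(big[, cols])
      next
    }
    idx <- do.call(rbind, lapply(strsplit(idx_txt, ","), as.integer))
    dims <- apply(idx, 2, max)
    arr <- array(NA_real_, dim = c(nrow(big), dims))
    for (j in seq_along(cols)) {
      pos <- cbind(seq_len(nrow(big)),
                   matrix(idx[j, ], nrow(big), length(dims), byrow = TRUE))
      arr[pos] <- big[, cols[j]]
    }
    out[[nm]] <- arr
  }
  attr(out, "n_draws") <- nrow(big)
  attr(out, "n_chains") <- length(mats)
  out
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit %s> %d obs, %d persons, %d items; %d chains x %d draws\n",
              x$spec$variant, x$meta$n_obs, length(x$person_levels),
              length(x$item_levels), x$meta$chains, x$meta$iter))
  cat(sprintf("  converged (all R-hat < 1.05): %s (max R-hat %.3f)\n",
              x$converged, max(x$diagnostics$rhat, na.rm = TRUE)))
  print(tidy(x), n = 15)
  invisible(x)
}

structural_draws <- function(fit) {
  d <- fit$draws
  out <- list()
  for (j in seq_along(fit$spec$covariates)) {
    out[[paste0("b_", fit$spec$covariates[j])]] <- d$beta[, j]
  }
  out$disc_int <- d$disc_int
  out$sd_disc <- d$sd_disc
  if (!fit$spec$item_specific_thresholds) {
    out$sd_thr <- d$sd_thr
    out$cor_dt <- d$cor_dt
    for (k in seq_len(dim(d$tau0)[2])) out[[paste0("tau0_", k)]] <- d$tau0[, k]
  }
  out
}

#' Tidy posterior summaries of a graded-response fit
#'
#' @param x A `grm_fit`.
#' @param pars `"structural"` (coefficients, discrimination intercept,
#'   variance components, shared thresholds), `"theta"` (person traits), or
#'   `"all"`.
#' @param conf.level Credible-interval level (equal-tailed).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (posterior mean), `std.error` (posterior
#'   SD), `conf.low`, `conf.high`.
#' @method tidy grm_fit
#' @export
tidy.grm_fit <- function(x, pars = c("structural", "theta", "all"),
                         conf.level = 0.95, ...) {
  pars <- match.arg(pars)
  dr <- switch(pars,
    structural = structural_draws(x),
    theta = setNames(lapply(seq_along(x$person_levels),
                            function(i) x$draws$theta[, i]),
                     paste0("theta_", x$person_levels)),
    all = c(structural_draws(x),
            setNames(lapply(seq_along(x$person_levels),
                            function(i) x$draws$theta[, i]),
                     paste0("theta_", x$person_levels)))
  )
  a <- (1 - conf.level) / 2
  purrr::map_dfr(names(dr), function(nm) {
    v <- dr[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' One-row model overview
#'
#' @param x A `grm_fit`.
#' @param ... Unused.
#' @return Tibble with data size, sampler settings, convergence flag and
#'   maximum R-hat.
#' @method glance grm_fit
#' @export
glance.grm_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    n_obs = x$meta$n_obs,
    n_persons = length(x$person_levels),
    n_items = length(x$item_levels),
    chains = x$meta$chains,
    draws = attr(x$draws, "n_draws"),
    converged = x$converged,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}
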