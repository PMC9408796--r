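#' Draws-by-observations log-likelihood array
#'
#' Evaluates, for every retained posterior draw, the log-likelihood of every
#' observed item response (the LOO observation unit is one person-wave-item
#' response, matching the likelihood's pointwise factorization).
#'
#' @param fit A [fit_grm()] result.
#' @return Numeric matrix, draws x observations; observation order matches
#'   `fit$responses`.
#' @export
pointwise_loglik <- function(fit) {
  obs <- fit$responses
  design <- fit$design
  X <- as.matrix(design[, fit$spec$covariates, drop = FALSE])
  pid <- match(design$person_id, fit$person_levels)
  row_id <- match(paste(obs$person_id, obs$wave),
                  paste(design$person_id, design$wave))
  item <- match(obs$item, fit$item_levels)
  y <- obs$response
  S <- attr(fit$draws, "n_draws")
  K1 <- dim(fit$draws$tau)[3]
  ll <- matrix(NA_real_, S, nrow(obs))
  lo_k <- pmax(y, 1L)        # threshold index below the response
  hi_k <- pmin(y + 1L, K1)   # threshold index above the response
  at_bottom <- y == 0
  at_top <- y == K1
  for (s in seq_len(S)) {
    eta_pw <- fit$draws$theta[s, pid] +
      as.vector(X %*% fit$draws$beta[s, ])
    eta <- eta_pw[row_id]
    a <- fit$draws$disc[s, item]
    tau_s <- matrix(fit$draws$tau[s, , ], ncol = K1)
    cum_lo <- ifelse(at_bottom, 0, plogis(a * (tau_s[cbind(item, lo_k)] - eta)))
    cum_hi <- ifelse(at_top, 1, plogis(a * (tau_s[cbind(item, hi_k)] - eta)))
    ll[s, ] <- log(pmax(cum_hi - cum_lo, 1e-300))
  }
  ll
}

# Zhang & Stephens (2009) empirical-Bayes fit of the generalized Pareto
# distribution to exceedances x (location 0). Returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_of_b <- vapply(b, function(bj) -mean(log1p(-bj * x)), numeric(1))
  l_b <- n * (log(b / k_of_b) + k_of_b - 1)
  w <- exp(l_b - log_sum_exp(l_b))
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  sigma_hat <- k_hat / b_hat
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance weights (unnormalized).
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- as.integer(ceiling(min(0.2 * S, 3 * sqrt(S))))
  if (tail_len < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(S - tail_len + 1):S]
  cut <- exp(lw[ord[S - tail_len]])
  exceed <- exp(lw[tail_idx]) - cut
  if (max(exceed) <= 0) return(list(lw = lw, k = NA_real_))
  fitted <- gpd_fit(exceed)
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(cut + gpd_quantile(p, fitted$k, fitted$sigma))
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
  list(lw = lw, k = fitted$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes PSIS-LOO from a draws-by-observations log-likelihood matrix: per
#' observation the importance ratios \eqn{1/p(y_i \mid \theta_s)} are
#' tail-smoothed with a generalized-Pareto fit, and the expected log pointwise
#' predictive density (elpd) is the weighted log mean of the likelihoods.
#' `looic = -2 * elpd_loo`. The Pareto shape diagnostic k is reported per
#' observation; values above 0.7 make that observation's estimate unreliable
#' (a warning summarizes the fraction).
#'
#' @param log_lik Matrix, draws x observations (at least 2 distinct draws).
#' @return A `ghq_loo` object: `elpd_loo`, `se`, `looic`, `n`, `pointwise`
#'   tibble (`elpd`, `pareto_k`).
#' @export
psis_loo <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  S <- nrow(log_lik)
  if (S < 2) abort("Need at least 2 draws.", class = "ghqwave_error")
  if (!all(is.finite(log_lik))) {
    abort("Log-likelihoods must be finite.", class = "ghqwave_error")
  }
  if (all(apply(log_lik, 2, function(x) max(x) - min(x)) == 0)) {
    abort("All draws identical: importance weights degenerate.",
          class = "ghqwave_degenerate")
  }
  res <- apply(log_lik, 2, function(ll) {
    sm <- psis_smooth(-ll)
    elpd <- log_sum_exp(sm$lw + ll) - log_sum_exp(sm$lw)
    c(elpd = elpd, k = sm$k)
  })
  pointwise <- tibble::tibble(elpd = res["elpd", ], pareto_k = res["k", ])
  n <- ncol(log_lik)
  elpd_loo <- sum(pointwise$elpd)
  bad <- mean(pointwise$pareto_k > 0.7, na.rm = TRUE)
  if (is.finite(bad) && bad > 0) {
    warn(sprintf("%.1f%% of observations have Pareto k > 0.7; their elpd contributions may be unreliable.",
                 100 * bad))
  }
  structure(
    list(elpd_loo = elpd_loo,
         se = sqrt(n * var(pointwise$elpd)),
         looic = -2 * elpd_loo,
         n = n, n_draws = S, pointwise = pointwise),
    class = "ghq_loo"
  )
}

#' @export
print.ghq_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d observations (%d draws)\n", x$n, x$n_draws))
  cat(sprintf("  elpd_loo %.1f (SE %.1f)   looic %.1f\n",
              x$elpd_loo, x$se, x$looic))
  cat(sprintf("  Pareto k > 0.7: %d observation(s)\n",
              sum(x$pointwise$pareto_k > 0.7, na.rm = TRUE)))
  invisible(x)
}

#' PSIS-LOO for a fitted graded-response model
#'
#' @param fit A [fit_grm()] result.
#' @return A `ghq_loo` object (see [psis_loo()]).
#' @export
grm_loo <- function(fit) {
  psis_loo(pointwise_loglik(fit))
}

#' Compare two models by LOOIC
#'
#' Sign convention, stated explicitly because conventions differ across
#' software: `delta_looic = looic(a) - looic(b)`, so a POSITIVE `delta_looic`
#' means model `a` has the worse (higher) LOOIC and model `b` is preferred;
#' equivalently `delta_elpd = elpd(a) - elpd(b)` is negative when `a` is
#' worse. The standard error is computed from the paired pointwise elpd
#' differences.
#'
#' @param a,b `ghq_loo` results computed on the identical observation set.
#' @return One-row tibble: `delta_looic`, `delta_elpd`, `se_delta_elpd`,
#'   `se_delta_looic`, `preferred` (`"a"` or `"b"`).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "ghq_loo"), inherits(b, "ghq_loo"))
  if (a$n != b$n) {
    abort("Models were evaluated on different numbers of observations.",
          class = "ghqwave_error")
  }
  d <- a$pointwise$elpd - b$pointwise$elpd
  se_d <- sqrt(a$n * var(d))
  tibble::tibble(
    delta_looic = a$looic - b$looic,
    delta_elpd = a$elpd_loo - b$elpd_loo,
    se_delta_elpd = se_d,
    se_delta_looic = 2 * se_d,
    preferred = ifelse(a$looic <= b$looic, "a", "b")
  )
}
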