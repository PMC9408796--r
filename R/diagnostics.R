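# Convergence diagnostics. R-hat is the rank-normalized split-chain version:
# each chain is split in half, all draws are rank-transformed jointly and
# mapped through the normal quantile function, and the classic
# between/within-chain variance-ratio statistic is computed on the z-scores.

classic_rhat <- function(z) {
  # z: iterations x chains
  n <- nrow(z)
  m <- ncol(z)
  mu <- colMeans(z)
  W <- mean(apply(z, 2, var))
  B <- n * var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split-chain R-hat
#'
#' @param draws Numeric matrix, iterations x chains (at least 2 chains after
#'   splitting, i.e. at least 1 chain with >= 4 iterations).
#' @return The R-hat statistic; `NA` for constant draws.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- (nrow(draws) %/% 2) * 2
  if (n < 4) abort("Need at least 4 iterations per chain.", class = "ghqwave_error")
  half <- n / 2
  sc <- cbind(draws[1:half, , drop = FALSE],
              draws[(half + 1):n, , drop = FALSE])
  if (length(unique(as.vector(sc))) == 1) return(NA_real_)
  r <- matrix(rank(sc, ties.method = "average"), nrow = half)
  z <- stats::qnorm((r - 3 / 8) / (length(sc) + 1 / 4))
  classic_rhat(z)
}

# Per-parameter diagnostics for an mcmc.list.
mcmc_diagnostics <- function(samples) {
  pars <- coda::varnames(samples)
  mat_list <- lapply(samples, as.matrix)
  ess <- coda::effectiveSize(samples)
  rhat <- vapply(seq_along(pars), function(j) {
    split_rhat(vapply(mat_list, function(m) m[, j], numeric(nrow(mat_list[[1]]))))
  }, numeric(1))
  tibble::tibble(parameter = pars, rhat = rhat, ess = as.numeric(ess[pars]))
}

#' Check MCMC convergence against an R-hat gate
#'
#' Passes when every parameter's rank-normalized split R-hat is strictly below
#' `rhat_max` (default 1.05, the analysis' convergence gate). Parameters with
#' undefined R-hat (constant draws) are ignored.
#'
#' @param x A [fit_grm()] result, a pooled fit, or a diagnostics data frame
#'   with columns `parameter` and `rhat`.
#' @param rhat_max Strict upper bound for R-hat.
#' @return A `ghq_convergence` list: `pass` (logical), `offending` (tibble of
#'   parameters at or above the gate), `rhat_max`.
#' @export
check_convergence <- function(x, rhat_max = 1.05) {
  UseMethod("check_convergence")
}

#' @export
check_convergence.grm_fit <- function(x, rhat_max = 1.05) {
  if (x$meta$chains < 2) {
    abort("R-hat requires at least 2 chains.", class = "ghqwave_error")
  }
  check_convergence(x$diagnostics, rhat_max = rhat_max)
}

#' @export
check_convergence.grm_pooled_fit <- function(x, rhat_max = 1.05) {
  res <- lapply(x$fits, check_convergence, rhat_max = rhat_max)
  off <- dplyr::bind_rows(lapply(seq_along(res), function(i) {
    dplyr::mutate(res[[i]]$offending, dataset = i)
  }))
  structure(list(pass = all(vapply(res, `[[`, logical(1), "pass")),
                 offending = off, rhat_max = rhat_max),
            class = "ghq_convergence")
}

#' @export
check_convergence.data.frame <- function(x, rhat_max = 1.05) {
  off <- x[!is.na(x$rhat) & x$rhat >= rhat_max,
           intersect(c("parameter", "rhat"), names(x))]
  structure(list(pass = nrow(off) == 0,
                 offending = tibble::as_tibble(off),
                 rhat_max = rhat_max),
            class = "ghq_convergence")
}

#' @export
print.ghq_convergence <- function(x, ...) {
  if (x$pass) {
    cat(sprintf("Converged: all R-hat < %.3f\n", x$rhat_max))
  } else {
    cat(sprintf("NOT converged: %d parameter(s) with R-hat >= %.3f\n",
                nrow(x$offending), x$rhat_max))
    print(utils::head(x$offending, 10))
  }
  invisible(x)
}
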