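#' Graded-response category probabilities
#'
#' Cumulative-logit graded-response model: with discrimination
#' \eqn{a = \exp(\mathrm{log\_disc})} and ordered thresholds \eqn{\tau_k},
#' \deqn{\Pr(y \le k) = \mathrm{logit}^{-1}\{a(\tau_k - \eta)\},}
#' and category probabilities are successive differences of the cumulative
#' probabilities. Larger \eqn{\eta} (more latent distress) shifts mass to
#' higher categories.
#'
#' @param eta Numeric vector of latent linear-predictor values.
#' @param log_disc Log discrimination (scalar).
#' @param thresholds Strictly increasing vector of K-1 thresholds.
#' @return A `length(eta)` x K matrix of category probabilities (columns are
#'   categories `0:(K-1)`); each row sums to 1.
#' @examples
#' grm_category_probs(0, 0, c(-1, 0, 1))
#' @export
grm_category_probs <- function(eta, log_disc = 0, thresholds) {
  if (any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be strictly increasing.", class = "ghqwave_error")
  }
  a <- exp(log_disc)
  cum <- vapply(thresholds, function(tk) plogis(a * (tk - eta)),
                numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  K <- length(thresholds) + 1L
  p <- matrix(NA_real_, length(eta), K)
  p[, 1] <- cum[, 1]
  if (K > 2) {
    for (k in 2:(K - 1)) p[, k] <- cum[, k] - cum[, k - 1]
  }
  p[, K] <- 1 - cum[, K - 1]
  colnames(p) <- as.character(0:(K - 1))
  p
}

#' Log-likelihood of observed responses under a parameter set
#'
#' Evaluates the graded-response log-likelihood pointwise: for each observed
#' response the log of its category probability at
#' \eqn{\eta = \theta_p + \sum_j \beta_j x_j}. Missing responses contribute
#' nothing; the total is the sum of the pointwise values.
#'
#' @param responses Long response tibble (`person_id`, `wave`, `item`,
#'   `response`); `NA` responses are dropped.
#' @param design Design tibble from [build_design()] (one row per person-wave,
#'   columns matching `names(params$beta)`).
#' @param params List with `beta` (named numeric), `theta` (named by
#'   `person_id`), `log_disc` (length `n_items`), and `thresholds`
#'   (`n_items` x (K-1) matrix, rows strictly increasing).
#' @return List with `total` (scalar) and `pointwise` (tibble `person_id`,
#'   `wave`, `item`, `log_lik`).
#' @export
grm_loglik <- function(responses, design, params) {
  obs <- responses |> dplyr::filter(!is.na(.data$response))
  if (any(!obs$response %in% 0:3)) {
    abort("Responses must be categories 0..3.", class = "ghqwave_error")
  }
  if (any(apply(params$thresholds, 1, function(r) any(diff(r) <= 0)))) {
    abort("Item thresholds must be strictly increasing.", class = "ghqwave_error")
  }
  X <- as.matrix(design[, names(params$beta), drop = FALSE])
  eta_pw <- params$theta[as.character(design$person_id)] +
    as.vector(X %*% as.numeric(params$beta))
  key <- match(paste(obs$person_id, obs$wave),
               paste(design$person_id, design$wave))
  if (anyNA(key)) {
    abort("Every observed response needs a design row.", class = "ghqwave_error")
  }
  eta <- eta_pw[key]
  a <- exp(params$log_disc[obs$item])
  tau <- params$thresholds
  K1 <- ncol(tau)
  cum_lo <- ifelse(obs$response == 0, 0,
                   plogis(a * (tau[cbind(obs$item, pmax(obs$response, 1))] - eta)))
  cum_hi <- ifelse(obs$response == K1, 1,
                   plogis(a * (tau[cbind(obs$item, pmin(obs$response + 1L, K1))] - eta)))
  ll <- log(pmax(cum_hi - cum_lo, 1e-300))
  list(
    total = sum(ll),
    pointwise = tibble::tibble(person_id = obs$person_id, wave = obs$wave,
                               item = obs$item, log_lik = ll)
  )
}
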