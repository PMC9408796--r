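# JAGS model code for the graded-response variants. The observation block is
# shared: the person-wave linear predictor mu[r] plus cumulative-logit category
# probabilities per observed response. Priors (weakly informative, documented
# in the methods vignette): coefficients Normal(0, 5); thresholds and the
# log-discrimination intercept Student-t(3, 0, 2.5); random-effect SDs
# half-Student-t(3, 0, 2.5); the threshold/discrimination random-effect
# correlation uniform on (-1, 1). The person trait is fixed to
# Normal(0, person_sd) for identification.

jags_obs_block <- "
  for (r in 1:R) { mu[r] <- theta[pid[r]] + inprod(X[r, ], beta[]) }
  for (n in 1:N) {
    for (k in 1:(K - 1)) {
      q[n, k] <- ilogit(disc[item[n]] * (tau[item[n], k] - mu[row[n]]))
    }
    p[n, 1] <- q[n, 1]
    for (k in 2:(K - 1)) { p[n, k] <- q[n, k] - q[n, k - 1] }
    p[n, K] <- 1 - q[n, K - 1]
    y[n] ~ dcat(p[n, 1:K])
  }
  for (s in 1:NP) { theta[s] ~ dnorm(0, prec_theta) }
  for (j in 1:J) { beta[j] ~ dnorm(0, 0.04) }
  disc_int ~ dt(0, 0.16, 3)
  sd_disc ~ dt(0, 0.16, 3) T(0,)
"

jags_model_m1 <- function() {
  paste0("model {", jags_obs_block, "
  sd_thr ~ dt(0, 0.16, 3) T(0,)
  cor_dt ~ dunif(-1, 1)
  Sig[1, 1] <- pow(sd_disc, 2) + 1.0E-9
  Sig[2, 2] <- pow(sd_thr, 2) + 1.0E-9
  Sig[1, 2] <- cor_dt * sd_disc * sd_thr
  Sig[2, 1] <- Sig[1, 2]
  Omega[1:2, 1:2] <- inverse(Sig[1:2, 1:2])
  t0 ~ dt(0, 0.16, 3)
  tau0[1] <- t0
  for (k in 2:(K - 1)) {
    inc0[k - 1] ~ dt(0, 0.16, 3) T(0,)
    tau0[k] <- tau0[k - 1] + inc0[k - 1]
  }
  for (i in 1:NI) {
    u[i, 1:2] ~ dmnorm(zero2[1:2], Omega[1:2, 1:2])
    disc[i] <- exp(disc_int + u[i, 1])
    for (k in 1:(K - 1)) { tau[i, k] <- tau0[k] + u[i, 2] }
  }
}")
}

jags_model_item_specific <- function() {
  paste0("model {", jags_obs_block, "
  for (i in 1:NI) {
    ud[i] ~ dnorm(0, 1)
    disc[i] <- exp(disc_int + sd_disc * ud[i])
    tfirst[i] ~ dt(0, 0.16, 3)
    tau[i, 1] <- tfirst[i]
    for (k in 2:(K - 1)) {
      inc[i, k - 1] ~ dt(0, 0.16, 3) T(0,)
      tau[i, k] <- tau[i, k - 1] + inc[i, k - 1]
    }
  }
}")
}

jags_inits <- function(spec, chains, seed, n_items, K) {
  lapply(seq_len(chains), function(ch) {
    base <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (abs(as.integer(seed)) * 7L + ch * 1009L) %% 2147483646L + 1L,
      disc_int = 0, sd_disc = 0.3
    )
    if (spec$item_specific_thresholds) {
      c(base, list(
        ud = rep(0, n_items),
        tfirst = rep(-1.5, n_items),
        inc = matrix(1.5, n_items, K - 2)
      ))
    } else {
      c(base, list(
        sd_thr = 1, cor_dt = 0, t0 = -1.5, inc0 = rep(1.5, K - 2),
        u = matrix(0, n_items, 2)
      ))
    }
  })
}

# Assemble indexed data for JAGS from responses + design.
jags_data <- function(obs, design, spec, person_levels, item_levels, K) {
  X <- as.matrix(design[, spec$covariates, drop = FALSE])
  pw_key <- paste(design$person_id, design$wave)
  row_id <- match(paste(obs$person_id, obs$wave), pw_key)
  if (anyNA(row_id)) {
    abort("Every observed response needs a design row.", class = "ghqwave_error")
  }
  list(
    N = nrow(obs),
    y = as.integer(obs$response) + 1L,
    item = match(obs$item, item_levels),
    row = row_id,
    R = nrow(design),
    pid = match(design$person_id, person_levels),
    X = X,
    J = ncol(X),
    NP = length(person_levels),
    NI = length(item_levels),
    K = K,
    prec_theta = 1 / spec$person_sd^2,
    zero2 = if (!spec$item_specific_thresholds) c(0, 0) else NULL
  )
}
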