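# Shared fixtures: everything is generated in code at test time.

# Independent closed-form multivariate-normal log-likelihood: per-row density
# via solve() and determinant(), deliberately not using the package's
# pattern-grouped sufficient-statistic path.
mvn_loglik_oracle <- function(Y, mu, sigma) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    if (!length(obs)) next
    d <- Y[i, obs] - mu[obs]
    so <- sigma[obs, obs, drop = FALSE]
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) +
                        as.numeric(determinant(so)$modulus) +
                        drop(d %*% solve(so) %*% d))
  }
  ll
}

# A saturated specification: every mean, variance and covariance free.
build_saturated_spec <- function(var_names, start_mu = NULL, start_sigma = NULL) {
  spec <- model_spec(observed = var_names)
  p <- length(var_names)
  if (is.null(start_mu)) start_mu <- rep(0, p)
  if (is.null(start_sigma)) start_sigma <- diag(p)
  for (i in seq_len(p)) {
    spec <- add_mean(spec, var_names[i], label = paste0("m_", i),
                     value = start_mu[i], free = TRUE)
    for (j in i:p) {
      spec <- add_cov(spec, var_names[i], var_names[j],
                      label = paste0("s_", i, "_", j),
                      value = start_sigma[i, j], free = TRUE)
    }
  }
  spec
}

# Small complete mutualism-world dataset shared by several tests.
sim_mutualism_data <- function(n = 227, coupling = c(0.35, 0.25), seed = 42,
                               missing_rate = 0) {
  cfg <- mutualism_generating_preset(coupling = coupling, n = n,
                                     missing_rate = missing_rate)
  simulate_dataset(cfg, seed = seed)
}

study_variances <- function() rbind(c(36, 40, 44), c(25, 28, 31))
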