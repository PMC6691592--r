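test_that("implied moments reproduce hand algebra", {
  # no paths, unit variances, zero means -> identity moments
  s <- model_spec(c("x", "y"))
  s <- add_cov(s, "x", "x", value = 1, free = FALSE)
  s <- add_cov(s, "y", "y", value = 1, free = FALSE)
  m <- implied_moments(s)
  expect_equal(m$sigma, diag(2), ignore_attr = TRUE)
  expect_equal(unname(m$mu), c(0, 0))

  # single path x -> y: var(y) = b^2 + psi, cov = b
  b <- 0.7; psi <- 0.5
  s2 <- model_spec(c("x", "y"))
  s2 <- add_cov(s2, "x", "x", value = 1, free = FALSE)
  s2 <- add_cov(s2, "y", "y", value = psi, free = FALSE)
  s2 <- add_path(s2, "x", "y", value = b, free = FALSE)
  m2 <- implied_moments(s2)
  expect_equal(m2$sigma["y", "y"], b^2 + psi)
  expect_equal(m2$sigma["x", "y"], b)
})

test_that("a structural cycle raises a singularity error", {
  s <- model_spec(c("x", "y"))
  s <- add_path(s, "x", "y", value = 1, free = FALSE)
  s <- add_path(s, "y", "x", value = 1, free = FALSE)
  s <- add_cov(s, "x", "x", value = 1, free = FALSE)
  s <- add_cov(s, "y", "y", value = 1, free = FALSE)
  expect_error(implied_moments(s), "cycle|singular")
})

test_that("FIML equals the closed-form MVN log-likelihood on complete data", {
  cfg <- mutualism_generating_preset(coupling = 0.25, n = 80)
  dat <- simulate_dataset(cfg, seed = 5)
  mom <- implied_moments(cfg$spec, cfg$true_values)
  ll_pkg <- fiml_loglik(cfg$spec, cfg$true_values, dat)
  ll_ora <- mvn_loglik_oracle(dat$scores, mom$mu, mom$sigma)
  expect_equal(ll_pkg, ll_ora, tolerance = 1e-8)
})

test_that("a fully missing person contributes zero to the likelihood", {
  cfg <- mutualism_generating_preset(coupling = 0.25, n = 20)
  dat <- simulate_dataset(cfg, seed = 8)
  ll0 <- fiml_loglik(cfg$spec, cfg$true_values, dat$scores)
  augmented <- rbind(dat$scores, NA)
  expect_equal(fiml_loglik(cfg$spec, cfg$true_values, augmented), ll0)
})

test_that("FIML marginalizes missing entries exactly", {
  # 6-variable case: dropping one entry equals the 5-dimensional marginal
  cfg <- mutualism_generating_preset(coupling = 0.25, n = 1)
  mom <- implied_moments(cfg$spec, cfg$true_values)
  y <- simulate_dataset(cfg, seed = 2)$scores
  y[1, 3] <- NA
  ll <- fiml_loglik(cfg$spec, cfg$true_values, y)
  expect_equal(ll, mvn_loglik_oracle(y, mom$mu, mom$sigma), tolerance = 1e-10)

  # 2-variable toy against brute-force numerical integration
  s <- model_spec(c("x", "y"))
  s <- add_cov(s, "x", "x", value = 2, free = FALSE)
  s <- add_cov(s, "y", "y", value = 1.5, free = FALSE)
  s <- add_cov(s, "x", "y", value = 0.8, free = FALSE)
  s <- add_mean(s, "x", value = 1, free = FALSE)
  s <- add_mean(s, "y", value = -0.5, free = FALSE)
  yobs <- matrix(c(0.3, NA), 1, 2, dimnames = list(NULL, c("x", "y")))
  ll_marg <- fiml_loglik(s, NULL, yobs)
  mom2 <- implied_moments(s)
  joint <- function(yy) {
    vapply(yy, function(v) {
      d <- c(0.3, v) - mom2$mu
      si <- solve(mom2$sigma)
      exp(-0.5 * drop(d %*% si %*% d)) /
        (2 * pi * sqrt(det(mom2$sigma)))
    }, numeric(1))
  }
  marginal <- stats::integrate(joint, -30, 30, rel.tol = 1e-12)$value
  expect_equal(ll_marg, log(marginal), tolerance = 1e-8)
})

test_that("a saturated fit reproduces the sample moments", {
  cfg <- mutualism_generating_preset(coupling = 0.3, n = 150)
  dat <- simulate_dataset(cfg, seed = 17)
  Y <- dat$scores
  mu_ml <- colMeans(Y)
  sig_ml <- crossprod(sweep(Y, 2, mu_ml)) / nrow(Y)
  spec <- build_saturated_spec(colnames(Y), mu_ml * 0.9,
                               diag(diag(sig_ml)) * 1.2)
  fit <- fit_model(spec, dat, se = FALSE,
                   control = list(iter.max = 5000, eval.max = 20000,
                                  rel.tol = 1e-12))
  mom <- implied_moments(spec, fit$estimates)
  expect_equal(mom$mu, mu_ml, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mom$sigma, sig_ml, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(2 * (fit$loglik_sat - fit$loglik), 0, tolerance = 1e-4)
})

test_that("saturated FIML moments under missingness maximize the likelihood", {
  cfg <- mutualism_generating_preset(coupling = 0.3, n = 300,
                                     missing_rate = 0.2)
  dat <- simulate_dataset(cfg, seed = 23)
  Y <- dat$scores[rowSums(!is.na(dat$scores)) > 0, ]
  sat <- bivlcs:::saturated_moments(Y)
  ll_sat <- mvn_loglik_oracle(Y, sat$mu, sat$sigma)
  # EM solution beats the generating moments and pairwise moments
  mom <- implied_moments(cfg$spec, cfg$true_values)
  expect_gt(ll_sat, mvn_loglik_oracle(Y, mom$mu, mom$sigma))
})
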