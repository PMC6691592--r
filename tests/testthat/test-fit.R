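test_that("data matching the implied moments exactly are recovered with chisq ~ 0", {
  cfg <- mutualism_generating_preset(coupling = c(0.3, 0.2), n = 227)
  target <- implied_moments(cfg$spec, cfg$true_values)
  raw <- simulate_dataset(cfg, seed = 31)$scores
  # rotate the draw so its ML moments equal the target exactly
  mu_ml <- colMeans(raw)
  sig_ml <- crossprod(sweep(raw, 2, mu_ml)) / nrow(raw)
  Z <- sweep(raw, 2, mu_ml) %*% solve(chol(sig_ml)) %*% chol(target$sigma)
  Y <- sweep(Z, 2, target$mu, `+`)
  colnames(Y) <- colnames(raw)
  fit <- fit_model(cfg$spec, Y, se = FALSE)
  expect_true(fit$converged)
  expect_equal(2 * (fit$loglik_sat - fit$loglik), 0, tolerance = 1e-3)
  expect_equal(fit$estimates[names(cfg$true_values)], cfg$true_values,
               tolerance = 1e-3)
})

test_that("estimates at n = 1000 fall within three standard errors of truth", {
  cfg <- mutualism_generating_preset(coupling = c(0.3, 0.2), n = 1000)
  dat <- simulate_dataset(cfg, seed = 77)
  fit <- fit_model(cfg$spec, dat)
  expect_true(fit$converged)
  for (lb in c("gamma_voc_mat", "gamma_mat_voc", "beta_voc", "beta_mat")) {
    expect_lt(abs(fit$estimates[[lb]] - cfg$true_values[[lb]]),
              3 * fit$se[[lb]])
  }
})

test_that("underidentified problems are refused", {
  cfg <- mutualism_generating_preset(coupling = 0.2, n = 10)
  dat <- simulate_dataset(cfg, seed = 1)
  expect_error(fit_model(cfg$spec, dat), "identification|fewer persons")
})

test_that("AIC and BIC orderings are invariant to consistent rescaling", {
  dat <- sim_mutualism_data(n = 227, seed = 55)
  scaled <- dat
  scaled$scores <- dat$scores * 2
  specs <- list(build_mutualism_lcs(), build_gfactor_lcs())
  d_aic <- function(d) {
    # the misspecified g-factor fit is expected to warn (Heywood case)
    f <- suppressWarnings(lapply(specs, fit_model, data = d, se = FALSE))
    diff(vapply(f, function(x) -2 * x$loglik + 2 * x$n_free, numeric(1)))
  }
  expect_equal(d_aic(dat), d_aic(scaled), tolerance = 0.02)
})

test_that("standardization matches hand algebra and flags degenerate variances", {
  # path with b = 1 between unit-variance variables -> standardized 1
  s <- model_spec(c("x", "y"))
  s <- add_cov(s, "x", "x", value = 1, free = FALSE)
  s <- add_cov(s, "y", "y", label = "psi", value = 0, free = FALSE)
  s <- add_path(s, "x", "y", label = "b", value = 1, free = TRUE)
  std <- standardize(s, c(b = 1))
  expect_equal(std$std[std$label == "b"], 1)
  # all-unit-variance model: standardized equals raw
  s2 <- edit_constraint(s, "fix", "psi", value = 0.51)
  std2 <- standardize(s2, c(b = 0.7))
  expect_equal(std2$std[std2$label == "b"], 0.7, tolerance = 1e-12)
  # zero implied variance is flagged
  s3 <- edit_constraint(s, "fix", "psi", value = 0)
  expect_warning(standardize(s3, c(b = 0)), "zero or negative implied variance")
})

test_that("wald_test returns estimate/se based z and two-sided p", {
  dat <- sim_mutualism_data(n = 227, seed = 12)
  fit <- fit_model(build_mutualism_lcs(), dat)
  w <- wald_test(fit, "gamma_voc_mat")
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_error(wald_test(fit, "not_a_label"), "unknown label")
})
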