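test_that("RMSEA reproduces the published statistics to three decimals", {
  # mutualism LCS: chisq(8) = 9.849 at n = 227
  expect_equal(round(rmsea_point(9.849, 8, 227), 3), 0.032)
  expect_equal(round(rmsea_ci(9.849, 8, 227), 3), c(0.000, 0.088))
  # parallel-process: chisq(9) = 18.72 at n = 227
  expect_equal(round(rmsea_point(18.72, 9, 227), 3), 0.069)
  expect_equal(round(rmsea_ci(18.72, 9, 227), 3), c(0.022, 0.113))
})

test_that("RMSEA edge cases follow the noncentral chi-square convention", {
  expect_equal(rmsea_point(8, 8, 227), 0)   # chisq = df
  expect_equal(rmsea_point(5, 8, 227), 0)   # chisq < df
  expect_true(is.na(rmsea_point(3, 0, 227))) # df = 0 undefined
  ci <- rmsea_ci(5, 8, 227)
  expect_equal(ci[1], 0)
})

test_that("information criteria and CFI follow their formulas", {
  dat <- sim_mutualism_data(n = 227, seed = 21)
  fit <- fit_model(build_mutualism_lcs(), dat, se = FALSE)
  ix <- fit_indices(fit)
  expect_equal(ix$aic, -2 * fit$loglik + 2 * 19)
  expect_equal(ix$bic, -2 * fit$loglik + 19 * log(227))
  expect_gt(ix$bic, ix$aic) # ln(227) > 2
  expect_equal(ix$chisq, 2 * (fit$loglik_sat - fit$loglik))
  expect_gte(ix$chisq, -1e-6)
  expect_true(ix$cfi >= 0 && ix$cfi <= 1)
  expect_gte(ix$srmr, 0)
})

test_that("the likelihood-ratio test is zero for identical models", {
  dat <- sim_mutualism_data(n = 120, seed = 9)
  f1 <- fit_model(build_investment_lcs(), dat, se = FALSE)
  f2 <- fit_model(build_investment_lcs(), dat, se = FALSE)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$delta_chisq, 0, tolerance = 1e-6)
  expect_equal(lrt$delta_df, 0)
  # restricted vs full on the same data is non-negative
  full <- fit_model(build_mutualism_lcs(), dat, se = FALSE)
  lrt2 <- likelihood_ratio_test(f1, full)
  expect_gte(lrt2$delta_chisq, 0)
  expect_equal(lrt2$delta_df, 1)
})

test_that("cross-sample z follows the pooled-standard-error formula", {
  expect_equal(cross_sample_z(0.4, 0.1, 0.4, 0.2), 0)
  expect_equal(cross_sample_z(0.5, 0.1, 0.2, 0.1), 2.121, tolerance = 1e-3)
  expect_error(cross_sample_z(0.5, 0, 0.2, 0.1), "positive")
  # back-solve the published comparison: -0.27 vs -0.602 with pooled SE 0.0582
  se_each <- (0.602 - 0.27) / 5.7 / sqrt(2)
  expect_equal(cross_sample_z(-0.27, se_each, -0.602, se_each), 5.7,
               tolerance = 1e-6)
})

test_that("default and Fisher z variants agree for small effects", {
  # identical estimates: both variants are exactly zero
  expect_equal(cross_sample_z(0.25, 0.1, 0.25, 0.1, fisher = TRUE), 0)
  # small standardized effects: near-equality on the z scale
  small <- expand.grid(b1 = c(-0.1, -0.05, 0.05, 0.1), b2 = c(-0.08, 0, 0.1),
                       se = c(0.05, 0.1))
  for (i in seq_len(nrow(small))) {
    g <- small[i, ]
    expect_lt(abs(cross_sample_z(g$b1, g$se, g$b2, g$se) -
                    cross_sample_z(g$b1, g$se, g$b2, g$se, fisher = TRUE)),
              0.02)
  }
  # moderate effects up to |beta| = 0.3: agreement within 6% relative
  wide <- expand.grid(b1 = c(-0.3, 0.3), b2 = c(-0.2, 0.25), se = c(0.05, 0.1))
  for (i in seq_len(nrow(wide))) {
    g <- wide[i, ]
    z0 <- cross_sample_z(g$b1, g$se, g$b2, g$se)
    z1 <- cross_sample_z(g$b1, g$se, g$b2, g$se, fisher = TRUE)
    expect_lt(abs(z0 - z1) / max(abs(z0), 1e-9), 0.06)
  }
})
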