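test_that("simulation is deterministic in the seed and has the right shape", {
  cfg <- mutualism_generating_preset(coupling = 0.2, n = 227)
  d1 <- simulate_dataset(cfg, seed = 123)
  d2 <- simulate_dataset(cfg, seed = 123)
  d3 <- simulate_dataset(cfg, seed = 124)
  expect_identical(d1$scores, d2$scores)
  expect_false(identical(d1$scores, d3$scores))
  expect_equal(dim(d1$scores), c(227L, 6L))
  expect_false(anyNA(d1$scores))
})

test_that("large samples reproduce the implied covariance (law of large numbers)", {
  cfg <- mutualism_generating_preset(coupling = 0.25, n = 100000)
  dat <- simulate_dataset(cfg, seed = 7)
  implied <- implied_moments(cfg$spec, cfg$true_values)
  S <- stats::cov(dat$scores) * (nrow(dat$scores) - 1) / nrow(dat$scores)
  rel <- abs(S - implied$sigma) / (abs(implied$sigma) + 0.5)
  expect_lt(max(rel), 0.03)
  expect_equal(colMeans(dat$scores), implied$mu, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("MCAR masking hits the requested rate and preserves means", {
  cfg <- mutualism_generating_preset(coupling = 0.2, n = 50000,
                                     missing_rate = 0.25)
  # at this rate a handful of persons lose all six cells; the constructor warns
  dat <- suppressWarnings(simulate_dataset(cfg, seed = 10))
  expect_equal(mean(is.na(dat$scores)), 0.25, tolerance = 0.01)
  implied <- implied_moments(cfg$spec, cfg$true_values)
  rel <- abs(colMeans(dat$scores, na.rm = TRUE) - implied$mu) / abs(implied$mu)
  expect_lt(max(rel), 0.02)
})

test_that("the g-factor preset produces steady, monotone growth", {
  # zero self-feedback: constant mean increments per wave
  cfg0 <- gfactor_generating_preset(self_feedback = 0, mean_change = 4)
  mu0 <- implied_moments(cfg0$spec, cfg0$true_values)$mu
  voc <- unname(mu0[paste0("voc_t", 1:3)])
  expect_equal(diff(voc)[1], diff(voc)[2], tolerance = 1e-10)
  # default: monotone increase in both domains
  cfg <- gfactor_generating_preset()
  mu <- implied_moments(cfg$spec, cfg$true_values)$mu
  expect_true(all(diff(mu[paste0("voc_t", 1:3)]) > 0))
  expect_true(all(diff(mu[paste0("mat_t", 1:3)]) > 0))
  # the negative self-feedback robustness variant needs a larger increment
  cfgn <- gfactor_generating_preset(self_feedback = -0.2, mean_change = 6)
  mun <- implied_moments(cfgn$spec, cfgn$true_values)$mu
  expect_true(all(diff(mun[paste0("voc_t", 1:3)]) > 0))
  expect_error(gfactor_generating_preset(self_feedback = 1.2), "< 1")
})

test_that("the mutualism preset hits the requested standardized coupling", {
  for (target in c(0, 0.1, 0.3)) {
    cfg <- mutualism_generating_preset(coupling = target)
    std <- standardize(cfg$spec, cfg$true_values)
    got <- std$std[std$location %in% c("d_mat_t2~voc_t1", "d_voc_t2~mat_t1")]
    expect_equal(got, rep(target, 2), tolerance = 0.01)
    if (target == 0) {
      expect_equal(cfg$true_values[["gamma_voc_mat"]], 0)
      expect_equal(cfg$true_values[["gamma_mat_voc"]], 0)
    }
  }
  expect_error(mutualism_generating_preset(coupling = 0.7), "\\[0, 0.5\\]")
})

test_that("larger generating couplings yield larger estimated couplings", {
  est_at <- function(coupling) {
    cfg <- mutualism_generating_preset(coupling = coupling, n = 227)
    fits <- vapply(1:15, function(r) {
      dat <- simulate_dataset(cfg, seed = 3000 + r)
      f <- suppressWarnings(fit_model(cfg$spec, dat, se = FALSE))
      std <- standardize(f)
      std$std[std$location == "d_mat_t2~voc_t1"]
    }, numeric(1))
    mean(fits)
  }
  expect_gt(est_at(0.3), est_at(0.1))
})

test_that("generator validation rejects broken configurations", {
  spec <- build_mutualism_lcs()
  tv <- mutualism_generating_preset(coupling = 0.2)$true_values
  expect_error(generator_config(spec, tv[-1], n = 10), "no value supplied")
  expect_error(generator_config(spec, tv, n = 10, missing_rate = 1),
               "missing_rate")
  bad <- tv; bad[["var_voc_t1"]] <- -5
  cfg <- generator_config(spec, bad, n = 10)
  expect_error(simulate_dataset(cfg), "not\\s+positive definite")
})
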