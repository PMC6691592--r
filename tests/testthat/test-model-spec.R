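test_that("every builder's free parameters plus df equal the 27 observed moments", {
  design <- study_design()
  specs <- list(
    build_mutualism_lcs(design),
    build_investment_lcs(design),
    build_gfactor_lcs(design),
    build_parallel_process(design),
    build_parallel_process(design, cross_domain_only = FALSE),
    build_riclpm(design)
  )
  for (s in specs) expect_equal(n_free(s) + spec_df(s), 27)
  expect_equal(spec_df(build_mutualism_lcs(design)), 8)
  expect_equal(spec_df(build_parallel_process(design)), 9)
  expect_equal(n_free(build_riclpm(design)), 20)
})

test_that("nesting structure: mutualism > investment > no-coupling", {
  mut <- build_mutualism_lcs()
  inv <- build_investment_lcs()
  expect_equal(n_free(mut) - n_free(inv), 1)
  none <- edit_constraint(inv, "fix", "gamma_mat_voc", value = 0)
  expect_equal(n_free(inv) - n_free(none), 1)
  # collapsing both couplings from mutualism reaches the same spec
  none2 <- edit_constraint(
    edit_constraint(mut, "fix", "gamma_voc_mat", value = 0),
    "fix", "gamma_mat_voc", value = 0)
  expect_equal(free_params(none), free_params(none2))
})

test_that("constraint edits update df bookkeeping and round-trip", {
  mut <- build_mutualism_lcs()
  # fully constrained vocabulary-change intercept differs by exactly 1 df
  constrained <- build_mutualism_lcs(free_vocab_intercept = FALSE)
  expect_equal(spec_df(constrained) - spec_df(mut), 1)
  # within-domain growth paths add exactly 2 parameters
  pp <- build_parallel_process()
  pp_within <- build_parallel_process(cross_domain_only = FALSE)
  expect_equal(n_free(pp_within) - n_free(pp), 2)
  # fixing a cross path changes df by +1
  fixed <- edit_constraint(pp, "fix", "b_ivoc_smat", value = 0)
  expect_equal(spec_df(fixed) - spec_df(pp), 1)
  # fix-then-free round trip restores the original tables
  back <- edit_constraint(
    edit_constraint(mut, "fix", "gamma_voc_mat", value = 0),
    "free", "gamma_voc_mat", value = 0)
  expect_equal(back, mut)
  # equating two free labels reduces the free count by one
  eq <- edit_constraint(mut, "equate", c("zeta_voc", "zeta_mat"))
  expect_equal(n_free(eq), n_free(mut) - 1)
})

test_that("unknown labels are rejected with the available labels listed", {
  expect_error(edit_constraint(build_mutualism_lcs(), "fix", "nope", 0),
               "unknown parameter label.*available labels")
})

test_that("text serialization round-trips a specification", {
  for (spec in list(build_mutualism_lcs(), build_gfactor_lcs())) {
    back <- spec_from_text(spec_to_text(spec))
    expect_equal(back$variables, spec$variables)
    expect_equal(back$paths, spec$paths)
    expect_equal(back$covs, spec$covs)
    expect_equal(back$means, spec$means)
  }
})

test_that("the reliability adjustment fixes residuals without changing df", {
  s2 <- 4.0
  expect_equal(reliability_residual_variance(s2, 1.0), 0)
  expect_equal(reliability_residual_variance(s2, 0.75), 1)
  expect_equal(reliability_residual_variance(2.5, 0.9), 0.25)
  expect_error(reliability_residual_variance(4, 0), "reliability")
  expect_error(reliability_residual_variance(4, 1.2), "reliability")

  des <- study_design(variances = study_variances(),
                      reliabilities = matrix(0.9, 2, 3))
  plain <- build_mutualism_lcs()
  adj <- build_mutualism_lcs(des)
  expect_equal(spec_df(adj), spec_df(plain))
  # implied observed covariance gains exactly S^2(1-Rxx) on the diagonal
  tv <- mutualism_generating_preset(coupling = 0.2)$true_values
  diff <- implied_moments(adj, tv)$sigma - implied_moments(plain, tv)$sigma
  expect_equal(diff, diag(0.1 * as.vector(t(study_variances()))),
               ignore_attr = TRUE, tolerance = 1e-10)
})
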