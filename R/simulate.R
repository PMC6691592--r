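#' Bundle a data-generating configuration
#'
#' @param spec a [model_spec()] acting as the generating model.
#' @param true_values named vector valuing every free label of \code{spec}.
#' @param n number of persons to draw.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param missing_rate probability that each cell is missing completely at
#'   random, in [0, 1).
#' @param design the [study_design()] the spec was built from (used to label
#'   waves and domains of simulated datasets).
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(spec, true_values, n, seed = 1L,
                             missing_rate = 0, design = study_design()) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n >= 1)
  cs <- compile_spec(spec)
  resolve_values(cs, true_values) # errors if a label is missing
  structure(list(spec = spec, true_values = true_values, n = as.integer(n),
                 seed = as.integer(seed), missing_rate = missing_rate,
                 design = design),
            class = "generator_config")
}

#' Simulate a longitudinal dataset from a generating configuration
#'
#' Draws independent person-vectors from the multivariate normal distribution
#' with the generating model's implied mean and covariance (the same implied
#' moments used for estimation), then applies an MCAR mask.
#'
#' @param cfg a [generator_config()].
#' @param seed optional override of the configuration's seed.
#' @return An \code{lcs_data} dataset.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  mom <- implied_moments(cfg$spec, cfg$true_values)
  ch <- tryCatch(chol(mom$sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("generator error: implied covariance of the generating model is not ",
         "positive definite")
  }
  set.seed(seed)
  Y <- MASS::mvrnorm(cfg$n, mu = mom$mu, Sigma = mom$sigma)
  if (cfg$n == 1) Y <- matrix(Y, nrow = 1)
  colnames(Y) <- names(mom$mu)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(Y)) < cfg$missing_rate,
                   nrow(Y), ncol(Y))
    Y[mask] <- NA_real_
  }
  longitudinal_data(Y, wave_labels = paste0("T", seq_len(cfg$design$n_waves)),
                    domain_labels = cfg$design$domains)
}

#' Generating preset: common-factor LCS world
#'
#' A g-factor latent change score generating configuration with steady mean
#' increments in the factor and (by default) modest positive self-feedback,
#' so that higher-g children gain slightly more per occasion. Raw parameter
#' magnitudes are this package's documented defaults, chosen so simulated
#' scores live on the scale of raw Wechsler-type vocabulary and matrix
#' reasoning scores in middle childhood (wave-1 means near 23 and 12, wave-1
#' variances near 36 and 25, within-wave cross-domain correlation near 0.4 —
#' so the factor carries well under half of each indicator's variance).
#'
#' @param self_feedback factor self-feedback (|value| < 1); the 0 and -0.2
#'   variants are the documented robustness settings.
#' @param n persons per dataset.
#' @param mean_change per-occasion factor increment; raise it when
#'   self-feedback is zero or negative so scores still improve globally.
#' @param seed,missing_rate passed to [generator_config()].
#' @return A [generator_config()] over [build_gfactor_lcs()].
#' @export
gfactor_generating_preset <- function(self_feedback = 0.2, n = 227,
                                      mean_change = 4, seed = 1L,
                                      missing_rate = 0) {
  if (abs(self_feedback) >= 1) stop("|self_feedback| must be < 1")
  design <- study_design(variances = rbind(c(36, 45, 56), c(25, 31, 38)))
  spec <- build_gfactor_lcs(design)
  truth <- c(
    lambda_mat = 0.83,
    theta_voc = 21.6, theta_mat = 15.1,
    tau_voc = 23, tau_mat = 12,
    var_g_t1 = 14.4,
    beta_g = self_feedback,
    alpha_g = mean_change,
    zeta_g = 3,
    cov_dg = 0
  )
  generator_config(spec, truth, n = n, seed = seed,
                   missing_rate = missing_rate, design = design)
}

#' Generating preset: mutualism LCS world
#'
#' A bivariate mutualism generating configuration whose first-lag
#' standardized cross-domain couplings equal the requested values; the raw
#' couplings are solved numerically from the implied moments. All other raw
#' parameters are this package's documented defaults, mirroring the scale and
#' the standardized dynamics of raw Wechsler-type scores in middle childhood:
#' negative self-feedback (standardized roughly -0.2 and -0.3), a wave-1
#' cross-domain correlation of 0.4, contemporaneous change-residual
#' correlation 0.3, and larger vocabulary gains between the first pair of
#' occasions than the second.
#'
#' @param coupling standardized coupling value(s) in [0, 0.5]: either a
#'   scalar applied to both directions or a length-2 vector
#'   (vocabulary-to-reasoning, reasoning-to-vocabulary).
#' @param n persons per dataset.
#' @param seed,missing_rate passed to [generator_config()].
#' @return A [generator_config()] over [build_mutualism_lcs()].
#' @export
mutualism_generating_preset <- function(coupling = c(0.35, 0.25), n = 227,
                                        seed = 1L, missing_rate = 0) {
  if (length(coupling) == 1) coupling <- rep(coupling, 2)
  if (any(coupling < 0 | coupling > 0.5)) {
    stop("standardized couplings must lie in [0, 0.5]")
  }
  design <- study_design(variances = rbind(c(36, 40, 44), c(25, 28, 31)))
  spec <- build_mutualism_lcs(design)
  truth <- c(
    beta_voc = -0.07, gamma_mat_voc = 0,
    beta_mat = -0.12, gamma_voc_mat = 0,
    zeta_voc = 4, zeta_mat = 4,
    var_voc_t1 = 36, var_mat_t1 = 25,
    mu_voc_t1 = 23, mu_mat_t1 = 12,
    cov_voc_mat_t1 = 12,
    cov_change_contemp = 1.2,
    cov_d_voc = 0, cov_d_mat = 0,
    cov_d_voc2_mat3 = 0, cov_d_mat2_voc3 = 0,
    alpha_voc_t2 = 6, alpha_voc_t3 = 4.5,
    alpha_mat = 4
  )
  truth <- solve_standardized_couplings(spec, truth, coupling)
  generator_config(spec, truth, n = n, seed = seed,
                   missing_rate = missing_rate, design = design)
}

# Solve raw couplings so the wave-2 (first-lag) standardized couplings equal
# the requested values, by damped fixed-point iteration on the ratio of
# requested to achieved standardized value.
solve_standardized_couplings <- function(spec, truth, target) {
  labs <- c("gamma_voc_mat", "gamma_mat_voc")
  locs <- c("d_mat_t2~voc_t1", "d_voc_t2~mat_t1")
  std_at <- function(tr) {
    tab <- standardize(spec, tr)
    vapply(locs, function(l) tab$std[tab$location == l][1], numeric(1))
  }
  # initial guess from marginal scales
  tr <- truth
  tr[labs] <- target * c(sqrt(truth[["zeta_mat"]] / truth[["var_voc_t1"]]),
                         sqrt(truth[["zeta_voc"]] / truth[["var_mat_t1"]]))
  for (it in 1:100) {
    cur <- std_at(tr)
    if (all(abs(cur - target) < 1e-10)) break
    adj <- ifelse(target == 0, 0,
                  ifelse(cur == 0, tr[labs] + 0.01, tr[labs] * target / cur))
    tr[labs] <- ifelse(target == 0, 0, adj)
    if (it == 100 && any(abs(std_at(tr) - target) > 1e-6)) {
      stop("requested standardized coupling unattainable under the default ",
           "variances; values in [0, 0.5] are supported")
    }
  }
  tr
}
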