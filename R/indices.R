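#' Fit indices for a fitted model
#'
#' Computes the likelihood-ratio chi-square against the saturated model,
#' RMSEA with a 90\% confidence interval from the noncentral chi-square
#' distribution, CFI against the independence baseline (free variances and
#' means, zero covariances), SRMR over the standardized covariance residuals,
#' and AIC/BIC.
#'
#' Formulae: \eqn{\chi^2 = 2(\ell_{sat} - \ell_{model})};
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (n-1))}} with CI bounds from
#' inverting the noncentral chi-square at 5\%/95\%;
#' \eqn{CFI = 1 - \max(\chi^2 - df, 0)/\max(\chi^2_b - df_b, 0)};
#' \eqn{AIC = -2\ell + 2k}; \eqn{BIC = -2\ell + k \log n}.
#'
#' @param fit an \code{lcs_fit}.
#' @param n sample size; defaults to the fitted n.
#' @return An object of class \code{fit_indices} (a named list).
#' @export
fit_indices <- function(fit, n = fit$n) {
  chisq <- 2 * (fit$loglik_sat - fit$loglik)
  df <- fit$df
  p_obs <- fit$p
  chisq_b <- 2 * (fit$loglik_sat - fit$loglik_indep)
  df_b <- p_obs * (p_obs + 3) / 2 - 2 * p_obs
  out <- list(
    chisq = chisq, df = df,
    p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    rmsea = rmsea_point(chisq, df, n),
    rmsea_ci = rmsea_ci(chisq, df, n),
    cfi = cfi_value(chisq, df, chisq_b, df_b),
    srmr = srmr_value(fit),
    aic = -2 * fit$loglik + 2 * fit$n_free,
    bic = -2 * fit$loglik + fit$n_free * log(n),
    n = n, n_free = fit$n_free
  )
  class(out) <- "fit_indices"
  out
}

#' RMSEA from a chi-square statistic
#'
#' @param chisq likelihood-ratio statistic.
#' @param df model degrees of freedom.
#' @param n sample size (the \code{n - 1} divisor convention is used).
#' @return RMSEA point value; \code{NA} when \code{df == 0}.
#' @export
rmsea_point <- function(chisq, df, n) {
  if (df <= 0) return(NA_real_)
  sqrt(max(chisq - df, 0) / (df * (n - 1)))
}

#' 90\% confidence interval for RMSEA
#'
#' Bounds are obtained by inverting the noncentral chi-square distribution:
#' the lower (upper) bound uses the noncentrality at which the observed
#' statistic sits at the 95th (5th) percentile.
#'
#' @inheritParams rmsea_point
#' @return Length-2 vector (lower, upper); \code{NA}s when \code{df == 0}.
#' @export
rmsea_ci <- function(chisq, df, n) {
  if (df <= 0) return(c(NA_real_, NA_real_))
  bound <- function(prob) {
    f <- function(ncp) stats::pchisq(chisq, df, ncp = ncp) - prob
    if (f(0) < 0) return(0)
    hi <- max(chisq * 2, df + 50)
    while (f(hi) > 0 && hi < 1e7) hi <- hi * 2
    if (f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lam_low <- bound(0.95)
  lam_high <- bound(0.05)
  c(sqrt(lam_low / (df * (n - 1))), sqrt(lam_high / (df * (n - 1))))
}

cfi_value <- function(chisq, df, chisq_b, df_b) {
  denom <- max(chisq_b - df_b, 0)
  if (denom == 0) return(1)
  1 - max(chisq - df, 0) / denom
}

# SRMR over covariance residuals standardized by the sample (saturated FIML)
# standard deviations; covariance-only by default, the common convention.
srmr_value <- function(fit, include_means = FALSE) {
  mom <- implied_moments(fit$spec, fit$estimates)
  s <- fit$sample_sigma
  sig <- mom$sigma
  sd_s <- sqrt(diag(s))
  D <- outer(sd_s, sd_s)
  R <- (s - sig) / D
  res <- R[lower.tri(R, diag = TRUE)]^2
  if (include_means) {
    res <- c(res, ((fit$sample_mu - mom$mu) / sd_s)^2)
  }
  sqrt(mean(res))
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chisq(%d) = %.3f, p = %.3f\n", x$df, x$chisq, x$p))
  cat(sprintf("RMSEA = %.3f, 90%% CI [%.3f, %.3f]\n",
              x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2]))
  cat(sprintf("CFI = %.3f, SRMR = %.3f\n", x$cfi, x$srmr))
  cat(sprintf("AIC = %.2f, BIC = %.2f (k = %d, n = %d)\n",
              x$aic, x$bic, x$n_free, x$n))
  invisible(x)
}

#' Likelihood-ratio test of two nested fits
#'
#' The caller asserts nesting (the restricted model's parameter space lies
#' inside the full model's); nesting is not verified automatically.
#'
#' @param restricted,full \code{lcs_fit} objects fitted to the same data.
#' @return List with \code{delta_chisq}, \code{delta_df} and \code{p}. A
#'   negative statistic beyond numerical tolerance triggers a warning about
#'   non-nesting or convergence failure.
#' @export
likelihood_ratio_test <- function(restricted, full) {
  delta <- 2 * (full$loglik - restricted$loglik)
  ddf <- restricted$df - full$df
  if (delta < -1e-4 * (abs(full$loglik) + 1)) {
    warning("negative likelihood-ratio statistic: models may not be nested ",
            "or a fit failed to converge")
  }
  delta <- max(delta, 0)
  list(delta_chisq = delta, delta_df = ddf,
       p = if (ddf > 0) stats::pchisq(delta, ddf, lower.tail = FALSE) else NA_real_)
}

#' z statistic comparing a parameter across two independent samples
#'
#' Default: \eqn{z = (b_1 - b_2) / \sqrt{se_1^2 + se_2^2}}. For
#' correlation-like standardized parameters an optional Fisher-transformed
#' variant maps estimates through \code{atanh} with delta-method standard
#' errors before differencing.
#'
#' @param beta1,se1 estimate and standard error in sample 1.
#' @param beta2,se2 estimate and standard error in sample 2.
#' @param fisher use the Fisher-transformed variant.
#' @return The z statistic.
#' @export
cross_sample_z <- function(beta1, se1, beta2, se2, fisher = FALSE) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  if (fisher) {
    if (abs(beta1) >= 1 || abs(beta2) >= 1) {
      stop("Fisher variant requires |beta| < 1")
    }
    b1 <- atanh(beta1); b2 <- atanh(beta2)
    s1 <- se1 / (1 - beta1^2); s2 <- se2 / (1 - beta2^2)
    (b1 - b2) / sqrt(s1^2 + s2^2)
  } else {
    (beta1 - beta2) / sqrt(se1^2 + se2^2)
  }
}
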