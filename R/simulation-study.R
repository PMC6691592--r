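#' Model-recovery simulation
#'
#' Repeatedly simulates data from a generating configuration, fits every
#' candidate specification, and records which candidate AIC prefers.
#' Candidates need not be nested. Non-converged replicates are retained in
#' the per-replicate table but excluded from the preference denominator, with
#' the exclusion count reported; exact AIC ties are counted separately and
#' never broken.
#'
#' @param truth a [generator_config()].
#' @param candidates named list of [model_spec()] candidates.
#' @param reps number of replicates (>= 1).
#' @param base_seed replicate \code{r} uses seed \code{base_seed + r}.
#' @return An object of class \code{recovery_result}: preference counts, tie
#'   and failure counts, and the per-replicate AIC table.
#' @export
run_model_recovery <- function(truth, candidates, reps = 200, base_seed = 1L) {
  if (reps < 1) stop("reps must be >= 1")
  stopifnot(length(names(candidates)) == length(candidates))
  nm <- names(candidates)
  aic_tab <- matrix(NA_real_, reps, length(candidates),
                    dimnames = list(NULL, nm))
  conv_tab <- matrix(FALSE, reps, length(candidates), dimnames = list(NULL, nm))
  for (r in seq_len(reps)) {
    dat <- simulate_dataset(truth, seed = base_seed + r)
    for (j in seq_along(candidates)) {
      f <- tryCatch(
        suppressWarnings(fit_model(candidates[[j]], dat, se = FALSE)),
        error = function(e) NULL)
      if (!is.null(f)) {
        conv_tab[r, j] <- f$converged
        aic_tab[r, j] <- -2 * f$loglik + 2 * f$n_free
      }
    }
  }
  all_ok <- rowSums(conv_tab) == length(candidates)
  winners <- rep(NA_character_, reps)
  ties <- 0L
  for (r in which(all_ok)) {
    a <- aic_tab[r, ]
    best <- which(a <= min(a) + 1e-9)
    if (length(best) > 1) ties <- ties + 1L else winners[r] <- nm[best]
  }
  counts <- table(factor(winners, levels = nm))
  structure(list(
    reps = reps,
    preferred_counts = as.vector(counts) |> stats::setNames(nm),
    ties = ties,
    failures = sum(!all_ok),
    aic = as.data.frame(aic_tab),
    converged = as.data.frame(conv_tab)
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  denom <- x$reps - x$failures
  cat(sprintf("Model recovery over %d replicates (%d converged, %d ties, %d failures)\n",
              x$reps, denom, x$ties, x$failures))
  for (nm in names(x$preferred_counts)) {
    cat(sprintf("  %s preferred by AIC: %d/%d (%.1f%%)\n", nm,
                x$preferred_counts[[nm]], denom,
                100 * x$preferred_counts[[nm]] / denom))
  }
  invisible(x)
}

#' Monte-Carlo power curve for the cross-domain coupling
#'
#' For each standardized coupling value on the grid, simulates datasets from
#' the mutualism generating preset (both coupling directions set to the grid
#' value), fits the mutualism specification, and tests the
#' vocabulary-to-reasoning coupling against zero — by default a Wald z test
#' of the raw estimate at level \code{alpha}, optionally a 1-df
#' likelihood-ratio test. Power is the rejection proportion among converged
#' replicates with an exact (Clopper-Pearson) binomial confidence interval.
#' Grid points with more than 20\% non-convergence are flagged unreliable.
#'
#' @param couplings grid of standardized coupling values in [0, 0.5].
#' @param reps replicates per grid point.
#' @param n persons per dataset.
#' @param alpha test level in (0, 1).
#' @param base_seed replicate \code{r} of grid point \code{i} uses seed
#'   \code{base_seed + (i - 1) * 100000 + r}.
#' @param test \code{"wald"} (default) or \code{"lrt"}.
#' @param parameter label of the coupling tested.
#' @return An object of class \code{power_curve}: a data frame per grid value
#'   with rejections, power and its CI, mean estimate, and reliability flag.
#' @export
run_power_curve <- function(couplings, reps = 100, n = 227, alpha = 0.05,
                            base_seed = 1L, test = c("wald", "lrt"),
                            parameter = "gamma_voc_mat") {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  fit_spec <- build_mutualism_lcs(
    study_design(variances = rbind(c(36, 40, 44), c(25, 28, 31))))
  rows <- list()
  for (i in seq_along(couplings)) {
    cfg <- mutualism_generating_preset(coupling = couplings[i], n = n)
    reject <- logical(0); ests <- numeric(0); fails <- 0L
    for (r in seq_len(reps)) {
      dat <- simulate_dataset(cfg, seed = base_seed + (i - 1L) * 100000L + r)
      f <- tryCatch(
        suppressWarnings(fit_model(fit_spec, dat, se = (test == "wald"))),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) { fails <- fails + 1L; next }
      if (test == "wald") {
        w <- wald_test(f, parameter)
        if (is.na(w$z)) { fails <- fails + 1L; next }
        reject <- c(reject, w$p < alpha)
      } else {
        restricted <- edit_constraint(fit_spec, "fix", parameter, value = 0)
        rf <- tryCatch(
          suppressWarnings(fit_model(restricted, dat, se = FALSE)),
          error = function(e) NULL)
        if (is.null(rf)) { fails <- fails + 1L; next }
        lrt <- likelihood_ratio_test(rf, f)
        reject <- c(reject, lrt$p < alpha)
      }
      ests <- c(ests, f$estimates[[parameter]])
    }
    m <- length(reject)
    ci <- if (m > 0) stats::binom.test(sum(reject), m)$conf.int else c(NA, NA)
    rows[[i]] <- data.frame(
      coupling = couplings[i], reps = reps, converged = m,
      rejections = sum(reject),
      power = if (m > 0) mean(reject) else NA_real_,
      ci_lo = ci[1], ci_hi = ci[2],
      mean_estimate = if (length(ests)) mean(ests) else NA_real_,
      unreliable = fails > 0.2 * reps
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_curve", class(out))
  out
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Coupling power curve (Wald/LRT rejections at the nominal level)\n")
  df <- as.data.frame(x)
  df$power <- round(df$power, 3)
  df$ci_lo <- round(df$ci_lo, 3); df$ci_hi <- round(df$ci_hi, 3)
  df$mean_estimate <- round(df$mean_estimate, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
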