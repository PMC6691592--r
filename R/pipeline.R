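#' Fit the three theoretical accounts and compare them
#'
#' Fits the common-factor (g), investment, and mutualism latent change score
#' models to the same dataset, tabulates fit statistics and information
#' criteria, marks the model preferred by AIC and by BIC (ties are reported,
#' never broken silently), and runs the investment-versus-mutualism
#' likelihood-ratio test (the only nested pair).
#'
#' @param data an \code{lcs_data} dataset.
#' @param design a [study_design()].
#' @param se compute standard errors for each fit.
#' @return An object of class \code{comparison_table}: the table (ordered
#'   worst to best by AIC), the fits, and the LRT.
#' @export
run_three_model_comparison <- function(data, design = study_design(), se = TRUE) {
  specs <- list(
    gfactor = build_gfactor_lcs(design),
    investment = build_investment_lcs(design),
    mutualism = build_mutualism_lcs(design)
  )
  fits <- lapply(specs, function(s) {
    tryCatch(fit_model(s, data, se = se), error = function(e) e)
  })
  tab <- comparison_table(fits)
  lrt <- if (inherits(fits$investment, "lcs_fit") &&
             inherits(fits$mutualism, "lcs_fit")) {
    likelihood_ratio_test(fits$investment, fits$mutualism)
  } else NULL
  structure(list(table = tab, fits = fits, lrt_investment_vs_mutualism = lrt),
            class = "comparison_table_result")
}

comparison_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!inherits(f, "lcs_fit")) {
      return(data.frame(model = nm, converged = FALSE, chisq = NA, df = NA,
                        p = NA, rmsea = NA, rmsea_lo = NA, rmsea_hi = NA,
                        cfi = NA, srmr = NA, aic = NA, bic = NA))
    }
    ix <- fit_indices(f)
    data.frame(model = nm, converged = f$converged, chisq = ix$chisq,
               df = ix$df, p = ix$p, rmsea = ix$rmsea,
               rmsea_lo = ix$rmsea_ci[1], rmsea_hi = ix$rmsea_ci[2],
               cfi = ix$cfi, srmr = ix$srmr, aic = ix$aic, bic = ix$bic)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$aic), ] # worst to best
  ok <- tab$converged & !is.na(tab$aic)
  tol <- 1e-6
  tab$preferred_aic <- ok & tab$aic <= min(tab$aic[ok]) + tol
  tab$preferred_bic <- ok & tab$bic <= min(tab$bic[ok]) + tol
  tab$tie_aic <- sum(tab$preferred_aic) > 1
  tab$tie_bic <- sum(tab$preferred_bic) > 1
  rownames(tab) <- NULL
  tab
}

#' @export
print.comparison_table_result <- function(x, ...) {
  cat("Model comparison (ordered worst to best by AIC)\n")
  tab <- x$table
  show <- tab[, c("model", "chisq", "df", "rmsea", "cfi", "srmr", "aic", "bic")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round, 3)
  print(show, row.names = FALSE)
  pref_a <- tab$model[tab$preferred_aic]
  pref_b <- tab$model[tab$preferred_bic]
  cat("Preferred by AIC:", paste(pref_a, collapse = " = "),
      if (isTRUE(tab$tie_aic[1])) "(tie)" else "", "\n")
  cat("Preferred by BIC:", paste(pref_b, collapse = " = "),
      if (isTRUE(tab$tie_bic[1])) "(tie)" else "", "\n")
  if (!is.null(x$lrt_investment_vs_mutualism)) {
    l <- x$lrt_investment_vs_mutualism
    cat(sprintf("Investment vs mutualism LRT: delta-chisq(%d) = %.3f, p = %.4g\n",
                l$delta_df, l$delta_chisq, l$p))
  }
  invisible(x)
}

# --- multigroup machinery --------------------------------------------------

#' Fit a specification simultaneously in several groups
#'
#' All parameters are shared across groups except the labels listed in
#' \code{free_labels}, which receive group-specific copies. The model with an
#' empty freed set has the same likelihood as the single-group fit.
#'
#' @param spec a [model_spec()].
#' @param data an \code{lcs_data} with a grouping factor.
#' @param free_labels labels freed across groups.
#' @param start optional named starting values (e.g. single-group estimates).
#' @param control optimizer control.
#' @return List with the combined log-likelihood, estimates, group levels,
#'   free-parameter count and convergence flag.
#' @export
fit_multigroup <- function(spec, data, free_labels = character(),
                           start = NULL,
                           control = list(iter.max = 2000, eval.max = 8000)) {
  if (is.null(data$group)) stop("data carry no grouping variable")
  cs <- compile_spec(spec)
  obs <- cs$vars[cs$obs_idx]
  lev <- levels(data$group)
  if (length(lev) < 2) stop("need at least two groups")
  stats_by_group <- lapply(lev, function(g) {
    Y <- score_matrix(data, obs)[data$group == g, , drop = FALSE]
    pattern_stats(Y)
  })
  ns <- vapply(stats_by_group, attr, numeric(1), "n")
  bad <- setdiff(free_labels, cs$labels)
  if (length(bad)) stop("not free labels of the spec: ", paste(bad, collapse = ", "))
  shared <- setdiff(cs$labels, free_labels)
  group_labels <- if (length(free_labels)) {
    unlist(lapply(lev, function(g) paste0(free_labels, ".", g)))
  } else character(0)
  comb_labels <- c(shared, group_labels)
  k <- length(comb_labels)
  if (sum(ns) < k) stop("identification error: fewer persons than parameters")
  if (any(ns < 2)) stop("identification error: a group has too few persons")
  # map combined vector into each group's spec-order theta
  maps <- lapply(lev, function(g) {
    eff <- ifelse(cs$labels %in% free_labels,
                  paste0(cs$labels, ".", g), cs$labels)
    match(eff, comb_labels)
  })
  base_start <- if (is.null(start)) stats::setNames(cs$start, cs$labels) else start
  th0 <- numeric(k)
  th0[match(shared, comb_labels)] <- base_start[shared]
  if (length(free_labels)) {
    for (g in seq_along(lev)) {
      th0[match(paste0(free_labels, ".", lev[g]), comb_labels)] <-
        base_start[free_labels]
    }
  }
  neg <- function(theta) {
    total <- 0
    for (g in seq_along(lev)) {
      mom <- tryCatch(
        moments_from_matrices(cs, fill_matrices(cs, theta[maps[[g]]])),
        error = function(e) NULL)
      if (is.null(mom)) return(1e10)
      ll <- loglik_from_stats(stats_by_group[[g]], mom$mu, mom$sigma)
      if (is.na(ll) || !is.finite(ll)) return(1e10)
      total <- total - ll
    }
    total
  }
  opt <- stats::nlminb(th0, neg, control = control)
  ll_sat <- sum(vapply(seq_along(lev), function(g) {
    st <- stats_by_group[[g]]
    # rebuild the group's score matrix from patterns is not possible; compute
    # saturated moments from the raw subset instead
    Yg <- score_matrix(data, obs)[data$group == lev[g], , drop = FALSE]
    sat <- saturated_moments(Yg)
    loglik_from_stats(st, sat$mu, sat$sigma)
  }, numeric(1)))
  list(loglik = -opt$objective, loglik_sat = ll_sat,
       estimates = stats::setNames(opt$par, comb_labels),
       n_free = k, df = length(lev) * length(obs) * (length(obs) + 3) / 2 - k,
       n = sum(ns), groups = lev, converged = opt$convergence == 0)
}

#' Default group-freed parameter set for the invariance test
#'
#' The dynamic parameters of the bivariate LCS model: self-feedbacks,
#' couplings, change intercepts, change residual variances, the
#' contemporaneous and within-domain cross-wave change covariances, and the
#' wave-1 cross-domain covariance — 13 labels for the default mutualism
#' specification.
#'
#' @param spec a mutualism-family [model_spec()].
#' @param design the [study_design()] used to build it.
#' @return Character vector of labels present in the spec.
#' @export
default_multigroup_free <- function(spec, design = study_design()) {
  d1 <- design$domains[1]; d2 <- design$domains[2]
  cand <- c(paste0("beta_", c(d1, d2)),
            paste0("gamma_", d1, "_", d2), paste0("gamma_", d2, "_", d1),
            paste0("alpha_", d1, "_t2"), paste0("alpha_", d1, "_t3"),
            paste0("alpha_", d1), paste0("alpha_", d2),
            paste0("zeta_", c(d1, d2)),
            "cov_change_contemp",
            paste0("cov_d_", c(d1, d2)),
            paste0("cov_", d1, "_", d2, "_t1"))
  intersect(cand, free_params(spec)$label)
}

#' Multigroup invariance test
#'
#' Compares the all-parameters-equal multigroup model against a model in
#' which a configurable set of parameters is free per group, via a
#' likelihood-ratio test. The equal model's likelihood coincides with the
#' single-group fit.
#'
#' @param data an \code{lcs_data} with a grouping factor (or supply
#'   \code{group}).
#' @param spec the [model_spec()] under test.
#' @param group optional grouping factor overriding \code{data$group}.
#' @param free_labels parameters freed across groups; defaults to
#'   [default_multigroup_free()].
#' @param design design used for the default freed set.
#' @return List with \code{delta_chisq}, \code{delta_df}, \code{p} and both
#'   multigroup fits.
#' @export
run_multigroup_invariance <- function(data, spec, group = NULL,
                                      free_labels = NULL,
                                      design = study_design()) {
  if (!is.null(group)) data$group <- as.factor(group)
  if (is.null(data$group)) stop("no grouping variable available")
  if (is.null(free_labels)) free_labels <- default_multigroup_free(spec, design)
  equal_fit <- fit_model(spec, data, se = FALSE)
  start <- equal_fit$estimates
  mg_equal <- fit_multigroup(spec, data, character(), start = start)
  mg_free <- fit_multigroup(spec, data, free_labels, start = start)
  delta <- max(2 * (mg_free$loglik - mg_equal$loglik), 0)
  ddf <- mg_free$n_free - mg_equal$n_free
  list(delta_chisq = delta, delta_df = ddf,
       p = stats::pchisq(delta, ddf, lower.tail = FALSE),
       freed = free_labels, equal = mg_equal, free = mg_free)
}

# --- alternative specifications -------------------------------------------

#' Robustness analyses: parallel-process and RI-CLPM alternatives
#'
#' Fits the cross-domain-only parallel-process model; tests each cross-domain
#' path by a constrained refit and 1-df likelihood-ratio test; contrasts the
#' cross-domain-only variant with the within-domain-freed (Matthew-effect)
#' variant by a 2-df LRT and by AIC/BIC; and fits the random-intercept
#' cross-lagged panel model, reporting the signs of its cross-lagged paths.
#'
#' @param data an \code{lcs_data} dataset.
#' @param design a [study_design()].
#' @return An object of class \code{alternative_specs_result}.
#' @export
run_alternative_specs <- function(data, design = study_design()) {
  d1 <- design$domains[1]; d2 <- design$domains[2]
  pp_spec <- build_parallel_process(design, cross_domain_only = TRUE)
  pp_fit <- fit_model(pp_spec, data)
  cross_labels <- c(paste0("b_i", d1, "_s", d2), paste0("b_i", d2, "_s", d1))
  path_tests <- lapply(cross_labels, function(lb) {
    restricted <- edit_constraint(pp_spec, "fix", lb, value = 0)
    rfit <- fit_model(restricted, data, se = FALSE)
    lrt <- likelihood_ratio_test(rfit, pp_fit)
    c(list(label = lb, estimate = unname(pp_fit$estimates[lb]),
           se = unname(pp_fit$se[lb]),
           std = pp_fit$standardized$std[pp_fit$standardized$label == lb][1]),
      lrt)
  })
  names(path_tests) <- cross_labels
  within_fit <- fit_model(build_parallel_process(design, cross_domain_only = FALSE),
                          data, se = FALSE)
  matthew_lrt <- likelihood_ratio_test(pp_fit, within_fit)
  ic_pp <- fit_indices(pp_fit); ic_w <- fit_indices(within_fit)
  ri_fit <- fit_model(build_riclpm(design), data)
  cl_labels <- c(paste0("c_", d1, "_", d2), paste0("c_", d2, "_", d1))
  cross_lagged <- data.frame(
    label = cl_labels,
    estimate = unname(ri_fit$estimates[cl_labels]),
    se = unname(ri_fit$se[cl_labels]),
    positive = unname(ri_fit$estimates[cl_labels] > 0)
  )
  structure(list(
    parallel_fit = pp_fit, parallel_indices = ic_pp,
    cross_path_tests = path_tests,
    within_domain_fit = within_fit,
    matthew_lrt = matthew_lrt,
    delta_aic = ic_w$aic - ic_pp$aic, delta_bic = ic_w$bic - ic_pp$bic,
    riclpm_fit = ri_fit, riclpm_cross_lagged = cross_lagged
  ), class = "alternative_specs_result")
}

#' @export
print.alternative_specs_result <- function(x, ...) {
  cat("Parallel-process model (cross-domain only):\n")
  print(x$parallel_indices)
  cat("\nCross-domain path tests (fix-to-zero LRTs):\n")
  for (t in x$cross_path_tests) {
    cat(sprintf("  %s: b = %.3f (SE %.3f), std = %.2f; chisq(%d) = %.3f, p = %.4g\n",
                t$label, t$estimate, t$se, t$std, t$delta_df, t$delta_chisq, t$p))
  }
  cat(sprintf("\nWithin-domain (Matthew) contrast: chisq(%d) = %.3f, p = %.3f; ",
              x$matthew_lrt$delta_df, x$matthew_lrt$delta_chisq, x$matthew_lrt$p))
  cat(sprintf("delta-AIC = %.1f, delta-BIC = %.1f (positive favours cross-domain only)\n",
              x$delta_aic, x$delta_bic))
  cat("\nRI-CLPM cross-lagged paths:\n")
  print(x$riclpm_cross_lagged, row.names = FALSE)
  invisible(x)
}

# --- cross-sample comparison -----------------------------------------------

#' Published adolescent-sample (NSPN) standardized estimates
#'
#' Standardized parameter estimates for the mutualism LCS model reported in
#' the original adolescent sample (ages 14-25), used as the reference when
#' testing the prediction that couplings are stronger and self-feedbacks
#' weaker in younger children. Standard errors were not printed and are
#' \code{NA}; supply them explicitly for z tests.
#'
#' @return Data frame with parameter, label, reference beta, reference SE and
#'   the predicted magnitude direction in a younger sample.
#' @export
nspn_reference <- function() {
  data.frame(
    parameter = c("self-feedback reasoning", "self-feedback vocabulary",
                  "coupling reasoning->vocabulary change",
                  "coupling vocabulary->reasoning change",
                  "contemporaneous change residual correlation"),
    label = c("beta_mat", "beta_voc", "gamma_mat_voc", "gamma_voc_mat",
              "cov_change_contemp"),
    beta_ref = c(-0.602, -0.362, 0.155, 0.203, 0.1003),
    se_ref = NA_real_,
    predicted = c("weaker", "weaker", "stronger", "stronger", "stronger"),
    stringsAsFactors = FALSE
  )
}

#' Compare fitted standardized parameters with a reference sample
#'
#' For each reference parameter, extracts the standardized estimate(s) of the
#' matching label from the fit (one per wave where the raw parameter is
#' equated), forms the two-sample z statistic from the supplied standard
#' errors, and flags whether the magnitude comparison matches the predicted
#' direction. Rows without usable standard errors are reported as not
#' testable. Standardized standard errors are approximated by scaling the raw
#' standard error with the raw-to-standardized ratio.
#'
#' @param fit an \code{lcs_fit} of a mutualism-family model.
#' @param reference data frame as returned by [nspn_reference()]; fill
#'   \code{se_ref} to enable z tests.
#' @param fisher use the Fisher-transformed z variant.
#' @return Data frame with one row per parameter location.
#' @export
compare_to_reference_sample <- function(fit, reference = nspn_reference(),
                                        fisher = FALSE) {
  std <- fit$standardized
  rows <- list()
  for (i in seq_len(nrow(reference))) {
    ref <- reference[i, ]
    hits <- std[std$label == ref$label & std$matrix != "mean", , drop = FALSE]
    hits <- hits[!duplicated(hits$location), , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      raw <- fit$estimates[[ref$label]]
      se_raw <- fit$se[[ref$label]]
      se_std <- if (!is.na(se_raw) && is.finite(raw) && raw != 0) {
        abs(se_raw * hits$std[j] / raw)
      } else NA_real_
      testable <- !is.na(se_std) && !is.na(ref$se_ref) && se_std > 0 &&
        ref$se_ref > 0
      z <- if (testable) {
        cross_sample_z(hits$std[j], se_std, ref$beta_ref, ref$se_ref,
                       fisher = fisher)
      } else NA_real_
      match_dir <- if (is.na(ref$predicted)) NA else {
        if (ref$predicted == "stronger") abs(hits$std[j]) > abs(ref$beta_ref)
        else abs(hits$std[j]) < abs(ref$beta_ref)
      }
      rows[[length(rows) + 1]] <- data.frame(
        parameter = ref$parameter, location = hits$location[j],
        beta_current = hits$std[j], se_current = se_std,
        beta_reference = ref$beta_ref, se_reference = ref$se_ref,
        z = z, testable = testable,
        predicted = ref$predicted, matches_prediction = match_dir,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate the full observed-data analysis from a deposited CSV
#'
#' Runs the complete pipeline on a wide-format score table: three-model
#' comparison, the investment-versus-mutualism likelihood-ratio test,
#' alternative specifications, and (when a grouping column is mapped) the
#' multigroup invariance test. The deposited data are not bundled with the
#' package; download them and pass the local path.
#'
#' @param path CSV file of wide-format scores.
#' @param column_map see [read_wide_csv()].
#' @param design a [study_design()]; supply reliabilities/variances there to
#'   apply the single-indicator reliability adjustment.
#' @param group_col optional grouping column (e.g. gender).
#' @param id_col optional identifier column.
#' @return List with the dataset, the comparison, the alternatives report and
#'   (optionally) the multigroup test.
#' @export
replicate_study <- function(path, column_map, design = study_design(),
                            group_col = NULL, id_col = NULL) {
  data <- read_wide_csv(path, column_map, group_col = group_col,
                        id_col = id_col)
  comparison <- run_three_model_comparison(data, design)
  alternatives <- run_alternative_specs(data, design)
  multigroup <- if (!is.null(data$group)) {
    run_multigroup_invariance(data, build_mutualism_lcs(design),
                              design = design)
  } else NULL
  list(data = data, comparison = comparison, alternatives = alternatives,
       multigroup = multigroup)
}
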