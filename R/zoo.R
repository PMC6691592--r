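#' Describe the longitudinal study design
#'
#' Captures the fixed layout shared by all model builders: three measurement
#' occasions, two cognitive domains (by convention the first is the
#' crystallized/vocabulary-like domain and the second the fluid/reasoning
#' domain), optional per-domain-per-wave internal consistencies and sample
#' variances for the single-indicator reliability adjustment, and the growth
#' codes used by the parallel-process model.
#'
#' @param n_waves number of occasions (3 supported).
#' @param domains character vector of two domain labels.
#' @param reliabilities optional domains x waves matrix of internal
#'   consistencies in (0, 1].
#' @param variances optional domains x waves matrix of sample variances,
#'   required when \code{reliabilities} is supplied.
#' @param slope_loadings per-wave growth codes, strictly increasing.
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(n_waves = 3, domains = c("voc", "mat"),
                         reliabilities = NULL, variances = NULL,
                         slope_loadings = c(0, 1, 2)) {
  stopifnot(length(domains) == 2)
  if (any(diff(slope_loadings) <= 0)) {
    stop("slope_loadings must be strictly increasing")
  }
  if (!is.null(reliabilities)) {
    reliabilities <- as.matrix(reliabilities)
    if (any(reliabilities <= 0 | reliabilities > 1)) {
      stop("reliabilities must lie in (0, 1]")
    }
    if (is.null(variances)) {
      stop("variances are required to turn reliabilities into fixed residuals")
    }
    variances <- as.matrix(variances)
    stopifnot(all(dim(reliabilities) == c(2, n_waves)),
              all(dim(variances) == c(2, n_waves)))
  }
  structure(list(n_waves = n_waves, domains = domains,
                 reliabilities = reliabilities, variances = variances,
                 slope_loadings = slope_loadings),
            class = "study_design")
}

#' Fixed residual variance for a single-indicator latent true score
#'
#' Single indicators cannot estimate their own measurement residual; the
#' residual variance is instead fixed from the scale's internal consistency:
#' \eqn{S^2 (1 - R_{xx})}.
#'
#' @param s2 sample variance of the indicator.
#' @param rxx internal-consistency reliability in (0, 1].
#' @return The fixed residual variance.
#' @export
reliability_residual_variance <- function(s2, rxx) {
  if (s2 <= 0) stop("sample variance must be positive")
  if (rxx <= 0 || rxx > 1) stop("reliability must lie in (0, 1]")
  s2 * (1 - rxx)
}

check_design <- function(design) {
  if (!inherits(design, "study_design")) stop("design must be a study_design")
  if (design$n_waves != 3) {
    stop("only the 3-wave design is supported; generalizing the wave count ",
         "is a documented extension point")
  }
}

# Shared plumbing: either the observed scores are the model nodes, or (with a
# reliability adjustment) each observed score loads with a fixed unit loading
# on a latent true score whose indicator residual is fixed at S^2(1 - Rxx).
lcs_scaffold <- function(design) {
  d1 <- design$domains[1]; d2 <- design$domains[2]
  waves <- seq_len(design$n_waves)
  observed <- canonical_names(design$domains, design$n_waves)
  use_rel <- !is.null(design$reliabilities)
  node <- function(d, k) if (use_rel) paste0("l_", d, "_t", k) else paste0(d, "_t", k)
  list(d1 = d1, d2 = d2, waves = waves, observed = observed,
       use_rel = use_rel, node = node)
}

add_reliability_layer <- function(spec, design, sc) {
  for (di in 1:2) {
    d <- design$domains[di]
    for (k in sc$waves) {
      obs <- paste0(d, "_t", k)
      spec <- add_path(spec, sc$node(d, k), obs,
                       label = paste0("load_", obs), value = 1, free = FALSE)
      resid <- reliability_residual_variance(design$variances[di, k],
                                             design$reliabilities[di, k])
      spec <- add_cov(spec, obs, obs, label = paste0("theta_", obs),
                      value = resid, free = FALSE)
      spec <- add_mean(spec, obs, label = paste0("int_", obs),
                       value = 0, free = FALSE)
    }
  }
  spec
}

#' Bivariate mutualism latent change score model
#'
#' Three-wave bivariate LCS model in which each domain's latent change
#' \eqn{\Delta Y_t = \alpha_Y + \beta_Y Y_{t-1} + \gamma_{X \to Y} X_{t-1} +
#' \zeta_{Y,t}} receives free cross-domain couplings in both directions.
#' Self-feedback, couplings and change residual variances carry cross-wave
#' equality constraints; contemporaneous change residual covariances are
#' equated across waves while the cross-wave change covariances are free.
#' By default the first domain's (vocabulary) change intercept is freed
#' across occasions.
#'
#' When the design carries reliabilities, observed scores become single
#' indicators of latent true scores with residuals fixed at
#' \eqn{S^2(1 - R_{xx})}; the dynamic structure then lives on the true
#' scores and the model degrees of freedom are unchanged.
#'
#' @param design a [study_design()].
#' @param free_vocab_intercept free the first domain's change intercept per
#'   occasion (default) instead of equating it across waves.
#' @return A [model_spec()] with df = 8 for the 3-wave, 2-domain design.
#' @export
build_mutualism_lcs <- function(design = study_design(),
                                free_vocab_intercept = TRUE) {
  check_design(design)
  sc <- lcs_scaffold(design)
  d1 <- sc$d1; d2 <- sc$d2
  changes <- as.vector(outer(c(d1, d2), 2:3,
                             function(d, k) paste0("d_", d, "_t", k)))
  latent <- changes
  if (sc$use_rel) {
    latent <- c(latent, as.vector(outer(c(d1, d2), sc$waves,
                                        function(d, k) paste0("l_", d, "_t", k))))
  }
  spec <- model_spec(observed = sc$observed, latent = latent)
  if (sc$use_rel) spec <- add_reliability_layer(spec, design, sc)

  v_start <- if (!is.null(design$variances)) design$variances[, 1] else c(10, 10)
  for (di in 1:2) {
    d <- design$domains[di]
    oth <- design$domains[3 - di]
    for (k in 2:3) {
      dch <- paste0("d_", d, "_t", k)
      # composition links: Y_t = Y_{t-1} + dY_t
      spec <- add_path(spec, sc$node(d, k - 1), sc$node(d, k),
                       label = paste0("comp_", d, "_t", k), value = 1, free = FALSE)
      spec <- add_path(spec, dch, sc$node(d, k),
                       label = paste0("def_", dch), value = 1, free = FALSE)
      # dynamics: self-feedback and coupling, equated across waves
      spec <- add_path(spec, sc$node(d, k - 1), dch,
                       label = paste0("beta_", d), value = 0, free = TRUE)
      spec <- add_path(spec, sc$node(oth, k - 1), dch,
                       label = paste0("gamma_", oth, "_", d), value = 0, free = TRUE)
      # downstream level variables are deterministic compositions
      spec <- add_cov(spec, sc$node(d, k), sc$node(d, k),
                      label = paste0("res_", sc$node(d, k)), value = 0, free = FALSE)
      spec <- add_mean(spec, sc$node(d, k),
                       label = paste0("int_", sc$node(d, k)), value = 0, free = FALSE)
      # change residual variance, equated across waves
      spec <- add_cov(spec, dch, dch, label = paste0("zeta_", d),
                      value = max(v_start[di] * 0.2, 1), free = TRUE)
    }
    # wave-1 level: free variance and mean
    spec <- add_cov(spec, sc$node(d, 1), sc$node(d, 1),
                    label = paste0("var_", d, "_t1"), value = v_start[di],
                    free = TRUE)
    spec <- add_mean(spec, sc$node(d, 1), label = paste0("mu_", d, "_t1"),
                     value = 0, free = TRUE)
  }
  spec <- add_cov(spec, sc$node(d1, 1), sc$node(d2, 1),
                  label = paste0("cov_", d1, "_", d2, "_t1"),
                  value = 0.3 * sqrt(prod(v_start)), free = TRUE)
  # change-score covariances: contemporaneous equated, cross-wave free
  spec <- add_cov(spec, paste0("d_", d1, "_t2"), paste0("d_", d2, "_t2"),
                  label = "cov_change_contemp", value = 0, free = TRUE)
  spec <- add_cov(spec, paste0("d_", d1, "_t3"), paste0("d_", d2, "_t3"),
                  label = "cov_change_contemp", value = 0, free = TRUE)
  spec <- add_cov(spec, paste0("d_", d1, "_t2"), paste0("d_", d1, "_t3"),
                  label = paste0("cov_d_", d1), value = 0, free = TRUE)
  spec <- add_cov(spec, paste0("d_", d2, "_t2"), paste0("d_", d2, "_t3"),
                  label = paste0("cov_d_", d2), value = 0, free = TRUE)
  spec <- add_cov(spec, paste0("d_", d1, "_t2"), paste0("d_", d2, "_t3"),
                  label = paste0("cov_d_", d1, "2_", d2, "3"), value = 0, free = TRUE)
  spec <- add_cov(spec, paste0("d_", d2, "_t2"), paste0("d_", d1, "_t3"),
                  label = paste0("cov_d_", d2, "2_", d1, "3"), value = 0, free = TRUE)
  # change intercepts
  if (free_vocab_intercept) {
    spec <- add_mean(spec, paste0("d_", d1, "_t2"),
                     label = paste0("alpha_", d1, "_t2"), value = 0, free = TRUE)
    spec <- add_mean(spec, paste0("d_", d1, "_t3"),
                     label = paste0("alpha_", d1, "_t3"), value = 0, free = TRUE)
  } else {
    spec <- add_mean(spec, paste0("d_", d1, "_t2"),
                     label = paste0("alpha_", d1), value = 0, free = TRUE)
    spec <- add_mean(spec, paste0("d_", d1, "_t3"),
                     label = paste0("alpha_", d1), value = 0, free = TRUE)
  }
  spec <- add_mean(spec, paste0("d_", d2, "_t2"), label = paste0("alpha_", d2),
                   value = 0, free = TRUE)
  spec <- add_mean(spec, paste0("d_", d2, "_t3"), label = paste0("alpha_", d2),
                   value = 0, free = TRUE)
  spec
}

#' Investment-theory latent change score model
#'
#' Identical to [build_mutualism_lcs()] except that only one cross-domain
#' coupling direction is free; the other is fixed to zero. The default frees
#' the fluid-to-crystallized direction (second domain's level driving the
#' first domain's change), the classical investment operationalization; the
#' direction is exposed because substantive applications differ.
#'
#' @inheritParams build_mutualism_lcs
#' @param direction which coupling remains free.
#' @return A [model_spec()] with exactly one fewer free parameter than the
#'   mutualism model.
#' @export
build_investment_lcs <- function(design = study_design(),
                                 free_vocab_intercept = TRUE,
                                 direction = c("reasoning_to_vocabulary",
                                               "vocabulary_to_reasoning")) {
  direction <- match.arg(direction)
  spec <- build_mutualism_lcs(design, free_vocab_intercept)
  d1 <- design$domains[1]; d2 <- design$domains[2]
  drop_label <- if (direction == "reasoning_to_vocabulary") {
    paste0("gamma_", d1, "_", d2)   # fix vocabulary -> reasoning change
  } else {
    paste0("gamma_", d2, "_", d1)
  }
  edit_constraint(spec, "fix", drop_label, value = 0)
}

#' Common-factor (g-factor) latent change score model
#'
#' One latent general factor per wave loads on both domain scores, with
#' measurement invariance imposed: loadings, indicator intercepts and
#' indicator residual variances are equated across occasions. Development is
#' a univariate LCS on the factor:
#' \eqn{\Delta G_t = \alpha_g + \beta_g G_{t-1} + \zeta_t}, with the change
#' residuals free to covary across waves. The factor scale is set by a unit
#' loading on the first domain and a fixed zero factor mean at wave 1.
#'
#' @param design a [study_design()]. The reliability adjustment does not
#'   apply here: the two indicators per occasion identify free measurement
#'   residuals.
#' @return A [model_spec()] with 10 free parameters (df = 17).
#' @export
build_gfactor_lcs <- function(design = study_design()) {
  check_design(design)
  d1 <- design$domains[1]; d2 <- design$domains[2]
  observed <- canonical_names(design$domains, design$n_waves)
  latent <- c(paste0("g_t", 1:3), paste0("d_g_t", 2:3))
  spec <- model_spec(observed = observed, latent = latent)
  v_start <- if (!is.null(design$variances)) design$variances[, 1] else c(10, 10)
  for (k in 1:3) {
    g <- paste0("g_t", k)
    spec <- add_path(spec, g, paste0(d1, "_t", k),
                     label = paste0("load_", d1, "_t", k), value = 1, free = FALSE)
    spec <- add_path(spec, g, paste0(d2, "_t", k),
                     label = paste0("lambda_", d2), value = 0.8, free = TRUE)
    spec <- add_cov(spec, paste0(d1, "_t", k), paste0(d1, "_t", k),
                    label = paste0("theta_", d1), value = v_start[1] * 0.5,
                    free = TRUE)
    spec <- add_cov(spec, paste0(d2, "_t", k), paste0(d2, "_t", k),
                    label = paste0("theta_", d2), value = v_start[2] * 0.5,
                    free = TRUE)
    spec <- add_mean(spec, paste0(d1, "_t", k), label = paste0("tau_", d1),
                     value = 0, free = TRUE)
    spec <- add_mean(spec, paste0(d2, "_t", k), label = paste0("tau_", d2),
                     value = 0, free = TRUE)
  }
  spec <- add_cov(spec, "g_t1", "g_t1", label = "var_g_t1",
                  value = v_start[1] * 0.5, free = TRUE)
  spec <- add_mean(spec, "g_t1", label = "mu_g_t1", value = 0, free = FALSE)
  for (k in 2:3) {
    g <- paste0("g_t", k); gp <- paste0("g_t", k - 1); dg <- paste0("d_g_t", k)
    spec <- add_path(spec, gp, g, label = paste0("comp_g_t", k),
                     value = 1, free = FALSE)
    spec <- add_path(spec, dg, g, label = paste0("def_", dg),
                     value = 1, free = FALSE)
    spec <- add_path(spec, gp, dg, label = "beta_g", value = 0, free = TRUE)
    spec <- add_cov(spec, g, g, label = paste0("res_g_t", k),
                    value = 0, free = FALSE)
    spec <- add_mean(spec, g, label = paste0("int_g_t", k),
                     value = 0, free = FALSE)
    spec <- add_cov(spec, dg, dg, label = "zeta_g",
                    value = v_start[1] * 0.1, free = TRUE)
    spec <- add_mean(spec, dg, label = "alpha_g", value = 0, free = TRUE)
  }
  spec <- add_cov(spec, "d_g_t2", "d_g_t3", label = "cov_dg",
                  value = 0, free = TRUE)
  spec
}

#' Parallel-process (bivariate latent growth) model
#'
#' Intercept and linear-slope factors per domain with fixed loadings (unit
#' for intercepts, the design's growth codes 0, 1, 2 for slopes). Each
#' domain's slope is regressed on the other domain's intercept: baseline
#' ability in one domain driving the rate of gain in the other, the
#' growth-model rendering of mutualism. Within-domain intercept-to-slope
#' paths (the Matthew-effect contrast) are fixed to zero unless
#' \code{cross_domain_only = FALSE}. Indicator residual variances are free
#' per variable.
#'
#' @param design a [study_design()].
#' @param cross_domain_only fix within-domain intercept-to-slope paths to
#'   zero (default).
#' @return A [model_spec()]; df = 9 for the cross-domain-only variant, 7 when
#'   the two within-domain paths are freed.
#' @export
build_parallel_process <- function(design = study_design(),
                                   cross_domain_only = TRUE) {
  check_design(design)
  if (design$n_waves < 3) stop("growth model under-identified with < 3 waves")
  d1 <- design$domains[1]; d2 <- design$domains[2]
  observed <- canonical_names(design$domains, design$n_waves)
  latent <- c(paste0("i_", c(d1, d2)), paste0("s_", c(d1, d2)))
  spec <- model_spec(observed = observed, latent = latent)
  v_start <- if (!is.null(design$variances)) design$variances[, 1] else c(10, 10)
  for (di in 1:2) {
    d <- design$domains[di]
    for (k in 1:3) {
      obs <- paste0(d, "_t", k)
      spec <- add_path(spec, paste0("i_", d), obs,
                       label = paste0("li_", obs), value = 1, free = FALSE)
      spec <- add_path(spec, paste0("s_", d), obs,
                       label = paste0("ls_", obs),
                       value = design$slope_loadings[k], free = FALSE)
      spec <- add_cov(spec, obs, obs, label = paste0("res_", obs),
                      value = v_start[di] * 0.2, free = TRUE)
      spec <- add_mean(spec, obs, label = paste0("int_", obs),
                       value = 0, free = FALSE)
    }
    spec <- add_cov(spec, paste0("i_", d), paste0("i_", d),
                    label = paste0("var_i_", d), value = v_start[di] * 0.8,
                    free = TRUE)
    spec <- add_cov(spec, paste0("s_", d), paste0("s_", d),
                    label = paste0("var_s_", d), value = max(v_start[di] * 0.05, 0.5),
                    free = TRUE)
    spec <- add_mean(spec, paste0("i_", d), label = paste0("mu_i_", d),
                     value = 0, free = TRUE)
    spec <- add_mean(spec, paste0("s_", d), label = paste0("alpha_s_", d),
                     value = 0, free = TRUE)
  }
  spec <- add_cov(spec, paste0("i_", d1), paste0("i_", d2),
                  label = "cov_i", value = 0.3 * sqrt(prod(v_start)), free = TRUE)
  spec <- add_cov(spec, paste0("s_", d1), paste0("s_", d2),
                  label = "cov_s", value = 0, free = TRUE)
  # cross-domain driving paths: other domain's intercept -> this slope
  spec <- add_path(spec, paste0("i_", d2), paste0("s_", d1),
                   label = paste0("b_i", d2, "_s", d1), value = 0, free = TRUE)
  spec <- add_path(spec, paste0("i_", d1), paste0("s_", d2),
                   label = paste0("b_i", d1, "_s", d2), value = 0, free = TRUE)
  # within-domain (Matthew effect) paths
  spec <- add_path(spec, paste0("i_", d1), paste0("s_", d1),
                   label = paste0("b_i", d1, "_s", d1), value = 0,
                   free = !cross_domain_only)
  spec <- add_path(spec, paste0("i_", d2), paste0("s_", d2),
                   label = paste0("b_i", d2, "_s", d2), value = 0,
                   free = !cross_domain_only)
  spec
}

#' Random-intercept cross-lagged panel model (three waves)
#'
#' Separates stable between-person differences (one random intercept per
#' domain with unit loadings on all waves) from within-person dynamics:
#' lag-1 autoregressive and cross-lagged paths among the within-person
#' components, equated across the two lags by default, with wave-specific
#' within-person residual covariances. Observed means are free per variable.
#'
#' @param design a [study_design()].
#' @return A [model_spec()] with 20 free parameters (df = 7).
#' @export
build_riclpm <- function(design = study_design()) {
  check_design(design)
  d1 <- design$domains[1]; d2 <- design$domains[2]
  observed <- canonical_names(design$domains, design$n_waves)
  latent <- c(paste0("ri_", c(d1, d2)),
              as.vector(outer(c(d1, d2), 1:3, function(d, k) paste0("w_", d, "_t", k))))
  spec <- model_spec(observed = observed, latent = latent)
  v_start <- if (!is.null(design$variances)) design$variances[, 1] else c(10, 10)
  for (di in 1:2) {
    d <- design$domains[di]
    for (k in 1:3) {
      obs <- paste0(d, "_t", k); w <- paste0("w_", d, "_t", k)
      spec <- add_path(spec, paste0("ri_", d), obs,
                       label = paste0("lri_", obs), value = 1, free = FALSE)
      spec <- add_path(spec, w, obs, label = paste0("lw_", obs),
                       value = 1, free = FALSE)
      spec <- add_cov(spec, obs, obs, label = paste0("res_", obs),
                      value = 0, free = FALSE)
      spec <- add_mean(spec, obs, label = paste0("mu_", obs),
                       value = 0, free = TRUE)
    }
    spec <- add_cov(spec, paste0("ri_", d), paste0("ri_", d),
                    label = paste0("var_ri_", d), value = v_start[di] * 0.5,
                    free = TRUE)
    spec <- add_cov(spec, paste0("w_", d, "_t1"), paste0("w_", d, "_t1"),
                    label = paste0("var_w_", d, "_t1"), value = v_start[di] * 0.5,
                    free = TRUE)
    oth <- design$domains[3 - di]
    for (k in 2:3) {
      w <- paste0("w_", d, "_t", k)
      spec <- add_path(spec, paste0("w_", d, "_t", k - 1), w,
                       label = paste0("a_", d), value = 0.2, free = TRUE)
      spec <- add_path(spec, paste0("w_", oth, "_t", k - 1), w,
                       label = paste0("c_", oth, "_", d), value = 0, free = TRUE)
      spec <- add_cov(spec, w, w, label = paste0("u_", d),
                      value = v_start[di] * 0.3, free = TRUE)
    }
  }
  spec <- add_cov(spec, paste0("ri_", d1), paste0("ri_", d2),
                  label = "cov_ri", value = 0.2 * sqrt(prod(v_start)), free = TRUE)
  spec <- add_cov(spec, paste0("w_", d1, "_t1"), paste0("w_", d2, "_t1"),
                  label = "cov_w_t1", value = 0, free = TRUE)
  for (k in 2:3) {
    spec <- add_cov(spec, paste0("w_", d1, "_t", k), paste0("w_", d2, "_t", k),
                    label = paste0("cov_w_t", k), value = 0, free = TRUE)
  }
  spec
}
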