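#' Fit a latent-variable model by full-information maximum likelihood
#'
#' Maximizes the casewise (FIML) log-likelihood over the distinct free labels
#' of the specification, honouring equality constraints. Standard errors come
#' from the inverse observed information (numerical Hessian at the optimum).
#' The saturated log-likelihood (unrestricted mean and covariance, estimated
#' by FIML) and the independence-model log-likelihood (free means and
#' variances, zero covariances) are stored for fit indices.
#'
#' Starting values: free mean parameters are initialized by a least-squares
#' match of the implied to the observed means (the mean structure is linear
#' in mean parameters at fixed paths); other parameters start at the values
#' carried by the specification. On non-convergence the optimizer is
#' restarted from jittered starts with a fixed jitter seed.
#'
#' @param spec a [model_spec()].
#' @param data an \code{lcs_data} object or numeric matrix with the spec's
#'   observed variables as columns.
#' @param se compute standard errors (numerical Hessian); disable to speed up
#'   large simulation loops that only need likelihoods.
#' @param restarts maximum jittered restarts after a failed first attempt.
#' @param control passed to [stats::nlminb()].
#' @return An object of class \code{lcs_fit} with estimates, standard errors,
#'   log-likelihoods, degrees of freedom, convergence flag, any Heywood-case
#'   warning, and the standardized solution.
#' @export
fit_model <- function(spec, data, se = TRUE, restarts = 5,
                      control = list(iter.max = 1000, eval.max = 4000)) {
  cs <- compile_spec(spec)
  Y <- score_matrix(data, cs$vars[cs$obs_idx])
  n_empty <- sum(rowSums(!is.na(Y)) == 0)
  if (n_empty > 0) {
    warning(n_empty, " person(s) with all scores missing excluded from the likelihood")
  }
  st <- pattern_stats(Y)
  n <- attr(st, "n")
  p <- attr(st, "p")
  k <- cs$k
  df <- p * (p + 3) / 2 - k
  if (df < 0) stop("model not identified: more free parameters (", k,
                   ") than observed moments (", p * (p + 3) / 2, ")")
  if (n < k) stop("identification error: fewer persons (", n,
                  ") than free parameters (", k, ")")

  start <- mean_start_values(cs, st)
  neg2 <- function(theta) {
    mom <- tryCatch(
      moments_from_matrices(cs, fill_matrices(cs, theta)),
      error = function(e) NULL
    )
    if (is.null(mom)) return(1e10)
    ll <- loglik_from_stats(st, mom$mu, mom$sigma)
    if (is.na(ll) || !is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  attempts <- restarts + 1L
  for (r in seq_len(attempts)) {
    th0 <- if (r == 1) start else jitter_start(start, r)
    opt <- tryCatch(stats::nlminb(th0, neg2, control = control),
                    error = function(e) NULL)
    if (is.null(opt)) next
    ok <- opt$convergence == 0 && opt$objective < 1e9
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && opt$objective < best$opt$objective)) {
      best <- list(opt = opt, ok = ok)
    }
    if (ok) break
  }
  if (is.null(best)) stop("optimizer failed on every start")
  theta <- best$opt$par
  ll <- -best$opt$objective
  converged <- best$ok

  est <- stats::setNames(theta, cs$labels)
  se_vec <- stats::setNames(rep(NA_real_, k), cs$labels)
  vc <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(theta, neg2), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        dg <- diag(vc)
        se_vec[] <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
        dimnames(vc) <- list(cs$labels, cs$labels)
      }
    }
  }

  heywood <- any(est[names(est) %in% cs$variance_labels] < 0)
  if (heywood) warning("Heywood case: negative variance estimate")

  sat <- saturated_moments(Y)
  ll_sat <- loglik_from_stats(st, sat$mu, sat$sigma)
  ll_indep <- independence_loglik(Y)

  fit <- structure(list(
    spec = spec, estimates = est, se = se_vec, vcov = vc,
    loglik = ll, loglik_sat = ll_sat, loglik_indep = ll_indep,
    n = n, p = p, n_free = k, df = df,
    converged = converged, heywood = heywood,
    sample_mu = sat$mu, sample_sigma = sat$sigma
  ), class = "lcs_fit")
  fit$standardized <- standardize(fit)
  fit
}

# Least-squares starting values for free mean parameters: at the starting
# paths the implied observed means are linear in the mean parameters, so a
# regression of observed means on that design gives exact-scale starts.
mean_start_values <- function(cs, st) {
  start <- cs$start
  mean_pars <- unique(cs$m_par)
  if (!length(mean_pars)) return(start)
  th0 <- start
  th0[mean_pars] <- 0
  mats <- fill_matrices(cs, th0)
  B <- tryCatch(solve(diag(cs$q) - mats$A), error = function(e) NULL)
  if (is.null(B)) return(start)
  base_mu <- drop(B %*% mats$m)[cs$obs_idx]
  X <- matrix(0, length(cs$obs_idx), length(mean_pars))
  for (j in seq_along(mean_pars)) {
    e <- numeric(cs$q)
    e[cs$m_pos[cs$m_par == mean_pars[j]]] <- 1
    X[, j] <- drop(B %*% e)[cs$obs_idx]
  }
  # observed grand means weighted by pattern sizes
  p <- attr(st, "p"); n <- attr(st, "n")
  sums <- numeric(p); counts <- numeric(p)
  for (pt in st) {
    sums[pt$idx] <- sums[pt$idx] + pt$n * pt$xbar
    counts[pt$idx] <- counts[pt$idx] + pt$n
  }
  ybar <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  beta <- tryCatch(stats::lsfit(X, ybar - base_mu, intercept = FALSE)$coefficients,
                   error = function(e) NULL)
  if (!is.null(beta) && all(is.finite(beta))) start[mean_pars] <- beta
  start
}

jitter_start <- function(start, r) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(48151 + r)
  start * (1 + 0.3 * stats::rnorm(length(start))) +
    0.1 * stats::rnorm(length(start))
}

#' @export
print.lcs_fit <- function(x, ...) {
  cat("FIML fit:", x$n_free, "free parameters, df =", x$df,
      ", n =", x$n, "\n")
  cat(sprintf("  logLik = %.3f (saturated %.3f), converged: %s%s\n",
              x$loglik, x$loglik_sat, x$converged,
              if (x$heywood) ", Heywood case" else ""))
  est <- data.frame(estimate = round(x$estimates, 4), se = round(x$se, 4))
  print(est)
  invisible(x)
}

#' @export
logLik.lcs_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n,
            class = "logLik")
}

#' @export
coef.lcs_fit <- function(object, ...) object$estimates

#' @export
vcov.lcs_fit <- function(object, ...) object$vcov

#' Standardized solution of a fitted (or valued) model
#'
#' Paths are rescaled by the ratio of model-implied standard deviations of
#' the source and target variables, covariances become correlations, and
#' variances are expressed as proportions of the corresponding implied
#' variance. Because equality constraints hold on the raw scale, an equated
#' raw parameter can have different standardized values at different waves;
#' the solution is therefore reported per parameter location.
#'
#' @param fit an \code{lcs_fit}, or a [model_spec()] combined with
#'   \code{values}.
#' @param values named values for every free label when \code{fit} is a
#'   specification.
#' @return Data frame with one row per parameter location: matrix, location,
#'   label, raw estimate, standardized estimate.
#' @export
standardize <- function(fit, values = NULL) {
  if (inherits(fit, "lcs_fit")) {
    spec <- fit$spec
    values <- fit$estimates
  } else {
    spec <- fit
  }
  cs <- compile_spec(spec)
  theta <- resolve_values(cs, values)
  mom <- moments_from_matrices(cs, fill_matrices(cs, theta), full = TRUE)
  v <- diag(mom$sigma)
  sdev <- ifelse(v > 0, sqrt(pmax(v, 0)), NA_real_)
  names(sdev) <- cs$vars
  if (any(v <= 0)) {
    warning("zero or negative implied variance for: ",
            paste(cs$vars[v <= 0], collapse = ", "),
            "; standardized values undefined there")
  }
  val_of <- function(tab_row) {
    if (tab_row$free) unname(values[tab_row$label]) else tab_row$value
  }
  rows <- list()
  for (i in seq_len(nrow(spec$paths))) {
    r <- spec$paths[i, ]
    b <- val_of(r)
    rows[[length(rows) + 1]] <- data.frame(
      matrix = "path", location = paste0(r$to, "~", r$from), label = r$label,
      estimate = b, std = b * sdev[r$from] / sdev[r$to],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(spec$covs))) {
    r <- spec$covs[i, ]
    b <- val_of(r)
    std <- if (r$v1 == r$v2) b / v[match(r$v1, cs$vars)] else
      b / (sdev[r$v1] * sdev[r$v2])
    rows[[length(rows) + 1]] <- data.frame(
      matrix = "cov", location = paste0(r$v1, "~~", r$v2), label = r$label,
      estimate = b, std = unname(std), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(spec$means))) {
    r <- spec$means[i, ]
    b <- val_of(r)
    rows[[length(rows) + 1]] <- data.frame(
      matrix = "mean", location = paste0(r$variable, "~1"), label = r$label,
      estimate = b, std = b / unname(sdev[r$variable]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wald z test of a single free parameter against zero
#'
#' @param fit an \code{lcs_fit} with standard errors.
#' @param label a free-parameter label.
#' @return List with \code{estimate}, \code{se}, \code{z} and two-sided
#'   \code{p}.
#' @export
wald_test <- function(fit, label) {
  if (!label %in% names(fit$estimates)) {
    stop("unknown label: ", label)
  }
  est <- fit$estimates[[label]]
  s <- fit$se[[label]]
  z <- est / s
  list(estimate = est, se = s, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}
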