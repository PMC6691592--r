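# Internal compiled representation of a model_spec: pre-resolved matrix
# indices so the likelihood can rebuild A, S, m from a parameter vector
# without touching data frames.

compile_spec <- function(spec) {
  vars <- spec$variables$name
  q <- length(vars)
  obs_idx <- which(!spec$variables$latent)
  fp <- free_params(spec)
  par_index <- stats::setNames(seq_len(nrow(fp)), fp$label)

  A0 <- matrix(0, q, q, dimnames = list(vars, vars))
  S0 <- matrix(0, q, q, dimnames = list(vars, vars))
  m0 <- stats::setNames(numeric(q), vars)

  # single-index positions for free entries, parallel to parameter indices
  a_pos <- integer(0); a_par <- integer(0)
  for (i in seq_len(nrow(spec$paths))) {
    r <- spec$paths[i, ]
    ri <- match(r$to, vars); ci <- match(r$from, vars)
    if (r$free) {
      a_pos <- c(a_pos, (ci - 1L) * q + ri)
      a_par <- c(a_par, par_index[[r$label]])
    } else A0[ri, ci] <- r$value
  }
  s_pos <- integer(0); s_par <- integer(0)
  for (i in seq_len(nrow(spec$covs))) {
    r <- spec$covs[i, ]
    ri <- match(r$v1, vars); ci <- match(r$v2, vars)
    if (r$free) {
      s_pos <- c(s_pos, (ci - 1L) * q + ri, (ri - 1L) * q + ci)
      s_par <- c(s_par, rep(par_index[[r$label]], 2L))
    } else {
      S0[ri, ci] <- r$value; S0[ci, ri] <- r$value
    }
  }
  m_pos <- integer(0); m_par <- integer(0)
  for (i in seq_len(nrow(spec$means))) {
    r <- spec$means[i, ]
    ri <- match(r$variable, vars)
    if (r$free) {
      m_pos <- c(m_pos, ri)
      m_par <- c(m_par, par_index[[r$label]])
    } else m0[ri] <- r$value
  }
  # variance rows (v1 == v2) among free S entries, for Heywood checks
  var_labels <- unique(spec$covs$label[spec$covs$free &
                                         spec$covs$v1 == spec$covs$v2])
  list(q = q, vars = vars, obs_idx = obs_idx,
       labels = fp$label, start = fp$value, k = nrow(fp),
       A0 = A0, S0 = S0, m0 = m0,
       a_pos = a_pos, a_par = a_par,
       s_pos = s_pos, s_par = s_par,
       m_pos = m_pos, m_par = m_par,
       variance_labels = var_labels)
}

fill_matrices <- function(cs, theta) {
  A <- cs$A0; S <- cs$S0; m <- cs$m0
  if (length(cs$a_pos)) A[cs$a_pos] <- theta[cs$a_par]
  if (length(cs$s_pos)) S[cs$s_pos] <- theta[cs$s_par]
  if (length(cs$m_pos)) m[cs$m_pos] <- theta[cs$m_par]
  list(A = A, S = S, m = m)
}

moments_from_matrices <- function(cs, mats, full = FALSE) {
  IA <- diag(cs$q) - mats$A
  B <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(B)) {
    stop("structural cycle / singular (I - A); check composition links among: ",
         paste(cs$vars, collapse = ", "))
  }
  Sigma_all <- B %*% mats$S %*% t(B)
  mu_all <- drop(B %*% mats$m)
  if (full) {
    list(mu = mu_all, sigma = Sigma_all)
  } else {
    list(mu = mu_all[cs$obs_idx],
         sigma = Sigma_all[cs$obs_idx, cs$obs_idx, drop = FALSE])
  }
}

#' Model-implied moments of the observed variables
#'
#' Computes the mean vector and covariance matrix the model implies for the
#' observed variables under the reticular algebra
#' \eqn{\Sigma = F (I-A)^{-1} S (I-A)^{-T} F^T} and
#' \eqn{\mu = F (I-A)^{-1} m}, where \eqn{A} collects directed paths, \eqn{S}
#' variances/covariances, \eqn{m} means, and \eqn{F} selects observed
#' variables.
#'
#' @param spec a [model_spec()].
#' @param values named numeric vector giving a value for every free label;
#'   defaults to the starting values.
#' @return List with \code{mu} (named mean vector) and \code{sigma}
#'   (covariance matrix) over the observed variables.
#' @export
implied_moments <- function(spec, values = NULL) {
  cs <- compile_spec(spec)
  theta <- resolve_values(cs, values)
  moments_from_matrices(cs, fill_matrices(cs, theta))
}

resolve_values <- function(cs, values) {
  if (is.null(values)) return(cs$start)
  miss <- setdiff(cs$labels, names(values))
  if (length(miss)) {
    stop("no value supplied for free label(s): ", paste(miss, collapse = ", "))
  }
  unname(values[cs$labels])
}

# --- FIML machinery -------------------------------------------------------

# Collapse an n x p score matrix into per-missingness-pattern sufficient
# statistics: per pattern the observed-column index set, person count, mean
# vector and ML (divisor n_k) scatter matrix. The FIML log-likelihood then
# costs O(patterns * p^3) per evaluation, independent of n.
pattern_stats <- function(Y) {
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0) stop("no persons with any observed scores")
  mask <- !is.na(Y)
  key <- apply(mask, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(mask[rows[1], ])
    Z <- Y[rows, idx, drop = FALSE]
    nk <- nrow(Z)
    xbar <- colMeans(Z)
    Zc <- sweep(Z, 2, xbar)
    list(idx = idx, n = nk, xbar = xbar, S = crossprod(Zc) / nk)
  })
  attr(out, "n") <- nrow(Y)
  attr(out, "p") <- ncol(Y)
  out
}

loglik_from_stats <- function(stats_list, mu, sigma) {
  ll <- 0
  for (pt in stats_list) {
    so <- sigma[pt$idx, pt$idx, drop = FALSE]
    ch <- tryCatch(chol(so), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    logdet <- 2 * sum(log(diag(ch)))
    sinv <- chol2inv(ch)
    d <- pt$xbar - mu[pt$idx]
    pk <- length(pt$idx)
    ll <- ll - pt$n / 2 *
      (pk * log(2 * pi) + logdet + sum(sinv * pt$S) + drop(d %*% sinv %*% d))
  }
  ll
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Sums, over persons, the multivariate-normal log-density of each person's
#' observed sub-vector under the corresponding sub-moments of the
#' model-implied mean and covariance. Persons with no observed scores
#' contribute zero.
#'
#' @param spec a [model_spec()].
#' @param values named numeric vector of free-parameter values.
#' @param data an \code{lcs_data} object or numeric matrix whose columns match
#'   the spec's observed variables.
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(spec, values, data) {
  cs <- compile_spec(spec)
  Y <- score_matrix(data, cs$vars[cs$obs_idx])
  st <- pattern_stats(Y)
  mom <- implied_moments(spec, values)
  ll <- loglik_from_stats(st, mom$mu, mom$sigma)
  if (is.na(ll)) {
    stop("implied covariance not positive definite on an observed sub-pattern")
  }
  ll
}

score_matrix <- function(data, obs_names) {
  Y <- if (inherits(data, "lcs_data")) data$scores else as.matrix(data)
  missing_cols <- setdiff(obs_names, colnames(Y))
  if (length(missing_cols)) {
    stop("data lack observed variable(s): ", paste(missing_cols, collapse = ", "))
  }
  Y[, obs_names, drop = FALSE]
}

# Saturated-model (unrestricted mu, Sigma) FIML estimates. Closed form for
# complete data; EM iterations otherwise.
saturated_moments <- function(Y, max_iter = 1000L, tol = 1e-10) {
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (!anyNA(Y)) {
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    return(list(mu = mu, sigma = crossprod(Yc) / n))
  }
  # EM for multivariate normal with ignorable missingness
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, p)
  mask <- !is.na(Y)
  key <- apply(mask, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), key)
  st <- pattern_stats(Y)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    for (rows in groups) {
      o <- which(mask[rows[1], ]); m <- which(!mask[rows[1], ])
      Yo <- Y[rows, o, drop = FALSE]
      if (length(m) == 0) {
        sum_x <- sum_x + colSums(Yo)
        sum_xx <- sum_xx + crossprod(Yo)
        next
      }
      Soo <- sigma[o, o, drop = FALSE]
      ch <- chol(Soo)
      W <- chol2inv(ch)
      reg <- sigma[m, o, drop = FALSE] %*% W           # m x o
      cond_cov <- sigma[m, m, drop = FALSE] -
        reg %*% sigma[o, m, drop = FALSE]              # m x m
      dev <- sweep(Yo, 2, mu[o])                       # n_k x o
      Em <- matrix(mu[m], nrow(Yo), length(m), byrow = TRUE) +
        dev %*% t(reg)                                 # n_k x m
      X <- matrix(0, nrow(Yo), p)
      X[, o] <- Yo; X[, m] <- Em
      sum_x <- sum_x + colSums(X)
      cp <- crossprod(X)
      cp[m, m] <- cp[m, m] + nrow(Yo) * cond_cov
      sum_xx <- sum_xx + cp
    }
    mu <- sum_x / n
    sigma <- sum_xx / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- loglik_from_stats(st, mu, sigma)
    if (is.na(ll)) break
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma)
}

# Independence-model (free variances and means, zero covariances) FIML
# log-likelihood; separates per variable so the MLE is closed form even under
# missingness.
independence_loglik <- function(Y) {
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[!is.na(Y[, j]), j]
    nj <- length(y)
    if (nj == 0) next
    vj <- mean((y - mean(y))^2)
    ll <- ll - nj / 2 * (log(2 * pi) + log(vj) + 1)
  }
  ll
}
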