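# Layout in the form the compiled core consumes (0-based free ids).
cpp_layout <- function(spec) {
  lay <- param_layout(spec)
  list(mat = as.integer(lay$mat),
       mrow = as.integer(lay$mrow),
       mcol = as.integer(lay$mcol),
       free_id = as.integer(ifelse(is.na(lay$free_id), -1L, lay$free_id - 1L)),
       trans = as.integer(lay$trans),
       fixed_value = as.numeric(ifelse(is.na(lay$fixed_value), 0,
                                       lay$fixed_value)),
       I = spec$n_indicators, K = spec$n_raters, L = spec$n_occasions,
       ref = spec$reference_rater)
}

#' Full-information maximum likelihood log-likelihood
#'
#' Sum over dyads of the multivariate-normal log-density of each dyad's
#' observed subvector under the corresponding sub-mean and sub-covariance
#' of [implied_moments()].  Rows are grouped by missingness pattern and
#' reduced to sufficient statistics, so the value is exact and the cost is
#' independent of the number of dyads.  A non-positive-definite observed
#' sub-block yields a large finite penalty (-1e12), never `NaN`.
#'
#' @param params An [lst_parameters()] object.
#' @param spec The matching [lst_spec()].
#' @param data An [lst_panel()].
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(params, spec, data) {
  stopifnot(inherits(data, "lst_panel"))
  theta <- flatten_parameters(params, spec)
  pats <- pattern_stats(data$values)
  cpp_fiml_loglik(theta, cpp_layout(spec), unname(pats))
}

# Internal: loglik/gradient on the flat unconstrained vector.
fiml_loglik_theta <- function(theta, spec, pats, layout = cpp_layout(spec)) {
  cpp_fiml_loglik(theta, layout, unname(pats))
}

#' Saturated multivariate-normal fit under missing data
#'
#' ML estimate of an unstructured mean vector and covariance matrix by EM
#' for the multivariate normal.  With complete data this is the closed-form
#' sample mean and divide-by-n covariance (one EM step).  The saturated
#' log-likelihood anchors the chi-square statistic.
#'
#' @param data An [lst_panel()].
#' @param max_iter Iteration cap for EM.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return List with `mu`, `sigma`, `loglik`, `converged`, `iterations`.
#' @export
fit_saturated <- function(data, max_iter = 2000L, tol = 1e-10) {
  stopifnot(inherits(data, "lst_panel"))
  Y <- data$values
  n <- nrow(Y); P <- ncol(Y)
  pats <- pattern_stats(Y)
  complete <- length(pats) == 1L && length(pats[[1L]]$idx) == P
  if (complete) {
    mu <- colMeans(Y)
    sigma <- crossprod(sweep(Y, 2L, mu)) / n
    ll <- cpp_mvn_pattern_loglik(mu, sigma, unname(pats))
    return(list(mu = mu, sigma = sigma, loglik = ll, converged = TRUE,
                iterations = 0L))
  }
  # EM initialization from per-column observed moments
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE) * (1 - 1e-3)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, P)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  # per-pattern raw row data needed for conditional means
  for (it in seq_len(max_iter)) {
    sum_x <- numeric(P)
    sum_xx <- matrix(0, P, P)
    for (p in pats) {
      oi <- p$idx + 1L
      mi <- setdiff(seq_len(P), oi)
      X <- Y[p$rows, oi, drop = FALSE]
      if (length(mi) == 0L) {
        sum_x <- sum_x + colSums(X)
        sum_xx <- sum_xx + crossprod(X)
        next
      }
      Soo <- sigma[oi, oi, drop = FALSE]
      Smo <- sigma[mi, oi, drop = FALSE]
      B <- Smo %*% solve(Soo)
      # conditional means of the missing block given the observed block
      Xm <- matrix(mu[mi], nrow(X), length(mi), byrow = TRUE) +
        sweep(X, 2L, mu[oi]) %*% t(B)
      C <- sigma[mi, mi, drop = FALSE] - B %*% t(Smo)
      full <- matrix(0, nrow(X), P)
      full[, oi] <- X
      full[, mi] <- Xm
      sum_x <- sum_x + colSums(full)
      cp <- crossprod(full)
      cp[mi, mi] <- cp[mi, mi] + nrow(X) * C
      sum_xx <- sum_xx + cp
    }
    mu_new <- sum_x / n
    sigma_new <- sum_xx / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    mu <- mu_new; sigma <- sigma_new
    ll <- cpp_mvn_pattern_loglik(mu, sigma, unname(pats))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("saturated EM did not converge within ", max_iter, " iterations")
  names(mu) <- colnames(Y)
  dimnames(sigma) <- list(colnames(Y), colnames(Y))
  list(mu = mu, sigma = sigma, loglik = ll_old, converged = converged,
       iterations = it)
}

#' Independence (baseline) model fit
#'
#' Free means and variances, all covariances zero.  Under a diagonal
#' covariance the likelihood factorizes over columns, so the ML solution is
#' the per-column observed mean and divide-by-n variance even with missing
#' data.  Anchors the CFI.
#'
#' @param data An [lst_panel()].
#' @return List with `mu`, `sigma` (diagonal), `loglik`, `df` (baseline
#'   model df).
#' @export
fit_baseline <- function(data) {
  stopifnot(inherits(data, "lst_panel"))
  Y <- data$values
  P <- ncol(Y)
  nobs <- colSums(!is.na(Y))
  if (any(nobs == 0L)) stop("column with no observed values", call. = FALSE)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- colSums(sweep(Y, 2L, mu)^2, na.rm = TRUE) / nobs
  ll <- sum(-0.5 * (nobs * log(2 * pi) + nobs * log(v) + nobs))
  list(mu = mu, sigma = diag(v, P), loglik = ll,
       df = (P * (P + 3L)) %/% 2L - 2L * P)
}

#' Chi-square, CFI and RMSEA from log-likelihoods
#'
#' `chi2 = 2 (ll_sat - ll_mod)`;
#' `cfi = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, tiny)`;
#' `rmsea = sqrt(max(chi2 - df, 0) / (df (n - 1)))` with `n` the retained
#' dyad count.  With `df = 0` the RMSEA is undefined and reported `NA`.
#'
#' @param loglik_model,loglik_saturated,loglik_baseline Log-likelihoods.
#' @param df_model,df_baseline Degrees of freedom.
#' @param n Number of rows used.
#' @return List with `chi2`, `df`, `cfi`, `rmsea`, `chi2_baseline`,
#'   `df_baseline`.
#' @export
fit_indices <- function(loglik_model, loglik_saturated, loglik_baseline,
                        df_model, df_baseline, n) {
  stopifnot(n >= 2)
  chi2 <- 2 * (loglik_saturated - loglik_model)
  chi2_b <- 2 * (loglik_saturated - loglik_baseline)
  num <- max(chi2 - df_model, 0)
  den <- max(chi2_b - df_baseline, chi2 - df_model, .Machine$double.eps)
  cfi <- 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (df_model > 0)
    sqrt(max(chi2 - df_model, 0) / (df_model * (n - 1))) else NA_real_
  list(chi2 = chi2, df = df_model, cfi = cfi, rmsea = rmsea,
       chi2_baseline = chi2_b, df_baseline = df_baseline)
}
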