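#' Covariance matrix of an AR(1) occasion-factor process
#'
#' The occasion factors follow `O_1 = SR_1`, `O_l = beta_l O_{l-1} + SR_l`
#' with independent zero-mean state residuals, so
#' `Var(O_l) = beta_l^2 Var(O_{l-1}) + Var(SR_l)` and
#' `Cov(O_l, O_m) = prod(beta_{m+1..l}) Var(O_m)` for `l > m`.  The same
#' operator serves the rater-specific process `OPS_l`.
#'
#' @param betas Autoregressive weights, length `L - 1`.
#' @param sr_vars State residual variances, length `L`, all `>= 0`.
#' @return `L x L` positive semidefinite covariance matrix.
#' @examples
#' ar_factor_cov(c(0.5, 0.5, 0.5), c(1, 1, 1, 1))
#' @export
ar_factor_cov <- function(betas, sr_vars) {
  L <- length(sr_vars)
  stopifnot(length(betas) == L - 1L, all(sr_vars >= 0))
  v <- numeric(L)
  v[1] <- sr_vars[1]
  for (l in seq_len(L)[-1]) v[l] <- betas[l - 1L]^2 * v[l - 1L] + sr_vars[l]
  S <- diag(v, nrow = L)
  for (l in seq_len(L)) for (m in seq_len(L)) {
    if (l > m) {
      S[l, m] <- prod(betas[m:(l - 1L)]) * v[m]
      S[m, l] <- S[l, m]
    }
  }
  S
}

#' Model-implied moment structure
#'
#' Assembles the mean vector, observed covariance matrix, latent-factor
#' covariance and loading matrix implied by a parameter set:
#' `sigma = Lambda Phi Lambda' + diag(var_E)`, `mu = intercepts` (all
#' factor means are zero).  Latent factors are stacked as
#' `T_1..T_I[, TPS_1..TPS_I], O_1..O_L[, OPS_1..OPS_L]`; observed variables
#' are ordered rater-major, occasion next, indicator last.  Trait factors,
#' the occasion process and the rater-specific process are mutually
#' uncorrelated (residual definitions of the rater-specific factors).
#'
#' @param params An [lst_parameters()] object.
#' @param spec The matching [lst_spec()].
#' @return A list of class `lst_moments` with elements `mu`, `sigma`,
#'   `latent_cov`, `loading_matrix` and `error_var`.
#' @export
implied_moments <- function(params, spec) {
  stopifnot(inherits(params, "lst_parameters"), inherits(spec, "lst_spec"))
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  ref <- spec$reference_rater
  P <- n_observed(spec); Q <- n_latent(spec)

  Phi <- matrix(0, Q, Q)
  M <- I * kk_of(spec)
  Phi[seq_len(M), seq_len(M)] <- params$phi_T
  oi <- vapply(seq_len(L), function(l) latent_index_O(spec, l), 1L)
  Phi[oi, oi] <- ar_factor_cov(params$beta_O, params$var_SR)
  if (K == 2L) {
    pi_ <- vapply(seq_len(L), function(l) latent_index_OPS(spec, l), 1L)
    Phi[pi_, pi_] <- ar_factor_cov(params$beta_OPS, params$var_SRPS)
  }

  Lam <- matrix(0, P, Q)
  mu <- numeric(P)
  errv <- numeric(P)
  nonref <- if (K == 2L) setdiff(1:2, ref) else integer(0)
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I)) {
    r <- obs_index(spec, i, k, l)
    mu[r] <- params$a[i, k, l]
    errv[r] <- params$var_E[i, k, l]
    Lam[r, latent_index_T(spec, i)] <- params$lambda_T[i, k, l]
    Lam[r, latent_index_O(spec, l)] <- params$lambda_O[i, k, l]
    if (K == 2L && k == nonref) {
      Lam[r, latent_index_TPS(spec, i)] <- params$lambda_TPS[i, l]
      Lam[r, latent_index_OPS(spec, l)] <- params$lambda_OPS[i, l]
    }
  }
  sigma <- Lam %*% Phi %*% t(Lam)
  diag(sigma) <- diag(sigma) + errv
  sigma <- (sigma + t(sigma)) / 2
  nm <- obs_names(spec)
  ln <- latent_names(spec)
  dimnames(sigma) <- list(nm, nm)
  names(mu) <- nm; names(errv) <- nm
  dimnames(Lam) <- list(nm, ln)
  dimnames(Phi) <- list(ln, ln)
  structure(list(mu = mu, sigma = sigma, latent_cov = Phi,
                 loading_matrix = Lam, error_var = errv),
            class = "lst_moments")
}

#' @export
print.lst_moments <- function(x, ...) {
  cat("Model-implied moments over", length(x$mu), "observed variables\n")
  cat("  mean range:", signif(range(x$mu), 4), "\n")
  cat("  variance range:", signif(range(diag(x$sigma)), 4), "\n")
  invisible(x)
}

#' Export a moment structure as labeled CSV files
#'
#' Writes `<stem>_mean.csv`, `<stem>_cov.csv` and `<stem>_latent_cov.csv`
#' for inspection and for external cross-checks.
#'
#' @param moments An `lst_moments` object.
#' @param stem Output path stem.
#' @return The paths written, invisibly.
#' @export
write_moments <- function(moments, stem) {
  paths <- paste0(stem, c("_mean.csv", "_cov.csv", "_latent_cov.csv"))
  utils::write.csv(data.frame(variable = names(moments$mu),
                              mean = moments$mu, row.names = NULL),
                   paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(moments$sigma), paths[2], row.names = TRUE)
  utils::write.csv(as.data.frame(moments$latent_cov), paths[3],
                   row.names = TRUE)
  invisible(paths)
}
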