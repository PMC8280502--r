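# Random parameter sets conforming to a spec (ties and fixed slots
# respected).  Loadings and autoregressive weights are positive by
# construction; trait blocks are positive definite.
random_params <- function(spec, seed) {
  set.seed(seed)
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  ref <- spec$reference_rater
  nonref <- if (K == 2L) setdiff(1:2, ref) else integer(0)

  a <- array(round(runif(I * K * L, 3, 5), 3), c(I, K, L))
  lambda_T <- array(runif(I * K * L, 0.6, 1.3), c(I, K, L))
  lambda_T[, ref, 1] <- 1
  lambda_O <- array(0, c(I, K, L))
  for (k in seq_len(K)) {
    lo <- runif(I, 0.4, 1.3)
    if (k == ref) lo[1] <- 1
    for (l in seq_len(L)) lambda_O[, k, l] <- lo
  }
  M <- I * (if (K == 2L) 2L else 1L)
  rand_pd <- function(m) {
    B <- matrix(runif(m * m, -0.3, 0.5), m)
    B %*% t(B) + diag(runif(m, 0.4, 1), m)
  }
  phi <- matrix(0, M, M)
  phi[1:I, 1:I] <- rand_pd(I)
  beta_O <- rep(runif(1, 0.1, 0.7), L - 1)
  var_SR <- rep(runif(1, 0.3, 1), L)
  var_E <- array(runif(I * K * L, 0.3, 0.8), c(I, K, L))
  args <- list(spec = spec, a = a, lambda_T = lambda_T,
               lambda_O = lambda_O, phi_T = phi, beta_O = beta_O,
               var_SR = var_SR, var_E = var_E)
  if (K == 2L) {
    phi[I + 1:I, I + 1:I] <- rand_pd(I)
    for (i in seq_len(I)) for (j in seq_len(I)) {
      if (i != j) phi[I + i, j] <- phi[j, I + i] <- runif(1, -0.05, 0.1)
    }
    args$phi_T <- phi
    lambda_TPS <- matrix(runif(I * L, 0.7, 1.2), I, L)
    lambda_TPS[, 1] <- 1
    lambda_OPS <- matrix(0, I, L)
    lo <- runif(I, 0.5, 1.2); lo[1] <- 1
    for (l in seq_len(L)) lambda_OPS[, l] <- lo
    args$lambda_TPS <- lambda_TPS
    args$lambda_OPS <- lambda_OPS
    args$beta_OPS <- rep(runif(1, 0.05, 0.5), L - 1)
    args$var_SRPS <- rep(runif(1, 0.2, 0.8), L)
  }
  do.call(lst_parameters, args)
}

# Single-rater parameter set on a reduced spec, sliced from the packaged
# example values.
small_single_params <- function(spec) {
  p1 <- example_parameters_single(lst_spec(3, 4, 1))
  L <- spec$n_occasions
  lst_parameters(spec,
                 a = p1$a[, 1, seq_len(L), drop = FALSE],
                 lambda_T = p1$lambda_T[, 1, seq_len(L), drop = FALSE],
                 lambda_O = p1$lambda_O[, 1, seq_len(L), drop = FALSE],
                 phi_T = p1$phi_T,
                 beta_O = p1$beta_O[seq_len(L - 1)],
                 var_SR = p1$var_SR[seq_len(L)],
                 var_E = p1$var_E[, 1, seq_len(L), drop = FALSE])
}

# Direct complete-data multivariate-normal log-likelihood, evaluated row
# by row without pattern grouping; independent check of the FIML value.
rowwise_mvn_loglik <- function(Y, mu, sigma) {
  ll <- 0
  for (r in seq_len(nrow(Y))) {
    obs <- !is.na(Y[r, ])
    d <- Y[r, obs] - mu[obs]
    S <- sigma[obs, obs, drop = FALSE]
    ll <- ll - 0.5 * (sum(obs) * log(2 * pi) +
                        determinant(S, logarithm = TRUE)$modulus +
                        drop(d %*% solve(S, d)))
  }
  as.numeric(ll)
}
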