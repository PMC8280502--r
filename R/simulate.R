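#' Missingness specification for simulated panels
#'
#' Missingness is applied at the rater-occasion block level: a participant
#' who skips a wave misses all indicators of that wave, which is how panel
#' attrition manifests.  Mechanisms: `"mcar_occasion"` draws each
#' rater-wave participation independently at the given rate (rater waves
#' independent); `"monotone"` uses one shared uniform per rater so a
#' participant who drops out stays out (requires non-increasing rates);
#' `"none"` generates complete data.  Cell-level MCAR is available via
#' `cell_rate`.
#'
#' @param mechanism One of `"mcar_occasion"`, `"monotone"`, `"none"`.
#' @param rates `K x L` matrix of participation proportions in `(0, 1]`
#'   (rows: raters, columns: occasions).
#' @param cell_rate Optional additional probability that any observed cell
#'   is kept (independent cell-level MCAR thinning); default 1.
#' @return An object of class `lst_missingness`.
#' @seealso [study_missingness()] for the default study-like profile.
#' @export
missingness_spec <- function(mechanism = c("mcar_occasion", "monotone",
                                           "none"),
                             rates = NULL, cell_rate = 1) {
  mechanism <- match.arg(mechanism)
  if (mechanism != "none") {
    rates <- as.matrix(rates)
    if (any(rates <= 0) || any(rates > 1))
      stop("participation rates must lie in (0, 1]", call. = FALSE)
    if (mechanism == "monotone" &&
        any(apply(rates, 1L, function(r) any(diff(r) > 1e-12))))
      stop("monotone dropout requires non-increasing rates within rater",
           call. = FALSE)
  }
  stopifnot(cell_rate > 0, cell_rate <= 1)
  structure(list(mechanism = mechanism, rates = rates,
                 cell_rate = cell_rate),
            class = "lst_missingness")
}

#' Study-like wave participation profile
#'
#' Participation rates matching a four-wave dyadic panel of n = 575 dyads
#' in which 558/463/428/429 target reports and 405/384/341/323 parent
#' reports were observed per wave.  Because the target counts are not
#' monotone, the default mechanism is wave-level MCAR at these rates.
#'
#' @param spec An [lst_spec()] with 4 occasions (rates are recycled or
#'   truncated for other lengths).
#' @return An `lst_missingness` object.
#' @export
study_missingness <- function(spec) {
  target <- c(558, 463, 428, 429) / 575
  parent <- c(405, 384, 341, 323) / 575
  L <- spec$n_occasions
  take <- function(x) x[pmin(seq_len(L), length(x))]
  rates <- rbind(take(target))
  if (spec$n_raters == 2L) {
    rates <- rbind(take(target), take(parent))
    if (spec$reference_rater == 2L) rates <- rates[2:1, , drop = FALSE]
  }
  missingness_spec("mcar_occasion", rates = rates)
}

# Independent sub-seeds per stage so adding missingness does not perturb
# the drawn responses.  Kept below 2^31 - 1.
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}

# Draw n rows from a zero-mean MVN with covariance S via eigendecomposition
# (tolerates positive semidefinite S).
rmvn0 <- function(n, S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- e$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance block is not positive semidefinite", call. = FALSE)
  ev[ev < 0] <- 0
  Z <- matrix(stats::rnorm(n * ncol(S)), n)
  Z %*% (t(e$vectors) * sqrt(ev))
}

#' Simulate a dyadic panel from a parameter set
#'
#' Generative recipe: first-occasion traits (and rater-specific traits)
#' jointly multivariate normal with the trait covariance block; state
#' residuals independent zero-mean normal; occasion factors built by the
#' AR(1) recursions `O_1 = SR_1`, `O_l = beta_l O_{l-1} + SR_l` (and the
#' rater-specific analogue); observed values = intercepts + loadings x
#' latents + normal errors; then wave-level missingness.  Reproducible
#' under `seed`, with separate sub-streams for latents, errors and the
#' mask.
#'
#' @param params An [lst_parameters()] object.
#' @param spec The matching [lst_spec()].
#' @param n Number of dyads (`n >= 1`).
#' @param missing An [lst_missingness()] spec; default none.
#' @param seed Integer seed.
#' @return An [lst_panel()].
#' @export
simulate_lst <- function(params, spec, n, missing = missingness_spec("none"),
                         seed = 1L) {
  stopifnot(inherits(params, "lst_parameters"), inherits(spec, "lst_spec"),
            n >= 1)
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  mom <- implied_moments(params, spec)

  # latent draws
  set.seed(sub_seed(seed, 1L))
  M <- I * kk_of(spec)
  ev <- eigen((params$phi_T + t(params$phi_T)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("trait covariance block (phi_T) is not positive semidefinite",
         call. = FALSE)
  TT <- rmvn0(n, params$phi_T)                       # n x M
  SR <- sapply(seq_len(L), function(l)
    stats::rnorm(n, 0, sqrt(params$var_SR[l])))
  SR <- matrix(SR, n, L)
  O <- matrix(0, n, L)
  O[, 1L] <- SR[, 1L]
  for (l in seq_len(L)[-1L])
    O[, l] <- params$beta_O[l - 1L] * O[, l - 1L] + SR[, l]
  eta <- cbind(TT, O)
  if (K == 2L) {
    SRPS <- matrix(sapply(seq_len(L), function(l)
      stats::rnorm(n, 0, sqrt(params$var_SRPS[l]))), n, L)
    OPS <- matrix(0, n, L)
    OPS[, 1L] <- SRPS[, 1L]
    for (l in seq_len(L)[-1L])
      OPS[, l] <- params$beta_OPS[l - 1L] * OPS[, l - 1L] + SRPS[, l]
    eta <- cbind(TT, O, OPS)
  }
  # reorder latent columns into the package stacking
  if (K == 2L) {
    # TT already holds T then TPS; stacking is T, TPS, O, OPS: matches
  }

  # errors
  set.seed(sub_seed(seed, 2L))
  P <- n_observed(spec)
  E <- matrix(stats::rnorm(n * P), n, P)
  E <- sweep(E, 2L, sqrt(mom$error_var), `*`)

  Y <- matrix(rep(mom$mu, each = n), n, P) +
    eta %*% t(mom$loading_matrix) + E
  colnames(Y) <- obs_names(spec)

  # missingness mask
  set.seed(sub_seed(seed, 3L))
  if (missing$mechanism != "none") {
    rates <- missing$rates
    stopifnot(nrow(rates) == K, ncol(rates) == L)
    for (k in seq_len(K)) {
      if (missing$mechanism == "mcar_occasion") {
        part <- matrix(stats::runif(n * L), n, L) <=
          matrix(rates[k, ], n, L, byrow = TRUE)
      } else {  # monotone: one shared uniform per dyad-rater
        u <- stats::runif(n)
        part <- outer(u, rates[k, ], `<=`)
      }
      for (l in seq_len(L)) {
        cols <- vapply(seq_len(I), function(i) obs_index(spec, i, k, l), 1L)
        Y[!part[, l], cols] <- NA_real_
      }
    }
  }
  if (missing$cell_rate < 1) {
    keep <- matrix(stats::runif(n * P) <= missing$cell_rate, n, P)
    Y[!keep] <- NA_real_
  }
  lst_panel(Y, spec, dyad_id = seq_len(n))
}

#' Deterministic two-rater example parameter set
#'
#' A fixed MR-LST-AR parameter set whose coefficient profile matches what
#' dyadic attachment panels typically show: high reliability (~0.7), high
#' predictability by the first-occasion trait with a small accumulating
#' situational component for the reference rater, a practically absent
#' accumulating component for the non-reference rater, and rater
#' specificity in the 0.8-0.9 range.  Useful as simulation truth for
#' parameter-recovery and calibration studies.
#'
#' @param spec A default two-rater [lst_spec()] (3 indicators, 4
#'   occasions); the single-rater margin [example_parameters_single()] is
#'   derived from the same values.
#' @return An [lst_parameters()] object.
#' @export
example_parameters <- function(spec = lst_spec(3, 4, 2)) {
  stopifnot(spec$n_raters == 2L)
  I <- spec$n_indicators
  stopifnot(I == 3L, spec$n_occasions <= 4L)
  if (spec$n_occasions < 4L) {
    full <- example_parameters(lst_spec(3, 4, 2,
                                        reference_rater = spec$reference_rater))
    L <- spec$n_occasions
    return(lst_parameters(spec,
      a = full$a[, , seq_len(L), drop = FALSE],
      lambda_T = full$lambda_T[, , seq_len(L), drop = FALSE],
      lambda_O = full$lambda_O[, , seq_len(L), drop = FALSE],
      phi_T = full$phi_T,
      beta_O = full$beta_O[seq_len(L - 1L)],
      var_SR = full$var_SR[seq_len(L)],
      var_E = full$var_E[, , seq_len(L), drop = FALSE],
      lambda_TPS = full$lambda_TPS[, seq_len(L), drop = FALSE],
      lambda_OPS = full$lambda_OPS[, seq_len(L), drop = FALSE],
      beta_OPS = full$beta_OPS[seq_len(L - 1L)],
      var_SRPS = full$var_SRPS[seq_len(L)]))
  }
  L <- spec$n_occasions
  ref <- spec$reference_rater
  nonref <- setdiff(1:2, ref)

  a <- array(0, c(I, 2L, L))
  a[, ref, ] <- c(4.5, 4.45, 4.05)
  a[, nonref, ] <- c(4.55, 4.5, 4.3)

  lambda_T <- array(1, c(I, 2L, L))
  lambda_T[, nonref, ] <- 0.35
  lambda_O <- array(0, c(I, 2L, L))
  lamO_ref <- c(1, 0.9, 0.55)
  lamO_non <- c(0.25, 0.22, 0.2)
  for (l in seq_len(L)) {
    lambda_O[, ref, l] <- lamO_ref
    lambda_O[, nonref, l] <- lamO_non
  }

  phi <- matrix(0, 2L * I, 2L * I)
  trait_sd <- sqrt(c(1.0, 0.9, 1.3))
  trait_cor <- matrix(c(1, 0.5, 0.55,
                        0.5, 1, 0.65,
                        0.55, 0.65, 1), 3L)
  phi[1:3, 1:3] <- outer(trait_sd, trait_sd) * trait_cor
  tps_sd <- sqrt(c(0.8, 0.7, 0.9))
  tps_cor <- matrix(c(1, 0.55, 0.6,
                      0.55, 1, 0.55,
                      0.6, 0.55, 1), 3L)
  phi[4:6, 4:6] <- outer(tps_sd, tps_sd) * tps_cor
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      phi[3L + i, j] <- 0.08
      phi[j, 3L + i] <- 0.08
    }
  }

  beta_O <- rep(0.3, L - 1L)
  var_SR <- rep(0.6, L)
  beta_OPS <- rep(0.05, L - 1L)
  var_SRPS <- rep(0.35, L)

  var_E <- array(0, c(I, 2L, L))
  var_E[, ref, ] <- c(0.65, 0.7, 0.55)
  var_E[, nonref, ] <- c(0.55, 0.5, 0.6)

  lambda_TPS <- matrix(1, I, L)
  for (l in 2:L) lambda_TPS[, l] <- c(1.0, 0.95, 1.05)
  lambda_TPS[, 1L] <- 1
  lambda_OPS <- matrix(rep(c(1, 0.9, 0.95), L), I, L)
  lambda_OPS[1L, ] <- 1

  lst_parameters(spec, a = a, lambda_T = lambda_T, lambda_O = lambda_O,
                 phi_T = phi, beta_O = beta_O, var_SR = var_SR,
                 var_E = var_E, lambda_TPS = lambda_TPS,
                 lambda_OPS = lambda_OPS, beta_OPS = beta_OPS,
                 var_SRPS = var_SRPS)
}

#' @rdname example_parameters
#' @export
example_parameters_single <- function(spec = lst_spec(3, 4, 1)) {
  stopifnot(spec$n_raters == 1L, spec$n_indicators == 3L,
            spec$n_occasions <= 4L)
  L <- spec$n_occasions
  full <- example_parameters(lst_spec(3, 4, 2))
  lst_parameters(spec,
                 a = full$a[, 1L, seq_len(L), drop = FALSE],
                 lambda_T = full$lambda_T[, 1L, seq_len(L), drop = FALSE],
                 lambda_O = full$lambda_O[, 1L, seq_len(L), drop = FALSE],
                 phi_T = full$phi_T[1:3, 1:3],
                 beta_O = full$beta_O[seq_len(L - 1L)],
                 var_SR = full$var_SR[seq_len(L)],
                 var_E = full$var_E[, 1L, seq_len(L), drop = FALSE])
}
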