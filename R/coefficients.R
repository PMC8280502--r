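# Variance components of one observed variable, split into the trait part
# (first-occasion traits, including the rater-specific trait for the
# non-reference rater), the carry-over part (autoregressive paths from the
# previous occasion) and the occasion part (current state residuals).
# trait + carry + occ equals the true (error-free) variance exactly.
variance_components <- function(params, spec, i, k, l) {
  stopifnot(i >= 1, i <= spec$n_indicators,
            k >= 1, k <= spec$n_raters,
            l >= 1, l <= spec$n_occasions)
  ref <- spec$reference_rater
  vO <- diag(ar_factor_cov(params$beta_O, params$var_SR))
  lamT <- params$lambda_T[i, k, l]
  lamO <- params$lambda_O[i, k, l]
  varT <- params$phi_T[i, i]
  trait <- lamT^2 * varT
  carry <- if (l > 1L) lamO^2 * params$beta_O[l - 1L]^2 * vO[l - 1L] else 0
  occ <- lamO^2 * params$var_SR[l]
  if (spec$n_raters == 2L && k != ref) {
    I <- spec$n_indicators
    vOPS <- diag(ar_factor_cov(params$beta_OPS, params$var_SRPS))
    lamTPS <- params$lambda_TPS[i, l]
    lamOPS <- params$lambda_OPS[i, l]
    varTPS <- params$phi_T[I + i, I + i]
    trait <- trait + lamTPS^2 * varTPS
    carry <- carry +
      if (l > 1L) lamOPS^2 * params$beta_OPS[l - 1L]^2 * vOPS[l - 1L] else 0
    occ <- occ + lamOPS^2 * params$var_SRPS[l]
  }
  varE <- params$var_E[i, k, l]
  list(trait = trait, carry = carry, occ = occ, varE = varE,
       varY = trait + carry + occ + varE, true = trait + carry + occ)
}

#' Reliability coefficient
#'
#' Proportion of an indicator's variance that is true (error-free)
#' variance: `1 - Var(E_ikl) / Var(Y_ikl)`.
#'
#' @param params An [lst_parameters()] object.
#' @param spec The matching [lst_spec()].
#' @param i,k,l Indicator, rater, occasion (1-based).
#' @return Scalar in `[0, 1]`, or `NA` when the total variance is zero.
#' @export
reliability <- function(params, spec, i, k = 1L, l = 1L) {
  vc <- variance_components(params, spec, i, k, l)
  if (vc$varY <= 0) return(NA_real_)
  1 - vc$varE / vc$varY
}

#' Occasion specificity coefficient
#'
#' Proportion of true variance due to the current state residual(s):
#' occasion-specific situational and person-situation interaction effects
#' not explained by first-occasion traits or carry-over.  For the
#' non-reference rater the numerator includes the rater-specific state
#' residual part.
#'
#' @inheritParams reliability
#' @return Scalar in `[0, 1]`, `NA` when the true variance is zero.
#' @export
occasion_specificity <- function(params, spec, i, k = 1L, l = 1L) {
  vc <- variance_components(params, spec, i, k, l)
  if (vc$true <= 0) return(NA_real_)
  vc$occ / vc$true
}

#' Time consistency, predictability and unpredictability by the
#' first-occasion trait
#'
#' `time_consistency()` is the proportion of true variance explained by
#' earlier occasions (first-occasion traits plus autoregressive
#' carry-over); it complements [occasion_specificity()] exactly.
#' `predictability_trait1()` is the trait part alone and
#' `unpredictability_trait1()` the accumulated-situational part;
#' they sum to the time consistency exactly.  All three are undefined at
#' occasion 1 and return `NA` there.
#'
#' @inheritParams reliability
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
time_consistency <- function(params, spec, i, k = 1L, l) {
  if (l <= 1L) return(NA_real_)
  vc <- variance_components(params, spec, i, k, l)
  if (vc$true <= 0) return(NA_real_)
  (vc$trait + vc$carry) / vc$true
}

#' @rdname time_consistency
#' @export
predictability_trait1 <- function(params, spec, i, k = 1L, l) {
  if (l <= 1L) return(NA_real_)
  vc <- variance_components(params, spec, i, k, l)
  if (vc$true <= 0) return(NA_real_)
  vc$trait / vc$true
}

#' @rdname time_consistency
#' @export
unpredictability_trait1 <- function(params, spec, i, k = 1L, l) {
  if (l <= 1L) return(NA_real_)
  vc <- variance_components(params, spec, i, k, l)
  if (vc$true <= 0) return(NA_real_)
  vc$carry / vc$true
}

# Latent weight vector of the error-free state S_ikl over the stacked
# latent factors.
state_weights <- function(params, spec, i, k, l) {
  w <- numeric(n_latent(spec))
  w[latent_index_T(spec, i)] <- params$lambda_T[i, k, l]
  w[latent_index_O(spec, l)] <- params$lambda_O[i, k, l]
  if (spec$n_raters == 2L && k != spec$reference_rater) {
    w[latent_index_TPS(spec, i)] <- params$lambda_TPS[i, l]
    w[latent_index_OPS(spec, l)] <- params$lambda_OPS[i, l]
  }
  w
}

#' Latent retest correlation of the states
#'
#' Measurement-error-free correlation between the latent state at occasion
#' 1 and the state at occasion `l` for the same indicator and rater,
#' computed from the latent-factor covariance.  For the reference rater
#' this equals the closed forms in which the numerator is
#' `lambda_T Var(T) + lambda_SR lambda_O (prod of betas) Var(SR_1)`.
#'
#' @inheritParams reliability
#' @return Scalar correlation, `NA` when a variance degenerates.
#' @export
state_retest_correlation <- function(params, spec, i, k = 1L, l) {
  if (l <= 1L) return(NA_real_)
  Phi <- implied_moments(params, spec)$latent_cov
  w1 <- state_weights(params, spec, i, k, 1L)
  wl <- state_weights(params, spec, i, k, l)
  v1 <- drop(w1 %*% Phi %*% w1)
  vl <- drop(wl %*% Phi %*% wl)
  if (v1 <= 0 || vl <= 0) return(NA_real_)
  drop(w1 %*% Phi %*% wl) / sqrt(v1 * vl)
}

# Closed-form retest correlation for the reference rater: the numerator is
# lambda_T_il Var(T_i) + lambda_SR_i1 lambda_O_il (prod beta_2..l) Var(SR_1),
# the denominator the geometric mean of the true variances.  Kept separate
# from the generic latent-covariance route so the two can be cross-checked.
state_retest_closed_form <- function(params, spec, i, l) {
  stopifnot(l > 1L)
  k <- spec$reference_rater
  vc1 <- variance_components(params, spec, i, k, 1L)
  vcl <- variance_components(params, spec, i, k, l)
  if (vc1$true <= 0 || vcl$true <= 0) return(NA_real_)
  num <- params$lambda_T[i, k, l] * params$phi_T[i, i] +
    params$lambda_O[i, k, 1L] * params$lambda_O[i, k, l] *
    prod(params$beta_O[seq_len(l - 1L)]) * params$var_SR[1L]
  num / sqrt(vc1$true * vcl$true)
}

check_nonref <- function(spec, k) {
  if (spec$n_raters != 2L)
    stop("rater-consistency coefficients need a two-rater model",
         call. = FALSE)
  if (k == spec$reference_rater)
    stop("rater-consistency coefficients are defined for the non-reference ",
         "rater only", call. = FALSE)
  invisible(TRUE)
}

# Shared and rater-specific variance pieces of a non-reference indicator.
rater_components <- function(params, spec, i, l) {
  k <- setdiff(1:2, spec$reference_rater)
  I <- spec$n_indicators
  vO <- diag(ar_factor_cov(params$beta_O, params$var_SR))
  vOPS <- diag(ar_factor_cov(params$beta_OPS, params$var_SRPS))
  lamT <- params$lambda_T[i, k, l]; lamO <- params$lambda_O[i, k, l]
  lamTPS <- params$lambda_TPS[i, l]; lamOPS <- params$lambda_OPS[i, l]
  list(
    shared_trait = lamT^2 * params$phi_T[i, i],
    specific_trait = lamTPS^2 * params$phi_T[I + i, I + i],
    shared_occ_total = lamO^2 * vO[l],
    specific_occ_total = lamOPS^2 * vOPS[l],
    shared_carry = if (l > 1L)
      lamO^2 * params$beta_O[l - 1L]^2 * vO[l - 1L] else 0,
    specific_carry = if (l > 1L)
      lamOPS^2 * params$beta_OPS[l - 1L]^2 * vOPS[l - 1L] else 0,
    shared_sr = lamO^2 * params$var_SR[l],
    specific_sr = lamOPS^2 * params$var_SRPS[l]
  )
}

#' Rater specificity and rater consistency
#'
#' `rater_specificity()` is the proportion of the non-reference rater's
#' true variance not shared with the reference rater (rater-specific trait
#' and occasion factors); `rater_consistency()` is its complement (shared
#' trait and occasion factors).  They sum to 1 exactly.  The square root of
#' the consistency is the error-free correlation between the two raters'
#' ratings.
#'
#' @param params An [lst_parameters()] object of a two-rater spec.
#' @param spec The matching [lst_spec()].
#' @param i,l Indicator and occasion.
#' @return Scalar in `[0, 1]`, `NA` when the true variance is zero.
#' @export
rater_specificity <- function(params, spec, i, l) {
  check_nonref(spec, setdiff(1:2, spec$reference_rater))
  rc <- rater_components(params, spec, i, l)
  tot <- rc$shared_trait + rc$specific_trait +
    rc$shared_occ_total + rc$specific_occ_total
  if (tot <= 0) return(NA_real_)
  (rc$specific_trait + rc$specific_occ_total) / tot
}

#' @rdname rater_specificity
#' @export
rater_consistency <- function(params, spec, i, l) {
  check_nonref(spec, setdiff(1:2, spec$reference_rater))
  rc <- rater_components(params, spec, i, l)
  tot <- rc$shared_trait + rc$specific_trait +
    rc$shared_occ_total + rc$specific_occ_total
  if (tot <= 0) return(NA_real_)
  (rc$shared_trait + rc$shared_occ_total) / tot
}

#' Rater-consistent predictability by the first-occasion trait
#'
#' Ratio of the shared (reference-rater) trait variance to the total
#' trait-level variance of the non-reference indicator.  The complement is
#' the rater-specific predictability `RSPred = 1 - RConPred`.  Reported
#' from occasion 2 on; returns `NA` at occasion 1.
#'
#' @inheritParams rater_specificity
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
rater_consistent_pred_trait1 <- function(params, spec, i, l) {
  check_nonref(spec, setdiff(1:2, spec$reference_rater))
  if (l <= 1L) return(NA_real_)
  rc <- rater_components(params, spec, i, l)
  den <- rc$shared_trait + rc$specific_trait
  if (den <= 0) return(NA_real_)
  rc$shared_trait / den
}

#' Rater-consistent time consistency
#'
#' Proportion of the time-consistent variance of the non-reference rater's
#' indicator (first-occasion traits plus carry-over) explained by the
#' reference rater's time-consistent components:
#' `(shared trait + shared carry-over) / (total trait + total carry-over)`.
#' Equals [rater_consistent_pred_trait1()] when both autoregressive weights
#' are zero.  Returns `NA` at occasion 1.
#'
#' @inheritParams rater_specificity
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
rater_consistent_time_consistency <- function(params, spec, i, l) {
  check_nonref(spec, setdiff(1:2, spec$reference_rater))
  if (l <= 1L) return(NA_real_)
  rc <- rater_components(params, spec, i, l)
  den <- rc$shared_trait + rc$specific_trait +
    rc$shared_carry + rc$specific_carry
  if (den <= 0) return(NA_real_)
  (rc$shared_trait + rc$shared_carry) / den
}

#' Rater-consistent occasion specificity
#'
#' Proportion of the current state-residual variance of the non-reference
#' indicator shared with the reference rater's state residual:
#' `lambda_O^2 Var(SR_l) / (lambda_O^2 Var(SR_l) + lambda_OPS^2 Var(SRPS_l))`.
#' Under equal occasion loadings and equal state-residual variances it is
#' identical across occasions for a given indicator.  Its square root is
#' the error-free correlation of the occasion-specific deviations.
#'
#' @inheritParams rater_specificity
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
rater_consistent_occasion_specificity <- function(params, spec, i, l) {
  check_nonref(spec, setdiff(1:2, spec$reference_rater))
  rc <- rater_components(params, spec, i, l)
  den <- rc$shared_sr + rc$specific_sr
  if (den <= 0) return(NA_real_)
  rc$shared_sr / den
}

# Full coefficient table from a parameter set.  Undefined cells are NA.
# At occasion 1, TCon and Pred are reported as the trait share (the table
# convention: with no carry-over possible, the time-consistent share is the
# trait share), while the low-level accessors return NA there.
coefficient_table_params <- function(params, spec,
                                     occasion1_convention = TRUE) {
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  ref <- spec$reference_rater
  rows <- list()
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I)) {
    vc <- variance_components(params, spec, i, k, l)
    rel <- reliability(params, spec, i, k, l)
    os <- occasion_specificity(params, spec, i, k, l)
    tcon <- time_consistency(params, spec, i, k, l)
    pred <- predictability_trait1(params, spec, i, k, l)
    upred <- unpredictability_trait1(params, spec, i, k, l)
    if (l == 1L && occasion1_convention && vc$true > 0) {
      tcon <- vc$trait / vc$true
      pred <- tcon
    }
    rr <- if (l > 1L) state_retest_correlation(params, spec, i, k, l)
          else NA_real_
    row <- data.frame(indicator = i, rater = k, occasion = l,
                      variable = sprintf("indicator%d_rater%d_t%d", i, k, l),
                      Rel = rel, OS = os, TCon = tcon,
                      Pred_trait1 = pred, UPred_trait1 = upred,
                      r_S1_Sl = rr,
                      RS = NA_real_, RCon = NA_real_, rcon_corr = NA_real_,
                      RConOS = NA_real_, rconos_corr = NA_real_,
                      RConTCon = NA_real_, RConPred = NA_real_,
                      RSPred = NA_real_,
                      stringsAsFactors = FALSE)
    if (K == 2L && k != ref) {
      row$RS <- rater_specificity(params, spec, i, l)
      row$RCon <- rater_consistency(params, spec, i, l)
      row$rcon_corr <- if (is.na(row$RCon)) NA_real_ else sqrt(row$RCon)
      row$RConOS <- rater_consistent_occasion_specificity(params, spec, i, l)
      row$rconos_corr <- if (is.na(row$RConOS)) NA_real_ else sqrt(row$RConOS)
      row$RConTCon <- rater_consistent_time_consistency(params, spec, i, l)
      row$RConPred <- rater_consistent_pred_trait1(params, spec, i, l)
      row$RSPred <- if (is.na(row$RConPred)) NA_real_ else 1 - row$RConPred
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lst_coefficient_table", "data.frame")
  out
}

# Flatten the defined cells of a table into a named vector (for bootstrap
# replicate stacking).
coefficient_table_values <- function(tab) {
  cols <- c("Rel", "OS", "TCon", "Pred_trait1", "UPred_trait1", "r_S1_Sl",
            "RS", "RCon", "rcon_corr", "RConOS", "rconos_corr",
            "RConTCon", "RConPred", "RSPred")
  vals <- unlist(lapply(cols, function(cc) {
    v <- tab[[cc]]
    names(v) <- paste0(cc, ".", tab$variable)
    v
  }))
  vals
}

#' Variance-decomposition coefficient table
#'
#' One row per indicator x rater x occasion with every coefficient the
#' model defines: reliability, occasion specificity, time consistency,
#' predictability and unpredictability by the first-occasion trait, latent
#' retest correlation, and (non-reference rater) the rater-consistency
#' system.  Undefined cells are `NA`, never zero.  At occasion 1 the time
#' consistency and predictability columns report the trait share
#' (`1 - OS`), matching the usual presentation; set
#' `occasion1_convention = FALSE` for strict `NA`s there.
#'
#' @param fit A converged `lst_fit` (or an [lst_parameters()] object
#'   together with `spec`).
#' @param cis Optional `lst_boot` object from [bootstrap_lst()]; attaches
#'   one `<col>_lower`/`<col>_upper` pair per defined cell.
#' @param spec Required when `fit` is a parameter set.
#' @param occasion1_convention Report trait share as TCon/Pred at occasion
#'   1?
#' @return A data frame of class `lst_coefficient_table`.
#' @export
coefficient_table <- function(fit, cis = NULL, spec = NULL,
                              occasion1_convention = TRUE) {
  if (inherits(fit, "lst_fit")) {
    if (!isTRUE(fit$converged))
      stop("refusing to compute coefficients from a non-converged fit ",
           "(optimizer reported: ", fit$optimizer_report$message, ")",
           call. = FALSE)
    params <- fit$params
    spec <- fit$spec
  } else if (inherits(fit, "lst_parameters")) {
    if (is.null(spec)) stop("spec required with a raw parameter set",
                            call. = FALSE)
    params <- fit
  } else stop("fit must be an lst_fit or lst_parameters object",
              call. = FALSE)
  tab <- coefficient_table_params(params, spec, occasion1_convention)
  if (!is.null(cis)) {
    stopifnot(inherits(cis, "lst_boot"), !is.null(cis$coef_ci))
    ci <- cis$coef_ci
    cols <- c("Rel", "OS", "TCon", "Pred_trait1", "UPred_trait1", "r_S1_Sl",
              "RS", "RCon", "rcon_corr", "RConOS", "rconos_corr",
              "RConTCon", "RConPred", "RSPred")
    for (cc in cols) {
      lo <- hi <- rep(NA_real_, nrow(tab))
      key <- paste0(cc, ".", tab$variable)
      hit <- match(key, rownames(ci))
      ok <- !is.na(hit)
      lo[ok] <- ci[hit[ok], "lower"]
      hi[ok] <- ci[hit[ok], "upper"]
      tab[[paste0(cc, "_lower")]] <- lo
      tab[[paste0(cc, "_upper")]] <- hi
    }
  }
  tab
}

#' Write a coefficient table as CSV
#'
#' `wide` mirrors the table layout (one row per indicator-rater-occasion);
#' `long` is a tidy one-coefficient-per-row format for plotting.
#'
#' @param tab An `lst_coefficient_table`.
#' @param file Output path.
#' @param format `"wide"` or `"long"`.
#' @return The path, invisibly.
#' @export
write_coefficient_table <- function(tab, file, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(tab, file, row.names = FALSE, na = "")
  } else {
    idcols <- c("indicator", "rater", "occasion", "variable")
    meas <- setdiff(names(tab), idcols)
    long <- do.call(rbind, lapply(meas, function(cc) {
      data.frame(tab[idcols], coefficient = cc, value = tab[[cc]],
                 stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$value), ]
    utils::write.csv(long, file, row.names = FALSE)
  }
  invisible(file)
}
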