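#' Constraint flags for LST-AR / MR-LST-AR models
#'
#' Measurement-invariance and structural equality constraints.  Each flag
#' ties a set of parameters to a single free slot (or fixes covariances),
#' so every flag weakly reduces the free-parameter count and the model
#' degrees of freedom are a deterministic function of the flags.
#'
#' @param equal_O_loadings_over_time Tie the loadings on the occasion
#'   factors `O_l` (and, at occasion 1, on the state residual `SR_1`)
#'   across occasions, per indicator and rater.
#' @param equal_SR_variance_over_time One common `Var(SR_l)` for all
#'   occasions, including occasion 1.
#' @param equal_beta_over_time One common autoregressive weight `beta_O`.
#' @param mr_equal_OPS_loadings_over_time Tie loadings on the rater-specific
#'   occasion factors `OPS_l` across occasions (two-rater models only).
#' @param mr_equal_SRPS_variance_over_time One common `Var(SRPS_l)`.
#' @param mr_equal_betaOPS_over_time One common `beta_OPS`.
#' @param mr_tps_cross_trait_covariances Free cross-indicator covariances
#'   `Cov(TPS_i, T_j)`, `i != j`.  Same-indicator covariances are always
#'   fixed to zero (residual definition of the rater-specific traits).
#' @return An object of class `lst_constraints`.
#' @export
lst_constraints <- function(equal_O_loadings_over_time = TRUE,
                            equal_SR_variance_over_time = TRUE,
                            equal_beta_over_time = TRUE,
                            mr_equal_OPS_loadings_over_time = TRUE,
                            mr_equal_SRPS_variance_over_time = TRUE,
                            mr_equal_betaOPS_over_time = TRUE,
                            mr_tps_cross_trait_covariances = TRUE) {
  flags <- list(
    equal_O_loadings_over_time = isTRUE(equal_O_loadings_over_time),
    equal_SR_variance_over_time = isTRUE(equal_SR_variance_over_time),
    equal_beta_over_time = isTRUE(equal_beta_over_time),
    mr_equal_OPS_loadings_over_time = isTRUE(mr_equal_OPS_loadings_over_time),
    mr_equal_SRPS_variance_over_time = isTRUE(mr_equal_SRPS_variance_over_time),
    mr_equal_betaOPS_over_time = isTRUE(mr_equal_betaOPS_over_time),
    mr_tps_cross_trait_covariances = isTRUE(mr_tps_cross_trait_covariances)
  )
  structure(flags, class = "lst_constraints")
}

#' Define an LST-AR or MR-LST-AR model instance
#'
#' A model spec fixes the dimensions (indicators x occasions x raters), the
#' reference rater of the CT-C(M-1) structure, and the invariance
#' constraints.  The default spec encodes measurement invariance with equal
#' occasion-factor loadings, equal state-residual variances (all occasions)
#' and equal autoregressive weights.
#'
#' @param n_indicators Number of indicators per rater-occasion (>= 2;
#'   indicator-specific traits plus a unidimensional state residual need at
#'   least two indicators).
#' @param n_occasions Number of measurement occasions (>= 2; the
#'   autoregression is empty otherwise).
#' @param n_raters 1 (single-rater LST-AR) or 2 (MR-LST-AR).
#' @param reference_rater Index of the reference rater (two-rater models
#'   only); the other rater is contrasted against it.
#' @param constraints An [lst_constraints()] object.
#' @param indicator_labels,occasion_labels,rater_labels Optional character
#'   labels; deterministic defaults are generated.
#' @return An object of class `lst_spec`.
#' @examples
#' sp <- lst_spec(3, 4, 1)
#' count_free_parameters(sp)  # 43
#' model_df(sp)               # 47
#' @export
lst_spec <- function(n_indicators, n_occasions, n_raters = 1,
                     reference_rater = 1,
                     constraints = lst_constraints(),
                     indicator_labels = NULL,
                     occasion_labels = NULL,
                     rater_labels = NULL) {
  n_indicators <- as.integer(n_indicators)
  n_occasions <- as.integer(n_occasions)
  n_raters <- as.integer(n_raters)
  if (is.na(n_indicators) || n_indicators < 2L)
    stop("n_indicators must be >= 2 (indicator-specific traits require ",
         "at least two indicators)", call. = FALSE)
  if (is.na(n_occasions) || n_occasions < 2L)
    stop("n_occasions must be >= 2 (the autoregression requires at least ",
         "two occasions)", call. = FALSE)
  if (!n_raters %in% c(1L, 2L))
    stop("n_raters must be 1 or 2", call. = FALSE)
  if (n_raters == 1L) {
    reference_rater <- 1L
  } else {
    reference_rater <- as.integer(reference_rater)
    if (!reference_rater %in% c(1L, 2L))
      stop("reference_rater must be 1 or 2", call. = FALSE)
  }
  if (!inherits(constraints, "lst_constraints"))
    stop("constraints must be an lst_constraints() object", call. = FALSE)
  if (is.null(indicator_labels))
    indicator_labels <- paste0("indicator", seq_len(n_indicators))
  if (is.null(occasion_labels))
    occasion_labels <- paste0("t", seq_len(n_occasions))
  if (is.null(rater_labels))
    rater_labels <- paste0("rater", seq_len(n_raters))
  stopifnot(length(indicator_labels) == n_indicators,
            length(occasion_labels) == n_occasions,
            length(rater_labels) == n_raters)
  sp <- list(
    n_indicators = n_indicators,
    n_occasions = n_occasions,
    n_raters = n_raters,
    reference_rater = reference_rater,
    constraints = constraints,
    indicator_labels = as.character(indicator_labels),
    occasion_labels = as.character(occasion_labels),
    rater_labels = as.character(rater_labels)
  )
  structure(sp, class = "lst_spec")
}

#' @export
print.lst_spec <- function(x, ...) {
  kind <- if (x$n_raters == 2L) "MR-LST-AR" else "LST-AR"
  cat(sprintf("%s model spec: %d indicators x %d occasions x %d rater(s)\n",
              kind, x$n_indicators, x$n_occasions, x$n_raters))
  if (x$n_raters == 2L)
    cat(sprintf("  reference rater: %s\n", x$rater_labels[x$reference_rater]))
  on_flags <- names(x$constraints)[unlist(x$constraints)]
  cat("  constraints on:", paste(on_flags, collapse = ", "), "\n")
  cat(sprintf("  free parameters: %d, observed moments: %d, df: %d\n",
              count_free_parameters(x), n_moments(x), model_df(x)))
  invisible(x)
}

# Number of observed variables of a spec.
n_observed <- function(spec) {
  spec$n_indicators * spec$n_raters * spec$n_occasions
}

# Number of first- and second-order observed moments p(p+3)/2.
n_moments <- function(spec) {
  p <- n_observed(spec)
  (p * (p + 3L)) %/% 2L
}

# Number of latent factors in the stacked ordering
# (T_1..T_I, [TPS_1..TPS_I], O_1..O_L, [OPS_1..OPS_L]).
n_latent <- function(spec) {
  kk <- if (spec$n_raters == 2L) 2L else 1L
  spec$n_indicators * kk + spec$n_occasions * kk
}

#' Column index of observed variable Y_ikl
#'
#' Observed variables are ordered rater-major, occasion next, indicator
#' last; this ordering is a frozen constant of the package (coefficient
#' extraction and FIML pattern slicing index into it).
#'
#' @param spec An [lst_spec()].
#' @param i,k,l 1-based indicator, rater, occasion indices.
#' @return Integer column index.
#' @export
obs_index <- function(spec, i, k, l) {
  stopifnot(all(i >= 1 & i <= spec$n_indicators),
            all(k >= 1 & k <= spec$n_raters),
            all(l >= 1 & l <= spec$n_occasions))
  (k - 1L) * spec$n_occasions * spec$n_indicators +
    (l - 1L) * spec$n_indicators + i
}

#' Column names of the observed variables of a spec
#' @param spec An [lst_spec()].
#' @return Character vector `indicator<i>_rater<k>_t<l>` in package order.
#' @export
obs_names <- function(spec) {
  out <- character(n_observed(spec))
  for (k in seq_len(spec$n_raters))
    for (l in seq_len(spec$n_occasions))
      for (i in seq_len(spec$n_indicators))
        out[obs_index(spec, i, k, l)] <-
          sprintf("indicator%d_rater%d_t%d", i, k, l)
  out
}

# Latent stacking indices (1-based).
latent_index_T <- function(spec, i) i
latent_index_TPS <- function(spec, i) spec$n_indicators + i
latent_index_O <- function(spec, l) {
  kk <- if (spec$n_raters == 2L) 2L else 1L
  spec$n_indicators * kk + l
}
latent_index_OPS <- function(spec, l) {
  spec$n_indicators * kk_of(spec) + spec$n_occasions + l
}
kk_of <- function(spec) if (spec$n_raters == 2L) 2L else 1L

latent_names <- function(spec) {
  I <- spec$n_indicators; L <- spec$n_occasions
  nm <- paste0("T", seq_len(I))
  if (spec$n_raters == 2L) nm <- c(nm, paste0("TPS", seq_len(I)))
  nm <- c(nm, paste0("O", seq_len(L)))
  if (spec$n_raters == 2L) nm <- c(nm, paste0("OPS", seq_len(L)))
  nm
}

# ---------------------------------------------------------------------------
# Parameter layout: one row per structured parameter slot.  Tied slots share
# a free_id; fixed slots carry their fixed value and never enter the flat
# vector.  Variances are optimized on the log scale (trans = 1), everything
# else on the natural scale (trans = 0).  `mat` codes address the builder in
# the compiled likelihood core:
#   0 mu, 1 Lambda(mrow,mcol), 2 Phi_T(mrow,mcol), 3 error variance(mrow),
#   4 beta_O(mrow), 5 var_SR(mrow), 6 beta_OPS(mrow), 7 var_SRPS(mrow)
# (mrow/mcol 0-based for the core).
# ---------------------------------------------------------------------------
param_layout <- function(spec) {
  key <- spec_signature(spec)
  cached <- .layout_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- param_layout_build(spec)
  .layout_cache[[key]] <- out
  out
}

.layout_cache <- new.env(parent = emptyenv())

spec_signature <- function(spec) {
  paste(spec$n_indicators, spec$n_raters, spec$n_occasions,
        spec$reference_rater,
        paste(as.integer(unlist(spec$constraints)), collapse = ""),
        sep = "|")
}

param_layout_build <- function(spec) {
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  ref <- spec$reference_rater
  nonref <- if (K == 2L) setdiff(1:2, ref) else integer(0)
  cn <- spec$constraints

  cap <- 16L * I * K * L + (I * if (K == 2L) 2L else 1L)^2
  F_block <- character(cap); F_label <- character(cap)
  F_mat <- integer(cap); F_mrow <- integer(cap); F_mcol <- integer(cap)
  F_i <- rep(NA_integer_, cap); F_k <- rep(NA_integer_, cap)
  F_l <- rep(NA_integer_, cap)
  F_free <- logical(cap); F_id <- rep(NA_integer_, cap)
  F_fixed <- rep(NA_real_, cap); F_trans <- integer(cap)
  nrows <- 0L

  free_ids <- new.env(parent = emptyenv())
  next_id <- 0L
  get_id <- function(key) {
    if (!is.null(free_ids[[key]])) return(free_ids[[key]])
    next_id <<- next_id + 1L
    free_ids[[key]] <- next_id
    next_id
  }
  add <- function(block, label, mat, mrow, mcol = 0L,
                  i = NA_integer_, k = NA_integer_, l = NA_integer_,
                  free = TRUE, tie_key = label, fixed_value = NA_real_,
                  trans = 0L) {
    nrows <<- nrows + 1L
    r <- nrows
    F_block[r] <<- block; F_label[r] <<- label; F_mat[r] <<- mat
    F_mrow[r] <<- as.integer(mrow); F_mcol[r] <<- as.integer(mcol)
    F_i[r] <<- i; F_k[r] <<- k; F_l[r] <<- l
    F_free[r] <<- free
    F_id[r] <<- if (free) get_id(tie_key) else NA_integer_
    F_fixed[r] <<- fixed_value; F_trans[r] <<- as.integer(trans)
    invisible(NULL)
  }

  # intercepts: all free
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I))
    add("a", sprintf("a.i%d.k%d.l%d", i, k, l), 0L,
        obs_index(spec, i, k, l) - 1L, i = i, k = k, l = l)

  # trait loadings on target traits T_i: fixed 1 for reference rater at l=1,
  # free elsewhere (non-reference loadings free at every occasion; the trait
  # scale is set by the reference side).
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I)) {
    lab <- sprintf("lambda_T.i%d.k%d.l%d", i, k, l)
    mrow <- obs_index(spec, i, k, l) - 1L
    mcol <- latent_index_T(spec, i) - 1L
    if (k == ref && l == 1L)
      add("lambda_T", lab, 1L, mrow, mcol, i, k, l,
          free = FALSE, fixed_value = 1)
    else
      add("lambda_T", lab, 1L, mrow, mcol, i, k, l)
  }

  # rater-specific trait loadings (non-reference rater only): fixed 1 at l=1
  if (K == 2L) {
    k2 <- nonref
    for (l in seq_len(L)) for (i in seq_len(I)) {
      lab <- sprintf("lambda_TPS.i%d.l%d", i, l)
      mrow <- obs_index(spec, i, k2, l) - 1L
      mcol <- latent_index_TPS(spec, i) - 1L
      if (l == 1L)
        add("lambda_TPS", lab, 1L, mrow, mcol, i, k2, l,
            free = FALSE, fixed_value = 1)
      else
        add("lambda_TPS", lab, 1L, mrow, mcol, i, k2, l)
    }
  }

  # occasion-factor loadings: first indicator of the reference rater fixed 1
  # at every occasion; others free, tied over occasions under invariance.
  # The occasion-1 entries for the reference rater are the SR_1 loadings.
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I)) {
    lab <- sprintf("lambda_O.i%d.k%d.l%d", i, k, l)
    mrow <- obs_index(spec, i, k, l) - 1L
    mcol <- latent_index_O(spec, l) - 1L
    if (k == ref && i == 1L) {
      add("lambda_O", lab, 1L, mrow, mcol, i, k, l,
          free = FALSE, fixed_value = 1)
    } else {
      tie <- if (cn$equal_O_loadings_over_time)
        sprintf("lambda_O.i%d.k%d", i, k) else lab
      add("lambda_O", lab, 1L, mrow, mcol, i, k, l, tie_key = tie)
    }
  }

  # rater-specific occasion-factor loadings: first indicator fixed 1
  if (K == 2L) {
    k2 <- nonref
    for (l in seq_len(L)) for (i in seq_len(I)) {
      lab <- sprintf("lambda_OPS.i%d.l%d", i, l)
      mrow <- obs_index(spec, i, k2, l) - 1L
      mcol <- latent_index_OPS(spec, l) - 1L
      if (i == 1L) {
        add("lambda_OPS", lab, 1L, mrow, mcol, i, k2, l,
            free = FALSE, fixed_value = 1)
      } else {
        tie <- if (cn$mr_equal_OPS_loadings_over_time)
          sprintf("lambda_OPS.i%d", i) else lab
        add("lambda_OPS", lab, 1L, mrow, mcol, i, k2, l, tie_key = tie)
      }
    }
  }

  # trait variance/covariance block over (T_1..T_I[, TPS_1..TPS_I]):
  # variances on log scale; covariances unconstrained.  Same-indicator
  # Cov(TPS_i, T_i) fixed 0 (residual definition); cross-indicator
  # Cov(TPS_i, T_j) free iff flagged.
  M <- I * kk_of(spec)
  phi_name <- function(r) {
    if (r <= I) sprintf("T%d", r) else sprintf("TPS%d", r - I)
  }
  for (r in seq_len(M)) for (s in seq_len(r)) {
    lab <- sprintf("phi_T.%s.%s", phi_name(r), phi_name(s))
    if (r == s) {
      add("phi_T", lab, 2L, r - 1L, s - 1L, free = TRUE, trans = 1L)
    } else {
      cross <- (r > I) != (s > I)           # one trait, one rater-specific
      same_ind <- cross && ((r - 1L) %% I == (s - 1L) %% I)
      if (same_ind) {
        add("phi_T", lab, 2L, r - 1L, s - 1L, free = FALSE, fixed_value = 0)
      } else if (cross && !cn$mr_tps_cross_trait_covariances) {
        add("phi_T", lab, 2L, r - 1L, s - 1L, free = FALSE, fixed_value = 0)
      } else {
        add("phi_T", lab, 2L, r - 1L, s - 1L)
      }
    }
  }

  # autoregressive weights and state-residual variances (reference process)
  for (l in 2:L) {
    tie <- if (cn$equal_beta_over_time) "beta_O" else sprintf("beta_O.l%d", l)
    add("beta_O", sprintf("beta_O.l%d", l), 4L, l - 2L, l = l, tie_key = tie)
  }
  for (l in seq_len(L)) {
    tie <- if (cn$equal_SR_variance_over_time) "var_SR"
           else sprintf("var_SR.l%d", l)
    add("var_SR", sprintf("var_SR.l%d", l), 5L, l - 1L, l = l,
        tie_key = tie, trans = 1L)
  }

  if (K == 2L) {
    for (l in 2:L) {
      tie <- if (cn$mr_equal_betaOPS_over_time) "beta_OPS"
             else sprintf("beta_OPS.l%d", l)
      add("beta_OPS", sprintf("beta_OPS.l%d", l), 6L, l - 2L, l = l,
          tie_key = tie)
    }
    for (l in seq_len(L)) {
      tie <- if (cn$mr_equal_SRPS_variance_over_time) "var_SRPS"
             else sprintf("var_SRPS.l%d", l)
      add("var_SRPS", sprintf("var_SRPS.l%d", l), 7L, l - 1L, l = l,
          tie_key = tie, trans = 1L)
    }
  }

  # measurement error variances: all free, log scale
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I))
    add("var_E", sprintf("var_E.i%d.k%d.l%d", i, k, l), 3L,
        obs_index(spec, i, k, l) - 1L, i = i, k = k, l = l, trans = 1L)

  idx <- seq_len(nrows)
  out <- data.frame(block = F_block[idx], label = F_label[idx],
                    mat = F_mat[idx], mrow = F_mrow[idx],
                    mcol = F_mcol[idx], i = F_i[idx], k = F_k[idx],
                    l = F_l[idx], free = F_free[idx], free_id = F_id[idx],
                    fixed_value = F_fixed[idx], trans = F_trans[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_free") <- next_id
  out
}

#' Count the free parameters of a model spec
#'
#' The count drives the model degrees of freedom:
#' `df = p(p+3)/2 - count` with `p` observed variables.
#'
#' @param spec An [lst_spec()].
#' @return Integer number of free parameters.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "lst_spec"))
  attr(param_layout(spec), "n_free")
}

#' Model degrees of freedom implied by a spec
#' @param spec An [lst_spec()].
#' @return Integer df (observed moments minus free parameters).
#' @export
model_df <- function(spec) {
  n_moments(spec) - count_free_parameters(spec)
}

# Names of the free parameters in flat-vector order (natural scale).
free_parameter_names <- function(spec) {
  lay <- param_layout(spec)
  lay <- lay[lay$free, , drop = FALSE]
  # representative label per free id: first slot, with tied slots collapsing
  # to the tie key's first occurrence
  nm <- character(attr(param_layout(spec), "n_free"))
  for (r in seq_len(nrow(lay))) {
    id <- lay$free_id[r]
    if (nm[id] == "") nm[id] <- lay$label[r]
  }
  nm
}
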