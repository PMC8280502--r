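#' Construct a structured parameter set
#'
#' Holds every parameter of one model instance, including fixed entries at
#' their fixed values (reference loadings 1, same-indicator trait /
#' rater-specific-trait covariances 0).  All latent factors have mean zero;
#' observed means are carried entirely by the intercepts.
#'
#' @param spec An [lst_spec()].
#' @param a Intercept array, `I x K x L`.
#' @param lambda_T Loadings of `Y_ikl` on the (reference-rater) trait
#'   factors `T_i`, `I x K x L`; the reference rater's occasion-1 entries
#'   must be 1.
#' @param lambda_O Loadings on the occasion factors `O_l`, `I x K x L`;
#'   entries for the first indicator of the reference rater must be 1.
#'   The reference rater's occasion-1 column holds the `SR_1` loadings.
#' @param phi_T Trait covariance matrix over `(T_1..T_I)` for one rater, or
#'   `(T_1..T_I, TPS_1..TPS_I)` for two; same-indicator `Cov(TPS_i, T_i)`
#'   must be 0.
#' @param beta_O Autoregressive weights, length `L - 1` (transition into
#'   occasions `2..L`).
#' @param var_SR State residual variances, length `L`.
#' @param var_E Measurement error variance array, `I x K x L`.
#' @param lambda_TPS,lambda_OPS Non-reference-rater loadings on the
#'   rater-specific trait and occasion factors (`I x L`; first row of
#'   `lambda_OPS` and occasion-1 column of `lambda_TPS` fixed 1).  Two-rater
#'   models only.
#' @param beta_OPS,var_SRPS Rater-specific autoregression weights and state
#'   residual variances.  Two-rater models only.
#' @return An object of class `lst_parameters`.
#' @export
lst_parameters <- function(spec, a, lambda_T, lambda_O, phi_T,
                           beta_O, var_SR, var_E,
                           lambda_TPS = NULL, lambda_OPS = NULL,
                           beta_OPS = NULL, var_SRPS = NULL) {
  stopifnot(inherits(spec, "lst_spec"))
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  dim3 <- c(I, K, L)
  as_arr <- function(x, what) {
    x <- array(as.numeric(x), dim = dim3)
    dimnames(x) <- list(spec$indicator_labels, spec$rater_labels,
                        spec$occasion_labels)
    x
  }
  p <- list(
    a = as_arr(a), lambda_T = as_arr(lambda_T), lambda_O = as_arr(lambda_O),
    phi_T = as.matrix(phi_T),
    beta_O = as.numeric(beta_O), var_SR = as.numeric(var_SR),
    var_E = as_arr(var_E)
  )
  M <- I * kk_of(spec)
  if (!identical(dim(p$phi_T), c(M, M)))
    stop("phi_T must be ", M, " x ", M, call. = FALSE)
  dimnames(p$phi_T) <- rep(list(latent_names(spec)[seq_len(M)]), 2)
  if (length(p$beta_O) != L - 1L) stop("beta_O must have length L - 1",
                                       call. = FALSE)
  if (length(p$var_SR) != L) stop("var_SR must have length L", call. = FALSE)
  if (K == 2L) {
    if (is.null(lambda_TPS) || is.null(lambda_OPS) ||
        is.null(beta_OPS) || is.null(var_SRPS))
      stop("two-rater models need lambda_TPS, lambda_OPS, beta_OPS, var_SRPS",
           call. = FALSE)
    p$lambda_TPS <- matrix(as.numeric(lambda_TPS), I, L,
                           dimnames = list(spec$indicator_labels,
                                           spec$occasion_labels))
    p$lambda_OPS <- matrix(as.numeric(lambda_OPS), I, L,
                           dimnames = list(spec$indicator_labels,
                                           spec$occasion_labels))
    p$beta_OPS <- as.numeric(beta_OPS)
    p$var_SRPS <- as.numeric(var_SRPS)
    if (length(p$beta_OPS) != L - 1L || length(p$var_SRPS) != L)
      stop("beta_OPS must have length L - 1 and var_SRPS length L",
           call. = FALSE)
  }
  structure(p, class = "lst_parameters")
}

#' @export
print.lst_parameters <- function(x, ...) {
  cat("LST parameter set:",
      paste(dim(x$a), collapse = " x "),
      "(indicators x raters x occasions)\n")
  cat("  beta_O:", signif(x$beta_O, 4), " var_SR:", signif(x$var_SR, 4), "\n")
  if (!is.null(x$beta_OPS))
    cat("  beta_OPS:", signif(x$beta_OPS, 4),
        " var_SRPS:", signif(x$var_SRPS, 4), "\n")
  invisible(x)
}

# Read the structured value addressed by one layout row.
slot_value <- function(params, row) {
  switch(as.character(row$block),
    a = params$a[row$i, row$k, row$l],
    lambda_T = params$lambda_T[row$i, row$k, row$l],
    lambda_TPS = params$lambda_TPS[row$i, row$l],
    lambda_O = params$lambda_O[row$i, row$k, row$l],
    lambda_OPS = params$lambda_OPS[row$i, row$l],
    phi_T = params$phi_T[row$mrow + 1L, row$mcol + 1L],
    beta_O = params$beta_O[row$l - 1L],
    var_SR = params$var_SR[row$l],
    beta_OPS = params$beta_OPS[row$l - 1L],
    var_SRPS = params$var_SRPS[row$l],
    var_E = params$var_E[row$i, row$k, row$l],
    stop("unknown block ", row$block)
  )
}

#' Map a structured parameter set to the flat unconstrained vector
#'
#' Variances enter on the log scale; loadings, intercepts, covariances and
#' autoregressive weights on the natural scale.  Tied slots occupy one
#' vector element; fixed slots never appear.  `unflatten_parameters()`
#' inverts the map exactly.
#'
#' @param params An [lst_parameters()] object conforming to `spec` (fixed
#'   entries at their fixed values, tied entries equal).
#' @param spec An [lst_spec()].
#' @return Numeric vector of length `count_free_parameters(spec)` with the
#'   free-parameter labels as names.
#' @export
flatten_parameters <- function(params, spec) {
  stopifnot(inherits(params, "lst_parameters"), inherits(spec, "lst_spec"))
  lay <- param_layout(spec)
  nfree <- attr(lay, "n_free")
  theta <- rep(NA_real_, nfree)
  cols <- as.list(lay)
  for (r in seq_len(nrow(lay))) {
    row <- lapply(cols, `[`, r)
    v <- slot_value(params, row)
    if (!row$free) {
      if (!isTRUE(abs(v - row$fixed_value) < 1e-8))
        stop("parameter set does not conform to spec: fixed slot ",
             row$label, " has value ", v, " (expected ", row$fixed_value,
             ")", call. = FALSE)
      next
    }
    u <- if (row$trans == 1L) {
      if (v <= 0) stop("variance slot ", row$label,
                       " must be positive to flatten", call. = FALSE)
      log(v)
    } else v
    if (is.na(theta[row$free_id])) {
      theta[row$free_id] <- u
    } else if (abs(theta[row$free_id] - u) > 1e-8) {
      stop("parameter set does not conform to spec: tied slot ",
           row$label, " differs from its partners", call. = FALSE)
    }
  }
  names(theta) <- free_parameter_names(spec)
  theta
}

#' @rdname flatten_parameters
#' @param theta Numeric vector of length `count_free_parameters(spec)`.
#' @export
unflatten_parameters <- function(theta, spec) {
  stopifnot(inherits(spec, "lst_spec"))
  lay <- param_layout(spec)
  nfree <- attr(lay, "n_free")
  if (length(theta) != nfree)
    stop("theta has length ", length(theta), ", expected ", nfree,
         call. = FALSE)
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  M <- I * kk_of(spec)
  p <- list(a = array(0, c(I, K, L)), lambda_T = array(0, c(I, K, L)),
            lambda_O = array(0, c(I, K, L)), phi_T = matrix(0, M, M),
            beta_O = numeric(L - 1L), var_SR = numeric(L),
            var_E = array(0, c(I, K, L)))
  if (K == 2L) {
    p$lambda_TPS <- matrix(0, I, L)
    p$lambda_OPS <- matrix(0, I, L)
    p$beta_OPS <- numeric(L - 1L)
    p$var_SRPS <- numeric(L)
  }
  cols <- as.list(lay)
  for (r in seq_len(nrow(lay))) {
    row <- lapply(cols, `[`, r)
    v <- if (row$free) theta[row$free_id] else row$fixed_value
    if (row$free && row$trans == 1L) v <- exp(v)
    switch(as.character(row$block),
      a = { p$a[row$i, row$k, row$l] <- v },
      lambda_T = { p$lambda_T[row$i, row$k, row$l] <- v },
      lambda_TPS = { p$lambda_TPS[row$i, row$l] <- v },
      lambda_O = { p$lambda_O[row$i, row$k, row$l] <- v },
      lambda_OPS = { p$lambda_OPS[row$i, row$l] <- v },
      phi_T = { p$phi_T[row$mrow + 1L, row$mcol + 1L] <- v
                p$phi_T[row$mcol + 1L, row$mrow + 1L] <- v },
      beta_O = { p$beta_O[row$l - 1L] <- v },
      var_SR = { p$var_SR[row$l] <- v },
      beta_OPS = { p$beta_OPS[row$l - 1L] <- v },
      var_SRPS = { p$var_SRPS[row$l] <- v }
    )
    if (row$block == "var_E") p$var_E[row$i, row$k, row$l] <- v
  }
  do.call(lst_parameters, c(list(spec = spec), p))
}

#' Serialize a parameter set to a flat-key list / YAML file
#'
#' Keys follow the slot labels (e.g. `lambda_T.i2.k1.l3`); fixed slots are
#' written with a `fixed: true` marker.  `read_parameters()` inverts the
#' serialization.
#'
#' @param params An [lst_parameters()] object.
#' @param spec The matching [lst_spec()].
#' @param file Optional path; when given, YAML is written there.
#' @return The flat-key list, invisibly when writing to a file.
#' @export
write_parameters <- function(params, spec, file = NULL) {
  lay <- param_layout(spec)
  out <- vector("list", nrow(lay))
  names(out) <- lay$label
  for (r in seq_len(nrow(lay))) {
    row <- lay[r, ]
    v <- slot_value(params, row)
    out[[r]] <- if (row$free) list(value = unname(v))
                else list(value = unname(v), fixed = TRUE)
  }
  if (!is.null(file)) {
    yaml::write_yaml(out, file, precision = 15L)
    return(invisible(out))
  }
  out
}

#' @rdname write_parameters
#' @param x A flat-key list or a YAML file path produced by
#'   [write_parameters()].
#' @export
read_parameters <- function(x, spec) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  lay <- param_layout(spec)
  theta <- rep(NA_real_, attr(lay, "n_free"))
  for (r in seq_len(nrow(lay))) {
    row <- lay[r, ]
    ent <- x[[row$label]]
    if (is.null(ent)) stop("missing key ", row$label, call. = FALSE)
    v <- as.numeric(ent$value)
    if (!row$free) next
    theta[row$free_id] <- if (row$trans == 1L) log(v) else v
  }
  unflatten_parameters(theta, spec)
}
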