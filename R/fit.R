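# Deterministic starting values: intercepts at column means, error
# variances at half the column variances, trait variances/covariances from
# occasion-averaged indicator covariances, free loadings 1, autoregressive
# weights 0.3.  Cheap and well inside the feasible region.
start_parameters <- function(spec, data) {
  I <- spec$n_indicators; K <- spec$n_raters; L <- spec$n_occasions
  ref <- spec$reference_rater
  nonref <- if (K == 2L) setdiff(1:2, ref) else integer(0)
  Y <- data$values
  cm <- colMeans(Y, na.rm = TRUE)
  cv <- apply(Y, 2L, stats::var, na.rm = TRUE)
  cv[!is.finite(cv) | cv <= 0] <- 1
  cm[!is.finite(cm)] <- 0

  a <- array(0, c(I, K, L)); var_E <- array(0, c(I, K, L))
  lambda_T <- array(1, c(I, K, L)); lambda_O <- array(1, c(I, K, L))
  for (k in seq_len(K)) for (l in seq_len(L)) for (i in seq_len(I)) {
    j <- obs_index(spec, i, k, l)
    a[i, k, l] <- cm[j]
    var_E[i, k, l] <- cv[j] / 2
  }
  M <- I * kk_of(spec)
  phi_T <- matrix(0, M, M)
  # occasion-averaged covariances between indicators of the same rater
  avg_cov <- function(k, i, j) {
    vals <- vapply(seq_len(L), function(l) {
      x <- Y[, obs_index(spec, i, k, l)]
      y <- Y[, obs_index(spec, j, k, l)]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) > 2) stats::cov(x[ok], y[ok]) else NA_real_
    }, 1.0)
    m <- mean(vals, na.rm = TRUE)
    if (!is.finite(m)) 0.1 else m
  }
  for (i in seq_len(I)) for (j in seq_len(i)) {
    v <- avg_cov(ref, i, j)
    if (i == j) v <- max(v * 0.5, 0.05)
    phi_T[i, j] <- v; phi_T[j, i] <- v
  }
  if (K == 2L) {
    for (i in seq_len(I)) for (j in seq_len(i)) {
      v <- avg_cov(nonref, i, j)
      if (i == j) v <- max(v * 0.5, 0.05)
      phi_T[I + i, I + j] <- v; phi_T[I + j, I + i] <- v
    }
    # same-indicator cross covariances stay fixed at zero; cross-indicator
    # ones start at zero too
  }
  mean_var <- function(k) {
    mean(cv[vapply(seq_len(L), function(l)
      obs_index(spec, 1L, k, l), 1L)])
  }
  var_SR <- rep(max(mean_var(ref) * 0.25, 0.02), L)
  beta_O <- rep(0.3, L - 1L)
  args <- list(spec = spec, a = a, lambda_T = lambda_T, lambda_O = lambda_O,
               phi_T = phi_T, beta_O = beta_O, var_SR = var_SR,
               var_E = var_E)
  if (K == 2L) {
    lambda_TPS <- matrix(1, I, L)
    lambda_OPS <- matrix(1, I, L)
    # non-reference loadings on the shared factors start modestly positive
    args$lambda_T[, nonref, ] <- 0.5
    args$lambda_O[, nonref, ] <- 0.5
    args$lambda_TPS <- lambda_TPS
    args$lambda_OPS <- lambda_OPS
    args$beta_OPS <- rep(0.3, L - 1L)
    args$var_SRPS <- rep(max(mean_var(nonref) * 0.25, 0.02), L)
  }
  # fixed slots must sit exactly at their fixed values
  args$lambda_T[, ref, 1L] <- 1
  args$lambda_O[1L, ref, ] <- 1
  if (K == 2L) {
    args$lambda_TPS[, 1L] <- 1
    args$lambda_OPS[1L, ] <- 1
    for (i in seq_len(I)) {
      args$phi_T[i, I + i] <- 0
      args$phi_T[I + i, i] <- 0
    }
  }
  do.call(lst_parameters, args)
}

#' Fit an LST-AR / MR-LST-AR model by FIML
#'
#' Maximizes the full-information maximum likelihood over the flat
#' unconstrained parameter vector (variances on the log scale) with a
#' quasi-Newton optimizer and a compiled likelihood core.  The saturated
#' model (EM under missingness) and the independence baseline supply the
#' chi-square, CFI and RMSEA.  When the first start fails, up to three
#' jittered restarts with fixed sub-seeds are tried.  Non-convergence is
#' reported, never silently ignored.
#'
#' @param spec An [lst_spec()].
#' @param data An [lst_panel()] whose columns match the spec.
#' @param start Optional [lst_parameters()] starting values; defaults to
#'   deterministic data-driven starts.
#' @param se Compute standard errors from the numerically differentiated
#'   observed information (inverted and mapped to the natural scale)?
#' @param indices Compute saturated/baseline fits and fit indices?
#' @param control List: `iter_max` (default 2000), `rel_tol` (1e-10),
#'   `grad_tol` (1e-3, max-norm declaring convergence), `restarts` (3).
#' @return An object of class `lst_fit`.
#' @export
fit_lst <- function(spec, data, start = NULL, se = TRUE, indices = TRUE,
                    control = list()) {
  stopifnot(inherits(spec, "lst_spec"), inherits(data, "lst_panel"))
  if (ncol(data$values) != n_observed(spec))
    stop("data columns do not match spec", call. = FALSE)
  ctl <- utils::modifyList(list(iter_max = 2000L, rel_tol = 1e-10,
                                grad_tol = 1e-3, restarts = 3L), control)
  pats <- pattern_stats(data$values)
  layout <- cpp_layout(spec)
  n <- nrow(data$values)

  if (is.null(start)) start <- start_parameters(spec, data)
  theta0 <- flatten_parameters(start, spec)

  negll <- function(th) -cpp_fiml_loglik(th, layout, unname(pats))
  neggr <- function(th) -cpp_fiml_grad(th, layout, unname(pats))

  run_opt <- function(th0) {
    stats::nlminb(th0, objective = negll, gradient = neggr,
                  control = list(iter.max = ctl$iter_max,
                                 eval.max = 5L * ctl$iter_max,
                                 rel.tol = ctl$rel_tol))
  }
  opt <- run_opt(theta0)
  tried <- 1L
  best <- opt
  grad_norm <- max(abs(neggr(best$par)))
  ok <- is.finite(best$objective) && best$objective < 1e11 &&
    (best$convergence == 0L || grad_norm < ctl$grad_tol)
  while (!ok && tried <= ctl$restarts) {
    set.seed(90000L + tried)
    jit <- theta0 + stats::rnorm(length(theta0), 0, 0.1)
    o <- run_opt(jit)
    if (is.finite(o$objective) && o$objective < best$objective) best <- o
    grad_norm <- max(abs(neggr(best$par)))
    ok <- is.finite(best$objective) && best$objective < 1e11 &&
      (best$convergence == 0L || grad_norm < ctl$grad_tol)
    tried <- tried + 1L
  }
  theta_hat <- best$par
  ll_model <- -best$objective
  params_hat <- unflatten_parameters(theta_hat, spec)
  converged <- ok

  df <- model_df(spec)
  out <- list(spec = spec, params = params_hat, theta = theta_hat,
              loglik_model = ll_model, df = df, converged = converged,
              n_used = n, n_dropped = attr(data, "n_dropped"),
              optimizer_report = list(convergence = best$convergence,
                                      message = best$message,
                                      iterations = best$iterations,
                                      evaluations = best$evaluations,
                                      grad_max_norm = grad_norm,
                                      starts_tried = tried))
  if (indices) {
    sat <- fit_saturated(data)
    base <- fit_baseline(data)
    fi <- fit_indices(ll_model, sat$loglik, base$loglik, df, base$df, n)
    out$loglik_saturated <- sat$loglik
    out$loglik_baseline <- base$loglik
    out$chi2 <- fi$chi2
    out$cfi <- fi$cfi
    out$rmsea <- fi$rmsea
    out$chi2_baseline <- fi$chi2_baseline
    out$df_baseline <- fi$df_baseline
  }
  if (se) {
    out$se <- tryCatch(fit_standard_errors(theta_hat, spec, pats, layout),
                       error = function(e) {
                         warning("standard errors unavailable: ",
                                 conditionMessage(e))
                         NULL
                       })
  }
  # Heywood screen: negative definite trait block or boundary variances are
  # visible, not truncated
  ev <- eigen(params_hat$phi_T, symmetric = TRUE, only.values = TRUE)$values
  out$heywood <- min(ev) < -1e-8
  class(out) <- "lst_fit"
  out
}

# Observed-information standard errors.  The analytic gradient is
# differentiated by central differences on the unconstrained scale; SEs
# are mapped to the natural scale through the parameterization's Jacobian
# (d exp(u)/du = exp(u) for log-variances, identity elsewhere).
fit_standard_errors <- function(theta, spec, pats, layout = cpp_layout(spec)) {
  p <- length(theta)
  gr <- function(th) cpp_fiml_grad(th, layout, unname(pats))
  h <- 1e-5 * pmax(1, abs(theta))
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    tp <- theta; tp[i] <- theta[i] + h[i]
    tm <- theta; tm[i] <- theta[i] - h[i]
    H[i, ] <- (gr(tp) - gr(tm)) / (2 * h[i])
  }
  H <- (H + t(H)) / 2
  info <- -H
  V <- tryCatch(solve(info), error = function(e) {
    MASS_ginv(info)
  })
  se_u <- sqrt(pmax(diag(V), 0))
  # natural-scale back-transformation
  lay <- param_layout(spec)
  lay <- lay[lay$free, ]
  trans <- integer(length(theta))
  for (r in seq_len(nrow(lay))) trans[lay$free_id[r]] <- lay$trans[r]
  jac <- ifelse(trans == 1L, exp(theta), 1)
  se_nat <- se_u * abs(jac)
  names(se_nat) <- free_parameter_names(spec)
  se_nat
}

# Moore-Penrose fallback without adding a MASS dependency at runtime.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.lst_fit <- function(x, ...) {
  kind <- if (x$spec$n_raters == 2L) "MR-LST-AR" else "LST-AR"
  cat(sprintf("%s fit: n = %d, free parameters = %d, df = %d\n",
              kind, x$n_used, length(x$theta), x$df))
  cat(sprintf("  log-likelihood: %.3f  converged: %s\n",
              x$loglik_model, x$converged))
  if (!is.null(x$chi2)) {
    cat(sprintf("  chi2(%d) = %.3f, CFI = %.3f, RMSEA = %.3f\n",
                x$df, x$chi2, x$cfi, x$rmsea))
    advisories <- c(
      sprintf("chi2 < 2 df: %s", x$chi2 < 2 * x$df),
      sprintf("CFI > 0.97: %s", x$cfi > 0.97),
      sprintf("RMSEA < 0.05: %s", x$rmsea < 0.05))
    cat("  fit advisories:", paste(advisories, collapse = "; "), "\n")
  }
  if (isTRUE(x$heywood))
    cat("  warning: trait covariance block is not positive semidefinite",
        "(Heywood case)\n")
  invisible(x)
}

#' Coefficients method for LST fits
#' @param object An `lst_fit`.
#' @param ... Unused.
#' @return Named vector of free-parameter estimates on the natural scale.
#' @export
coef.lst_fit <- function(object, ...) {
  lay <- param_layout(object$spec)
  lay <- lay[lay$free, ]
  trans <- integer(length(object$theta))
  for (r in seq_len(nrow(lay))) trans[lay$free_id[r]] <- lay$trans[r]
  out <- ifelse(trans == 1L, exp(object$theta), object$theta)
  names(out) <- free_parameter_names(object$spec)
  out
}

#' @export
logLik.lst_fit <- function(object, ...) {
  structure(object$loglik_model, df = length(object$theta),
            nobs = object$n_used, class = "logLik")
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples dyads (whole rows, preserving within-dyad dependence) with
#' replacement, refits each replicate starting at the full-sample estimate,
#' and forms percentile intervals for every free parameter (natural scale)
#' and every variance-decomposition coefficient.  Non-converged replicates
#' are dropped and counted; more than 20% of them attaches a warning.
#'
#' @param spec An [lst_spec()].
#' @param data An [lst_panel()].
#' @param B Number of bootstrap resamples (`B >= 1`).
#' @param seed Integer seed; the same seed reproduces identical intervals.
#' @param level Confidence level (default 0.95).
#' @param fit Optional full-sample `lst_fit` to reuse.
#' @param coefficients Also bootstrap the coefficient table?
#' @return An object of class `lst_boot`: list with `param_ci`,
#'   `coef_ci` (optional), `replicates`, `n_failed`, `level`, `seed`.
#' @export
bootstrap_lst <- function(spec, data, B, seed = 1L, level = 0.95,
                          fit = NULL, coefficients = TRUE) {
  stopifnot(B >= 1L)
  if (is.null(fit)) fit <- fit_lst(spec, data, se = FALSE, indices = FALSE)
  start <- fit$params
  n <- nrow(data$values)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)

  par_mat <- NULL
  coef_mat <- NULL
  n_failed <- 0L
  set.seed(as.integer(seed))
  row_draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  for (b in seq_len(B)) {
    rows <- row_draws[b, ]
    db <- lst_panel(data$values[rows, , drop = FALSE], spec,
                    dyad_id = seq_len(n))
    fb <- tryCatch(
      fit_lst(spec, db, start = start, se = FALSE, indices = FALSE,
              control = list(restarts = 1L)),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est <- coef.lst_fit(fb)
    if (is.null(par_mat))
      par_mat <- matrix(NA_real_, B, length(est),
                        dimnames = list(NULL, names(est)))
    par_mat[b, ] <- est
    if (coefficients) {
      tab <- coefficient_table_params(fb$params, spec)
      vals <- coefficient_table_values(tab)
      if (is.null(coef_mat))
        coef_mat <- matrix(NA_real_, B, length(vals),
                           dimnames = list(NULL, names(vals)))
      coef_mat[b, ] <- vals
    }
  }
  ci_of <- function(mat) {
    if (is.null(mat)) return(NULL)
    t(apply(mat, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) return(c(NA_real_, NA_real_))
      stats::quantile(col, probs, na.rm = TRUE, names = FALSE, type = 7)
    }))
  }
  param_ci <- ci_of(par_mat)
  if (!is.null(param_ci)) colnames(param_ci) <- c("lower", "upper")
  coef_ci <- ci_of(coef_mat)
  if (!is.null(coef_ci)) colnames(coef_ci) <- c("lower", "upper")
  out <- list(param_ci = param_ci, coef_ci = coef_ci,
              replicates = list(params = par_mat, coefficients = coef_mat),
              n_failed = n_failed, B = B, level = level, seed = seed)
  if (n_failed > 0.2 * B)
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, B))
  class(out) <- "lst_boot"
  out
}

#' @export
print.lst_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: B = %d, level = %.0f%%, failed = %d\n",
              x$B, 100 * x$level, x$n_failed))
  invisible(x)
}
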