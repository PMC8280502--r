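test_that("FIML equals the direct complete-data MVN log-likelihood", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 200, seed = 17)
  m <- implied_moments(p, sp)
  expect_equal(fiml_loglik(p, sp, d),
               rowwise_mvn_loglik(d$values, m$mu, m$sigma),
               tolerance = 1e-8)
})

test_that("a single observed value reduces to the univariate normal
           density", {
  sp <- lst_spec(2, 2, 1)
  p <- random_params(sp, seed = 31)
  m <- implied_moments(p, sp)
  Y <- matrix(NA_real_, 1, 4)
  Y[1, 2] <- 1.7
  colnames(Y) <- obs_names(sp)
  d <- lst_panel(Y, sp)
  expect_equal(fiml_loglik(p, sp, d),
               dnorm(1.7, m$mu[2], sqrt(m$sigma[2, 2]), log = TRUE),
               tolerance = 1e-10)
})

test_that("pattern-grouped FIML equals ungrouped row-by-row evaluation", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 150,
                    missingness_spec("mcar_occasion",
                                     rates = matrix(c(0.9, 0.6), 1)),
                    seed = 23)
  m <- implied_moments(p, sp)
  expect_equal(fiml_loglik(p, sp, d),
               rowwise_mvn_loglik(d$values, m$mu, m$sigma),
               tolerance = 1e-8)
})

test_that("analytic gradient matches central differences", {
  for (K in 1:2) {
    sp <- lst_spec(3, 4, K)
    p <- random_params(sp, seed = 53 + K)
    d <- simulate_lst(p, sp, 300, study_missingness(sp), seed = 5)
    th <- flatten_parameters(p, sp)
    lay <- lstar:::cpp_layout(sp)
    pats <- unname(lstar:::pattern_stats(d$values))
    ga <- lstar:::cpp_fiml_grad(th, lay, pats)
    gn <- lstar:::cpp_fiml_grad_num(th, lay, pats)
    expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 1e-5)
  }
})

test_that("saturated fit reduces to closed-form moments with complete data
           and recovers truth under MCAR", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 400, seed = 3)
  sat <- fit_saturated(d)
  n <- nrow(d$values)
  expect_equal(sat$mu, colMeans(d$values))
  expect_equal(sat$sigma,
               crossprod(sweep(d$values, 2, colMeans(d$values))) / n)
  # MCAR-masked data: EM estimates near the generating moments
  dm <- simulate_lst(p, sp, 2000,
                     missingness_spec("mcar_occasion",
                                      rates = matrix(c(0.8, 0.7), 1)),
                     seed = 29)
  sat2 <- fit_saturated(dm)
  expect_true(sat2$converged)
  m <- implied_moments(p, sp)
  expect_lt(max(abs(sat2$mu - m$mu)), 0.12)
  expect_lt(max(abs(sat2$sigma - m$sigma)), 0.25)
})

test_that("likelihood-ratio nesting holds: baseline <= model <= saturated", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 300, study_missingness(sp), seed = 37)
  f <- fit_lst(sp, d, se = FALSE)
  expect_lte(f$loglik_baseline, f$loglik_model + 1e-6)
  expect_lte(f$loglik_model, f$loglik_saturated + 1e-6)
  expect_gte(f$chi2, -1e-6)
})

test_that("baseline fit equals summed per-column univariate ML fits on
           complete data, and a diagonal truth drives CFI to 1", {
  sp <- lst_spec(2, 2, 1)
  p <- random_params(sp, seed = 19)
  d <- simulate_lst(p, sp, 300, seed = 41)
  base <- fit_baseline(d)
  ll_cols <- sum(vapply(seq_len(ncol(d$values)), function(j) {
    x <- d$values[, j]
    v <- mean((x - mean(x))^2)
    sum(dnorm(x, mean(x), sqrt(v), log = TRUE))
  }, 1.0))
  expect_equal(base$loglik, ll_cols, tolerance = 1e-8)
  # diagonal-truth data: the independence model is true, so its chi-square
  # against the saturated model sits near its df
  p0 <- random_params(sp, seed = 20)
  p0$phi_T[] <- diag(1e-12, 2)
  p0$var_SR[] <- 1e-12
  d0 <- simulate_lst(p0, sp, 500, seed = 43)
  sat0 <- fit_saturated(d0)
  base0 <- fit_baseline(d0)
  chi2_b <- 2 * (sat0$loglik - base0$loglik)
  expect_gte(chi2_b, -1e-6)
  expect_lt(chi2_b, base0$df + 4 * sqrt(2 * base0$df))
})

test_that("fit indices follow their defining formulas and boundaries", {
  # exact-fit boundary: chi2 = df -> rmsea 0
  fi <- fit_indices(-100, -100 + 23.5, -400, df_model = 47,
                    df_baseline = 66, n = 200)
  expect_equal(fi$chi2, 47)
  expect_equal(fi$rmsea, 0)
  # model = saturated -> chi2 0, cfi 1
  fi2 <- fit_indices(-100, -100, -400, 47, 66, 200)
  expect_equal(fi2$chi2, 0)
  expect_equal(fi2$cfi, 1)
  # generic values recomputed by hand
  ll_m <- -5000; ll_s <- -4950; ll_b <- -5600
  fi3 <- fit_indices(ll_m, ll_s, ll_b, 47, 66, 575)
  chi2 <- 2 * (ll_s - ll_m); chi2_b <- 2 * (ll_s - ll_b)
  expect_equal(fi3$chi2, chi2)
  expect_equal(fi3$cfi, 1 - (chi2 - 47) / (chi2_b - 66))
  expect_equal(fi3$rmsea, sqrt((chi2 - 47) / (47 * 574)))
  # df = 0: rmsea undefined
  expect_true(is.na(fit_indices(-10, -10, -20, 0, 5, 100)$rmsea))
})

test_that("fitting recovers generating parameters on moderate samples", {
  sp <- lst_spec(3, 4, 1)
  p <- example_parameters_single(sp)
  d <- simulate_lst(p, sp, 2000, seed = 47)
  f <- fit_lst(sp, d)
  expect_true(f$converged)
  expect_identical(f$df, 47L)
  truth <- lstar:::flatten_natural(p, sp)
  z <- abs(coef(f) - truth) / f$se
  expect_lt(max(z), 4)
  expect_lt(mean(z > 2), 0.15)
})

test_that("row permutation leaves the fit unchanged and truth start
           reaches the same maximizer", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 300, seed = 53)
  f1 <- fit_lst(sp, d, se = FALSE, indices = FALSE)
  set.seed(1)
  perm <- sample.int(300)
  d2 <- lst_panel(d$values[perm, , drop = FALSE], sp)
  f2 <- fit_lst(sp, d2, se = FALSE, indices = FALSE)
  expect_equal(f1$loglik_model, f2$loglik_model, tolerance = 1e-6)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
  f3 <- fit_lst(sp, d, start = p, se = FALSE, indices = FALSE)
  expect_true(f3$converged)
  expect_equal(f3$loglik_model, f1$loglik_model, tolerance = 1e-6)
  expect_equal(f3$theta, f1$theta, tolerance = 1e-3)
})

test_that("bootstrap intervals are reproducible and collapse at B = 1", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 200, seed = 59)
  f <- fit_lst(sp, d, se = FALSE, indices = FALSE)
  b1 <- bootstrap_lst(sp, d, B = 1, seed = 4, fit = f,
                      coefficients = FALSE)
  expect_equal(b1$param_ci[, "lower"], b1$param_ci[, "upper"])
  b2 <- bootstrap_lst(sp, d, B = 25, seed = 8, fit = f,
                      coefficients = FALSE)
  b3 <- bootstrap_lst(sp, d, B = 25, seed = 8, fit = f,
                      coefficients = FALSE)
  expect_identical(b2$param_ci, b3$param_ci)
  b4 <- bootstrap_lst(sp, d, B = 25, seed = 9, fit = f,
                      coefficients = FALSE)
  expect_false(identical(b2$param_ci, b4$param_ci))
})
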