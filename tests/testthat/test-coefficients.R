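test_that("reliability boundary cases", {
  sp <- lst_spec(3, 4, 1)
  p <- random_params(sp, seed = 2)
  p$var_E[1, 1, 1] <- 1e-300
  expect_equal(reliability(p, sp, 1, 1, 1), 1)
  # all structural variance gone: reliability 0
  p2 <- random_params(sp, seed = 2)
  p2$phi_T[] <- diag(1e-300, 3)
  p2$var_SR[] <- 1e-300
  expect_equal(reliability(p2, sp, 1, 1, 1), 0, tolerance = 1e-12)
})

test_that("occasion specificity boundaries and complements", {
  sp <- lst_spec(3, 4, 1)
  # no trait variance, no carry-over: all true variance occasion-specific
  p <- random_params(sp, seed = 8)
  p$beta_O[] <- 0
  p$phi_T[] <- diag(1e-300, 3)
  expect_equal(occasion_specificity(p, sp, 2, 1, 3), 1, tolerance = 1e-10)
  # no state-residual variance: occasion specificity 0
  p2 <- random_params(sp, seed = 8)
  p2$var_SR[] <- 1e-300
  expect_equal(occasion_specificity(p2, sp, 2, 1, 3), 0, tolerance = 1e-10)
})

test_that("sum-to-one identities hold for random parameter sets", {
  for (s in 1:10) {
    K <- 1 + s %% 2
    sp <- lst_spec(3, 4, K)
    p <- random_params(sp, seed = 100 + s)
    for (k in seq_len(K)) for (i in 1:3) for (l in 2:4) {
      os <- occasion_specificity(p, sp, i, k, l)
      tc <- time_consistency(p, sp, i, k, l)
      pr <- predictability_trait1(p, sp, i, k, l)
      up <- unpredictability_trait1(p, sp, i, k, l)
      expect_equal(os + tc, 1, tolerance = 1e-12)
      expect_equal(pr + up, tc, tolerance = 1e-12)
    }
    if (K == 2) {
      nonref <- setdiff(1:2, sp$reference_rater)
      for (i in 1:3) for (l in 1:4) {
        expect_equal(rater_specificity(p, sp, i, l) +
                       rater_consistency(p, sp, i, l), 1,
                     tolerance = 1e-12)
        if (l > 1)
          expect_equal(rater_consistent_pred_trait1(p, sp, i, l) +
                         (1 - rater_consistent_pred_trait1(p, sp, i, l)),
                       1)
      }
    }
  }
})

test_that("unpredictability vanishes without autoregression", {
  sp <- lst_spec(3, 4, 1)
  p <- random_params(sp, seed = 77)
  p$beta_O[] <- 0
  for (l in 2:4) {
    expect_equal(unpredictability_trait1(p, sp, 1, 1, l), 0)
    expect_equal(time_consistency(p, sp, 1, 1, l),
                 predictability_trait1(p, sp, 1, 1, l))
  }
})

test_that("occasion-1 and rater-coefficient preconditions give NA or
           errors", {
  sp1 <- lst_spec(3, 4, 1)
  p1 <- random_params(sp1, seed = 3)
  expect_true(is.na(time_consistency(p1, sp1, 1, 1, 1)))
  expect_true(is.na(predictability_trait1(p1, sp1, 1, 1, 1)))
  expect_true(is.na(state_retest_correlation(p1, sp1, 1, 1, 1)))
  expect_error(rater_specificity(p1, sp1, 1, 2), "two-rater")
  sp2 <- lst_spec(3, 4, 2)
  p2 <- random_params(sp2, seed = 3)
  expect_true(is.na(rater_consistent_pred_trait1(p2, sp2, 1, 1)))
})

test_that("closed-form retest correlations match the generic
           latent-covariance route", {
  worst <- 0
  for (s in 1:25) {
    sp <- lst_spec(3, 4, 1)
    p <- random_params(sp, seed = 300 + s)
    for (i in 1:3) for (l in 2:4) {
      a <- state_retest_correlation(p, sp, i, 1, l)
      b <- lstar:::state_retest_closed_form(p, sp, i, l)
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("retest correlation limits: pure-trait and random-walk cases", {
  sp <- lst_spec(3, 4, 1)
  # beta = 0, trait loadings equal over time, equal variances: the
  # correlation is the trait share and constant in l
  p <- random_params(sp, seed = 55)
  p$beta_O[] <- 0
  for (l in 2:4) p$lambda_T[, 1, l] <- p$lambda_T[, 1, 1]
  p$var_E[] <- p$var_E[, , 1]
  rs <- sapply(2:4, function(l) state_retest_correlation(p, sp, 1, 1, l))
  expect_lt(diff(range(rs)), 1e-12)
  vc <- lstar:::variance_components(p, sp, 1, 1, 2)
  expect_equal(rs[1], vc$trait / vc$true, tolerance = 1e-12)
  # no trait variance, beta = 1, equal SR variances: r(S_1, S_l) = 1/sqrt(l)
  p2 <- random_params(sp, seed = 56)
  p2$phi_T[] <- diag(1e-300, 3)
  p2$beta_O[] <- 1
  p2$var_SR[] <- 0.8
  for (l in 2:4)
    expect_equal(state_retest_correlation(p2, sp, 1, 1, l), 1 / sqrt(l),
                 tolerance = 1e-9)
})

test_that("time consistency matches a Monte-Carlo regression oracle", {
  sp <- lst_spec(3, 4, 1)
  p <- small_single_params(sp)
  set.seed(71)
  n <- 2e5
  TT <- matrix(rnorm(n * 3), n) %*% chol(p$phi_T)
  O <- matrix(0, n, 4)
  O[, 1] <- rnorm(n, 0, sqrt(p$var_SR[1]))
  for (l in 2:4)
    O[, l] <- p$beta_O[l - 1] * O[, l - 1] + rnorm(n, 0, sqrt(p$var_SR[l]))
  i <- 2; l <- 3
  S_il <- p$lambda_T[i, 1, l] * TT[, i] + p$lambda_O[i, 1, l] * O[, l]
  r2 <- summary(lm(S_il ~ TT[, i] + O[, l - 1]))$r.squared
  expect_equal(time_consistency(p, sp, i, 1, l), r2, tolerance = 0.01)
  pred <- summary(lm(S_il ~ TT[, i]))$r.squared
  expect_equal(predictability_trait1(p, sp, i, 1, l), pred,
               tolerance = 0.01)
})

test_that("rater coefficients hit their boundary cases", {
  sp <- lst_spec(3, 4, 2)
  p <- random_params(sp, seed = 91)
  I <- 3
  # vanish the rater-specific factors: perfect agreement
  p0 <- p
  p0$phi_T[I + 1:I, ] <- 0; p0$phi_T[, I + 1:I] <- 0
  diag(p0$phi_T)[I + 1:I] <- 1e-300
  p0$var_SRPS[] <- 1e-300
  expect_equal(rater_consistency(p0, sp, 2, 3), 1, tolerance = 1e-10)
  expect_equal(rater_consistent_pred_trait1(p0, sp, 2, 3), 1,
               tolerance = 1e-10)
  expect_equal(rater_consistent_occasion_specificity(p0, sp, 2, 3), 1,
               tolerance = 1e-10)
  # no shared trait loading: RConPred = 0
  p1 <- p
  p1$lambda_T[2, setdiff(1:2, sp$reference_rater), 3] <- 0
  expect_equal(rater_consistent_pred_trait1(p1, sp, 2, 3), 0)
  # zero autoregressions collapse RConTCon onto RConPred
  p2 <- p
  p2$beta_O[] <- 0; p2$beta_OPS[] <- 0
  for (i in 1:3) for (l in 2:4)
    expect_equal(rater_consistent_time_consistency(p2, sp, i, l),
                 rater_consistent_pred_trait1(p2, sp, i, l),
                 tolerance = 1e-12)
})

test_that("rater-consistent occasion specificity is constant over
           occasions under invariance", {
  sp <- lst_spec(3, 4, 2)
  p <- random_params(sp, seed = 15)
  for (i in 1:3) {
    v <- sapply(1:4, function(l)
      rater_consistent_occasion_specificity(p, sp, i, l))
    expect_lt(diff(range(v)), 1e-12)
  }
})

test_that("coefficients are invariant to a common rescaling of the
           observed variables", {
  sp <- lst_spec(3, 4, 2)
  p <- random_params(sp, seed = 121)
  c0 <- coefficient_table(p, spec = sp)
  # rescale all observed variables by c: loadings fixed at 1 absorb the
  # scale into the factor variances, free loadings stay put
  cc <- 2.5
  p2 <- p
  p2$a <- p$a * cc
  p2$var_E <- p$var_E * cc^2
  M <- nrow(p$phi_T)
  p2$phi_T <- p$phi_T * cc^2
  p2$var_SR <- p$var_SR * cc^2
  p2$var_SRPS <- p$var_SRPS * cc^2
  c2 <- coefficient_table(p2, spec = sp)
  num <- vapply(c0, is.numeric, TRUE)
  expect_equal(as.matrix(c2[, num]), as.matrix(c0[, num]),
               tolerance = 1e-10)
})

test_that("coefficient table carries the table conventions, identities and
           CSV round trip", {
  sp <- lst_spec(3, 4, 2)
  p <- example_parameters(sp)
  tab <- coefficient_table(p, spec = sp)
  expect_identical(nrow(tab), 24L)
  occ1 <- tab$occasion == 1
  # occasion-1 convention: TCon = Pred = 1 - OS; UPred undefined
  expect_equal(tab$TCon[occ1], 1 - tab$OS[occ1], tolerance = 1e-12)
  expect_equal(tab$TCon[occ1], tab$Pred_trait1[occ1], tolerance = 1e-12)
  expect_true(all(is.na(tab$UPred_trait1[occ1])))
  # strict contract variant
  tab0 <- coefficient_table(p, spec = sp, occasion1_convention = FALSE)
  expect_true(all(is.na(tab0$TCon[tab0$occasion == 1])))
  # identities in every defined row
  late <- tab$occasion > 1
  expect_equal(tab$OS[late] + tab$TCon[late], rep(1, sum(late)),
               tolerance = 1e-12)
  expect_equal(tab$Pred_trait1[late] + tab$UPred_trait1[late],
               tab$TCon[late], tolerance = 1e-12)
  nonref <- tab$rater != sp$reference_rater
  expect_equal(tab$RS[nonref] + tab$RCon[nonref], rep(1, sum(nonref)),
               tolerance = 1e-12)
  expect_true(all(is.na(tab$RS[!nonref])))
  expect_equal(tab$rcon_corr[nonref], sqrt(tab$RCon[nonref]))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_coefficient_table(tab, f)
  back <- read.csv(f)
  expect_equal(back$Rel, tab$Rel, tolerance = 1e-9)
  expect_equal(back$RCon, tab$RCon, tolerance = 1e-9)
})

test_that("coefficient table refuses a non-converged fit and attaches
           bootstrap intervals when given", {
  sp <- lst_spec(3, 2, 1)
  p <- small_single_params(sp)
  d <- simulate_lst(p, sp, 150, seed = 5)
  f <- fit_lst(sp, d, se = FALSE, indices = FALSE)
  bad <- f
  bad$converged <- FALSE
  expect_error(coefficient_table(bad), "non-converged")
  b <- bootstrap_lst(sp, d, B = 20, seed = 2, fit = f)
  tab <- coefficient_table(f, cis = b)
  defined <- !is.na(tab$Rel)
  expect_true(all(!is.na(tab$Rel_lower[defined])))
  expect_true(all(tab$Rel_lower <= tab$Rel_upper, na.rm = TRUE))
  # one CI pair per defined cell, none for undefined cells
  expect_true(all(is.na(tab$UPred_trait1_lower[tab$occasion == 1])))
})
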