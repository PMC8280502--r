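test_that("simulation is reproducible under seed and varies across seeds", {
  sp <- lst_spec(3, 4, 2)
  p <- example_parameters(sp)
  d1 <- simulate_lst(p, sp, 100, study_missingness(sp), seed = 12)
  d2 <- simulate_lst(p, sp, 100, study_missingness(sp), seed = 12)
  d3 <- simulate_lst(p, sp, 100, study_missingness(sp), seed = 13)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, d3$values))
  # masking uses its own sub-stream: the observed responses are identical
  # with and without missingness
  d4 <- simulate_lst(p, sp, 100, seed = 12)
  obs <- !is.na(d1$values)
  expect_identical(d1$values[obs], d4$values[obs])
})

test_that("zero variances reproduce the intercepts exactly", {
  sp <- lst_spec(2, 2, 1)
  p <- lst_parameters(sp,
    a = array(c(1, 2, 3, 4), c(2, 1, 2)),
    lambda_T = array(1, c(2, 1, 2)),
    lambda_O = array(c(1, 0.5), c(2, 1, 2)),
    phi_T = diag(0, 2), beta_O = 0.4, var_SR = c(0, 0),
    var_E = array(0, c(2, 1, 2)))
  d <- simulate_lst(p, sp, 20, seed = 1)
  expect_equal(unname(d$values),
               matrix(rep(c(1, 2, 3, 4), each = 20), 20))
})

test_that("study-profile wave counts fall within binomial 99% bounds", {
  sp <- lst_spec(3, 4, 2)
  p <- example_parameters(sp)
  d <- simulate_lst(p, sp, 575, study_missingness(sp), seed = 2024)
  targets <- c(558, 463, 428, 429)
  parents <- c(405, 384, 341, 323)
  for (l in 1:4) {
    for (k in 1:2) {
      expected <- if (k == 1) targets[l] else parents[l]
      pr <- expected / 575
      col <- obs_index(sp, 1, k, l)
      n_obs <- sum(!is.na(d$values[, col]))
      half <- qnorm(0.995) * sqrt(575 * pr * (1 - pr))
      expect_gt(n_obs, expected - half - 1)
      expect_lt(n_obs, expected + half + 1)
    }
  }
  # a whole rater-wave is missing together
  for (k in 1:2) for (l in 1:4) {
    cols <- sapply(1:3, function(i) obs_index(sp, i, k, l))
    miss <- is.na(d$values[, cols])
    expect_true(all(rowSums(miss) %in% c(0, 3)))
  }
})

test_that("monotone dropout produces non-increasing participation and no
           returns", {
  sp <- lst_spec(3, 4, 1)
  p <- example_parameters_single(sp)
  rates <- matrix(c(1, 0.8, 0.6, 0.5), 1)
  d <- simulate_lst(p, sp, 800,
                    missingness_spec("monotone", rates = rates), seed = 31)
  part <- sapply(1:4, function(l)
    !is.na(d$values[, obs_index(sp, 1, 1, l)]))
  # once out, never back
  expect_true(all(part[, 2] >= part[, 3]))
  expect_true(all(part[, 3] >= part[, 4]))
  expect_true(all(diff(colSums(part)) <= 0))
  # increasing rates are rejected
  expect_error(missingness_spec("monotone", rates = matrix(c(0.5, 0.9), 1)),
               "non-increasing")
})

test_that("MCAR masking leaves observed-cell means unchanged", {
  sp <- lst_spec(3, 4, 1)
  p <- example_parameters_single(sp)
  n <- 30000
  d_full <- simulate_lst(p, sp, n, seed = 8)
  d_miss <- simulate_lst(p, sp, n, study_missingness(sp), seed = 8)
  m_full <- colMeans(d_full$values)
  m_miss <- colMeans(d_miss$values, na.rm = TRUE)
  sd_cols <- apply(d_full$values, 2, sd)
  z <- abs(m_full - m_miss) / (sd_cols / sqrt(colSums(!is.na(d_miss$values))))
  expect_lt(max(z), 4)
})

test_that("generated occasion factors have the implied lag-1
           autocorrelation", {
  sp <- lst_spec(3, 4, 1)
  p <- example_parameters_single(sp)
  set.seed(77)
  n <- 1e5
  O <- matrix(0, n, 4)
  O[, 1] <- rnorm(n, 0, sqrt(p$var_SR[1]))
  for (l in 2:4)
    O[, l] <- p$beta_O[l - 1] * O[, l - 1] + rnorm(n, 0, sqrt(p$var_SR[l]))
  vO <- diag(ar_factor_cov(p$beta_O, p$var_SR))
  for (l in 2:4) {
    r_theory <- p$beta_O[l - 1] * sqrt(vO[l - 1] / vO[l])
    expect_equal(cor(O[, l - 1], O[, l]), r_theory, tolerance = 0.02)
  }
})

test_that("a non-positive-semidefinite trait block is rejected with a
           named error", {
  sp <- lst_spec(3, 4, 1)
  p <- example_parameters_single(sp)
  p$phi_T[1, 2] <- p$phi_T[2, 1] <- 5   # breaks PSD
  expect_error(simulate_lst(p, sp, 10, seed = 1), "phi_T")
})

test_that("the packaged example parameters show the intended coefficient
           profile and serialize identically", {
  sp <- lst_spec(3, 4, 2)
  p <- example_parameters(sp)
  tab <- coefficient_table(p, spec = sp)
  ref <- sp$reference_rater
  tgt <- tab[tab$rater == ref & tab$occasion > 1, ]
  par <- tab[tab$rater != ref & tab$occasion > 1, ]
  expect_true(all(tgt$UPred_trait1 > 0))
  expect_true(all(par$UPred_trait1 < 0.01))
  expect_true(all(tab$RS[tab$rater != ref] >= 0.75 &
                    tab$RS[tab$rater != ref] <= 0.95))
  # deterministic and serialization-stable
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_parameters(p, sp, f)
  p2 <- read_parameters(f, sp)
  expect_equal(flatten_parameters(p2, sp), flatten_parameters(p, sp),
               tolerance = 1e-9)
  expect_identical(flatten_parameters(example_parameters(sp), sp),
                   flatten_parameters(p, sp))
})

test_that("panel CSV round trip preserves values and missingness", {
  sp <- lst_spec(3, 4, 2)
  p <- example_parameters(sp)
  d <- simulate_lst(p, sp, 50, study_missingness(sp), seed = 4)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_panel_csv(d, f)
  d2 <- read_panel_csv(f, sp)
  expect_equal(unname(d2$values), unname(d$values), tolerance = 1e-6)
  expect_equal(d2$dyad_id, d$dyad_id)
})

test_that("rows with no observed values are dropped with a message", {
  sp <- lst_spec(2, 2, 1)
  Y <- matrix(rnorm(12), 3, 4)
  Y[2, ] <- NA
  colnames(Y) <- obs_names(sp)
  expect_message(d <- lst_panel(Y, sp), "dropped")
  expect_identical(nrow(d$values), 2L)
  expect_identical(attr(d, "n_dropped"), 1L)
})
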