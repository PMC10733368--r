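test_that("signal-dependent noise ratio is affine in |e| and even", {
  m <- exp1_learning_mle()
  expect_equal(sd_ratio(0, m), 122.2)
  expect_equal(sd_ratio(30, m), 363.85)
  expect_equal(sd_ratio(-30, m), sd_ratio(30, m))
  m0 <- mle_params(gain = 1e5, ratio_sv = 50, constant_sigma = TRUE)
  expect_equal(sd_ratio(c(-40, 0, 40), m0), rep(50, 3))
})

test_that("single-cursor MLE response shrinks, saturates and stays odd", {
  m <- exp1_learning_mle()
  expect_identical(mle_single(0, m), 0)
  expect_equal(mle_single(-20, m), -mle_single(20, m))
  # high-precision reference values at the printed fit
  expect_equal(mle_single(c(7.5, 15, 30, 45), m),
               c(66.63752946, 75.25123879, 67.14363778, 56.75982902),
               tolerance = 1e-8)
  # saturation: the response is non-monotonic over the tested range
  expect_gt(mle_single(15, m), mle_single(45, m))

  # constant-sigma (ordinary MLE) limit is exactly linear
  m0 <- mle_params(gain = 1e5, ratio_sv = 50, constant_sigma = TRUE)
  e <- c(-45, -7.5, 1, 14, 40)
  expect_equal(mle_single(e, m0), e * (1e5 / (1 + 50^2)))
})

test_that("multi-cursor MLE reduces to the single form and accumulates evidence", {
  m <- exp1_learning_mle()
  for (e in c(-30, 7.5, 45)) expect_equal(mle_multi(e, m), mle_single(e, m))
  expect_identical(mle_multi(c(0, 0, 0), m), 0)
  expect_equal(mle_multi(-c(15, 30), m), -mle_multi(c(15, 30), m))

  # duplicated cursors are additional observations: response strictly grows
  r1 <- mle_multi(15, m)
  r2 <- mle_multi(rep(15, 2), m)
  r5 <- mle_multi(rep(15, 5), m)
  expect_lt(r1, r2)
  expect_lt(r2, r5)
})

test_that("only the gain and noise ratios are identifiable", {
  e_sets <- list(7.5, c(15, -30), c(10, 20, 40))
  a <- mle_params_absolute(gain = 2.963e5, sigma_p = 1, sigma_v = 122.2,
                           k_v = 8.055)
  b <- mle_params_absolute(gain = 2.963e5, sigma_p = 3.7, sigma_v = 3.7 * 122.2,
                           k_v = 3.7 * 8.055)
  for (e in e_sets) expect_equal(mle_multi(e, a), mle_multi(e, b))
  expect_equal(a$ratio_sv, b$ratio_sv)
})

test_that("DN and MLE disagree on duplicated cursors when fit to the same data", {
  e <- exp1_error_grid()
  p <- exp1_learning_dn()
  obs <- analytic_single(e, p)
  fit_mle <- fit_mle_single(e, obs)
  for (ev in c(15, 30, 45)) {
    expect_identical(dn_response(c(ev, ev), p), dn_response(ev, p))
    expect_gt(mle_multi(c(ev, ev), fit_mle$params), mle_single(ev, fit_mle$params))
  }
})

test_that("ordinary-MLE declining-rate ratio is unity for every dispersion", {
  m0 <- mle_params(gain = 2.963e5, ratio_sv = 122.2, constant_sigma = TRUE)
  r <- ordinary_mle_decline_ratio(14, 40, c(0, 7, 20), m0)
  expect_named(r, c("7", "20"))
  expect_equal(as.numeric(r), c(1, 1), tolerance = 1e-12)
  rates <- attr(r, "rates")
  expect_true(all(rates$small[c("7", "20")] > 0))

  # invariant to the parameter values, as long as sigma is error-independent
  r2 <- ordinary_mle_decline_ratio(14, 40, c(0, 7, 20),
                                   mle_params(gain = 3, ratio_sv = 1,
                                              constant_sigma = TRUE),
                                   uncertainty_scaling = 0.2)
  expect_equal(as.numeric(r2), c(1, 1), tolerance = 1e-12)

  # degenerate comparison of a mean size with itself
  r3 <- ordinary_mle_decline_ratio(25, 25, c(0, 7, 20), m0)
  expect_equal(as.numeric(r3), c(1, 1))

  # Monte-Carlo evaluation agrees with the analytic expectation
  r4 <- ordinary_mle_decline_ratio(14, 40, c(0, 7, 20), m0,
                                   n_draws = 20000, seed = 7)
  expect_equal(as.numeric(r4), c(1, 1), tolerance = 0.05)

  expect_error(ordinary_mle_decline_ratio(14, 40, c(0, 7), exp1_learning_mle()),
               "constant-sigma")
})

test_that("signal-dependent noise breaks the unit decline ratio", {
  # with per-cursor signal-dependent noise the shrinkage depends on the error
  # sizes in the cloud, so the declining rates at mu = 14 and mu = 40 differ
  m <- exp1_learning_mle()
  rate_at <- function(mu) {
    r <- vapply(c(0, 7, 20), function(sg)
      mle_cloud_response(cloud_spec(mu, sg, 5), m, n_draws = 20000,
                         seed = 31 + sg)$mean, numeric(1))
    declining_rate(stats::setNames(r, c(0, 7, 20)))
  }
  dr <- decline_ratio(rate_at(14), rate_at(40))
  expect_gt(max(abs(dr$ratio_small_over_large - 1)), 0.05)
})
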