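test_that("DN response is zero at zero error, odd, and duplicate-invariant", {
  p <- exp1_learning_dn()
  expect_identical(dn_response(0, p), 0)

  sets <- list(30, c(15, -30), c(7.5, 22.5, 45), c(-45, -30, -15))
  for (e in sets) {
    expect_identical(dn_response(-e, p), -dn_response(e, p))
    expect_identical(dn_response(c(e, e[1]), p), dn_response(e, p))
    expect_identical(dn_response(c(e, e, e), p), dn_response(e, p))
  }
})

test_that("discrete population response matches the closed forms", {
  p <- exp1_learning_dn()
  for (e in c(-45, -30, -15, -7.5, 7.5, 15, 30, 45)) {
    expect_equal(dn_response(e, p), analytic_single(e, p), tolerance = 1e-3)
    expect_equal(dn_response(e, p, normalization = FALSE),
                 linear_response_single(e, p), tolerance = 1e-3)
  }
})

test_that("closed-form single-cursor responses match independent evaluation", {
  # linear limit, hand-computed: sqrt(2*pi)*1e-4*22*10/(360*1e-6)
  p0 <- dn_params(w = 1e-4, k = 1e-6)
  expect_equal(linear_response_single(10, p0), 153.1828390052,
               tolerance = 1e-10)
  expect_identical(linear_response_single(0, p0), 0)
  expect_equal(linear_response_single(20, p0), 2 * linear_response_single(10, p0))

  # saturating curve with the printed learning-response parameters,
  # high-precision reference values
  p <- exp1_learning_dn()
  expect_equal(analytic_single(c(7.5, 15, 30, 45), p),
               c(61.53569826, 80.88620900, 68.22730868, 52.11501006),
               tolerance = 1e-8)
  expect_identical(analytic_single(0, p), 0)
  expect_equal(analytic_single(-33, p), -analytic_single(33, p))
})

test_that("single-cursor response saturates with a peak at the closed-form e*", {
  p <- exp1_learning_dn()
  estar <- analytic_peak(p)
  expect_gt(estar, 0)
  below <- seq(0.5, estar - 0.5, by = 0.5)
  above <- seq(estar + 0.5, 90, by = 0.5)
  expect_true(all(diff(analytic_single(below, p)) > 0))
  expect_true(all(diff(analytic_single(above, p)) < 0))
  # derivative changes sign across e*
  eps <- 1e-4
  expect_gt(analytic_single(estar, p) - analytic_single(estar - eps, p), 0)
  expect_gt(analytic_single(estar, p) - analytic_single(estar + eps, p), 0)
})

test_that("DN response is stable under grid refinement", {
  p <- exp1_learning_dn()
  p2 <- dn_params(p$w, p$k, p$s, M = 2L * p$M - 1L)  # halved spacing
  for (e in list(30, c(15, -30), c(-45, 30, 45))) {
    expect_equal(dn_response(e, p2), dn_response(e, p), tolerance = 1e-5)
  }
})

test_that("DN integration is sub-additive for same-sign cursor pairs", {
  p <- exp1_learning_dn()
  for (e1 in c(15, 30, 45)) for (e2 in c(15, 30, 45)) {
    expect_lt(dn_response(c(e1, e2), p),
              dn_response(e1, p) + dn_response(e2, p))
  }
})

test_that("nonlinearity index is w^2/k and separates learning from feedback", {
  expect_equal(nonlinearity_index(exp1_learning_dn()), 0.3647, tolerance = 5e-4)
  expect_equal(nonlinearity_index(exp1_feedback_dn()), 1.7741e-3,
               tolerance = 5e-5)
  expect_identical(nonlinearity_index(0, k = 1e-6), 0)
  expect_error(nonlinearity_index(1e-4, k = 0), "positive")
  # learning response is > 2 orders of magnitude more nonlinear than feedback
  expect_gt(nonlinearity_index(exp1_learning_dn()) /
              nonlinearity_index(exp1_feedback_dn()), 100)
})

test_that("cloud expectation degenerates correctly and shrinks its SE", {
  p <- exp2_learning_dn()
  r0 <- expected_cloud_response(cloud_spec(14, 0, 5), p, n_draws = 10, seed = 1)
  expect_equal(r0$mean, dn_response(14, p))
  expect_identical(r0$se, 0)

  r1 <- expected_cloud_response(cloud_spec(14, 7, 5), p, n_draws = 500, seed = 2)
  r4 <- expected_cloud_response(cloud_spec(14, 7, 5), p, n_draws = 2000, seed = 3)
  expect_equal(r4$se / r1$se, 0.5, tolerance = 0.35)  # 1/sqrt(n) scaling

  # reproducibility given seed
  r1b <- expected_cloud_response(cloud_spec(14, 7, 5), p, n_draws = 500, seed = 2)
  expect_identical(r1$mean, r1b$mean)
})

test_that("DN response to clouds declines with dispersion, less so at large mean", {
  p <- exp2_learning_dn()
  m14 <- vapply(c(0, 7, 20), function(sg)
    expected_cloud_response(cloud_spec(14, sg, 5), p, n_draws = 4000,
                            seed = 11)$mean, numeric(1))
  m40 <- vapply(c(0, 7, 20), function(sg)
    expected_cloud_response(cloud_spec(40, sg, 5), p, n_draws = 4000,
                            seed = 12)$mean, numeric(1))
  expect_true(all(diff(m14) < 0))  # strictly decreasing in sigma
  rel14 <- (m14[1] - m14[3]) / m14[1]
  rel40 <- (m40[1] - m40[3]) / m40[1]
  expect_gt(rel14, rel40)          # decline is relatively weaker at mu = 40
})
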