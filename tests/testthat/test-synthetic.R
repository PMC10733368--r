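test_that("multi-cursor schedule has the printed design cardinalities", {
  sched <- build_exp1_schedule()
  expect_equal(nrow(sched), 39)
  expect_equal(sum(sched$type == "single"), 9)
  expect_equal(sum(sched$type == "double"), 18)
  expect_equal(sum(sched$type == "triple"), 12)
  expect_equal(n_trials(sched), 1404)
  expect_equal(attr(sched, "cycles"), 9L)
  expect_false(anyDuplicated(sched$condition_id) > 0)
  dd <- sched[sched$type == "double", ]
  expect_true(all(abs(dd$e1) != abs(dd$e2)))
})

test_that("cursor-cloud schedule has the printed design cardinalities", {
  for (mode in c("online", "endpoint")) {
    sched <- build_exp23_schedule(mode)
    expect_equal(nrow(sched), 15)
    expect_equal(n_trials(sched), 720)
    expect_true(all(sched$n_cursors == 5))
    expect_equal(sort(unique(sched$mu)), c(-40, -14, 0, 14, 40))
    expect_equal(sort(unique(sched$sigma)), c(0, 7, 20))
    expect_true(any(sched$mu == 0 & sched$sigma == 0))  # pure null feedback
    expect_true(all(sched$feedback_mode == mode))
  }
})

test_that("collapsed condition sets follow the sign-pairing rules", {
  s1 <- collapsed_schedule(build_exp1_schedule())
  # 9 singles -> 4 mirror pairs + e = 0; 18 doubles -> 9 orbits;
  # 12 triples -> 6 orbits
  expect_equal(nrow(s1), 20)
  expect_equal(sum(s1$type == "single"), 5)
  expect_equal(sum(s1$type == "double"), 9)
  expect_equal(sum(s1$type == "triple"), 6)
  # triple representatives carry the positively oriented fixed cursors
  expect_true(all(s1$e2[s1$type == "triple"] == 30))

  s2 <- collapsed_schedule(build_exp23_schedule("online"))
  expect_equal(nrow(s2), 9)  # mu = 0 x 3 sigma self-mirrors + 6 orbit reps
  expect_true(all(s2$mu >= 0))
})

test_that("noiseless simulation reproduces the generating model exactly", {
  sched <- build_exp1_schedule()
  p <- exp1_learning_dn()
  tab <- simulate_responses(sched, p, noise_sd = 0, n_participants = 2,
                            seed = 5)
  expect_equal(nrow(tab), 2 * 39)
  conds <- schedule_conditions(sched)
  for (id in sched$condition_id[c(1, 12, 35)]) {
    expect_equal(unique(tab$response[tab$condition_id == id]),
                 dn_response(conds[[id]], p))
  }
  # zero-dispersion clouds equal the single-cursor response at mu
  s2 <- build_exp23_schedule("online")
  tab2 <- simulate_responses(s2, p, noise_sd = 0, n_participants = 2, seed = 5)
  id0 <- s2$condition_id[s2$mu == 14 & s2$sigma == 0]
  expect_equal(unique(round(tab2$response[tab2$condition_id == id0], 10)),
               round(dn_response(14, p), 10))
})

test_that("simulation is reproducible and exchangeable across participants", {
  sched <- build_exp23_schedule("online")
  p <- exp2_learning_dn()
  a <- simulate_responses(sched, p, n_participants = 4, seed = 42)
  b <- simulate_responses(sched, p, n_participants = 4, seed = 42)
  expect_identical(a, b)
  c4 <- simulate_responses(sched, p, n_participants = 4, seed = 43)
  expect_false(identical(a$response, c4$response))

  # across-participant SE shrinks roughly as 1/sqrt(n)
  se_of <- function(n, seed) {
    tab <- simulate_responses(build_exp1_schedule(), exp1_learning_dn(),
                              n_participants = n, seed = seed)
    cm <- condition_means(tab)
    mean(cm$se)
  }
  expect_equal(se_of(32, 7) / se_of(8, 8), 0.5, tolerance = 0.3)
})

test_that("sign-collapsing inverts odd generation and removes offsets", {
  sched <- build_exp1_schedule()
  p <- exp1_learning_dn()
  tab <- simulate_responses(sched, p, noise_sd = 0, n_participants = 1,
                            seed = 1)
  conds <- schedule_conditions(sched)
  # responses are generated oddly, so collapsing reproduces them exactly
  col <- collapse_symmetric(tab, sched)
  for (id in collapsed_schedule(sched)$condition_id) {
    expect_equal(col$response[col$condition_id == id],
                 dn_response(conds[[id]], p))
  }
  # a constant offset cancels in the antisymmetric combination
  tab_off <- tab
  tab_off$response <- tab_off$response + 11.3
  col_off <- collapse_symmetric(tab_off, sched)
  paired <- col$condition_id %in%
    sched$condition_id[!(sched$type == "single" & sched$e1 == 0)]
  expect_equal(col_off$response[paired], col$response[paired])

  # mirrored triples collapse onto a single condition
  expect_equal(sum(grepl("^T", col$condition_id)), 6)

  expect_error(collapse_symmetric(tab, sched[-2, ]), "missing mirror")
})

test_that("response tables and schedules round-trip through CSV", {
  tmp <- withr::local_tempdir()
  sched <- build_exp23_schedule("endpoint")
  f1 <- file.path(tmp, "sched.csv")
  write_schedule_csv(sched, f1)
  back <- read_schedule_csv(f1)
  expect_equal(nrow(back), nrow(sched))
  expect_equal(attr(back, "cycles"), attr(sched, "cycles"))
  expect_equal(back$condition_id, sched$condition_id)

  tab <- simulate_responses(sched, exp3_learning_dn(), n_participants = 2,
                            seed = 3)
  f2 <- file.path(tmp, "resp.csv")
  write_response_csv(tab, f2)
  tab2 <- read_response_csv(f2)
  expect_equal(tab2$response, tab$response)
  expect_error(read_response_csv(f1), "columns")
})

test_that("the full synthetic pipeline recovers the generating parameters", {
  sched <- build_exp1_schedule()
  p <- exp1_learning_dn()
  tab <- simulate_responses(sched, p, n_participants = 8, seed = 2024)
  col <- collapse_symmetric(tab, sched)
  cm <- condition_means(col)
  means <- stats::setNames(cm$mean_response, cm$condition_id)
  singles <- collapsed_schedule(sched)
  singles <- singles[singles$type == "single", ]
  fit <- fit_dn_single(singles$e1, means[singles$condition_id])
  # the gain is well identified; the normalization constant only weakly
  # (its share of the single-cursor denominator is a few percent), so the
  # end-to-end check asserts the gain and the recovered response curve
  expect_lt(relerr(fit$params$w, p$w), 0.10)
  e_chk <- c(7.5, 15, 30, 45)
  expect_lt(max(abs(analytic_single(e_chk, fit$params) /
                      analytic_single(e_chk, p) - 1)), 0.10)
})
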