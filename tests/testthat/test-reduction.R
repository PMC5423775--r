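test_that("initial slope of an exactly linear trace is exact", {
  tr <- data.frame(time = 0:49, fluorescence = 100 - 2 * (0:49))
  expect_equal(as.numeric(initial_slope(tr)), -2, tolerance = 1e-12)
  expect_equal(as.numeric(initial_slope(tr, window = 10)), -2,
               tolerance = 1e-12)
  expect_equal(as.numeric(initial_slope(tr, window = c(0, 20))), -2,
               tolerance = 1e-12)
  expect_error(initial_slope(tr[1:2, ]), "3 points")
})

test_that("initial slope approaches -F0 * k_unf for short windows", {
  tr <- gen_fluorescence_trace(k_unf = 0.002, F0 = 100, noise_sd = 0,
                               dt = 0.1, t_end = 300)
  s <- as.numeric(initial_slope(tr, window = c(0, 2)))
  expect_equal(s, -100 * 0.002, tolerance = 0.01)
})

test_that("noisy slope recovery is within 5% on average at 1% noise", {
  errs <- vapply(1:100, function(s) {
    tr <- gen_fluorescence_trace(k_unf = 0.002, F0 = 100, noise_sd = 1,
                                 dt = 0.2, t_end = 250, seed = 4000 + s)
    as.numeric(initial_slope(tr)) / (-100 * 0.002)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 1), 0.05)
})

test_that("normalization divides by the r = 0 mean and reports replicate SD", {
  rates <- data.frame(r = rep(c(0, 0.2, 0.4), each = 3),
                      rate = c(10, 11, 9, 5, 5, 5, 2, 3, 4))
  cv <- normalize_and_aggregate(rates)
  expect_equal(cv$activity[cv$r == 0], 1)
  expect_equal(cv$sd[cv$r == 0.2], 0)
  expect_equal(cv$activity[cv$r == 0.4], 0.3)
  expect_equal(cv$n_replicates, rep(3L, 3), ignore_attr = TRUE)
  expect_error(normalize_and_aggregate(data.frame(r = c(0.1, 0.2),
                                                  rate = c(1, 2))), "r = 0")
})

test_that("replicate SD estimates have chi-square coverage", {
  # triplicates from N(mu, sigma): 2 * s^2 / sigma^2 ~ chi^2_2
  sds <- vapply(1:500, function(s) {
    set.seed(s)
    rates <- data.frame(r = c(0, 0, 0, 0.5, 0.5, 0.5),
                        rate = c(rnorm(3, 1, 0.001), rnorm(3, 0.5, 0.05)))
    normalize_and_aggregate(rates)$sd[2]
  }, numeric(1))
  stat <- 2 * sds^2 / 0.05^2
  inside <- mean(stat > qchisq(0.025, 2) & stat < qchisq(0.975, 2))
  expect_gt(inside, 0.90)
  expect_lt(inside, 0.99)
})

test_that("threshold fit is exact on noiseless data and recovers m", {
  d <- gen_doping_dataset(list(m = 1), seq(0, 0.9, 0.1), noise_sd = 0,
                          seed = 1)
  ft <- fit_threshold_model(d)
  expect_equal(ft$best_m, 1)
  expect_equal(unname(ft$rss_by_m["1"]), 0, tolerance = 1e-20)
  expect_true(all(ft$rss_by_m[-1] > 0))

  d2 <- gen_doping_dataset(list(m = 2), seq(0, 0.9, 0.1), noise_sd = 0.02,
                           seed = 2)
  expect_equal(fit_threshold_model(d2)$best_m, 2)
  expect_error(fit_threshold_model(gen_doping_dataset(list(m = 1), c(0, 0.5),
                                                      seed = 1)),
               "3 distinct")
})

test_that("bootstrap selection frequencies concentrate on the true m", {
  d <- gen_doping_dataset(list(m = 1), seq(0, 0.9, 0.1), noise_sd = 0.02,
                          seed = 3)
  ft <- fit_threshold_model(d, n_bootstrap = 100, seed = 9)
  expect_equal(sum(ft$bootstrap_freq), 1)
  expect_gt(ft$bootstrap_freq["1"], 0.9)
})

test_that("threshold fit on simulator-generated data selects the hand-over-hand m = 1", {
  # closes the loop between the mechanistic simulator and the closed-form model
  d <- gen_doping_dataset(list(params = motor_params(), n_complexes = 200,
                               t_end = 150),
                          r_grid = c(0, 0.15, 0.3, 0.5), reps = 2,
                          noise_sd = 0.005, seed = 7)
  expect_equal(fit_threshold_model(d)$best_m, 1)
})

test_that("escape leaves systematically positive residuals against the m = 1 curve", {
  p <- motor_params(k_escape = 2, k_reengage = 2)
  act <- vapply(c(0.2, 0.3, 0.4), function(r)
    ensemble_activity(p, r, 400, 120, seed = 31)$activity, numeric(1))
  resid <- act - (1 - c(0.2, 0.3, 0.4))^6
  expect_true(all(resid > 0))
})

test_that("escape-rate fit hits the boundary for no-escape data and profiles the objective", {
  d <- gen_doping_dataset(list(m = 1), c(0, 0.2, 0.4), reps = 2,
                          noise_sd = 0, seed = 1)
  ef <- fit_escape_model(d, motor_params(k_reengage = 3),
                         k_escape_grid = c(0, 1, 4), n_complexes = 150,
                         t_end = 100, seed = 13)
  expect_equal(ef$k_escape_hat, 0)
  expect_equal(nrow(ef$profile), 3)
  expect_true(all(is.finite(ef$profile$objective)))
  # fitted curves shift monotonically upward in k_escape at fixed r
  a_by_k <- with(ef$curves[ef$curves$r == 0.4, ],
                 activity[order(k_escape)])
  expect_true(all(diff(a_by_k) > -0.05))
})

test_that("degradation quantification is exact on exponentials and flat on controls", {
  bt <- gen_band_timecourse(0.1, seq(0, 14, 2), noise_sd = 0)
  qd <- quantify_degradation(bt)
  rx <- qd$rates[qd$rates$condition == "reaction", ]
  expect_equal(rx$k_deg, 0.1, tolerance = 1e-10)
  ctrl <- qd$rates[qd$rates$condition == "control", ]
  expect_lt(abs(ctrl$k_deg), 3 * max(ctrl$se, 1e-12))
  expect_equal(qd$table$fraction[qd$table$time == 0], c(1, 1))
  bad <- data.frame(time = 0:3, intensity = c(1, 0.5, -0.1, 0.2))
  expect_error(quantify_degradation(bad), "positive")
})

test_that("noisy degradation rates are recovered within 10% on average", {
  ks <- vapply(1:100, function(s) {
    bt <- gen_band_timecourse(0.1, seq(0, 14, 2), noise_sd = 0.02,
                              seed = 6000 + s, include_control = FALSE)
    quantify_degradation(bt)$rates$k_deg
  }, numeric(1))
  expect_lt(abs(mean(ks) / 0.1 - 1), 0.1)
})
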