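test_that("helix fit round-trips the generator exactly at zero jitter", {
  ph <- gen_pore_loop_helix(rise = 13, twist = 60, jitter_sd = 0)
  for (lp in unique(ph$loop)) {
    f <- fit_helix(ph, lp)
    expect_equal(f$rise, 13, tolerance = 1e-9)
    expect_equal(f$twist, 60, tolerance = 1e-9)
    expect_equal(f$pitch, 13 * 360 / 60, tolerance = 1e-9)
    expect_equal(f$seam_index, attr(ph, "seam_index"))
    expect_lt(f$rms_residual, 1e-9)
  }
})

test_that("helix fit recovers other programmed geometries", {
  ph <- gen_pore_loop_helix(rise = 8, twist = 45, radius = 11, jitter_sd = 0,
                            seam_index = 3)
  f <- fit_helix(ph, "NBD1-PL1")
  expect_equal(f$rise, 8, tolerance = 1e-9)
  expect_equal(f$twist, 45, tolerance = 1e-9)
  expect_equal(f$radius, 11, tolerance = 1e-9)
  expect_equal(f$seam_index, 3)
})

test_that("helix parameters are invariant under rigid-body transforms", {
  ph <- gen_pore_loop_helix(jitter_sd = 0.3, seed = 8)
  f0 <- fit_helix(ph, "NBD2-PL1")
  f1 <- fit_helix(rigid_transform_pls(ph), "NBD2-PL1")
  expect_equal(f1$rise, f0$rise, tolerance = 1e-9)
  expect_equal(f1$twist, f0$twist, tolerance = 1e-9)
  expect_equal(f1$rms_residual, f0$rms_residual, tolerance = 1e-9)
  expect_equal(f1$seam_index, f0$seam_index)
})

test_that("jittered helix fits recover the programmed parameters within 5%", {
  # recovery study at 0.5 A jitter: the estimator is unbiased, so the study
  # recovers rise and twist within 5%; most individual fits land there too
  res <- vapply(1:100, function(s) {
    ph <- gen_pore_loop_helix(jitter_sd = 0.5, seed = s)
    f <- fit_helix(ph, "NBD1-PL1")
    c(f$rise, f$twist)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) / 13 - 1), 0.05)
  expect_lt(abs(mean(res[2, ]) / 60 - 1), 0.05)
  expect_gte(mean(abs(res[1, ] / 13 - 1) < 0.05), 0.75)
  expect_gte(mean(abs(res[2, ] / 60 - 1) < 0.05), 0.75)
})

test_that("degenerate helix inputs are refused", {
  line <- data.frame(protomer = 1:5, loop = "L",
                     x = 1:5, y = 2 * (1:5), z = 3 * (1:5))
  expect_error(fit_helix(line, "L"))
  expect_error(fit_helix(gen_pore_loop_helix()), "loop")
})

test_that("aperture implements the widest-cylinder (minimum radius) rule", {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  hexagon <- cbind(14 * cos(ang), 14 * sin(ang), 0)
  expect_equal(aperture(hexagon, axis_point = c(0, 0, 0)), 28,
               tolerance = 1e-12)
  pulled <- hexagon
  pulled[1, ] <- c(9, 0, 0)
  expect_equal(aperture(pulled, axis_point = c(0, 0, 0)), 18,
               tolerance = 1e-12)
  expect_error(aperture(hexagon[1:2, ]), "3 points")
})

test_that("aperture agrees with the brute-force inscribed-circle oracle", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:9, 1)
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, 6, 16)
    ring <- cbind(rad * cos(ang), rad * sin(ang), rnorm(n, 0, 0.5))
    got <- aperture(ring, axis_point = c(0, 0, 0))
    oracle <- aperture_oracle(ring, resolution = 0.005)
    expect_lt(abs(got - oracle), 2 * 0.005)
  }
})

test_that("pore tilt recovers programmed angles exactly and under jitter", {
  tw <- two_ring_fixture(0)
  expect_equal(pore_tilt(tw$ring1, tw$ring2), 0, tolerance = 1e-9)
  tw <- two_ring_fixture(45, h = 20)
  expect_equal(pore_tilt(tw$ring1, tw$ring2), 45, tolerance = 1e-9)
  set.seed(14)
  tilts <- vapply(1:50, function(i) {
    tw <- two_ring_fixture(15, radius = 14, jitter_sd = 0.3, n = 12)
    pore_tilt(tw$ring1, tw$ring2)
  }, numeric(1))
  expect_lt(abs(mean(tilts) - 15), 0.5)
  expect_lt(sd(tilts), 0.5)
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(pore_tilt(line, two_ring_fixture(0)$ring1), "collinear")
})

test_that("grip extent is an axial projection span, invariant to rigid motion", {
  two <- rbind(c(0, 0, 0), c(0, 0, 80))
  expect_equal(grip_extent(two), 80, tolerance = 1e-9)
  # 5 + 5 staircase points across both rings: projection span equals the
  # direct max - min of axial coordinates
  ph <- gen_pore_loop_helix(jitter_sd = 0)
  grip <- rbind(pore_loop_coords(ph, "NBD1-PL1", protomers = 1:5),
                pore_loop_coords(ph, "NBD2-PL1", protomers = 1:5))
  expect_equal(grip_extent(grip, axis = c(0, 0, 1)),
               max(grip[, 3]) - min(grip[, 3]), tolerance = 1e-12)
  expect_equal(grip_extent(grip, axis = c(0, 0, 1)), 80, tolerance = 1e-12)
  moved <- rigid_transform(grip)
  expect_equal(grip_extent(moved, axis = rigid_transform(rbind(c(0, 0, 0),
                                                               c(0, 0, 1)),
                                                         translation = c(0, 0, 0))[2, ]),
               80, tolerance = 1e-9)
})

test_that("layer-line prediction and measurement agree on synthetic filaments", {
  expect_equal(layer_line(55), 1 / 55)
  expect_equal(layer_line(110), layer_line(55) / 2)
  z <- seq(0, 549, by = 1)
  prof <- 1 + cos(2 * pi * z / 55)
  got <- measure_layer_line(prof, spacing = 1)
  expect_lt(abs(got - 1 / 55), attr(got, "bin_width"))
  # noisy profile, period 40
  set.seed(2)
  prof2 <- 1 + cos(2 * pi * z / 40) + rnorm(length(z), 0, 0.2)
  got2 <- measure_layer_line(prof2, spacing = 1)
  expect_lt(abs(got2 - 1 / 40), attr(got2, "bin_width"))
  expect_error(measure_layer_line(rep(1, 100)), "maximum")
  expect_error(layer_line(0), "positive")
})
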