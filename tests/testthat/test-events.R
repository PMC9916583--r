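test_that("gait events interpolate threshold crossings of a trapezoid", {
  tt <- seq(0, 3, by = 0.005)
  fz <- pmax(0, pmin(1, (tt - 1) / 0.02, (1.6 - tt) / 0.02)) * 800
  ev <- detect_gait_events(tt, fz, threshold = 20, foot = "left")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_strike, 1.0, tolerance = 0.005)
  expect_equal(ev$t_toeoff, 1.6, tolerance = 0.005)
  expect_true(is.na(ev$t_next_strike))
  expect_error(detect_gait_events(tt, rep(0, length(tt))), "no events")
})

test_that("debounce collapses threshold-grazing chatter into one stance", {
  tt <- seq(0, 2, by = 0.001)
  fz <- ifelse(tt > 0.5 & tt < 1.5, 600, 0)
  # inject 10 ms dropouts around the strike
  fz[tt > 0.52 & tt < 0.53] <- 5
  fz[tt > 0.55 & tt < 0.56] <- 12
  ev <- detect_gait_events(tt, fz, threshold = 20, debounce = 0.05)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_strike, 0.5, tolerance = 0.01)
  expect_equal(ev$t_toeoff, 1.5, tolerance = 0.01)
})

test_that("event detection is invariant to a uniform time shift", {
  tt <- seq(0, 3, by = 0.005)
  fz <- pmax(0, sin(2 * pi * (tt - 0.4) / 2)) * 700
  e1 <- detect_gait_events(tt, fz)
  e2 <- detect_gait_events(tt + 11.3, fz)
  expect_equal(e2$t_strike - e1$t_strike, rep(11.3, nrow(e1)),
               tolerance = 1e-9)
  ok <- stats::complete.cases(e1$t_toeoff)
  expect_equal(e2$t_toeoff[ok] - e1$t_toeoff[ok], rep(11.3, sum(ok)),
               tolerance = 1e-9)
})

test_that("braking/propulsion split at the posterior-to-anterior zero crossing", {
  tt <- seq(0, 2, by = 0.002)
  ap <- ifelse(tt < 1, -sin(pi * tt), sin(pi * (tt - 1)))
  bp <- split_braking_propulsion(tt, ap, stance = c(0, 2))
  expect_equal(bp$t_boundary, 1, tolerance = 0.002)
  expect_equal(bp$braking, c(0, bp$t_boundary))
  expect_equal(bp$propulsion, c(bp$t_boundary, 2))
  # all-posterior stance: warning and empty propulsion
  expect_warning(bp2 <- split_braking_propulsion(tt, -abs(ap) - 0.1,
                                                 stance = c(0, 2)),
                 "posterior")
  expect_true(is.na(bp2$t_boundary))
  expect_null(bp2$propulsion)
})

test_that("maneuver phases find the 3 s hold and honour activation timestamps", {
  mt <- generate_maneuver_torso("sit_to_stand", seed = 3)
  ph <- detect_maneuver_phases(mt$time, mt$torso_deg, "sit_to_stand",
                               activation_time = mt$activation_time)
  expect_equal(ph$t_hold_end, mt$activation_time)  # passthrough
  expect_equal(ph$hold_duration, 3.0, tolerance = 0.1)
  expect_gt(ph$t_complete, ph$t_hold_end)
  # plateau-only fallback when no activation stamp exists
  ph2 <- detect_maneuver_phases(mt$time, mt$torso_deg, "sit_to_stand")
  expect_equal(ph2$t_hold_end, mt$activation_time, tolerance = 0.3)
  # backward lean for stand-to-sit
  ms <- generate_maneuver_torso("stand_to_sit", seed = 4)
  phs <- detect_maneuver_phases(ms$time, ms$torso_deg, "stand_to_sit",
                                activation_time = ms$activation_time)
  expect_equal(phs$hold_duration, 3.0, tolerance = 0.1)
  # a pure ramp has no plateau structure
  expect_error(detect_maneuver_phases(seq(0, 5, by = 0.01),
                                      seq(0, 50, length.out = 501),
                                      "sit_to_stand"),
               "plateau")
})

test_that("time normalization is exact for ramps and interpolation-accurate for sines", {
  tt <- seq(0, 2, by = 0.01)
  ramp <- 3 * tt
  tn <- time_normalize(tt, ramp, c(0, 2))
  expect_equal(tn$percent, seq(0, 100, 1))
  expect_equal(tn$values, 3 * seq(0, 2, length.out = 101), tolerance = 1e-12)
  cn <- time_normalize(tt, rep(2.5, length(tt)), c(0.3, 1.7))
  expect_true(all(cn$values == 2.5))
  sn <- time_normalize(tt, sin(2 * pi * tt), c(0, 2), n_points = 101)
  expect_lt(max(abs(sn$values - sin(2 * pi * seq(0, 2, length.out = 101)))),
            (2 * pi * 0.01)^2)
  expect_error(time_normalize(tt, ramp, c(1, 1)), "degenerate")
  expect_error(time_normalize(tt, ramp, c(-1, 2)), "support")
})

test_that("ensemble statistics: mean, n-1 SD, degenerate single trial", {
  x <- sin(seq(0, 2 * pi, length.out = 101))
  e1 <- ensemble_average(list(x, x, x))
  expect_equal(e1$mean, x)
  expect_true(all(e1$sd == 0))
  e2 <- ensemble_average(list(x, -x))
  expect_equal(e2$mean, rep(0, 101))
  expect_equal(e2$sd, abs(x) * sqrt(2), tolerance = 1e-12)
  expect_warning(e3 <- ensemble_average(list(x)), "single trial")
  expect_true(all(e3$sd == 0))
  # permutation invariance
  set.seed(8)
  trials <- lapply(1:5, function(i) x + rnorm(101, 0, 0.1))
  ea <- ensemble_average(trials)
  eb <- ensemble_average(rev(trials))
  expect_equal(ea$mean, eb$mean)
  expect_equal(ea$sd, eb$sd)
})

test_that("peak summaries are means of per-trial peaks", {
  trials <- list(rep(50, 101), rep(51, 101), rep(49, 101))
  pk <- peak_summary(trials, "knee_flexion")
  expect_equal(pk$mean, 50)
  expect_equal(pk$sd, 1)
  mins <- list(seq(-0.17, 0, length.out = 101),
               seq(-0.18, 0, length.out = 101),
               seq(-0.16, 0, length.out = 101))
  pn <- peak_summary(mins, direction = "min")
  expect_equal(pn$mean, -0.17)
  expect_equal(pn$sd, 0.01, tolerance = 1e-12)
  expect_error(peak_summary(trials, window = c(200, 300)), "empty phase")
  # identical aligned trials: mean of peaks equals the peak of the mean
  x <- sin(seq(0, pi, length.out = 101))
  expect_equal(peak_summary(list(x, x))$mean,
               max(ensemble_average(list(x, x))$mean))
})
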