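test_that("Butterworth responses: DC gain, cutoff gain, highpass of constants", {
  fs <- 2000
  tt <- seq(0, 4, by = 1 / fs)
  # lowpass passes DC exactly
  const <- rep(3.7, length(tt))
  expect_equal(butterworth_filter(const, "lowpass", cutoff = 15, fs = fs),
               const, tolerance = 1e-9)
  # single-pass gain at the design cutoff is 1/sqrt(2)
  fc <- 15
  x <- sin(2 * pi * fc * tt)
  y <- butterworth_filter(x, "lowpass", cutoff = fc, fs = fs,
                          zero_phase = FALSE)
  gain <- max(abs(y[tt > 2])) / 1
  expect_equal(gain, 1 / sqrt(2), tolerance = 0.01)
  # zero-phase doubles the attenuation: |H|^2 at cutoff = 1/2
  y2 <- butterworth_filter(x, "lowpass", cutoff = fc, fs = fs)
  expect_equal(max(abs(y2[tt > 2 & tt < 3])), 0.5, tolerance = 0.01)
  # highpass of a constant decays to zero
  yh <- butterworth_filter(const, "highpass", cutoff = 30, fs = fs,
                           zero_phase = FALSE)
  expect_lt(max(abs(utils::tail(yh, 1000))), 1e-6)
  expect_error(butterworth_filter(x, "lowpass", cutoff = 1500, fs = fs),
               "Nyquist")
})

test_that("filters are linear and time-invariant", {
  fs <- 500
  set.seed(14)
  x <- rnorm(2000)
  f <- function(v) butterworth_filter(v, "lowpass", cutoff = 10, fs = fs)
  expect_equal(f(3.2 * x), 3.2 * f(x), tolerance = 1e-9)
  y <- f(x)
  # shift-invariance in the interior (away from edge padding)
  xs <- c(rep(0, 100), x)
  ys <- f(xs)
  expect_equal(ys[500:1500 + 100], y[500:1500], tolerance = 1e-6)
})

test_that("GRF conditioning: passband transparency and rolloff attenuation", {
  fs <- 2000
  tt <- seq(0, 2, by = 1 / fs)
  slow <- 500 * (1 - cos(2 * pi * 2 * tt))   # 2 Hz content
  grf <- grf_record(tt, cbind(0, 0, slow), matrix(0, length(tt), 3))
  out <- process_grf(grf)
  mid <- tt > 0.25 & tt < 1.75
  expect_lt(max(abs(out$force[mid, 3] - slow[mid])) / max(slow), 0.005)
  # 100 Hz hum is crushed by the 15 Hz 4th-order (x2 passes) rolloff
  hum <- slow + 50 * sin(2 * pi * 100 * tt)
  grf2 <- grf_record(tt, cbind(0, 0, hum), matrix(0, length(tt), 3))
  out2 <- process_grf(grf2)
  resid <- out2$force[mid, 3] - out$force[mid, 3]
  expect_lt(max(abs(resid)) / 50, (1 / (1 + (100 / 15)^8)))
  # zero in, zero out
  z <- grf_record(tt, matrix(0, length(tt), 3), matrix(0, length(tt), 3))
  expect_true(all(process_grf(z)$force == 0))
})

test_that("GRF normalization uses the condition's weight and round-trips", {
  tt <- seq(0, 0.1, by = 5e-4)
  f <- matrix(877.0, length(tt), 3)
  grf <- grf_record(tt, f, matrix(0, length(tt), 3))
  bw <- normalize_grf(grf, "unassisted", subject_mass = 89.4, g = 9.81)
  expect_equal(bw$force[1, 3], 877.0 / (89.4 * 9.81), tolerance = 1e-12)
  expect_equal(bw$force[1, 3], 1.000, tolerance = 1e-3)
  expect_equal(bw$units, "BW")
  back <- denormalize_grf(bw)
  expect_equal(back$force, grf$force, tolerance = 1e-12)
  # combined weight denominator shrinks the assisted value
  bwa <- normalize_grf(grf, "assisted", subject_mass = 89.4, exo_mass = 23)
  expect_lt(bwa$force[1, 3], bw$force[1, 3])
  z <- grf_record(tt, matrix(0, length(tt), 3), matrix(0, length(tt), 3))
  expect_true(all(normalize_grf(z, "unassisted", 89.4)$force == 0))
  expect_error(normalize_grf(grf, "unassisted", 0), "subject_mass")
})

test_that("MVC table takes the envelope peak over trials and rejects silence", {
  fs <- 2000
  tt <- seq(0, 2, by = 1 / fs)
  set.seed(6)
  mk <- function(amp) amp * exp(-((tt - 1) / 0.5)^4) *
    sin(2 * pi * 80 * tt) + 0.01
  trials <- list(quad = lapply(c(0.4, 0.9, 0.7, 0.8, 0.6), mk))
  mvc <- compute_mvc(trials, fs = fs)
  peaks <- vapply(trials$quad, function(x)
    max(exogait:::emg_envelope(x, fs)), 0)
  expect_equal(mvc[["quad"]], max(peaks))
  expect_equal(which.max(peaks), 2L)  # the 0.9-amplitude trial
  single <- compute_mvc(list(quad = trials$quad[2]), fs = fs)
  expect_equal(single[["quad"]], peaks[2])
  expect_error(compute_mvc(list(quad = list(rep(0, 4000))), fs = fs),
               "nonpositive MVC")
})

test_that("the EMG pipeline self-normalizes and nulls resting input", {
  fs <- 2000
  tt <- seq(0, 3, by = 1 / fs)
  resting <- rep(0.05, length(tt))
  expect_equal(compute_resting_mean(resting), 0.05)
  env0 <- process_emg(resting, resting_mean = 0.05, mvc = 1, fs = fs)
  expect_lt(max(abs(env0[1000:5000])), 1e-6)
  # a 50 Hz tone of amplitude A with mvc = 2A/pi gives a unit envelope
  A <- 0.8
  tone <- A * sin(2 * pi * 50 * tt) + 0.05
  env <- process_emg(tone, resting_mean = 0.05, mvc = 2 * A / pi, fs = fs)
  mid <- tt > 0.5 & tt < 2.5
  expect_equal(mean(env[mid]), 1.0, tolerance = 0.05)
  expect_error(process_emg(tone, 0.05, mvc = 0, fs = fs), "mvc")
  # envelope is non-negative up to filter ringing
  expect_gt(min(env), -0.01)
})

test_that("analog traces enforce uniform sampling and declared units", {
  expect_error(analog_trace(c(0, 1e-3, 3e-3), 1:3, "mV"), "uniform")
  expect_error(analog_trace(c(0, 1e-3), 1:2, ""), "units")
  tr <- analog_trace(seq(0, 1, by = 5e-4), sin(seq(0, 1, by = 5e-4)), "mV")
  expect_equal(tr$fs, 2000)
  f <- butterworth_filter(tr, "lowpass", cutoff = 6)
  expect_s3_class(f, "analog_trace")
})
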