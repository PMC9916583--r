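#' Uniformly sampled analog trace
#'
#' @param time time stamps, s (uniform; nominally 2000 Hz for force-plate
#'   and EMG channels).
#' @param values numeric vector or n x k matrix of samples.
#' @param units unit label (non-empty).
#' @return an object of class `analog_trace` with the sampling rate in
#'   `$fs`.
#' @export
analog_trace <- function(time, values, units) {
  if (!nzchar(units)) stopf("units must be declared")
  values <- if (is.matrix(values)) values else as.numeric(values)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (length(time) != n) stopf("time and values lengths differ")
  dt <- diff(time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 + 1e-9 * dt[1L])
    stopf("analog trace must be uniformly sampled (jitter > 1e-9 s)")
  structure(list(time = as.numeric(time), values = values, units = units,
                 fs = if (length(dt)) 1 / dt[1L] else NA_real_),
            class = "analog_trace")
}

#' @export
print.analog_trace <- function(x, ...) {
  k <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<analog_trace: %d samples x %d channel(s), %.0f Hz, units '%s'>\n",
              length(x$time), k, x$fs, x$units))
  invisible(x)
}

# Butterworth filtering core. zero_phase uses a reflection-padded
# forward-backward pass (doubles the effective order; -6 dB instead of
# -3 dB at the design cutoff).
bw_filter <- function(x, kind = c("low", "high"), order = 4, cutoff, fs,
                      zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stopf("cutoff must be in (0, Nyquist = %g Hz)", fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = kind)
  if (is.matrix(x)) return(apply(x, 2L, bw_filter, kind = kind,
                                 order = order, cutoff = cutoff, fs = fs,
                                 zero_phase = zero_phase))
  x <- as.numeric(x)
  n <- length(x)
  if (!zero_phase) return(as.numeric(signal::filter(bf, x)))
  # forward-backward pass with reflection padding and steady-state
  # initialization (removes the startup transient exactly for constants)
  H1 <- sum(bf$b) / sum(bf$a)
  flt <- function(v) as.numeric(signal::filter(
    bf$b, bf$a, v,
    init.x = rep(v[1L], length(bf$b) - 1L),
    init.y = rep(H1 * v[1L], length(bf$a) - 1L)))
  p <- min(n - 1L, max(3L * order, ceiling(3 * fs / cutoff)))
  if (p < 1L) return(x)
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- flt(c(pre, x, post))
  y <- rev(flt(rev(y)))
  y[(p + 1L):(p + n)]
}

#' Butterworth filter a signal
#'
#' Standard Butterworth response of the stated design order per pass.
#' `zero_phase = TRUE` (the offline default) runs forward-backward passes
#' with reflection padding, which cancels phase lag and doubles the
#' effective attenuation order.
#'
#' @param x numeric vector, matrix (channels in columns) or
#'   [analog_trace()].
#' @param kind `"lowpass"` or `"highpass"`.
#' @param order design order per pass (default 4).
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param fs sampling rate, Hz (taken from the trace if omitted).
#' @param zero_phase forward-backward filtering (default TRUE).
#' @return object of the same type as `x`, filtered.
#' @export
butterworth_filter <- function(x, kind = c("lowpass", "highpass"),
                               order = 4, cutoff, fs = NULL,
                               zero_phase = TRUE) {
  kind <- switch(match.arg(kind), lowpass = "low", highpass = "high")
  if (inherits(x, "analog_trace")) {
    x$values <- bw_filter(x$values, kind, order, cutoff, x$fs, zero_phase)
    return(x)
  }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  bw_filter(x, kind, order, cutoff, fs, zero_phase)
}

#' Force-plate record
#'
#' @param time time stamps, s.
#' @param force n x 3 ground reaction force, N (global frame).
#' @param cop n x 3 centre of pressure, m.
#' @param free_moment n x 3 free moment, N m.
#' @param plate plate identifier.
#' @param units force unit label (`"N"` raw, `"BW"` after
#'   [normalize_grf()]).
#' @return an object of class `grf_record`.
#' @export
grf_record <- function(time, force, cop, free_moment = NULL, plate = NA,
                       units = "N") {
  force <- as.matrix(force); cop <- as.matrix(cop)
  if (is.null(free_moment)) free_moment <- matrix(0, nrow(force), 3L)
  structure(list(time = as.numeric(time), force = force, cop = cop,
                 free_moment = as.matrix(free_moment), plate = plate,
                 units = units, normalizing_weight = NA_real_),
            class = "grf_record")
}

#' Condition a raw ground-reaction-force record
#'
#' Low-pass filters the force (and free-moment) channels with a
#' fourth-order Butterworth at 15 Hz, the standard conditioning for
#' overground force plates sampled at 2000 Hz; optionally resamples onto
#' a lower rate for alignment with 100 Hz kinematics.
#'
#' @param grf a [grf_record()].
#' @param cutoff low-pass cutoff, Hz (default 15).
#' @param order design order (default 4).
#' @param zero_phase forward-backward filtering (default TRUE).
#' @param resample_to optional output rate, Hz.
#' @return the filtered `grf_record`.
#' @export
process_grf <- function(grf, cutoff = 15, order = 4, zero_phase = TRUE,
                        resample_to = NULL) {
  fs <- 1 / mean(diff(grf$time))
  grf$force <- bw_filter(grf$force, "low", order, cutoff, fs, zero_phase)
  grf$free_moment <- bw_filter(grf$free_moment, "low", order, cutoff, fs,
                               zero_phase)
  if (!is.null(resample_to)) {
    tt <- seq(grf$time[1L], grf$time[length(grf$time)], by = 1 / resample_to)
    re <- function(M) apply(M, 2L, function(col)
      stats::approx(grf$time, col, xout = tt)$y)
    grf <- grf_record(tt, re(grf$force), re(grf$cop), re(grf$free_moment),
                      grf$plate, grf$units)
  }
  grf
}

#' Normalize ground reaction forces to body (or body + device) weight
#'
#' Assisted-locomotion forces are normalized to the combined weight of
#' the participant and the exoskeleton; unassisted forces to the
#' participant's body weight.
#'
#' @param grf a [grf_record()] in N.
#' @param condition `"assisted"` or `"unassisted"`.
#' @param subject_mass participant mass, kg.
#' @param exo_mass device mass, kg.
#' @param g gravitational acceleration, m/s^2.
#' @return the record with `force` in BW units.
#' @export
normalize_grf <- function(grf, condition = c("assisted", "unassisted"),
                          subject_mass, exo_mass = 0, g = 9.81) {
  condition <- match.arg(condition)
  if (!is.finite(subject_mass) || subject_mass <= 0)
    stopf("subject_mass must be > 0")
  if (grf$units == "BW") stopf("record is already normalized")
  m <- if (condition == "assisted") subject_mass + exo_mass else subject_mass
  w <- m * g
  grf$force <- grf$force / w
  grf$units <- "BW"
  grf$normalizing_weight <- w
  grf
}

#' @rdname normalize_grf
#' @export
denormalize_grf <- function(grf) {
  if (grf$units != "BW") stopf("record is not normalized")
  grf$force <- grf$force * grf$normalizing_weight
  grf$units <- "N"
  grf$normalizing_weight <- NA_real_
  grf
}

# rectified linear envelope: high-pass, full-wave rectify, low-pass
emg_envelope <- function(x, fs, hp = 30, lp = 6, order = 4,
                         zero_phase = TRUE) {
  y <- bw_filter(x, "high", order, hp, fs, zero_phase)
  bw_filter(abs(y), "low", order, lp, fs, zero_phase)
}

#' Mean resting EMG level
#'
#' Arithmetic mean of a quiet-standing trial's raw samples, used to
#' offset locomotion EMG to zero before filtering.
#'
#' @param x numeric vector or [analog_trace()].
#' @return scalar mean.
#' @export
compute_resting_mean <- function(x) {
  v <- if (inherits(x, "analog_trace")) x$values else x
  if (!length(v)) stopf("empty resting trial")
  mean(v)
}

#' Maximum voluntary contraction table
#'
#' Per muscle, the peak of the rectified linear envelope over all
#' contraction trials (conventionally 5 per muscle group) is assigned as
#' the muscle's maximum activation.
#'
#' @param trials named list (one entry per muscle) of lists of trials;
#'   each trial a numeric vector or [analog_trace()].
#' @param fs sampling rate, Hz, for plain numeric trials.
#' @param hp,lp,order envelope filter settings (30 Hz high-pass, 6 Hz
#'   low-pass, 4th order).
#' @return named numeric vector of maximum activations (class
#'   `mvc_table`).
#' @export
compute_mvc <- function(trials, fs = NULL, hp = 30, lp = 6, order = 4) {
  if (!length(trials)) stopf("empty MVC trial set")
  out <- vapply(trials, function(tt) {
    if (!length(tt)) stopf("muscle with no MVC trials")
    max(vapply(tt, function(tr) {
      v <- if (inherits(tr, "analog_trace")) tr$values else tr
      f <- if (inherits(tr, "analog_trace")) tr$fs else fs
      if (is.null(f)) stopf("fs required for plain numeric MVC trials")
      max(emg_envelope(v, f, hp, lp, order))
    }, 0))
  }, 0)
  if (any(out <= 0)) stopf("nonpositive MVC for muscle(s): %s",
                           paste(names(out)[out <= 0], collapse = ", "))
  class(out) <- c("mvc_table", class(out))
  out
}

#' Process a raw EMG channel to a normalized linear envelope
#'
#' Pipeline order: subtract the resting mean, 30 Hz fourth-order
#' Butterworth high-pass (motion-artifact removal), full-wave
#' rectification, 6 Hz fourth-order Butterworth low-pass (linear
#' envelope), then division by the muscle's maximum voluntary activation.
#'
#' @param raw numeric vector or [analog_trace()] (2000 Hz nominal).
#' @param resting_mean resting EMG level to subtract.
#' @param mvc muscle maximum activation (> 0), same units as `raw`.
#' @param fs sampling rate, Hz, for plain numeric input.
#' @param hp,lp,order,zero_phase filter settings.
#' @return normalized envelope (unitless, nominally 0-1), same type as
#'   `raw`.
#' @export
process_emg <- function(raw, resting_mean, mvc, fs = NULL, hp = 30, lp = 6,
                        order = 4, zero_phase = TRUE) {
  if (!is.finite(mvc) || mvc <= 0) stopf("mvc must be > 0")
  if (inherits(raw, "analog_trace")) {
    raw$values <- emg_envelope(raw$values - resting_mean, raw$fs, hp, lp,
                               order, zero_phase) / mvc
    raw$units <- "MVC"
    return(raw)
  }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  emg_envelope(raw - resting_mean, fs, hp, lp, order, zero_phase) / mvc
}
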