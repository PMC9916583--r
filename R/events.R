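# Gait events, maneuver phases, cycle normalization and ensemble
# statistics.

#' Detect gait cycles from a vertical GRF trace
#'
#' Foot strike is an upward crossing of the force threshold, toe-off a
#' downward crossing; crossings are debounced so threshold-grazing noise
#' does not split stance. Crossing times are refined by linear
#' interpolation between samples.
#'
#' @param time time stamps, s.
#' @param fz vertical GRF of one foot, N (filtered).
#' @param threshold detection threshold, N (default 20).
#' @param debounce minimum event spacing, s (default 0.05).
#' @param foot `"left"` or `"right"` label carried into the output.
#' @return data frame with columns `foot`, `t_strike`, `t_toeoff`,
#'   `t_next_strike` (`NA` when the trial ends mid-cycle), one row per
#'   strike.
#' @export
detect_gait_events <- function(time, fz, threshold = 20, debounce = 0.05,
                               foot = "right") {
  stopifnot(length(time) == length(fz))
  above <- fz >= threshold
  if (!any(above) || all(above)) stopf("no events: GRF never crosses %g N",
                                       threshold)
  dt <- mean(diff(time))
  deb_n <- max(1L, round(debounce / dt))
  # merge runs shorter than the debounce window into their neighbours
  repeat {
    r <- rle(above)
    k <- length(r$lengths)
    if (k <= 1L) break
    interior <- which(r$lengths < deb_n)
    interior <- setdiff(interior, c(1L, k))
    if (!length(interior)) break
    j <- interior[which.min(r$lengths[interior])]
    ends <- cumsum(r$lengths)
    idx <- (ends[j] - r$lengths[j] + 1L):ends[j]
    above[idx] <- !above[idx]
  }
  cross_t <- function(i) {
    # linear interpolation of the threshold crossing between i and i+1
    f0 <- fz[i]; f1 <- fz[i + 1L]
    if (f1 == f0) return(time[i + 1L])
    time[i] + (threshold - f0) / (f1 - f0) * (time[i + 1L] - time[i])
  }
  d <- diff(above)
  strikes <- vapply(which(d == 1L), cross_t, 0)
  toeoffs <- vapply(which(d == -1L), cross_t, 0)
  if (!length(strikes)) stopf("no foot strikes detected")
  rows <- lapply(strikes, function(ts) {
    to <- toeoffs[toeoffs > ts]
    to <- if (length(to)) to[1L] else NA_real_
    nxt <- strikes[strikes > ts]
    nxt <- if (length(nxt)) nxt[1L] else NA_real_
    if (is.finite(to) && is.finite(nxt) && to >= nxt) to <- NA_real_
    data.frame(foot = foot, t_strike = ts, t_toeoff = to,
               t_next_strike = nxt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a stance phase into braking and propulsion
#'
#' The boundary is the last posterior-to-anterior zero crossing of the
#' anterior-posterior shear force within stance (anterior positive). If
#' the force never changes sign the whole stance is labelled by its
#' dominant sign with a warning.
#'
#' @param time time stamps, s.
#' @param ap anterior-posterior GRF, anterior positive.
#' @param stance numeric length-2 window `c(t_strike, t_toeoff)`, s.
#' @return list with `t_boundary`, `braking` and `propulsion` windows
#'   (length-2 or `NULL`), and `dominant` (`NA` unless degenerate).
#' @export
split_braking_propulsion <- function(time, ap, stance) {
  sel <- which(time >= stance[1L] & time <= stance[2L])
  if (length(sel) < 2L) stopf("stance window contains < 2 samples")
  tt <- time[sel]; aa <- ap[sel]
  i <- which(aa[-length(aa)] < 0 & aa[-1L] >= 0)
  if (!length(i)) {
    dom <- if (mean(aa) >= 0) "anterior" else "posterior"
    warnf("no posterior-to-anterior zero crossing in stance; whole stance labelled %s",
          dom)
    return(list(t_boundary = NA_real_,
                braking = if (dom == "posterior") stance else NULL,
                propulsion = if (dom == "anterior") stance else NULL,
                dominant = dom))
  }
  i <- i[length(i)]
  tb <- tt[i] + (0 - aa[i]) / (aa[i + 1L] - aa[i]) * (tt[i + 1L] - tt[i])
  list(t_boundary = tb, braking = c(stance[1L], tb),
       propulsion = c(tb, stance[2L]), dominant = NA_character_)
}

#' Detect sit-to-stand / stand-to-sit phases
#'
#' The maneuver protocol is: a positioning lean of the torso, a 3 s hold
#' with the crutches loaded, then motor activation completes the
#' maneuver. Positioning ends when the torso angle settles onto its hold
#' plateau (within `plateau_tol` of the plateau value); the hold ends at
#' the motor-activation timestamp when available, otherwise at the end of
#' the plateau; completion is the start of the final posture plateau.
#'
#' @param time time stamps, s.
#' @param torso_deg torso pitch angle, deg.
#' @param maneuver `"sit_to_stand"` or `"stand_to_sit"`.
#' @param activation_time optional motor-activation timestamp, s
#'   (preferred for the hold end).
#' @param plateau_tol plateau tolerance, deg (default 0.5).
#' @param min_plateau minimum plateau duration, s (default 0.5).
#' @return an object of class `maneuver_phases`: `maneuver`,
#'   `t_position_end`, `t_hold_end`, `t_complete`, `hold_duration`.
#' @export
detect_maneuver_phases <- function(time, torso_deg,
                                   maneuver = c("sit_to_stand",
                                                "stand_to_sit"),
                                   activation_time = NULL,
                                   plateau_tol = 0.5, min_plateau = 0.5) {
  maneuver <- match.arg(maneuver)
  n <- length(time)
  stopifnot(length(torso_deg) == n, n >= 3L)
  dt <- mean(diff(time))
  win <- max(3L, round(min_plateau / dt))
  # a sample is on a plateau when the local range is within the tolerance
  local_range <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - win):min(n, i + win)
    diff(range(torso_deg[j]))
  }, 0)
  flat <- local_range <= plateau_tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  plat <- which(r$values & r$lengths >= win)
  if (length(plat) < 2L)
    stopf("no detectable hold plateau in the torso angle")
  # first plateau after initial movement = the hold; last = final posture
  first_move <- which(!flat)[1L]
  hold <- plat[starts[plat] > first_move][1L]
  if (is.na(hold)) stopf("no detectable hold plateau after positioning")
  # refine phase boundaries to where the angle enters/leaves the band
  # within plateau_tol of the plateau value (the local-range mask is
  # conservative near the ramps)
  pv <- stats::median(torso_deg[starts[hold]:ends[hold]])
  i0 <- starts[hold]
  while (i0 > 1L && abs(torso_deg[i0 - 1L] - pv) <= plateau_tol)
    i0 <- i0 - 1L
  t_position_end <- time[i0]
  if (!is.null(activation_time)) {
    t_hold_end <- activation_time
  } else {
    i1 <- ends[hold]
    while (i1 < n && abs(torso_deg[i1 + 1L] - pv) <= plateau_tol)
      i1 <- i1 + 1L
    t_hold_end <- time[i1]
  }
  final <- plat[length(plat)]
  if (final == hold) stopf("no final posture plateau after the hold")
  pv2 <- stats::median(torso_deg[starts[final]:ends[final]])
  i2 <- starts[final]
  while (i2 > 1L && abs(torso_deg[i2 - 1L] - pv2) <= plateau_tol)
    i2 <- i2 - 1L
  t_complete <- time[i2]
  structure(list(maneuver = maneuver, t_position_end = t_position_end,
                 t_hold_end = t_hold_end, t_complete = t_complete,
                 hold_duration = t_hold_end - t_position_end),
            class = "maneuver_phases")
}

#' Time-normalize a series onto a 0-100% cycle grid
#'
#' @param time time stamps, s.
#' @param values numeric vector or n x k matrix.
#' @param window length-2 window (s) to normalize over (within the series
#'   support).
#' @param n_points grid size (default 101: 0, 1, ..., 100%).
#' @return list with `percent` (0-100) and `values` (vector or matrix on
#'   the grid).
#' @export
time_normalize <- function(time, values, window = range(time),
                           n_points = 101L) {
  if (diff(window) <= 0) stopf("degenerate window")
  if (window[1L] < time[1L] - 1e-9 || window[2L] > time[length(time)] + 1e-9)
    stopf("window outside series support")
  tt <- seq(window[1L], window[2L], length.out = n_points)
  out <- if (is.matrix(values))
    apply(values, 2L, function(col) stats::approx(time, col, xout = tt)$y)
  else stats::approx(time, values, xout = tt)$y
  list(percent = seq(0, 100, length.out = n_points), values = out)
}

#' Ensemble mean and SD over time-normalized trials
#'
#' @param trials list of numeric vectors (or one-column matrices) on a
#'   shared grid.
#' @param percent optional grid labels (default 0-100).
#' @return an object of class `ensemble_curve`: `percent`, `mean`, `sd`
#'   (sample SD, n-1 denominator), `n_trials`.
#' @export
ensemble_average <- function(trials, percent = NULL) {
  if (!length(trials)) stopf("no trials to average")
  M <- vapply(trials, function(x) as.numeric(x), numeric(length(trials[[1L]])))
  M <- matrix(M, ncol = length(trials))
  if (ncol(M) == 1L) {
    warnf("single trial: SD reported as 0")
    sdv <- rep(0, nrow(M))
  } else sdv <- apply(M, 1L, stats::sd)
  structure(list(percent = percent %||% seq(0, 100, length.out = nrow(M)),
                 mean = rowMeans(M), sd = sdv, n_trials = ncol(M)),
            class = "ensemble_curve")
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve: %d points, %d trial(s), mean range [%.3g, %.3g]>\n",
              length(x$mean), x$n_trials, min(x$mean), max(x$mean)))
  invisible(x)
}

#' Mean +/- SD of per-trial peaks
#'
#' Computes each trial's extremum within a phase window, then the mean
#' and sample SD across trials (mean of per-trial peaks, not the peak of
#' the mean curve).
#'
#' @param trials list of numeric vectors on a shared grid.
#' @param quantity label for the output row.
#' @param window length-2 window in grid units (default whole grid).
#' @param direction `"max"` or `"min"`.
#' @param grid grid values matching the series (default 0-100).
#' @return data frame with `quantity`, `direction`, `mean`, `sd`, `n`.
#' @export
peak_summary <- function(trials, quantity = "peak", window = NULL,
                         direction = c("max", "min"), grid = NULL) {
  direction <- match.arg(direction)
  if (!length(trials)) stopf("no trials")
  len <- length(trials[[1L]])
  grid <- grid %||% seq(0, 100, length.out = len)
  sel <- if (is.null(window)) seq_len(len)
  else which(grid >= window[1L] & grid <= window[2L])
  if (!length(sel)) stopf("empty phase window")
  peaks <- vapply(trials, function(x) {
    v <- as.numeric(x)[sel]
    if (direction == "max") max(v) else min(v)
  }, 0)
  data.frame(quantity = quantity, direction = direction,
             mean = mean(peaks),
             sd = if (length(peaks) > 1L) stats::sd(peaks) else 0,
             n = length(peaks), stringsAsFactors = FALSE)
}
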