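#' Generalized-coordinate trajectory
#'
#' @param time strictly increasing time stamps, s.
#' @param q n_frames x n_coordinates matrix (rad for rotations, m for
#'   translations); column names are the coordinate names.
#' @param qdot,qddot optional derivative matrices of the same shape.
#' @return an object of class `coordinate_trajectory`.
#' @export
coordinate_trajectory <- function(time, q, qdot = NULL, qddot = NULL) {
  q <- as.matrix(q)
  if (length(time) != nrow(q)) stopf("time and q have different lengths")
  if (length(time) > 1L && any(diff(time) <= 0))
    stopf("time must be strictly increasing")
  for (d in list(qdot, qddot))
    if (!is.null(d) && !identical(dim(as.matrix(d)), dim(q)))
      stopf("derivative dimensions do not match q")
  structure(list(time = as.numeric(time), q = q, qdot = qdot, qddot = qddot),
            class = "coordinate_trajectory")
}

#' @export
print.coordinate_trajectory <- function(x, ...) {
  cat(sprintf("<coordinate_trajectory: %d frames x %d coordinates, %.3f-%.3f s%s>\n",
              nrow(x$q), ncol(x$q), x$time[1L], x$time[length(x$time)],
              if (!is.null(x$qddot)) ", with derivatives" else ""))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$q)

#' Extract one coordinate's series from a trajectory
#'
#' @param traj a `coordinate_trajectory`.
#' @param name coordinate name.
#' @param degrees convert to degrees (default TRUE; rotational
#'   coordinates are stored in radians).
#' @return numeric vector.
#' @export
get_coordinate <- function(traj, name, degrees = TRUE) {
  if (!name %in% colnames(traj$q)) stopf("no coordinate '%s'", name)
  v <- traj$q[, name]
  if (degrees) rad2deg(v) else v
}

#' Subset a trajectory to a model's coordinates
#'
#' Used to pass the human part of a coupled-model solution to the lumped
#' inverse-dynamics model.
#'
#' @param traj a `coordinate_trajectory`.
#' @param model target `multibody_model` (or character vector of names).
#' @return a `coordinate_trajectory` with the target's coordinate columns.
#' @export
subset_trajectory <- function(traj, model) {
  nms <- if (is.character(model)) model else coordinate_names(model)
  missing <- setdiff(nms, colnames(traj$q))
  if (length(missing))
    stopf("trajectory lacks coordinate(s): %s", paste(missing, collapse = ", "))
  coordinate_trajectory(traj$time, traj$q[, nms, drop = FALSE],
                        if (!is.null(traj$qdot)) traj$qdot[, nms, drop = FALSE],
                        if (!is.null(traj$qddot)) traj$qddot[, nms, drop = FALSE])
}

#' Differentiate a coordinate trajectory
#'
#' Optionally applies a zero-phase Butterworth low-pass to the
#' coordinates, then central differences (second-order one-sided at the
#' endpoints). The default 6 Hz, 4th-order smoothing suits 100 Hz gait
#' kinematics; disable it (`smoothing = FALSE`) when the input is already
#' noise-free.
#'
#' @param traj a `coordinate_trajectory` with uniform sampling.
#' @param smoothing logical; low-pass filter the coordinates first.
#' @param cutoff low-pass cutoff, Hz.
#' @param order Butterworth design order per pass.
#' @return the trajectory with `qdot` and `qddot` filled in.
#' @export
differentiate_trajectory <- function(traj, smoothing = TRUE, cutoff = 6,
                                     order = 4) {
  n <- n_frames(traj)
  if (n < 3L) stopf("need at least 3 frames to differentiate")
  dt <- diff(traj$time)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stopf("differentiation requires uniform sampling")
  h <- dt[1L]
  q <- traj$q
  if (isTRUE(smoothing)) {
    fs <- 1 / h
    q <- apply(q, 2L, bw_filter, kind = "low", order = order,
               cutoff = cutoff, fs = fs, zero_phase = TRUE)
  }
  qd <- q; qdd <- q
  i <- 2:(n - 1L)
  qd[i, ] <- (q[i + 1L, ] - q[i - 1L, ]) / (2 * h)
  qd[1L, ] <- (-3 * q[1L, ] + 4 * q[2L, ] - q[3L, ]) / (2 * h)
  qd[n, ] <- (3 * q[n, ] - 4 * q[n - 1L, ] + q[n - 2L, ]) / (2 * h)
  qdd[i, ] <- (q[i + 1L, ] - 2 * q[i, ] + q[i - 1L, ]) / h^2
  qdd[1L, ] <- qdd[2L, ]
  qdd[n, ] <- qdd[n - 1L, ]
  coordinate_trajectory(traj$time, q, qd, qdd)
}

#' Marker trajectory set
#'
#' @param time time stamps, s (nominally 100 Hz).
#' @param positions array `[n_frames, n_markers, 3]` of global positions,
#'   m, with marker names as the second dimnames; `NA` rows mark
#'   occlusions.
#' @return an object of class `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(time, positions) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3L] == 3L,
            dim(positions)[1L] == length(time))
  if (is.null(dimnames(positions)[[2L]]))
    stopf("positions must carry marker names")
  occluded <- apply(is.na(positions), c(1L, 2L), any)
  structure(list(time = as.numeric(time), positions = positions,
                 names = dimnames(positions)[[2L]], occluded = occluded),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf("<marker_trajectory_set: %d frames, %d markers, %.1f Hz, %.1f%% occluded>\n",
              length(x$time), length(x$names),
              1 / mean(diff(x$time)), 100 * mean(x$occluded)))
  invisible(x)
}

# one frame as an n x 3 matrix with rownames
mts_frame <- function(mts, i) {
  X <- matrix(mts$positions[i, , ], ncol = 3L)
  rownames(X) <- mts$names
  X
}

#' Mean absolute human-robot angle difference after offset removal
#'
#' The constant offset between a human joint angle and the corresponding
#' robot angle (due to differing segment axis definitions) is estimated as
#' the trial-mean difference and removed; the mean absolute residual
#' difference is returned.
#'
#' @param human_angle,robot_angle angle series on a shared time base, deg.
#' @return list with `offset` (deg), `mean_abs_diff`, `sd_abs_diff`.
#' @export
compare_human_robot_angles <- function(human_angle, robot_angle) {
  if (length(human_angle) != length(robot_angle))
    stopf("series lengths differ (%d vs %d)",
          length(human_angle), length(robot_angle))
  offset <- mean(human_angle - robot_angle)
  d <- abs(human_angle - robot_angle - offset)
  list(offset = offset, mean_abs_diff = mean(d),
       sd_abs_diff = if (length(d) > 1L) stats::sd(d) else 0)
}

#' RMS difference between IK and encoder joint angles
#'
#' The encoder stream is linearly resampled onto the IK time base, a
#' constant offset (trial-mean difference) is removed, and the RMS of the
#' residual is returned.
#'
#' @param ik_time,ik_angle IK series (s, deg).
#' @param encoder_time,encoder_angle encoder series (s, deg).
#' @return list with `rms` (deg), `offset` (deg) and `n` overlapping
#'   frames.
#' @export
compare_ik_encoder <- function(ik_time, ik_angle, encoder_time,
                               encoder_angle) {
  keep <- ik_time >= encoder_time[1L] &
    ik_time <= encoder_time[length(encoder_time)]
  if (!any(keep)) stopf("empty overlap window between IK and encoder")
  enc <- stats::approx(encoder_time, encoder_angle, xout = ik_time[keep])$y
  d <- ik_angle[keep] - enc
  offset <- mean(d)
  list(rms = sqrt(mean((d - offset)^2)), offset = offset, n = sum(keep))
}
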