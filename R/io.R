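# TRC / MOT-STO / CSV readers and writers.
#
# Values are written with 8 significant digits so that write-read round
# trips are bit-stable; the internal frame is Z-up and SI, with unit and
# axis conversion at the file boundary.

#' Read a TRC marker-trajectory file
#'
#' Values are converted to SI on read (`mm` files divided by 1000); blank
#' coordinate cells become occlusion flags. Files are assumed to share
#' the package's Z-up lab convention.
#'
#' @param path file path.
#' @return a [marker_trajectory_set()] (positions in m).
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) stopf("truncated TRC file: %s", path)
  hdr_names <- strsplit(lines[2L], "\t")[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t")[[1L]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  n_frames <- as.integer(hdr$NumFrames)
  n_markers <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  scale <- switch(units, mm = 1e-3, m = 1, stopf("unknown TRC units '%s'", units))
  mk_row <- strsplit(lines[4L], "\t")[[1L]]
  mk_names <- mk_row[-(1:2)]
  mk_names <- mk_names[nzchar(mk_names)]
  if (length(mk_names) != n_markers)
    stopf("TRC header mismatch: %d marker names vs NumMarkers=%d",
          length(mk_names), n_markers)
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_frames)
    stopf("TRC header mismatch: %d data rows vs NumFrames=%d",
          length(body), n_frames)
  pos <- array(NA_real_, c(n_frames, n_markers, 3L),
               dimnames = list(NULL, mk_names, c("x", "y", "z")))
  time <- numeric(n_frames)
  ncol_exp <- 2L + 3L * n_markers
  for (i in seq_len(n_frames)) {
    f <- strsplit(body[i], "\t")[[1L]]
    length(f) <- ncol_exp
    v <- suppressWarnings(as.numeric(f))
    time[i] <- v[2L]
    pos[i, , ] <- matrix(v[-(1:2)], n_markers, 3L, byrow = TRUE) * scale
  }
  marker_trajectory_set(time, pos)
}

#' Write a TRC marker-trajectory file
#'
#' @param mts a [marker_trajectory_set()].
#' @param path output path.
#' @param units `"m"` (default) or `"mm"`.
#' @return the path, invisibly.
#' @export
write_trc <- function(mts, path, units = "m") {
  scale <- switch(units, mm = 1e3, m = 1, stopf("unknown TRC units '%s'", units))
  n_frames <- length(mts$time)
  n_markers <- length(mts$names)
  rate <- if (n_frames > 1L) 1 / mean(diff(mts$time)) else 100
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(paste(fmt_num(rate), fmt_num(rate), n_frames, n_markers, units,
                   fmt_num(rate), 1L, n_frames, sep = "\t"), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(mts$names, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), n_markers),
                                    rep(seq_len(n_markers), each = 3L))),
                   collapse = "\t"), con)
  for (i in seq_len(n_frames)) {
    vals <- as.vector(t(matrix(mts$positions[i, , ], n_markers, 3L))) * scale
    writeLines(paste(c(i, fmt_num(mts$time[i]), fmt_num(vals)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MOT/STO motion or loads file
#'
#' @param path file path.
#' @return data frame of the columns (first column `time`); attribute
#'   `in_degrees` records the header flag.
#' @export
read_mot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) stopf("no 'endheader' line in %s", path)
  hdr <- lines[seq_len(end - 1L)]
  get_flag <- function(key) {
    ln <- grep(paste0("^", key, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(".*=", "", ln[1L]))
  }
  n_rows <- as.integer(get_flag("nRows"))
  n_cols <- as.integer(get_flag("nColumns"))
  in_deg <- identical(tolower(get_flag("inDegrees")), "yes")
  cn <- strsplit(lines[end + 1L], "\t")[[1L]]
  if (is.finite(n_cols) && length(cn) != n_cols)
    stopf("parse error at line %d: %d columns declared, %d found",
          end + 1L, n_cols, length(cn))
  body <- lines[-(seq_len(end + 1L))]
  body <- body[nzchar(trimws(body))]
  if (is.finite(n_rows) && length(body) != n_rows)
    stopf("truncated file: nRows=%d but %d data rows", n_rows, length(body))
  M <- matrix(NA_real_, length(body), length(cn))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t")[[1L]]))
    if (length(v) != length(cn))
      stopf("parse error at line %d: expected %d values, got %d",
            end + 1L + i, length(cn), length(v))
    M[i, ] <- v
  }
  df <- as.data.frame(M)
  names(df) <- cn
  if (any(diff(df[[1L]]) <= 0)) stopf("time column not strictly increasing")
  attr(df, "in_degrees") <- in_deg
  df
}

#' Write a MOT/STO file
#'
#' @param df data frame, first column `time`.
#' @param path output path.
#' @param in_degrees value of the `inDegrees` header flag.
#' @param name header name line.
#' @return the path, invisibly.
#' @export
write_mot <- function(df, path, in_degrees = FALSE, name = basename(path)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(df)),
               sprintf("nColumns=%d", ncol(df)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(df), collapse = "\t")), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(fmt_num(as.numeric(df[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Write / read a coordinate trajectory as a MOT file
#'
#' Rotational coordinates are converted to degrees on write (when
#' `in_degrees`) and back to radians on read, using the model's
#' coordinate kinds.
#'
#' @param traj a `coordinate_trajectory`.
#' @param path file path.
#' @param model the `multibody_model` defining coordinate kinds.
#' @param in_degrees write rotations in degrees (default TRUE).
#' @return `read_motion()` returns a `coordinate_trajectory`.
#' @export
write_motion <- function(traj, path, model, in_degrees = TRUE) {
  rot <- model$coords$kind == "rotation"
  Q <- traj$q[, coordinate_names(model), drop = FALSE]
  if (in_degrees) Q[, rot] <- rad2deg(Q[, rot])
  df <- data.frame(time = traj$time, Q, check.names = FALSE)
  write_mot(df, path, in_degrees = in_degrees)
}

#' @rdname write_motion
#' @export
read_motion <- function(path, model) {
  df <- read_mot(path)
  nms <- coordinate_names(model)
  missing <- setdiff(nms, names(df))
  if (length(missing))
    stopf("motion file lacks coordinate(s): %s", paste(missing, collapse = ", "))
  Q <- as.matrix(df[nms])
  if (isTRUE(attr(df, "in_degrees"))) {
    rot <- model$coords$kind == "rotation"
    Q[, rot] <- deg2rad(Q[, rot])
  }
  coordinate_trajectory(df$time, Q)
}

#' Write / read foot loads as an STO file
#'
#' Columns per plate: `<side>_ground_force_v{x,y,z}`,
#' `<side>_ground_force_p{x,y,z}`, `<side>_ground_torque_{x,y,z}`.
#'
#' @param loads list of [external_load()]s named by side (`left`,
#'   `right`).
#' @param path file path.
#' @return `read_loads()` returns the named list of `external_load`s.
#' @export
write_loads <- function(loads, path) {
  df <- data.frame(time = loads[[1L]]$time)
  for (side in names(loads)) {
    ld <- loads[[side]]
    for (k in 1:3) df[[paste0(side, "_ground_force_v", c("x", "y", "z")[k])]] <- ld$force[, k]
    for (k in 1:3) df[[paste0(side, "_ground_force_p", c("x", "y", "z")[k])]] <- ld$cop[, k]
    for (k in 1:3) df[[paste0(side, "_ground_torque_", c("x", "y", "z")[k])]] <- ld$free_moment[, k]
  }
  attr(df, "bodies") <- vapply(loads, `[[`, "", "body")
  write_mot(df, path, in_degrees = FALSE)
  invisible(path)
}

#' @rdname write_loads
#' @param bodies named character vector mapping side prefix to the body
#'   the load acts on (default the study feet).
#' @export
read_loads <- function(path, bodies = c(left = "calcn_l", right = "calcn_r")) {
  df <- read_mot(path)
  out <- list()
  for (side in names(bodies)) {
    fcols <- paste0(side, "_ground_force_v", c("x", "y", "z"))
    pcols <- paste0(side, "_ground_force_p", c("x", "y", "z"))
    tcols <- paste0(side, "_ground_torque_", c("x", "y", "z"))
    if (!all(c(fcols, pcols, tcols) %in% names(df))) next
    out[[side]] <- external_load(bodies[[side]], df$time,
                                 as.matrix(df[fcols]), as.matrix(df[pcols]),
                                 as.matrix(df[tcols]))
  }
  if (!length(out)) stopf("no ground-load column groups found in %s", path)
  out
}

#' Write / read a multi-channel EMG CSV (`time,<channel>...`)
#'
#' @param time time stamps, s.
#' @param channels matrix with named columns.
#' @param path file path.
#' @return `read_emg_csv()` returns a list with `time`, `channels`, `fs`.
#' @export
write_emg_csv <- function(time, channels, path) {
  df <- data.frame(time = fmt_num(time))
  for (cc in colnames(channels)) df[[cc]] <- fmt_num(channels[, cc])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(time = df$time,
       channels = as.matrix(df[-1L]),
       fs = 1 / mean(diff(df$time)))
}

#' Write gait events to JSON
#'
#' @param events data frame from [detect_gait_events()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
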