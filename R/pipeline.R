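# End-to-end walking analysis: IK -> conditioning -> ID -> events ->
# cycle normalization -> peak summaries, mirroring the measurement
# pipeline of an instrumented gait session.

# quantities reported per leg, on the 101-point cycle grid
leg_angle_coords <- function(sfx) c(
  hip = paste0("hip_", sfx, "_flexion"),
  knee = paste0("knee_", sfx, "_angle"),
  ankle = paste0("ankle_", sfx, "_angle"))

#' Analyze one walking trial
#'
#' Runs the full measurement chain on one trial: inverse kinematics on
#' the marker data, 6 Hz conditioning and differentiation, inverse
#' dynamics with the foot loads on the (lumped) dynamics model, moment
#' and GRF normalization, gait-event detection per foot, and
#' time-normalization of angles, forces and moments onto the 0-100%
#' cycle grid of each leg's first complete cycle.
#'
#' @param markers a [marker_trajectory_set()].
#' @param loads named list of [external_load()]s (`left`, `right`).
#' @param models a [build_study_models()] list.
#' @param condition `"assisted"` or `"unassisted"`.
#' @param encoder optional encoder data frame (from [generate_encoder()]
#'   or a device log) for the IK-vs-encoder comparison.
#' @param event_threshold gait-event force threshold, N.
#' @return a `trial_analysis` list: `ik`, `trajectory` (conditioned),
#'   `moments` (`normalized_moments`), `events`, `cycles` (per leg),
#'   `curves` (per leg, 101-point), `peaks` (data frame),
#'   `encoder_rms` (worst joint, deg, or `NA`).
#' @export
analyze_walking_trial <- function(markers, loads, models,
                                  condition = c("assisted", "unassisted"),
                                  encoder = NULL, event_threshold = 20) {
  condition <- match.arg(condition)
  assisted <- condition == "assisted"
  mk_model <- if (assisted) models$coupled else models$human
  id_model <- if (assisted) models$lumped else models$human
  ik <- solve_ik(mk_model, markers)
  traj <- differentiate_trajectory(ik$trajectory, smoothing = TRUE)
  traj_id <- subset_trajectory(traj, id_model)
  gf <- inverse_dynamics(id_model, traj_id, loads)
  nm <- normalize_moments(gf, condition, models$subject_mass,
                          models$exo_mass)
  bw <- (models$subject_mass + if (assisted) models$exo_mass else 0) * 9.81

  events <- list()
  cycles <- list()
  curves <- list()
  peaks <- list()
  for (side in c("left", "right")) {
    sfx <- substr(side, 1L, 1L)
    ld <- loads[[side]]
    ev <- detect_gait_events(ld$time, ld$force[, 3L],
                             threshold = event_threshold, foot = side)
    events[[side]] <- ev
    full <- ev[stats::complete.cases(ev), , drop = FALSE]
    if (!nrow(full)) stopf("no complete %s gait cycle in trial", side)
    cyc <- full[1L, ]
    cycles[[side]] <- cyc
    win <- c(cyc$t_strike, cyc$t_next_strike)
    stance <- c(cyc$t_strike, cyc$t_toeoff)
    bp <- split_braking_propulsion(ld$time, ld$force[, 1L], stance)

    ang <- leg_angle_coords(sfx)
    cv <- list()
    for (a in names(ang))
      cv[[a]] <- time_normalize(traj$time, rad2deg(traj$q[, ang[[a]]]), win)$values
    cv$grf_vertical <- time_normalize(ld$time, ld$force[, 3L] / bw, win)$values
    cv$grf_ap <- time_normalize(ld$time, ld$force[, 1L] / bw, win)$values
    cv$grf_ml <- time_normalize(ld$time, ld$force[, 2L] / bw, win)$values
    for (a in names(ang))
      cv[[paste0(a, "_moment")]] <-
        time_normalize(gf$time, nm$tau_norm[, ang[[a]]], win)$values
    curves[[side]] <- cv

    pct <- function(t) 100 * (t - win[1L]) / diff(win)
    to_pct <- pct(cyc$t_toeoff)
    bd_pct <- if (is.finite(bp$t_boundary)) pct(bp$t_boundary) else NA_real_
    in_win <- function(x, w) {
      g <- seq(0, 100, length.out = length(x))
      x[g >= w[1L] & g <= w[2L]]
    }
    stance_w <- c(0, to_pct)
    brake_w <- c(0, bd_pct)
    prop_w <- c(bd_pct, to_pct)
    pk <- list(
      peak_knee_flexion = max(cv$knee),
      peak_hip_extension = -min(cv$hip),
      peak_ankle_plantarflexion = -min(cv$ankle),
      ankle_range_propulsion = if (is.finite(bd_pct))
        diff(range(in_win(cv$ankle, prop_w))) else NA_real_,
      grf_vertical_braking = if (is.finite(bd_pct))
        max(in_win(cv$grf_vertical, brake_w)) else NA_real_,
      grf_vertical_propulsion = if (is.finite(bd_pct))
        max(in_win(cv$grf_vertical, prop_w)) else NA_real_,
      grf_posterior_braking = if (is.finite(bd_pct))
        -min(in_win(cv$grf_ap, brake_w)) else NA_real_,
      grf_anterior_propulsion = if (is.finite(bd_pct))
        max(in_win(cv$grf_ap, prop_w)) else NA_real_,
      peak_knee_extension_moment = -min(in_win(cv$knee_moment, stance_w)),
      peak_hip_flexion_moment = max(cv$hip_moment),
      peak_ankle_plantarflexion_moment = -min(in_win(cv$ankle_moment,
                                                     stance_w)),
      toeoff_pct = to_pct)
    peaks[[side]] <- data.frame(leg = side, quantity = names(pk),
                                value = as.numeric(pk),
                                stringsAsFactors = FALSE)
  }

  encoder_rms <- NA_real_
  if (!is.null(encoder)) {
    cols <- grep("_deg$", names(encoder), value = TRUE)
    rr <- vapply(cols, function(cc) {
      coord <- sub("_deg$", "", cc)
      if (!coord %in% colnames(traj$q)) return(NA_real_)
      compare_ik_encoder(traj$time, rad2deg(traj$q[, coord]),
                         encoder$time, encoder[[cc]])$rms
    }, 0)
    encoder_rms <- max(rr, na.rm = TRUE)
  }

  structure(list(ik = ik, trajectory = traj, moments = nm, events = events,
                 cycles = cycles, curves = curves,
                 peaks = do.call(rbind, peaks), encoder_rms = encoder_rms),
            class = "trial_analysis")
}

#' Aggregate trial analyses into a condition report
#'
#' Peak tables are the mean +/- sample SD of per-trial peaks (not peaks
#' of the mean curve); ensemble curves carry pointwise mean and SD.
#'
#' @param analyses list of `trial_analysis` objects.
#' @param condition condition label for the report.
#' @return a `gait_report` list: `table` (data frame: condition, leg,
#'   quantity, mean, sd, n), `ensembles` (per leg/quantity
#'   [ensemble_average()] curves), `ik_rms` (mean, sd over trials, m),
#'   `encoder_rms_worst` (deg).
#' @export
gait_report <- function(analyses, condition) {
  stopifnot(length(analyses) >= 1L)
  qs <- unique(analyses[[1L]]$peaks$quantity)
  rows <- list()
  ensembles <- list()
  for (side in c("left", "right")) {
    for (qq in qs) {
      vals <- vapply(analyses, function(a)
        a$peaks$value[a$peaks$leg == side & a$peaks$quantity == qq], 0)
      rows[[paste(side, qq)]] <- data.frame(
        condition = condition, leg = side, quantity = qq,
        mean = mean(vals),
        sd = if (length(vals) > 1L) stats::sd(vals) else 0,
        n = length(vals), stringsAsFactors = FALSE)
    }
    ensembles[[side]] <- lapply(
      stats::setNames(nm = names(analyses[[1L]]$curves[[side]])),
      function(cv) ensemble_average(
        lapply(analyses, function(a) a$curves[[side]][[cv]])))
  }
  ikr <- vapply(analyses, function(a) a$ik$mean_rms, 0)
  enc <- vapply(analyses, function(a) a$encoder_rms, 0)
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 ensembles = ensembles,
                 ik_rms = c(mean = mean(ikr),
                            sd = if (length(ikr) > 1L) stats::sd(ikr) else 0),
                 encoder_rms_worst = if (all(is.na(enc))) NA_real_
                 else max(enc, na.rm = TRUE)),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report: %s, %d trials, IK marker RMS %.2f +/- %.2f mm>\n",
              x$table$condition[1L], x$table$n[1L],
              1000 * x$ik_rms[["mean"]], 1000 * x$ik_rms[["sd"]]))
  key <- x$table[x$table$quantity %in%
                   c("peak_knee_flexion", "peak_hip_extension",
                     "peak_ankle_plantarflexion",
                     "peak_knee_extension_moment"), ]
  for (i in seq_len(nrow(key)))
    cat(sprintf("  %-32s %-5s %7.2f +/- %.2f\n", key$quantity[i], key$leg[i],
                key$mean[i], key$sd[i]))
  if (is.finite(x$encoder_rms_worst))
    cat(sprintf("  worst IK-encoder RMS: %.2f deg\n", x$encoder_rms_worst))
  invisible(x)
}

#' Write a report table as deterministic CSV
#'
#' @param report a `gait_report` (or its `table`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  tb <- if (inherits(report, "gait_report")) report$table else report
  tb$mean <- fmt_num(tb$mean)
  tb$sd <- fmt_num(tb$sd)
  utils::write.table(tb, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study for one condition
#'
#' Generates the trial set and runs every trial through the analysis
#' chain.
#'
#' @param condition `"assisted"` or `"unassisted"`.
#' @param n_trials trials per condition (default 6).
#' @param seed base RNG seed.
#' @param models optional shared [build_study_models()] list.
#' @param config optional [synth_config()] override.
#' @return list with `report` ([gait_report()]), `analyses`, `trials`,
#'   `models`.
#' @export
run_condition_study <- function(condition = c("assisted", "unassisted"),
                                n_trials = 6L, seed = 1L, models = NULL,
                                config = NULL) {
  condition <- match.arg(condition)
  ts <- generate_walking_trials(condition, n_trials = n_trials, seed = seed,
                                config = config, models = models)
  analyses <- lapply(ts$trials, function(tr)
    analyze_walking_trial(tr$markers, tr$loads, ts$models, condition,
                          encoder = tr$encoder))
  list(report = gait_report(analyses, condition), analyses = analyses,
       trials = ts$trials, models = ts$models)
}
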