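# Synthetic trial generation with known ground truth.
#
# Joint waveforms are idealized truncated Fourier (harmonic) series, so
# exact analytic velocities and accelerations exist for every coordinate;
# ground loads are constructed to satisfy the whole-body Newton-Euler
# balance frame by frame, which makes the inverse-dynamics residual test
# exact by construction.

# exact harmonic representation of a smooth periodic waveform f(s),
# s in [0, 1): returns cosine/sine coefficients up to order K
harmonic_fit <- function(fun, K = 12L) {
  N <- max(4L * K, 32L)
  s <- (seq_len(N) - 1L) / N
  y <- vapply(s, fun, 0)
  ft <- stats::fft(y) / N
  list(a0 = Re(ft[1L]),
       a = 2 * Re(ft[2:(K + 1L)]),
       b = -2 * Im(ft[2:(K + 1L)]))
}

# evaluate a harmonic series (plus optional linear trend) and its first
# two time derivatives; t in seconds, period T
harmonic_eval <- function(h, t, T, lin = c(0, 0)) {
  K <- length(h$a)
  w <- 2 * pi / T
  val <- rep(h$a0 + lin[1L], length(t)) + lin[2L] * t
  d1 <- rep(lin[2L], length(t))
  d2 <- rep(0, length(t))
  for (j in seq_len(K)) {
    cj <- cos(j * w * t); sj <- sin(j * w * t)
    val <- val + h$a[j] * cj + h$b[j] * sj
    d1 <- d1 + j * w * (-h$a[j] * sj + h$b[j] * cj)
    d2 <- d2 - (j * w)^2 * (h$a[j] * cj + h$b[j] * sj)
  }
  list(val = val, d1 = d1, d2 = d2)
}

# smooth periodic bump centred at c with sharpness k (max exactly 1)
phase_bump <- function(s, centre, k) ((1 + cos(2 * pi * (s - centre))) / 2)^k

#' Synthetic-trial configuration
#'
#' Defaults define the two study conditions: exoskeletal-assisted gait at
#' 0.47 m/s with a 50.1 deg commanded peak knee flexion and a reduced
#' propulsion-phase plantarflexion range, and unassisted gait at
#' 1.11 m/s with a 68.6 deg peak knee flexion.
#'
#' @param condition `"assisted"` or `"unassisted"`.
#' @param ... overrides for any default field.
#' @return a `synth_config` list. Key fields: `cycle_duration` (s),
#'   `speed` (m/s), `knee_peak_deg`, `hip_max_deg`, `hip_min_deg`,
#'   `ankle_plantar_deg`, `marker_noise_sd` (m), `occlusion_rate`,
#'   `encoder_offset_deg`, `encoder_noise_sd_deg`, `frame_offset_deg`,
#'   `amplitude_jitter_sd_deg`, `double_support` (cycle fraction),
#'   `rate` (Hz), `n_cycles`, `lead_in` (s, margin before the first left
#'   strike so filter transients fall outside the analyzed cycles),
#'   `seed`.
#' @export
synth_config <- function(condition = c("assisted", "unassisted"), ...) {
  condition <- match.arg(condition)
  cfg <- if (condition == "assisted") list(
    condition = "assisted",
    cycle_duration = 2.1, speed = 0.47,
    knee_peak_deg = 50.1, knee_peak_phase = 0.72,
    hip_max_deg = 35, hip_min_deg = -3.1,
    ankle_dorsi_deg = 3, ankle_plantar_deg = 8,
    torso_lean_deg = 5,
    pelvis_height = 0.92, pelvis_bob = 0.010, pelvis_sway = 0.035,
    pelvis_surge = 0.020,
    emg_amp = 0.35
  ) else list(
    condition = "unassisted",
    cycle_duration = 1.2, speed = 1.11,
    knee_peak_deg = 68.6, knee_peak_phase = 0.72,
    hip_max_deg = 30, hip_min_deg = -27.2,
    ankle_dorsi_deg = 5, ankle_plantar_deg = 28,
    torso_lean_deg = 0,
    pelvis_height = 0.92, pelvis_bob = 0.015, pelvis_sway = 0.018,
    pelvis_surge = 0.015,
    emg_amp = 0.9
  )
  cfg <- c(cfg, list(
    rate = 100, n_cycles = 2L, lead_in = 0.35, double_support = 0.1,
    marker_noise_sd = 0.002, occlusion_rate = 0,
    encoder_offset_deg = 5, encoder_noise_sd_deg = 1.0,
    frame_offset_deg = 12,
    amplitude_jitter_sd_deg = 0.2,
    mtp_deg = 8, subtalar_deg = 2,
    emg_fs = 2000, resting_offset = 0.01,
    n_trials = 6L, seed = 1L))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "synth_config")
}

#' Build the study's model set
#'
#' The generic human model scaled to the participant (1.76 m, 89.4 kg),
#' the exoskeleton model, the coupled human-robot model (pelvic-band
#' anchor) and the lumped inverse-dynamics model.
#'
#' @param anthro a [subject_anthropometry()] (default: the study
#'   participant).
#' @param device_mass exoskeleton mass, kg.
#' @param frame_offset_deg constant pitch offset between pelvis and
#'   pelvic-band axes (see [pelvic_anchor_joint()]).
#' @return list with `human`, `exo`, `coupled`, `lumped` models, the
#'   `anchor` joint and the `subject_mass` / `exo_mass` scalars.
#' @export
build_study_models <- function(anthro = subject_anthropometry(89.4, 1.76),
                               device_mass = 23,
                               frame_offset_deg = 12) {
  human <- scale_model(build_human_model(), anthro)
  exo <- build_exoskeleton_model(default_exoskeleton_config(device_mass))
  anchor <- pelvic_anchor_joint(frame_offset_deg = frame_offset_deg)
  list(human = human, exo = exo,
       coupled = couple_models(human, exo, anchor),
       lumped = lump_exoskeleton_inertia(human, exo, anchor = anchor),
       anchor = anchor,
       subject_mass = anthro$total_mass, exo_mass = total_mass(exo))
}

# per-coordinate waveform table: harmonic series (rad or m) + linear
# trend, left leg strikes at t = 0
gait_waveforms <- function(config, model) {
  T <- config$cycle_duration
  d2r <- pi / 180
  knee <- function(sp) function(s)
    deg2rad(config$knee_peak_deg) * (1 - cos(2 * pi * (s - sp + 0.5)))^2 / 4
  hip_mid <- deg2rad((config$hip_max_deg + config$hip_min_deg) / 2)
  hip_amp <- deg2rad((config$hip_max_deg - config$hip_min_deg) / 2)
  hip <- function(ph) function(s) hip_mid + hip_amp * cos(2 * pi * (s - ph))
  ankle <- function(ph) function(s) {
    sv <- s - ph
    deg2rad(config$ankle_dorsi_deg) * phase_bump(sv, 0.30, 4) -
      deg2rad(config$ankle_plantar_deg) * phase_bump(sv, 0.57, 10)
  }
  mtp <- function(ph) function(s)
    deg2rad(config$mtp_deg %||% 8) * phase_bump(s - ph, 0.55, 8)
  subt <- function(ph) function(s)
    deg2rad(config$subtalar_deg %||% 2) * sin(2 * pi * (s - ph))
  wf <- list()
  add <- function(name, fun, lin = c(0, 0), K = 12L) {
    if (name %in% model$coords$name)
      wf[[name]] <<- list(h = harmonic_fit(fun, K), lin = lin)
  }
  add("ground_pelvis_tx", function(s) config$pelvis_surge * sin(4 * pi * s),
      lin = c(0, config$speed))
  add("ground_pelvis_ty", function(s) config$pelvis_sway * sin(2 * pi * s))
  add("ground_pelvis_tz", function(s) -config$pelvis_bob * cos(4 * pi * s),
      lin = c(config$pelvis_height, 0))
  add("back_flexion", function(s) deg2rad(config$torso_lean_deg))
  for (sfx in c("l", "r")) {
    ph <- if (sfx == "l") 0 else 0.5
    add(paste0("hip_", sfx, "_flexion"), hip(ph))
    add(paste0("knee_", sfx, "_angle"),
        function(s) knee(config$knee_peak_phase)(s - ph))
    add(paste0("ankle_", sfx, "_angle"), ankle(ph))
    add(paste0("subtalar_", sfx, "_angle"), subt(ph))
    add(paste0("mtp_", sfx, "_angle"), mtp(ph))
  }
  # exoskeleton drives: hip pins track human hip flexion shifted by the
  # frame offset; knee pins track the human knee exactly
  if (any(grepl("^exo_hip_", model$coords$name))) {
    dlt <- deg2rad(config$frame_offset_deg)
    for (sfx in c("l", "r")) {
      ph <- if (sfx == "l") 0 else 0.5
      add(paste0("exo_hip_", sfx, "_angle"),
          function(s) hip(ph)(s) - dlt)
      add(paste0("exo_knee_", sfx, "_angle"),
          function(s) knee(config$knee_peak_phase)(s - ph))
    }
  }
  wf
}

#' Generate a smooth gait coordinate trajectory with exact derivatives
#'
#' Periodic truncated-Fourier joint waveforms (left/right half-cycle
#' phase offset, pelvis translating at the configured speed) evaluated
#' analytically, so `qdot` and `qddot` are exact. Amplitude defaults are
#' the study-condition values in [synth_config()]; the pre-noise peak
#' knee flexion equals the commanded amplitude exactly.
#'
#' @param config a [synth_config()].
#' @param model the `multibody_model` the trajectory is for (coupled for
#'   assisted trials, human for unassisted).
#' @return a `coordinate_trajectory` with derivatives.
#' @export
generate_gait_trajectory <- function(config, model) {
  if (config$knee_peak_deg < 0 || config$knee_peak_deg > 140)
    stopf("knee amplitude out of joint range")
  T <- config$cycle_duration
  tt <- seq(-(config$lead_in %||% 0), config$n_cycles * T,
            by = 1 / config$rate)
  wf <- gait_waveforms(config, model)
  nq <- model$n_q
  nt <- length(tt)
  Q <- matrix(0, nt, nq, dimnames = list(NULL, model$coords$name))
  Qd <- Q; Qdd <- Q
  for (nm in names(wf)) {
    ev <- harmonic_eval(wf[[nm]]$h, tt, T, wf[[nm]]$lin)
    Q[, nm] <- ev$val; Qd[, nm] <- ev$d1; Qdd[, nm] <- ev$d2
  }
  coordinate_trajectory(tt, Q, Qd, Qdd)
}

# stance weight of the left foot at cycle phase s (right = phase s + 0.5)
stance_weight <- function(s, ds) {
  s <- s %% 1
  ifelse(s < ds, 0.5 * (1 - cos(pi * s / ds)),
         ifelse(s < 0.5, 1,
                ifelse(s < 0.5 + ds, 0.5 * (1 + cos(pi * (s - 0.5) / ds)), 0)))
}

#' Generate dynamically consistent ground loads for a gait trajectory
#'
#' The whole-body Newton-Euler resultant wrench required by the motion is
#' computed each frame from the exact accelerations and distributed
#' between the feet by a raised-cosine stance-weight function (single
#' support gives one foot everything; double support blends over the
#' configured fraction of the cycle). The centre of pressure tracks under
#' the stance foot from heel to toe; the free moment takes up the moment
#' balance exactly, so the loads satisfy the whole-body equations of
#' motion to machine precision.
#'
#' @param model the inverse-dynamics model (human or lumped).
#' @param traj `coordinate_trajectory` with exact derivatives.
#' @param config the [synth_config()] used to generate `traj`.
#' @return list of two [external_load()]s (`left` on `calcn_l`, `right`
#'   on `calcn_r`).
#' @export
generate_consistent_loads <- function(model, traj, config) {
  nt <- length(traj$time)
  T <- config$cycle_duration
  ds <- config$double_support
  duty <- 0.5 + ds
  g <- model$gravity
  ci <- match(coordinate_names(model), colnames(traj$q))
  b_l <- match("calcn_l", model$order); b_r <- match("calcn_r", model$order)
  if (is.na(b_l) || is.na(b_r))
    stopf("model lacks foot segments calcn_l/calcn_r")
  F_l <- matrix(0, nt, 3L); F_r <- matrix(0, nt, 3L)
  P_l <- matrix(0, nt, 3L); P_r <- matrix(0, nt, 3L)
  M_l <- matrix(0, nt, 3L); M_r <- matrix(0, nt, 3L)
  for (i in seq_len(nt)) {
    kin <- fk_pass(model, traj$q[i, ci], traj$qdot[i, ci],
                   traj$qddot[i, ci])
    Ft <- c(0, 0, 0); Mt <- c(0, 0, 0)
    for (b in seq_len(model$n_segments)) {
      seg <- model$segments[[model$order[b]]]
      Rb <- kin$R[[b]]
      c_g <- as.numeric(Rb %*% seg$com)
      xc <- kin$p[, b] + c_g
      w <- kin$w[, b]; al <- kin$al[, b]
      a_com <- kin$a[, b] + cross3(al, c_g) + cross3(w, cross3(w, c_g))
      f <- seg$mass * (a_com - g)
      Ig <- Rb %*% seg$inertia %*% t(Rb)
      Ft <- Ft + f
      Mt <- Mt + cross3(xc, f) + as.numeric(Ig %*% al) +
        cross3(w, as.numeric(Ig %*% w))
    }
    s <- (traj$time[i] / T) %% 1
    wl <- stance_weight(s, ds); wr <- stance_weight(s + 0.5, ds)
    tot <- wl + wr
    if (tot <= 0) stopf("flight phase at t=%.3f s: not modeled", traj$time[i])
    wl <- wl / tot; wr <- wr / tot
    prog_l <- min(1, (s %% 1) / duty)
    prog_r <- min(1, ((s + 0.5) %% 1) / duty)
    P_l[i, ] <- c(kin$p[1L, b_l] - 0.03 + 0.18 * prog_l, kin$p[2L, b_l], 0)
    P_r[i, ] <- c(kin$p[1L, b_r] - 0.03 + 0.18 * prog_r, kin$p[2L, b_r], 0)
    F_l[i, ] <- wl * Ft; F_r[i, ] <- wr * Ft
    Mfree <- Mt - cross3(P_l[i, ], F_l[i, ]) - cross3(P_r[i, ], F_r[i, ])
    M_l[i, ] <- wl * Mfree; M_r[i, ] <- wr * Mfree
  }
  list(left = external_load("calcn_l", traj$time, F_l, P_l, M_l),
       right = external_load("calcn_r", traj$time, F_r, P_r, M_r))
}

#' Generate a noisy marker trajectory set from a motion
#'
#' Forward-kinematics marker positions plus i.i.d. Gaussian noise;
#' occlusions as random gaps (`NA`).
#'
#' @param model the `multibody_model` carrying the marker set.
#' @param traj `coordinate_trajectory`.
#' @param noise_sd isotropic noise SD, m.
#' @param occlusion_rate per-marker-per-frame occlusion probability.
#' @param seed RNG seed.
#' @return a [marker_trajectory_set()]; the noise-free positions are in
#'   `attr(, "truth")`.
#' @export
generate_markers <- function(model, traj, noise_sd = 0.002,
                             occlusion_rate = 0, seed = 1L) {
  set.seed(seed)
  nt <- length(traj$time)
  nm <- length(model$markers)
  nms <- coordinate_names(model)
  pos <- array(0, c(nt, nm, 3L),
               dimnames = list(NULL, names(model$markers), c("x", "y", "z")))
  for (i in seq_len(nt)) {
    fk <- fk_pass(model, traj$q[i, nms])
    pos[i, , ] <- t(marker_positions(model, fk))
  }
  truth <- pos
  if (noise_sd > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, noise_sd), dim(pos))
  if (occlusion_rate > 0) {
    occ <- matrix(stats::runif(nt * nm) < occlusion_rate, nt, nm)
    for (k in 1:3) pos[, , k][occ] <- NA_real_
  }
  out <- marker_trajectory_set(traj$time, pos)
  attr(out, "truth") <- truth
  out
}

EMG_MUSCLES <- c("rectus_femoris", "vastus_lateralis", "vastus_medialis",
                 "semitendinosus", "biceps_femoris",
                 "gastrocnemius_medialis", "soleus", "tibialis_anterior")

# burst placements per muscle (cycle phase centres, sharpness, relative
# amplitude); propulsion-phase muscles carry the condition scaling
emg_burst_table <- function(emg_amp) {
  list(
    rectus_femoris = list(c = c(0.03, 0.65), k = c(8, 10), a = c(0.7, 0.25)),
    vastus_lateralis = list(c = 0.05, k = 8, a = 0.8),
    vastus_medialis = list(c = 0.05, k = 8, a = 0.75),
    semitendinosus = list(c = 0.92, k = 8, a = 0.7),
    biceps_femoris = list(c = 0.92, k = 8, a = 0.65),
    gastrocnemius_medialis = list(c = 0.45, k = 6, a = emg_amp),
    soleus = list(c = 0.47, k = 6, a = emg_amp),
    tibialis_anterior = list(c = c(0.02, 0.75), k = c(10, 4),
                             a = c(emg_amp, emg_amp * 0.8)))
}

#' Generate a 16-channel synthetic EMG montage with MVC trials
#'
#' Band-limited noise carriers amplitude-modulated by phase-locked burst
#' envelopes (8 muscles per leg, right leg half a cycle out of phase),
#' plus a constant resting offset. Also generates 5 isometric-contraction
#' trials per muscle whose peak defines the maximum voluntary activation,
#' and a quiet-standing resting trial.
#'
#' @param config a [synth_config()].
#' @param duration trial length, s.
#' @param seed RNG seed.
#' @return list with `time`, `channels` (matrix, columns
#'   `<muscle>_l`/`<muscle>_r`, mV), `fs`, `mvc_trials` (per muscle, 5
#'   vectors), `mvc_true` (commanded maxima), `resting` (vector),
#'   `resting_offset`.
#' @export
generate_emg <- function(config, duration = config$n_cycles *
                           config$cycle_duration, seed = 1L) {
  set.seed(seed)
  fs <- config$emg_fs
  tt <- seq(0, duration, by = 1 / fs)
  n <- length(tt)
  T <- config$cycle_duration
  bursts <- emg_burst_table(config$emg_amp)
  carrier <- function(n) {
    x <- stats::rnorm(n)
    y <- bw_filter(x, "high", 2, 30, fs, zero_phase = FALSE)
    y / stats::sd(y)
  }
  chans <- matrix(0, n, 16L)
  cn <- character(16L)
  k <- 0L
  for (sfx in c("l", "r")) {
    ph <- if (sfx == "l") 0 else 0.5
    for (mu in EMG_MUSCLES) {
      k <- k + 1L
      cn[k] <- paste0(mu, "_", sfx)
      bs <- bursts[[mu]]
      env <- rep(0, n)
      s <- (tt / T - ph) %% 1
      for (j in seq_along(bs$c))
        env <- pmax(env, bs$a[j] * phase_bump(s, bs$c[j], bs$k[j]))
      chans[, k] <- env * carrier(n) + config$resting_offset
    }
  }
  colnames(chans) <- cn
  # MVC trials: plateau contractions, the strongest sets the maximum
  mvc_true <- stats::setNames(
    vapply(EMG_MUSCLES, function(mu) 1.2 * max(bursts[[mu]]$a), 0),
    EMG_MUSCLES)
  tm <- seq(0, 3, by = 1 / fs)
  nm <- length(tm)
  plateau <- exp(-((tm - 1.5) / 0.9)^4)  # smooth on-hold-off profile
  mvc_trials <- lapply(EMG_MUSCLES, function(mu) {
    lapply(1:5, function(i) {
      amp <- mvc_true[[mu]] * (0.75 + 0.05 * i)  # trial 5 hits the max
      amp * plateau * carrier(nm) + config$resting_offset
    })
  })
  names(mvc_trials) <- EMG_MUSCLES
  resting <- rep(config$resting_offset, 5L * fs)
  list(time = tt, channels = chans, fs = fs, mvc_trials = mvc_trials,
       mvc_true = mvc_true, resting = resting,
       resting_offset = config$resting_offset)
}

#' Generate an exoskeleton encoder stream from a motion
#'
#' Encoder angle = exoskeleton joint angle + constant offset + white
#' noise, sampled on the motion clock; motor-activation timestamps (for
#' maneuver trials) are carried through as an attribute.
#'
#' @param traj `coordinate_trajectory` containing the exoskeleton
#'   coordinates.
#' @param offset_deg constant encoder offset, deg.
#' @param noise_sd_deg white-noise SD, deg.
#' @param seed RNG seed.
#' @param activation_times optional motor-activation timestamps, s.
#' @return data frame `time` + one `<coordinate>_deg` column per
#'   exoskeleton hip/knee coordinate; activation times in
#'   `attr(, "activation_times")`.
#' @export
generate_encoder <- function(traj, offset_deg = 5, noise_sd_deg = 1,
                             seed = 1L, activation_times = NULL) {
  set.seed(seed)
  cols <- grep("^exo_(hip|knee)_", colnames(traj$q), value = TRUE)
  if (!length(cols)) stopf("trajectory has no exoskeleton joint coordinates")
  out <- data.frame(time = traj$time)
  for (cc in cols)
    out[[paste0(cc, "_deg")]] <- rad2deg(traj$q[, cc]) + offset_deg +
      stats::rnorm(length(traj$time), 0, noise_sd_deg)
  attr(out, "activation_times") <- activation_times
  out
}

#' Generate one fully labelled synthetic walking trial
#'
#' @param config a [synth_config()].
#' @param models a [build_study_models()] list.
#' @param trial trial index (drives the per-trial RNG stream and the
#'   small commanded-amplitude jitter).
#' @return a `synth_trial` list: `condition`, `config` (with the trial's
#'   jittered amplitudes), `markers`, `loads`, `emg`, `encoder` (assisted
#'   only) and `truth` (trajectories, generator torques, event times).
#' @export
generate_walking_trial <- function(config, models, trial = 1L) {
  seed0 <- config$seed + 7919L * trial
  set.seed(seed0)
  tcfg <- config
  if (config$amplitude_jitter_sd_deg > 0) {
    tcfg$knee_peak_deg <- config$knee_peak_deg +
      stats::rnorm(1, 0, config$amplitude_jitter_sd_deg)
    tcfg$ankle_plantar_deg <- max(0.5, config$ankle_plantar_deg +
                                    stats::rnorm(1, 0, config$amplitude_jitter_sd_deg))
  }
  assisted <- config$condition == "assisted"
  mk_model <- if (assisted) models$coupled else models$human
  id_model <- if (assisted) models$lumped else models$human
  traj <- generate_gait_trajectory(tcfg, mk_model)
  traj_id <- subset_trajectory(traj, id_model)
  loads <- generate_consistent_loads(id_model, traj_id, tcfg)
  markers <- generate_markers(mk_model, traj, tcfg$marker_noise_sd,
                              tcfg$occlusion_rate, seed = seed0 + 1L)
  emg <- generate_emg(tcfg, seed = seed0 + 2L)
  encoder <- if (assisted)
    generate_encoder(traj, tcfg$encoder_offset_deg,
                     tcfg$encoder_noise_sd_deg, seed = seed0 + 3L)
  gf <- inverse_dynamics(id_model, traj_id, loads)
  T <- tcfg$cycle_duration
  duty <- 0.5 + tcfg$double_support
  events <- data.frame(
    foot = c("left", "right"),
    t_strike = c(0, 0.5 * T),
    t_toeoff = c(duty * T, (0.5 + duty) * T))
  structure(list(condition = config$condition, config = tcfg,
                 markers = markers, loads = loads, emg = emg,
                 encoder = encoder,
                 truth = list(trajectory = traj, trajectory_id = traj_id,
                              torques = gf, events = events)),
            class = "synth_trial")
}

#' Generate a set of synthetic walking trials
#'
#' @param condition `"assisted"` or `"unassisted"`.
#' @param n_trials number of trials (default 6, the study's successful
#'   trial count per condition).
#' @param seed base RNG seed.
#' @param config optional [synth_config()] override.
#' @param models optional [build_study_models()] list (built once if
#'   omitted).
#' @return a `synth_trial_set` list: `condition`, `config`, `models`,
#'   `trials`.
#' @export
generate_walking_trials <- function(condition = c("assisted", "unassisted"),
                                    n_trials = 6L, seed = 1L,
                                    config = NULL, models = NULL) {
  condition <- match.arg(condition)
  config <- config %||% synth_config(condition, seed = seed)
  config$seed <- seed
  models <- models %||% build_study_models(
    frame_offset_deg = config$frame_offset_deg)
  trials <- lapply(seq_len(n_trials), function(i)
    generate_walking_trial(config, models, trial = i))
  structure(list(condition = condition, config = config, models = models,
                 trials = trials), class = "synth_trial_set")
}

#' Synthetic torso-pitch profile for a sit-stand maneuver
#'
#' Positioning lean, 3 s hold, motor-driven completion: the device
#' protocol's phase structure with a known activation timestamp.
#'
#' @param maneuver `"sit_to_stand"` (9 deg forward lean) or
#'   `"stand_to_sit"` (6 deg backward lean).
#' @param hold hold duration, s (default 3, the device protocol).
#' @param rate sampling rate, Hz.
#' @param noise_sd_deg measurement noise SD, deg.
#' @param seed RNG seed.
#' @return list with `time`, `torso_deg`, `activation_time`, `maneuver`.
#' @export
generate_maneuver_torso <- function(maneuver = c("sit_to_stand",
                                                 "stand_to_sit"),
                                    hold = 3, rate = 100,
                                    noise_sd_deg = 0.05, seed = 1L) {
  maneuver <- match.arg(maneuver)
  set.seed(seed)
  lean <- if (maneuver == "sit_to_stand") 9 else -6
  t_ramp0 <- 1; ramp <- 1.2; t_hold0 <- t_ramp0 + ramp
  activation <- t_hold0 + hold
  rise <- 1.5; t_end <- activation + rise + 2
  tt <- seq(0, t_end, by = 1 / rate)
  smooth01 <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }
  ang <- lean * smooth01((tt - t_ramp0) / ramp) -
    lean * smooth01((tt - activation) / rise)
  ang <- ang + stats::rnorm(length(tt), 0, noise_sd_deg)
  list(time = tt, torso_deg = ang, activation_time = activation,
       maneuver = maneuver)
}
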