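test_that("commanded joint amplitudes appear exactly in the pre-noise trajectory", {
  m <- study_models()
  for (cond in c("assisted", "unassisted")) {
    cfg <- synth_config(cond, amplitude_jitter_sd_deg = 0, n_cycles = 1L,
                        lead_in = 0, rate = 500)  # dense grid for the peak
    model <- if (cond == "assisted") m$coupled else m$human
    traj <- generate_gait_trajectory(cfg, model)
    peak <- max(traj$q[, "knee_l_angle"]) * 180 / pi
    expect_equal(peak, cfg$knee_peak_deg, tolerance = 1e-3)
  }
  expect_error(generate_gait_trajectory(
    synth_config("assisted", knee_peak_deg = 200), m$human), "range")
})

test_that("zero amplitudes produce a static standing trajectory", {
  m <- study_models()$human
  cfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0, speed = 0,
                      knee_peak_deg = 0, hip_max_deg = 0, hip_min_deg = 0,
                      ankle_dorsi_deg = 0, ankle_plantar_deg = 0,
                      mtp_deg = 0, subtalar_deg = 0, pelvis_bob = 0,
                      pelvis_sway = 0, pelvis_surge = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, m)
  expect_lt(max(abs(sweep(traj$q, 2L, traj$q[1, ]))), 1e-12)
  expect_true(all(traj$qdot == 0) && all(traj$qddot == 0))
})

test_that("markers reproduce forward kinematics, injected noise and seeds", {
  m <- study_models()$human
  cfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, m)
  sub <- 1:20
  traj <- coordinate_trajectory(traj$time[sub], traj$q[sub, ])
  clean <- generate_markers(m, traj, noise_sd = 0, seed = 1)
  fk1 <- forward_kinematics(m, traj$q[5, ])$markers
  expect_equal(matrix(clean$positions[5, , ], ncol = 3,
                      dimnames = list(clean$names, NULL)),
               fk1, tolerance = 1e-12, ignore_attr = TRUE)
  noisy <- generate_markers(m, traj, noise_sd = 0.004, seed = 2)
  d <- noisy$positions - attr(noisy, "truth")
  expect_equal(stats::sd(d), 0.004, tolerance = 0.05)
  again <- generate_markers(m, traj, noise_sd = 0.004, seed = 2)
  expect_identical(noisy$positions, again$positions)
  occ <- generate_markers(m, traj, noise_sd = 0, occlusion_rate = 0.3,
                          seed = 3)
  expect_equal(mean(occ$occluded), 0.3, tolerance = 0.05)
})

test_that("generated loads balance the whole-body equations frame by frame", {
  m <- study_models()$human
  cfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, m)
  sub <- seq(1, length(traj$time), by = 5)
  traj <- coordinate_trajectory(traj$time[sub], traj$q[sub, ],
                                traj$qdot[sub, ], traj$qddot[sub, ])
  loads <- generate_consistent_loads(m, traj, cfg)
  # sum of foot forces equals the whole-body Newton resultant
  masses <- vapply(m$segments, `[[`, 0, "mass")[m$order]
  nms <- coordinate_names(m)
  for (i in c(1, 10, 20)) {
    kin <- exogait:::fk_pass(m, traj$q[i, nms], traj$qdot[i, nms],
                             traj$qddot[i, nms])
    Ft <- c(0, 0, 0)
    for (b in seq_len(n_segments(m))) {
      seg <- m$segments[[m$order[b]]]
      cg <- as.numeric(kin$R[[b]] %*% seg$com)
      a_com <- kin$a[, b] + exogait:::cross3(kin$al[, b], cg) +
        exogait:::cross3(kin$w[, b], exogait:::cross3(kin$w[, b], cg))
      Ft <- Ft + seg$mass * (a_com - m$gravity)
    }
    tot <- loads$left$force[i, ] + loads$right$force[i, ]
    expect_equal(tot, Ft, tolerance = 1e-9)
  }
  # single support: the swing foot is unloaded
  s <- (traj$time / cfg$cycle_duration) %% 1
  swing_r <- which(s > 0.15 & s < 0.45)
  expect_true(all(abs(loads$right$force[swing_r, ]) < 1e-9))
  # COP stays on the ground plane
  expect_true(all(loads$left$cop[, 3] == 0))
})

test_that("static standing with even weight distribution puts half the weight on each foot", {
  m <- study_models()$human
  cfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0, speed = 0,
                      knee_peak_deg = 0, hip_max_deg = 0, hip_min_deg = 0,
                      ankle_dorsi_deg = 0, ankle_plantar_deg = 0,
                      mtp_deg = 0, subtalar_deg = 0, pelvis_bob = 0,
                      pelvis_sway = 0, pelvis_surge = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, m)
  loads <- generate_consistent_loads(m, traj, cfg)
  W <- total_mass(m) * 9.81
  # mid weight-transfer instant: stance weights are exactly 0.5/0.5
  s <- (traj$time / cfg$cycle_duration) %% 1
  i <- which.min(abs(s - cfg$double_support / 2))
  expect_equal(loads$left$force[i, 3], W / 2, tolerance = 1e-9)
  expect_equal(loads$right$force[i, 3], W / 2, tolerance = 1e-9)
  # every frame sums to exactly one body weight
  expect_equal(loads$left$force[, 3] + loads$right$force[, 3],
               rep(W, length(traj$time)), tolerance = 1e-9)
})

test_that("generated EMG self-normalizes through the conditioning chain", {
  cfg <- synth_config("assisted", n_cycles = 1L, lead_in = 0)
  emg <- generate_emg(cfg, duration = 2.1, seed = 4)
  expect_equal(dim(emg$channels)[2], 16L)
  mvc <- compute_mvc(emg$mvc_trials, fs = emg$fs)
  rest_mean <- compute_resting_mean(emg$resting)
  expect_equal(rest_mean, cfg$resting_offset, tolerance = 1e-12)
  # the strongest MVC trial normalizes to a unit peak by construction
  mu <- "soleus"
  peaks5 <- vapply(emg$mvc_trials[[mu]], function(tr)
    max(process_emg(tr, rest_mean, mvc[[mu]], fs = emg$fs)), 0)
  expect_equal(max(peaks5), 1.0, tolerance = 1e-9)
  # locomotion envelopes stay in a plausible sub-maximal band
  env <- process_emg(emg$channels[, "soleus_l"], rest_mean, mvc[[mu]],
                     fs = emg$fs)
  expect_lt(max(env), 1.2)
  expect_gt(max(env), 0.05)
  # a burst-free channel from the resting trial stays near zero
  env0 <- process_emg(emg$resting, rest_mean, mvc[[mu]], fs = emg$fs)
  expect_lt(max(abs(env0)), 1e-6)
  # burst placement: plantarflexor activity peaks in the propulsion half
  tn <- (emg$time / cfg$cycle_duration) %% 1
  expect_true(tn[which.max(env)] > 0.25 && tn[which.max(env)] < 0.7)
})

test_that("encoder streams carry the offset and are seed-deterministic", {
  m <- study_models()
  cfg <- synth_config("assisted", n_cycles = 1L, lead_in = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, m$coupled)
  enc0 <- generate_encoder(traj, offset_deg = 12, noise_sd_deg = 0, seed = 1)
  r <- compare_ik_encoder(traj$time, rad2deg(traj$q[, "exo_hip_l_angle"]),
                          enc0$time, enc0$exo_hip_l_angle_deg)
  expect_equal(r$rms, 0, tolerance = 1e-9)
  expect_equal(r$offset, -12, tolerance = 1e-9)
  e1 <- generate_encoder(traj, seed = 9)
  e2 <- generate_encoder(traj, seed = 9)
  expect_identical(e1, e2)
  expect_error(generate_encoder(
    coordinate_trajectory(traj$time,
                          traj$q[, 1:6, drop = FALSE])), "exoskeleton")
})

test_that("whole trials are reproducible under a fixed seed", {
  m <- study_models()
  cfg <- synth_config("assisted", n_cycles = 1L, lead_in = 0)
  t1 <- generate_walking_trial(cfg, m, trial = 2L)
  t2 <- generate_walking_trial(cfg, m, trial = 2L)
  expect_identical(t1$markers$positions, t2$markers$positions)
  expect_identical(t1$loads$left$force, t2$loads$left$force)
  expect_identical(t1$emg$channels, t2$emg$channels)
  expect_identical(t1$encoder, t2$encoder)
  expect_identical(t1$truth$torques$tau, t2$truth$torques$tau)
})
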