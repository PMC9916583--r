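static_traj <- function(model, q) {
  n <- n_coordinates(model)
  coordinate_trajectory(0, matrix(q, 1, n,
                                  dimnames = list(NULL, coordinate_names(model))),
                        matrix(0, 1, n), matrix(0, 1, n))
}

test_that("pendulum statics match the closed form m g l_c", {
  pend <- make_pendulum(mass = 2, length = 1)
  # +90 deg about the -Y flexion axis brings the rod horizontal
  gf <- inverse_dynamics(pend, static_traj(pend, pi / 2))
  expect_equal(abs(unname(gf$tau[1, 1])), 2 * 9.81 * 0.5,
               tolerance = 1e-12)
  gf0 <- inverse_dynamics(pend, static_traj(pend, 0))
  expect_equal(unname(gf0$tau[1, 1]), 0, tolerance = 1e-12)
})

test_that("static ID equals an independent lever-arm moment balance", {
  ch <- make_random_chain(21, 3L)
  set.seed(22)
  q <- rnorm(3, 0, 0.5)
  gf <- inverse_dynamics(ch, static_traj(ch, q))
  # oracle: explicit gravity moment about each pin axis via lever arms
  fk <- forward_kinematics(ch, q)
  kin <- exogait:::fk_pass(ch, q)
  for (k in 1:3) {
    u <- kin$ax[, k]; pk <- kin$org[, k]
    mom <- 0
    for (b in k:3) {
      seg <- ch$segments[[ch$order[b]]]
      xc <- fk$segments[[ch$order[b]]]$p +
        as.numeric(fk$segments[[ch$order[b]]]$R %*% seg$com)
      Fg <- seg$mass * c(0, 0, -9.81)
      arm <- xc - pk
      mom <- mom + sum(u * c(arm[2] * Fg[3] - arm[3] * Fg[2],
                             arm[3] * Fg[1] - arm[1] * Fg[3],
                             arm[1] * Fg[2] - arm[2] * Fg[1]))
    }
    expect_equal(unname(gf$tau[1, k]), -mom, tolerance = 1e-10)
  }
})

test_that("forward dynamics conserves energy and the small-angle period", {
  pend <- make_pendulum(mass = 2, length = 1)
  te <- seq(0, 10, by = 0.02)
  sol <- forward_dynamics_oracle(pend, q0 = 0.5, qdot0 = 0, t_eval = te)
  E <- vapply(seq_along(te), function(i)
    total_energy(pend, sol$q[i, ], sol$qdot[i, ]), 0)
  expect_lt(max(abs(E - E[1])), 1e-8)
  # small-angle limit: T = 2 pi sqrt(I_pivot / (m g l_c))
  I_pivot <- 2 * 1^2 / 12 + 2 * 0.5^2
  Texp <- 2 * pi * sqrt(I_pivot / (2 * 9.81 * 0.5))
  fine <- seq(0, 4, by = 0.002)
  sol2 <- forward_dynamics_oracle(pend, q0 = 0.01, qdot0 = 0, t_eval = fine)
  qq <- sol2$q[, 1]
  up <- which(qq[-length(qq)] <= 0 & qq[-1] > 0)
  # subsample-accurate crossings by linear interpolation
  tcross <- fine[up] - qq[up] * 0.002 / (qq[up + 1] - qq[up])
  expect_equal(mean(diff(tcross)), Texp, tolerance = 1e-3)
  # zero state, zero torque, zero gravity stays identically zero
  p0 <- make_pendulum()
  p0$gravity <- c(0, 0, 0)
  solz <- forward_dynamics_oracle(p0, 0, 0, t_eval = seq(0, 1, by = 0.1))
  expect_true(all(solz$q == 0) && all(solz$qdot == 0))
})

test_that("ID recovers the torques that drove the forward-dynamics oracle", {
  for (seed in c(1, 2, 3)) {
    ndof <- 3L + seed %% 3L
    ch <- make_random_chain(seed, ndof)
    tau <- make_chain_torque(seed, ndof)
    te <- seq(0, 1.2, by = 0.01)
    sol <- forward_dynamics_oracle(ch, q0 = rep(0.1, ndof),
                                   qdot0 = rep(0, ndof), tau = tau,
                                   t_eval = te)
    gf <- inverse_dynamics(ch, sol)
    ref <- t(vapply(te, tau, numeric(ndof)))
    expect_lt(max(abs(gf$tau - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("ID is linear in external loads and accelerations", {
  ch <- make_random_chain(31, 3L)
  set.seed(32)
  n <- 5L
  tt <- seq(0, 0.4, length.out = n)
  nm <- coordinate_names(ch)
  Q <- matrix(rnorm(n * 3, 0, 0.3), n, 3, dimnames = list(NULL, nm))
  Qd <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  Qdd1 <- matrix(rnorm(n * 3), n, 3)
  Qdd2 <- matrix(rnorm(n * 3), n, 3)
  mk_load <- function(scale) external_load(
    "link3", tt, force = scale * matrix(rnorm(n * 3, 0, 20), n, 3),
    cop = matrix(rnorm(n * 3, 0, 0.2), n, 3))
  set.seed(33); ldA <- mk_load(1)
  # superposition in qdd at fixed (q, qd): tau(a+b) + tau(0) = tau(a) + tau(b)
  tr <- function(qdd) coordinate_trajectory(tt, Q, Qd, qdd)
  t_a <- inverse_dynamics(ch, tr(Qdd1))$tau
  t_b <- inverse_dynamics(ch, tr(Qdd2))$tau
  t_ab <- inverse_dynamics(ch, tr(Qdd1 + Qdd2))$tau
  t_0 <- inverse_dynamics(ch, tr(0 * Qdd1))$tau
  expect_equal(t_ab + t_0, t_a + t_b, tolerance = 1e-9)
  # doubling a load doubles its contribution
  t_noload <- inverse_dynamics(ch, tr(Qdd1))$tau
  t_l1 <- inverse_dynamics(ch, tr(Qdd1), list(ldA))$tau
  ld2 <- external_load(ldA$body, tt, 2 * ldA$force, ldA$cop,
                       2 * ldA$free_moment)
  t_l2 <- inverse_dynamics(ch, tr(Qdd1), list(ld2))$tau
  expect_equal(t_l2 - t_noload, 2 * (t_l1 - t_noload), tolerance = 1e-9)
})

test_that("moment normalization divides by the condition's mass and round-trips", {
  gf <- structure(list(time = 0, tau = matrix(19.62, 1, 1),
                       kinds = "rotation", residual_idx = integer(0)),
                  class = "generalized_forces")
  nm <- normalize_moments(gf, "unassisted", subject_mass = 89.4)
  expect_equal(nm$tau_norm[1, 1], 19.62 / 89.4, tolerance = 1e-12)
  expect_equal(nm$tau_norm[1, 1], 0.2195, tolerance = 5e-4)
  expect_equal(denormalize_moments(nm)$tau, gf$tau, tolerance = 1e-12)
  nma <- normalize_moments(gf, "assisted", subject_mass = 89.4, exo_mass = 23)
  expect_equal(nma$tau_norm[1, 1], 19.62 / 112.4, tolerance = 1e-12)
  # assisted with a zero-mass device degenerates to unassisted
  nm0 <- normalize_moments(gf, "assisted", subject_mass = 89.4, exo_mass = 0)
  expect_equal(nm0$tau_norm, nm$tau_norm)
  expect_equal(normalize_moments(gf, "unassisted", 89.4)$tau_norm[1, 1] * 89.4,
               19.62, tolerance = 1e-12)
  expect_error(normalize_moments(gf, "unassisted", -1), "subject_mass")
  gf0 <- gf; gf0$tau[] <- 0
  expect_equal(normalize_moments(gf0, "unassisted", 89.4)$tau_norm[1, 1], 0)
})

test_that("synthetic loads null the base residuals; zeroing or doubling them shifts the vertical residual by one weight", {
  m <- study_models()
  model <- m$human
  # moving gait fixture: residuals vanish to machine precision
  cfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0,
                      amplitude_jitter_sd_deg = 0)
  traj <- generate_gait_trajectory(cfg, model)
  sub <- seq(1, length(traj$time), by = 10)
  traj <- coordinate_trajectory(traj$time[sub], traj$q[sub, ],
                                traj$qdot[sub, ], traj$qddot[sub, ])
  loads <- generate_consistent_loads(model, traj, cfg)
  gf <- inverse_dynamics(model, traj, loads)
  res <- check_residuals(gf, model, traj, loads)
  expect_lt(res$frac_weight, 1e-9)
  expect_lt(res$max_mismatch, 1e-6)

  # static standing: the load shift equals exactly one model weight
  scfg <- synth_config("unassisted", n_cycles = 1L, lead_in = 0,
                       speed = 0, knee_peak_deg = 0, hip_max_deg = 0,
                       hip_min_deg = 0, ankle_dorsi_deg = 0,
                       ankle_plantar_deg = 0, mtp_deg = 0, subtalar_deg = 0,
                       pelvis_bob = 0, pelvis_sway = 0, pelvis_surge = 0,
                       amplitude_jitter_sd_deg = 0)
  straj <- generate_gait_trajectory(scfg, model)
  sub <- seq(1, length(straj$time), by = 20)
  straj <- coordinate_trajectory(straj$time[sub], straj$q[sub, ],
                                 straj$qdot[sub, ], straj$qddot[sub, ])
  expect_true(all(straj$qddot == 0))
  sloads <- generate_consistent_loads(model, straj, scfg)
  W <- total_mass(model) * 9.81
  sgf <- inverse_dynamics(model, straj, sloads)
  tz <- grep("_tz$", coordinate_names(model))[1]
  expect_lt(max(abs(sgf$tau[, tz])), 1e-9 * W)
  sgf0 <- inverse_dynamics(model, straj)        # loads zeroed
  expect_equal(unname(sgf0$tau[, tz] - sgf$tau[, tz]),
               rep(W, nrow(sgf$tau)), tolerance = 1e-9)
  dbl <- lapply(sloads, function(ld)
    external_load(ld$body, ld$time, 2 * ld$force, ld$cop, 2 * ld$free_moment))
  sgf2 <- inverse_dynamics(model, straj, dbl)
  expect_equal(unname(sgf2$tau[, tz] - sgf$tau[, tz]),
               rep(-W, nrow(sgf$tau)), tolerance = 1e-9)
})
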