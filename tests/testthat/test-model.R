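test_that("default human model has 24 segments and 37 coordinates with the per-joint DoF audit", {
  h <- build_human_model()
  expect_equal(n_segments(h), 24L)
  expect_equal(n_coordinates(h), 37L)
  # per-leg audit: ball hip 3 + coupled knee 1 + ankle/subtalar/mtp pins 3
  for (sfx in c("l", "r")) {
    leg <- sum(lengths(lapply(paste0(c("hip_", "knee_", "ankle_",
                                       "subtalar_", "mtp_"), sfx),
                              joint_coord_indices, model = h)))
    expect_equal(leg, 7L)
    arm <- sum(lengths(lapply(paste0(c("shoulder_", "elbow_", "radioulnar_",
                                       "wrist_"), sfx),
                              joint_coord_indices, model = h)))
    expect_equal(arm, 7L)
  }
  expect_length(joint_coord_indices(h, "ground_pelvis"), 6L)
  expect_length(joint_coord_indices(h, "back"), 3L)
  # a legs-only layout carries 6 + 7 + 7 coordinates
  legs <- build_human_model(default_human_config(arms = FALSE, torso = FALSE))
  expect_equal(n_coordinates(legs), 20L)
})

test_that("exoskeleton model has 7 segments, 4 pin coordinates and welded ankles", {
  e <- build_exoskeleton_model()
  expect_equal(n_segments(e), 7L)
  expect_equal(n_coordinates(e), 4L)
  expect_equal(get_joint(e, "exo_ankle_l")$type, "weld")
  expect_length(joint_coord_indices(e, "exo_ankle_l"), 0L)
  # faithful mode rejects a ball hip
  cfg <- default_exoskeleton_config()
  i <- which(vapply(cfg$joints, `[[`, "", "name") == "exo_hip_l")
  cfg$joints[[i]]$type <- "ball"
  cfg$joints[[i]]$axes <- NULL   # take the ball default axis triple
  cfg$expect <- NULL
  expect_error(build_exoskeleton_model(cfg), "must be a pin")
})

test_that("model invariants are enforced", {
  s2 <- list(segment("a", 1), segment("b", 1))
  expect_error(multibody_model(
    list(segment("a", 1), segment("a", 1)),
    list(joint("j1", "pin", "ground", "a"))), "duplicate segment")
  # cycle: a -> b -> a
  expect_error(multibody_model(
    s2, list(joint("j1", "pin", "a", "b"), joint("j2", "pin", "b", "a"))),
    "non-tree")
  expect_error(segment("x", -1), "mass")
  expect_error(segment("x", 1, inertia = matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
    "positive semidefinite")
  expect_error(marker("m", "a", c(0, 0, 0), weight = -1), "weight")
})

test_that("coupling the models yields 37 + 4 + 6 coordinates and rejects collisions", {
  m <- study_models()
  expect_equal(n_coordinates(m$coupled), 47L)
  locked <- couple_models(m$human, m$exo, lock_anchor = TRUE)
  expect_equal(n_coordinates(locked), 41L)
  expect_error(couple_models(m$human, m$human), "anchor")
  bad <- pelvic_anchor_joint()
  bad$type <- "pin"
  expect_error(couple_models(m$human, m$exo, anchor = bad), "universal6")
})

test_that("scaling preserves mass fractions and scales geometry by length ratios", {
  h <- build_human_model()
  # marker at local -0.20 on a segment scaled 1.1 moves to -0.22
  gen_len <- h$segments$femur_l$length
  anthro <- subject_anthropometry(total_mass(h),
                                  segment_lengths = c(femur_l = 1.1 * gen_len))
  hs <- scale_model(h, anthro)
  expect_equal(hs$segments$femur_l$com, h$segments$femur_l$com * 1.1)
  expect_equal(hs$markers$LKNE$local_position,
               h$markers$LKNE$local_position * 1.1)
  # the knee joint sits in the femur frame, so its location scales too
  expect_equal(hs$joints$tibia_l$location, h$joints$tibia_l$location * 1.1)

  # subject mass: every segment mass scaled by the same factor
  h2 <- scale_model(h, subject_anthropometry(89.4, 1.76))
  expect_equal(total_mass(h2), 89.4, tolerance = 1e-12)
  f <- 89.4 / total_mass(h)
  expect_equal(h2$segments$pelvis$mass, h$segments$pelvis$mass * f)

  # identity anthropometry leaves the model unchanged
  hi <- scale_model(h, subject_anthropometry(total_mass(h)))
  for (s in names(h$segments)) {
    expect_equal(hi$segments[[s]]$mass, h$segments[[s]]$mass, tolerance = 1e-12)
    expect_equal(hi$segments[[s]]$inertia, h$segments[[s]]$inertia,
                 tolerance = 1e-12)
  }
})

test_that("inertia lumping follows the parallel-axis theorem and conserves mass", {
  # point-mass transfer oracle: human (5 kg at origin, I = 0.1 diag) +
  # device point mass 5 kg offset 0.2 m -> com midway, Ixx by explicit
  # parallel-axis transfer of both halves
  human <- multibody_model(
    list(segment("pelvis", 5, com = c(0, 0, 0), inertia = diag(3) * 0.1)),
    list(joint("ground_pelvis", "universal6", "ground", "pelvis")))
  exo <- multibody_model(
    list(segment("exo_pelvic_band", 5, com = c(0, 0.2, 0),
                 inertia = diag(3) * 0)),
    list(joint("exo_ground", "weld", "ground", "exo_pelvic_band")))
  anchor <- joint("pelvic_anchor", "universal6", "pelvis",
                  "exo_pelvic_band", location = c(0, 0, 0))
  lum <- lump_exoskeleton_inertia(human, exo,
                                  mapping = c(exo_pelvic_band = "pelvis"),
                                  anchor = anchor)
  seg <- lum$segments$pelvis
  expect_equal(seg$mass, 10)
  expect_equal(seg$com, c(0, 0.1, 0))
  expect_equal(seg$inertia[1, 1], 0.1 + 5 * 0.1^2 + 5 * 0.1^2)

  # zero-mass device leaves the human segment untouched
  exo0 <- multibody_model(
    list(segment("exo_pelvic_band", 0, com = c(0, 0.2, 0))),
    list(joint("exo_ground", "weld", "ground", "exo_pelvic_band")))
  lum0 <- lump_exoskeleton_inertia(human, exo0,
                                   mapping = c(exo_pelvic_band = "pelvis"),
                                   anchor = anchor)
  expect_equal(lum0$segments$pelvis, human$segments$pelvis)

  # full study models: exact mass conservation, SPD inertia, topology kept
  m <- study_models()
  expect_equal(total_mass(m$lumped), total_mass(m$human) + total_mass(m$exo),
               tolerance = 1e-12)
  expect_equal(n_coordinates(m$lumped), 37L)
  for (s in names(m$lumped$segments)) {
    I <- m$lumped$segments[[s]]$inertia
    expect_true(all(abs(I - t(I)) < 1e-12))
    expect_true(all(eigen(I, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
  expect_error(lump_exoskeleton_inertia(m$human, m$exo, mapping = c()),
               "unmapped")
})
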