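# Generic model-definition configs.
#
# The generic human geometry (segment lengths, mass fractions, marker
# offsets) is an editable approximation of a standard whole-body gait
# model: the generic total mass is 75.16 kg and the generic stature
# 1.80 m, with segment mass fractions from standard gait-model tables.
# Exoskeleton inertial properties are user-supplied config inputs; the
# defaults below are documented placeholders summing to a configurable
# device mass. All frames are Z-up, X forward, Y left; units SI.

# inertia of a uniform rod of length L along Z with radius r
rod_inertia <- function(m, L, r = 0.12 * L) {
  if (!is.finite(L) || L <= 0) return(diag(3L) * 0)
  diag(c(m * (L^2 / 12 + r^2 / 4), m * (L^2 / 12 + r^2 / 4), m * r^2 / 2))
}

box_inertia <- function(m, dx, dy, dz) {
  diag(c(m * (dy^2 + dz^2), m * (dx^2 + dz^2), m * (dx^2 + dy^2)) / 12)
}

# mirror a config entry to the right side: flip Y of 3-vectors
mirror_y <- function(v) v * c(1, -1, 1)

GENERIC_STATURE <- 1.80
GENERIC_TOTAL_MASS <- 75.16

#' Default human model-definition config
#'
#' A generic 24-segment, 37-coordinate whole-body layout: a 6-DoF
#' ground-to-pelvis joint, per leg a 3-DoF ball hip, a 1-DoF coupled knee
#' (prescribed tibia translation table, all-zero by default), and 1-DoF
#' pin ankle, subtalar and metatarsal joints; a 3-DoF ball torso joint;
#' per arm a 3-DoF ball shoulder, pin elbow, pin radioulnar joint and a
#' 2-DoF wrist. The patella is carried by the femur (weld) and the
#' neck/head are welded, so they add segments but no coordinates.
#' Marker offsets approximate a conventional whole-body gait template
#' plus forefoot markers.
#'
#' @param legs,torso,arms include the respective branches (pelvis is
#'   always present). `torso = FALSE` also drops the arms and head.
#' @return a nested config list with elements `segments`, `joints`,
#'   `markers` and `expect` (declared segment/coordinate counts), suitable
#'   for [build_human_model()] or [write_model_config()].
#' @export
default_human_config <- function(legs = TRUE, torso = TRUE, arms = TRUE) {
  if (!torso) arms <- FALSE
  masses <- c(pelvis = 11.777, femur = 9.2152, patella = 0.0862,
              tibia = 3.7075, talus = 0.1, calcn = 1.25, toes = 0.2166,
              humerus = 2.0325, ulna = 0.6075, radius = 0.6075,
              hand = 0.4575, neck = 1.1, head = 4.2)
  masses["torso"] <- GENERIC_TOTAL_MASS -
    (masses[["pelvis"]] + 2 * sum(masses[c("femur", "patella", "tibia",
                                           "talus", "calcn", "toes",
                                           "humerus", "ulna", "radius",
                                           "hand")]) +
       masses[["neck"]] + masses[["head"]])

  segs <- list(list(name = "pelvis", mass = masses[["pelvis"]],
                    com = c(-0.01, 0, 0.02),
                    inertia = box_inertia(masses[["pelvis"]], 0.22, 0.26, 0.18),
                    length = 0.10))
  jnts <- list(list(name = "ground_pelvis", type = "universal6",
                    parent = "ground", child = "pelvis",
                    location = c(0, 0, 0)))
  mks <- list(
    list(name = "LASI", segment = "pelvis", local_position = c(0.02, 0.12, 0.02)),
    list(name = "RASI", segment = "pelvis", local_position = c(0.02, -0.12, 0.02)),
    list(name = "LPSI", segment = "pelvis", local_position = c(-0.14, 0.05, 0.04)),
    list(name = "RPSI", segment = "pelvis", local_position = c(-0.14, -0.05, 0.04)),
    list(name = "LICT", segment = "pelvis", local_position = c(-0.05, 0.13, 0.12)),
    list(name = "RICT", segment = "pelvis", local_position = c(-0.05, -0.13, 0.12)),
    list(name = "SACR", segment = "pelvis", local_position = c(-0.15, 0, 0.10)))

  side <- function(sfx, sgn) {
    # sgn = +1 for left (+Y), -1 for right
    m <- function(v) v * c(1, sgn, 1)
    segs <<- c(segs, list(
      list(name = paste0("femur_", sfx), mass = masses[["femur"]],
           com = c(0, 0, -0.17), inertia = rod_inertia(masses[["femur"]], 0.41),
           length = 0.41),
      list(name = paste0("patella_", sfx), mass = masses[["patella"]],
           com = c(0, 0, 0), inertia = diag(3) * 2e-5, length = 0.04),
      list(name = paste0("tibia_", sfx), mass = masses[["tibia"]],
           com = c(0, 0, -0.19), inertia = rod_inertia(masses[["tibia"]], 0.43),
           length = 0.43),
      list(name = paste0("talus_", sfx), mass = masses[["talus"]],
           com = c(0, 0, 0), inertia = diag(3) * 1e-4, length = 0.05),
      list(name = paste0("calcn_", sfx), mass = masses[["calcn"]],
           com = c(0.08, 0, -0.01),
           inertia = box_inertia(masses[["calcn"]], 0.22, 0.08, 0.06),
           length = 0.22),
      list(name = paste0("toes_", sfx), mass = masses[["toes"]],
           com = c(0.03, 0, -0.01),
           inertia = box_inertia(masses[["toes"]], 0.08, 0.07, 0.03),
           length = 0.08)))
    jnts <<- c(jnts, list(
      list(name = paste0("hip_", sfx), type = "ball", parent = "pelvis",
           child = paste0("femur_", sfx), location = m(c(0, 0.09, -0.07))),
      list(name = paste0("patellofemoral_", sfx), type = "weld",
           parent = paste0("femur_", sfx), child = paste0("patella_", sfx),
           location = c(0.045, 0, -0.38)),
      list(name = paste0("knee_", sfx), type = "coupled_knee",
           parent = paste0("femur_", sfx), child = paste0("tibia_", sfx),
           location = c(0, 0, -0.41), axes = list(c(0, 1, 0))),
      list(name = paste0("ankle_", sfx), type = "pin",
           parent = paste0("tibia_", sfx), child = paste0("talus_", sfx),
           location = c(0, 0, -0.43), axes = list(c(0, -1, 0))),
      list(name = paste0("subtalar_", sfx), type = "pin",
           parent = paste0("talus_", sfx), child = paste0("calcn_", sfx),
           location = c(-0.045, 0, -0.04), axes = list(c(1, 0, 0))),
      list(name = paste0("mtp_", sfx), type = "pin",
           parent = paste0("calcn_", sfx), child = paste0("toes_", sfx),
           location = c(0.16, 0, -0.01), axes = list(c(0, -1, 0)))))
    SFX <- toupper(sfx)
    mks <<- c(mks, list(
      list(name = paste0(SFX, "THI"), segment = paste0("femur_", sfx),
           local_position = m(c(0.02, 0.06, -0.25))),
      list(name = paste0(SFX, "THI2"), segment = paste0("femur_", sfx),
           local_position = m(c(0.05, 0.05, -0.10))),
      list(name = paste0(SFX, "KNE"), segment = paste0("femur_", sfx),
           local_position = m(c(0, 0.06, -0.40))),
      list(name = paste0(SFX, "KNM"), segment = paste0("femur_", sfx),
           local_position = m(c(0, -0.055, -0.40))),
      list(name = paste0(SFX, "TIB"), segment = paste0("tibia_", sfx),
           local_position = m(c(0.01, 0.055, -0.20))),
      list(name = paste0(SFX, "TIB2"), segment = paste0("tibia_", sfx),
           local_position = m(c(0.04, 0.03, -0.08))),
      list(name = paste0(SFX, "ANK"), segment = paste0("tibia_", sfx),
           local_position = m(c(0, 0.05, -0.42))),
      list(name = paste0(SFX, "ANM"), segment = paste0("tibia_", sfx),
           local_position = m(c(0, -0.045, -0.42))),
      list(name = paste0(SFX, "HEE"), segment = paste0("calcn_", sfx),
           local_position = m(c(-0.04, 0, 0.0))),
      list(name = paste0(SFX, "P5M"), segment = paste0("calcn_", sfx),
           local_position = m(c(0.06, 0.055, -0.02))),
      list(name = paste0(SFX, "D5M"), segment = paste0("calcn_", sfx),
           local_position = m(c(0.15, 0.05, -0.02))),
      list(name = paste0(SFX, "D1M"), segment = paste0("calcn_", sfx),
           local_position = m(c(0.15, -0.04, -0.02))),
      list(name = paste0(SFX, "TOE"), segment = paste0("toes_", sfx),
           local_position = m(c(0.06, 0, -0.01)))))
  }
  if (legs) { side("l", 1); side("r", -1) }

  if (torso) {
    segs <- c(segs, list(
      list(name = "torso", mass = masses[["torso"]], com = c(0, 0, 0.22),
           inertia = box_inertia(masses[["torso"]], 0.22, 0.30, 0.45),
           length = 0.40),
      list(name = "neck", mass = masses[["neck"]], com = c(0, 0, 0.05),
           inertia = rod_inertia(masses[["neck"]], 0.10), length = 0.10),
      list(name = "head", mass = masses[["head"]], com = c(0.01, 0, 0.08),
           inertia = diag(3) * 0.025, length = 0.15)))
    jnts <- c(jnts, list(
      list(name = "back", type = "ball", parent = "pelvis", child = "torso",
           location = c(-0.03, 0, 0.08)),
      list(name = "torso_neck", type = "weld", parent = "torso",
           child = "neck", location = c(0, 0, 0.42)),
      list(name = "neck_head", type = "weld", parent = "neck",
           child = "head", location = c(0, 0, 0.10))))
    mks <- c(mks, list(
      list(name = "C7", segment = "torso", local_position = c(-0.07, 0, 0.40)),
      list(name = "T10", segment = "torso", local_position = c(-0.08, 0, 0.16)),
      list(name = "CLAV", segment = "torso", local_position = c(0.06, 0, 0.37)),
      list(name = "STRN", segment = "torso", local_position = c(0.09, 0, 0.22)),
      list(name = "LFHD", segment = "head", local_position = c(0.08, 0.06, 0.06)),
      list(name = "RFHD", segment = "head", local_position = c(0.08, -0.06, 0.06)),
      list(name = "LBHD", segment = "head", local_position = c(-0.08, 0.06, 0.06)),
      list(name = "RBHD", segment = "head", local_position = c(-0.08, -0.06, 0.06))))
  }

  if (arms) {
    arm <- function(sfx, sgn) {
      m <- function(v) v * c(1, sgn, 1)
      segs <<- c(segs, list(
        list(name = paste0("humerus_", sfx), mass = masses[["humerus"]],
             com = c(0, 0, -0.15),
             inertia = rod_inertia(masses[["humerus"]], 0.33), length = 0.33),
        list(name = paste0("ulna_", sfx), mass = masses[["ulna"]],
             com = c(0, 0, -0.12),
             inertia = rod_inertia(masses[["ulna"]], 0.26), length = 0.26),
        list(name = paste0("radius_", sfx), mass = masses[["radius"]],
             com = c(0, 0, -0.11),
             inertia = rod_inertia(masses[["radius"]], 0.26), length = 0.26),
        list(name = paste0("hand_", sfx), mass = masses[["hand"]],
             com = c(0, 0, -0.07),
             inertia = rod_inertia(masses[["hand"]], 0.18), length = 0.18)))
      jnts <<- c(jnts, list(
        list(name = paste0("shoulder_", sfx), type = "ball", parent = "torso",
             child = paste0("humerus_", sfx), location = m(c(0, 0.19, 0.36))),
        list(name = paste0("elbow_", sfx), type = "pin",
             parent = paste0("humerus_", sfx), child = paste0("ulna_", sfx),
             location = c(0.01, 0, -0.33), axes = list(c(0, -1, 0))),
        list(name = paste0("radioulnar_", sfx), type = "pin",
             parent = paste0("ulna_", sfx), child = paste0("radius_", sfx),
             location = c(0.01, 0, -0.03), axes = list(c(0, 0, 1))),
        list(name = paste0("wrist_", sfx), type = "universal2",
             parent = paste0("radius_", sfx), child = paste0("hand_", sfx),
             location = c(0, 0, -0.23))))
      SFX <- toupper(sfx)
      mks <<- c(mks, list(
        list(name = paste0(SFX, "UPA"), segment = paste0("humerus_", sfx),
             local_position = m(c(0, 0.045, -0.15))),
        list(name = paste0(SFX, "ELB"), segment = paste0("humerus_", sfx),
             local_position = m(c(0.01, 0.045, -0.31))),
        list(name = paste0(SFX, "FRM"), segment = paste0("radius_", sfx),
             local_position = m(c(0.02, 0.03, -0.12))),
        list(name = paste0(SFX, "WRA"), segment = paste0("radius_", sfx),
             local_position = m(c(0.02, 0.03, -0.22))),
        list(name = paste0(SFX, "WRB"), segment = paste0("radius_", sfx),
             local_position = m(c(-0.02, -0.03, -0.22))),
        list(name = paste0(SFX, "FIN"), segment = paste0("hand_", sfx),
             local_position = m(c(0.02, 0, -0.10)))))
    }
    arm("l", 1); arm("r", -1)
  }

  n_seg <- length(segs)
  n_q <- 6L + (if (legs) 14L else 0L) + (if (torso) 3L else 0L) +
    (if (arms) 14L else 0L)
  list(name = "human", stature = GENERIC_STATURE, segments = segs,
       joints = jnts, markers = mks,
       expect = list(n_segments = n_seg, n_coordinates = n_q))
}

#' Default exoskeleton model-definition config
#'
#' A 7-segment lower-extremity device: pelvic band, thigh/shank/foot-plate
#' pairs; pin hip and knee joints, welded ankles. Segment masses and
#' inertias are placeholders summing to `device_mass` (the device is not
#' characterized here; supply measured values for real work).
#'
#' @param device_mass total device mass, kg (default 23).
#' @return a nested config list as for [default_human_config()].
#' @export
default_exoskeleton_config <- function(device_mass = 23) {
  frac <- c(band = 9, thigh = 3, shank = 2.5, foot = 1.5) / 23 * device_mass
  segs <- list(list(name = "exo_pelvic_band", mass = frac[["band"]],
                    com = c(-0.06, 0, 0),
                    inertia = box_inertia(frac[["band"]], 0.25, 0.40, 0.20),
                    length = 0.20))
  jnts <- list(list(name = "exo_ground", type = "weld", parent = "ground",
                    child = "exo_pelvic_band", location = c(0, 0, 0)))
  mks <- list(
    list(name = "EXO_PB1", segment = "exo_pelvic_band", local_position = c(-0.16, 0.12, 0.05)),
    list(name = "EXO_PB2", segment = "exo_pelvic_band", local_position = c(-0.16, -0.12, 0.05)),
    list(name = "EXO_PB3", segment = "exo_pelvic_band", local_position = c(0.02, 0.16, 0.0)),
    list(name = "EXO_PB4", segment = "exo_pelvic_band", local_position = c(0.02, -0.16, 0.0)))
  side <- function(sfx, sgn) {
    m <- function(v) v * c(1, sgn, 1)
    segs <<- c(segs, list(
      list(name = paste0("exo_thigh_", sfx), mass = frac[["thigh"]],
           com = c(0, 0, -0.20), inertia = rod_inertia(frac[["thigh"]], 0.41, 0.03),
           length = 0.41),
      list(name = paste0("exo_shank_", sfx), mass = frac[["shank"]],
           com = c(0, 0, -0.20), inertia = rod_inertia(frac[["shank"]], 0.43, 0.03),
           length = 0.43),
      list(name = paste0("exo_foot_", sfx), mass = frac[["foot"]],
           com = c(0.08, 0, -0.03),
           inertia = box_inertia(frac[["foot"]], 0.25, 0.09, 0.04),
           length = 0.25)))
    jnts <<- c(jnts, list(
      list(name = paste0("exo_hip_", sfx), type = "pin",
           parent = "exo_pelvic_band", child = paste0("exo_thigh_", sfx),
           location = m(c(0, 0.125, -0.07)), axes = list(c(0, -1, 0))),
      list(name = paste0("exo_knee_", sfx), type = "pin",
           parent = paste0("exo_thigh_", sfx), child = paste0("exo_shank_", sfx),
           location = c(0, 0, -0.41), axes = list(c(0, 1, 0))),
      list(name = paste0("exo_ankle_", sfx), type = "weld",
           parent = paste0("exo_shank_", sfx), child = paste0("exo_foot_", sfx),
           location = c(0, 0, -0.43))))
    SFX <- toupper(sfx)
    mks <<- c(mks, list(
      list(name = paste0("EXO_", SFX, "TH1"), segment = paste0("exo_thigh_", sfx),
           local_position = m(c(0.03, 0.05, -0.12))),
      list(name = paste0("EXO_", SFX, "TH2"), segment = paste0("exo_thigh_", sfx),
           local_position = m(c(0.03, 0.05, -0.35))),
      list(name = paste0("EXO_", SFX, "SK1"), segment = paste0("exo_shank_", sfx),
           local_position = m(c(0.03, 0.04, -0.10))),
      list(name = paste0("EXO_", SFX, "SK2"), segment = paste0("exo_shank_", sfx),
           local_position = m(c(0.03, 0.04, -0.33))),
      list(name = paste0("EXO_", SFX, "FT1"), segment = paste0("exo_foot_", sfx),
           local_position = m(c(0.15, 0.04, -0.05)))))
  }
  side("l", 1); side("r", -1)
  list(name = "exoskeleton", segments = segs, joints = jnts, markers = mks,
       expect = list(n_segments = 7L, n_coordinates = 4L))
}

config_to_model <- function(config, gravity = c(0, 0, -9.81)) {
  segs <- lapply(config$segments, function(s)
    segment(s$name, s$mass, s$com %||% c(0, 0, 0), s$inertia %||% 0,
            s$length %||% NA_real_))
  jnts <- lapply(config$joints, function(j)
    joint(j$name, j$type, j$parent, j$child, j$location %||% c(0, 0, 0),
          j$orientation %||% diag(3), j$axes, j$coupling))
  mks <- lapply(config$markers %||% list(), function(m)
    marker(m$name, m$segment, m$local_position, m$weight %||% 1))
  model <- multibody_model(segs, jnts, mks, gravity = gravity,
                           name = config$name %||% "model")
  if (!is.null(config$expect)) {
    if (!is.null(config$expect$n_segments) &&
        n_segments(model) != config$expect$n_segments)
      stopf("segment count mismatch vs declared layout: %d != %d",
            n_segments(model), config$expect$n_segments)
    if (!is.null(config$expect$n_coordinates) &&
        n_coordinates(model) != config$expect$n_coordinates)
      stopf("DoF count mismatch vs declared layout: %d != %d",
            n_coordinates(model), config$expect$n_coordinates)
  }
  model$stature <- config$stature %||% NA_real_
  model
}

#' Build the human multibody model
#'
#' @param config a model-definition config (default
#'   [default_human_config()]).
#' @return a `multibody_model`; the default config yields 24 segments and
#'   37 generalized coordinates.
#' @export
build_human_model <- function(config = default_human_config()) {
  config_to_model(config)
}

#' Build the exoskeleton multibody model
#'
#' In faithful mode the hip and knee joints must be 1-DoF pins and the
#' ankle joints welds, matching the device architecture; other layouts are
#' rejected.
#'
#' @param config a model-definition config (default
#'   [default_exoskeleton_config()]).
#' @param faithful enforce the pin-hip/pin-knee/welded-ankle topology.
#' @return a `multibody_model`; the default config yields 7 segments and 4
#'   generalized coordinates.
#' @export
build_exoskeleton_model <- function(config = default_exoskeleton_config(),
                                    faithful = TRUE) {
  model <- config_to_model(config)
  if (faithful) {
    for (j in model$joints) {
      if (grepl("^exo_(hip|knee)_", j$name) && j$type != "pin")
        stopf("faithful mode: joint '%s' must be a pin, got '%s'",
              j$name, j$type)
      if (grepl("^exo_ankle_", j$name) && j$type != "weld")
        stopf("faithful mode: joint '%s' must be a weld, got '%s'",
              j$name, j$type)
    }
    for (s in names(model$segments)) {
      sg <- model$segments[[s]]
      if (!is.finite(sg$mass)) stopf("segment '%s': missing mass", s)
    }
  }
  model
}

#' Default pelvic-band anchor joint
#'
#' The human-robot interaction joint: a 6-DoF universal joint from the
#' human pelvis to the exoskeleton pelvic band.
#'
#' @param location anchor centre in the pelvis frame, m.
#' @param frame_offset_deg constant pitch offset between the pelvis and
#'   pelvic-band coordinate axes, deg (emulates the differing segment axis
#'   definitions of the two templates).
#' @return an `exo_joint` of type `universal6`.
#' @export
pelvic_anchor_joint <- function(location = c(0, 0, 0.05),
                                frame_offset_deg = 0) {
  joint("pelvic_anchor", "universal6", parent = "pelvis",
        child = "exo_pelvic_band", location = location,
        orientation = rot3(c(0, -1, 0), deg2rad(frame_offset_deg)))
}

#' Couple the human and exoskeleton models at the pelvic band
#'
#' Replaces the exoskeleton's ground attachment with an anchor joint from
#' the human pelvis to the pelvic band. The default anchor is the 6-DoF
#' universal joint [pelvic_anchor_joint()]; with `lock_anchor = TRUE` all
#' six anchor coordinates are welded instead.
#'
#' @param human,exo `multibody_model`s to combine.
#' @param anchor anchor joint (must be type `universal6` and connect the
#'   human pelvis to the exoskeleton root segment).
#' @param lock_anchor weld the anchor (0 coordinates) instead.
#' @return the combined `multibody_model` (37 + 4 + 6 = 47 coordinates
#'   with the default models and free anchor).
#' @export
couple_models <- function(human, exo, anchor = pelvic_anchor_joint(),
                          lock_anchor = FALSE) {
  if (anchor$type != "universal6")
    stopf("anchor joint must be of type universal6, got '%s'", anchor$type)
  exo_root <- exo$order[[1L]]
  if (anchor$parent != "pelvis" || !("pelvis" %in% names(human$segments)))
    stopf("anchor parent must be the human pelvis")
  if (anchor$child != exo_root)
    stopf("anchor child must be the exoskeleton root segment '%s'", exo_root)
  if (lock_anchor)
    anchor <- joint(anchor$name, "weld", anchor$parent, anchor$child,
                    anchor$location, anchor$orientation)
  dup <- intersect(names(human$segments), names(exo$segments))
  if (length(dup))
    stopf("duplicate segment names: %s", paste(dup, collapse = ", "))
  exo_joints <- Filter(function(j) j$parent != "ground", exo$joints)
  multibody_model(c(unname(human$segments), unname(exo$segments)),
                  c(unname(human$joints), list(anchor), unname(exo_joints)),
                  c(unname(human$markers), unname(exo$markers)),
                  gravity = human$gravity,
                  name = paste0(human$name, "+", exo$name))
}

#' Read / write a model-definition config
#'
#' Configs are stored as YAML with the same nested structure produced by
#' [default_human_config()].
#'
#' @param path file path.
#' @return `read_model_config()` returns the config list.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (i in seq_along(cfg$segments)) {
    s <- cfg$segments[[i]]
    if (!is.null(s$inertia)) {
      iv <- unlist(s$inertia)
      cfg$segments[[i]]$inertia <-
        if (length(iv) == 9L) matrix(iv, 3L, 3L) else iv
    }
  }
  cfg
}

#' @rdname read_model_config
#' @param config config list to serialize.
#' @export
write_model_config <- function(config, path) {
  for (i in seq_along(config$segments)) {
    s <- config$segments[[i]]
    if (is.matrix(s$inertia))
      config$segments[[i]]$inertia <- as.numeric(s$inertia)
  }
  yaml::write_yaml(config, path, precision = 12L)
  invisible(path)
}
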