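#' Subject anthropometry
#'
#' @param total_mass subject mass, kg (> 0).
#' @param height subject stature, m (optional; used as a global length
#'   factor for segments without an explicit target length).
#' @param segment_lengths named numeric vector of target segment lengths, m.
#' @return an object of class `subject_anthropometry`.
#' @export
subject_anthropometry <- function(total_mass, height = NA_real_,
                                  segment_lengths = numeric(0)) {
  if (!is.finite(total_mass) || total_mass <= 0)
    stopf("total_mass must be > 0")
  if (length(segment_lengths) && any(segment_lengths <= 0))
    stopf("segment lengths must be > 0")
  structure(list(total_mass = total_mass, height = height,
                 segment_lengths = segment_lengths),
            class = "subject_anthropometry")
}

#' Scale a generic model to subject anthropometry
#'
#' Segment geometry (COM offsets, marker positions, joint locations) is
#' scaled by per-segment length ratios (target length / generic length,
#' falling back to the stature ratio, then 1). Segment masses are scaled
#' by a single factor so the total equals the subject mass while
#' preserving the generic mass fractions. Inertia tensors scale by
#' (mass ratio) x (length ratio)^2.
#'
#' @param model generic `multibody_model` (with `$stature` set for the
#'   global factor to apply).
#' @param anthro a [subject_anthropometry()].
#' @return the scaled `multibody_model`.
#' @export
scale_model <- function(model, anthro) {
  stopifnot(inherits(model, "multibody_model"),
            inherits(anthro, "subject_anthropometry"))
  global <- if (is.finite(anthro$height) && isTRUE(is.finite(model$stature)))
    anthro$height / model$stature else 1
  gen_mass <- total_mass(model)
  if (gen_mass <= 0) stopf("generic model has zero total mass")
  mass_ratio <- anthro$total_mass / gen_mass

  factor_of <- function(seg) {
    tgt <- anthro$segment_lengths[seg$name]
    if (length(tgt) == 1L && is.finite(tgt)) {
      if (!is.finite(seg$length) || seg$length <= 0)
        stopf("segment '%s': zero/negative generic length", seg$name)
      return(unname(tgt) / seg$length)
    }
    global
  }
  factors <- vapply(model$segments, factor_of, 0)

  for (s in names(model$segments)) {
    f <- factors[[s]]
    seg <- model$segments[[s]]
    seg$com <- seg$com * f
    seg$length <- seg$length * f
    seg$mass <- seg$mass * mass_ratio
    seg$inertia <- seg$inertia * mass_ratio * f^2
    model$segments[[s]] <- seg
  }
  for (j in names(model$joints)) {
    par <- model$joints[[j]]$parent
    f <- if (par == "ground") 1 else factors[[par]]
    model$joints[[j]]$location <- model$joints[[j]]$location * f
  }
  for (m in names(model$markers)) {
    f <- factors[[model$markers[[m]]$segment]]
    model$markers[[m]]$local_position <- model$markers[[m]]$local_position * f
  }
  if (isTRUE(is.finite(model$stature))) model$stature <- model$stature * global
  compile_model(model)
}

# relative pose of each exoskeleton segment in its mapped human segment's
# frame, evaluated at the reference (neutral) configuration of the coupled
# model
relative_exo_poses <- function(human, exo, mapping, anchor) {
  coupled <- couple_models(human, exo, anchor)
  fk <- fk_pass(coupled, neutral_pose(coupled))
  out <- list()
  for (e in names(mapping)) {
    h <- mapping[[e]]
    ih <- match(h, coupled$order); ie <- match(e, coupled$order)
    Rh <- fk$R[[ih]]; ph <- fk$p[, ih]
    Re <- fk$R[[ie]]; pe <- fk$p[, ie]
    out[[e]] <- list(R = t(Rh) %*% Re, p = as.numeric(t(Rh) %*% (pe - ph)))
  }
  out
}

#' Lump exoskeleton inertia into the human segments
#'
#' For inverse dynamics the human-robot model is simplified by adding each
#' exoskeleton segment's mass to its mapped human segment, moving the
#' human segment's COM to the combined COM, and transferring both inertia
#' tensors to the combined COM by the parallel-axis theorem. The result is
#' a human-topology model (same coordinates) carrying the combined
#' inertial properties.
#'
#' @param human human `multibody_model`.
#' @param exo exoskeleton `multibody_model`.
#' @param mapping named character vector: exoskeleton segment -> human
#'   segment. Must cover every exoskeleton segment.
#' @param anchor anchor joint defining the device's pose relative to the
#'   pelvis (used to express each device segment in its human segment's
#'   frame at the neutral configuration).
#' @return a `multibody_model` with human topology and combined inertia.
#' @export
lump_exoskeleton_inertia <- function(human, exo,
                                     mapping = default_exo_mapping(),
                                     anchor = pelvic_anchor_joint()) {
  missing <- setdiff(names(exo$segments), names(mapping))
  if (length(missing))
    stopf("unmapped exoskeleton segment(s): %s",
          paste(missing, collapse = ", "))
  bad <- setdiff(unname(mapping), names(human$segments))
  if (length(bad))
    stopf("mapping targets unknown human segment(s): %s",
          paste(bad, collapse = ", "))
  rel <- relative_exo_poses(human, exo, mapping, anchor)
  lumped <- human
  for (e in names(exo$segments)) {
    es <- exo$segments[[e]]
    h <- mapping[[e]]
    hs <- lumped$segments[[h]]
    if (es$mass == 0) next
    m <- hs$mass + es$mass
    if (m <= 0) stopf("zero combined mass for '%s' + '%s'", h, e)
    com_e <- rel[[e]]$p + as.numeric(rel[[e]]$R %*% es$com)  # in human frame
    com <- (hs$mass * hs$com + es$mass * com_e) / m
    I_e <- rel[[e]]$R %*% es$inertia %*% t(rel[[e]]$R)
    I <- parallel_axis(hs$inertia, hs$mass, hs$com - com) +
      parallel_axis(I_e, es$mass, com_e - com)
    hs$mass <- m; hs$com <- com; hs$inertia <- I
    lumped$segments[[h]] <- hs
  }
  lumped$name <- paste0(human$name, "_lumped")
  compile_model(lumped)
}

#' Default exoskeleton-to-human segment mapping for inertia lumping
#' @return named character vector (exo segment -> human segment).
#' @export
default_exo_mapping <- function() {
  c(exo_pelvic_band = "pelvis",
    exo_thigh_l = "femur_l", exo_thigh_r = "femur_r",
    exo_shank_l = "tibia_l", exo_shank_r = "tibia_r",
    exo_foot_l = "calcn_l", exo_foot_r = "calcn_r")
}
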