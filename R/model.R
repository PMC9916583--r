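# Joint types and the number of generalized coordinates each contributes.
JOINT_DOF <- c(pin = 1L, ball = 3L, universal2 = 2L, universal6 = 6L,
               weld = 0L, coupled_knee = 1L)

# Default rotation axes (segment-local, Z-up frames): flexion about -Y,
# adduction about +X, axial rotation about +Z.
AXIS_FLEXION <- c(0, -1, 0)
AXIS_ADDUCTION <- c(1, 0, 0)
AXIS_AXIAL <- c(0, 0, 1)

#' Define an inertial segment
#'
#' @param name segment identifier.
#' @param mass segment mass in kg (non-negative).
#' @param com centre of mass in the segment frame, m.
#' @param inertia 3x3 symmetric positive semidefinite inertia tensor about
#'   the COM, kg m^2. A scalar is expanded to an isotropic tensor and a
#'   length-3 vector to a diagonal tensor.
#' @param length characteristic segment length in m (used for scaling).
#' @return an object of class `exo_segment`.
#' @export
segment <- function(name, mass, com = c(0, 0, 0), inertia = diag(3) * 0,
                    length = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("segment name must be a non-empty string")
  if (!is.finite(mass) || mass < 0) stopf("segment '%s': mass must be >= 0", name)
  if (length(inertia) == 1L) inertia <- diag(3L) * inertia
  if (is.vector(inertia) && length(inertia) == 3L) inertia <- diag(inertia)
  inertia <- matrix(as.numeric(inertia), 3L, 3L)
  if (!is_symmetric_psd(inertia))
    stopf("segment '%s': inertia must be symmetric positive semidefinite", name)
  structure(list(name = name, mass = as.numeric(mass),
                 com = as.numeric(com), inertia = inertia,
                 length = as.numeric(length)),
            class = "exo_segment")
}

#' Define a joint between two segments
#'
#' Joint types: `pin` (1 rotation), `ball` (3-rotation intrinsic
#' flexion-adduction-axial sequence), `universal2` (2 rotations),
#' `universal6` (3 translations then 3 rotations), `weld` (rigid, 0
#' coordinates) and `coupled_knee` (1 rotation driving an optional
#' prescribed translation table).
#'
#' @param name joint identifier.
#' @param type one of `"pin"`, `"ball"`, `"universal2"`, `"universal6"`,
#'   `"weld"`, `"coupled_knee"`.
#' @param parent,child segment names (`parent` may be `"ground"`).
#' @param location joint centre in the parent frame, m.
#' @param orientation 3x3 rotation from parent frame to joint frame.
#' @param axes list of unit axes for the rotational coordinates (defaults
#'   per type); a single vector is accepted for 1-DoF joints.
#' @param coupling optional coupling table for `coupled_knee`: a list with
#'   `angle` (rad) and `tx`,`ty`,`tz` (m) giving prescribed tibia
#'   translations as a function of knee angle. Default all-zero (pure hinge).
#' @return an object of class `exo_joint`.
#' @export
joint <- function(name, type, parent, child, location = c(0, 0, 0),
                  orientation = diag(3), axes = NULL, coupling = NULL) {
  type <- match.arg(type, names(JOINT_DOF))
  if (!is.null(axes) && !is.list(axes)) axes <- list(axes)
  axes <- switch(type,
    pin = ,
    coupled_knee = axes %||% list(AXIS_FLEXION),
    ball = ,
    universal6 = axes %||% list(AXIS_FLEXION, AXIS_ADDUCTION, AXIS_AXIAL),
    universal2 = axes %||% list(AXIS_FLEXION, AXIS_ADDUCTION),
    weld = list())
  n_rot <- switch(type, pin = 1L, coupled_knee = 1L, ball = 3L,
                  universal6 = 3L, universal2 = 2L, weld = 0L)
  if (length(axes) != n_rot)
    stopf("joint '%s': type '%s' needs %d rotation axes", name, type, n_rot)
  axes <- lapply(axes, unit3)
  if (type == "coupled_knee") {
    coupling <- coupling %||% list(angle = c(-3, 3), tx = c(0, 0),
                                   ty = c(0, 0), tz = c(0, 0))
    stopifnot(length(coupling$angle) >= 2L,
              length(coupling$tx) == length(coupling$angle),
              length(coupling$ty) == length(coupling$angle),
              length(coupling$tz) == length(coupling$angle))
  } else if (!is.null(coupling)) {
    stopf("joint '%s': coupling table only allowed for coupled_knee", name)
  }
  structure(list(name = name, type = type, parent = parent, child = child,
                 location = as.numeric(location),
                 orientation = matrix(as.numeric(orientation), 3L, 3L),
                 axes = axes, coupling = coupling),
            class = "exo_joint")
}

#' Define a marker attachment
#'
#' @param name marker label (unique within a model).
#' @param segment segment carrying the marker.
#' @param local_position marker position in the segment frame, m.
#' @param weight non-negative inverse-kinematics weight (default 1).
#' @return an object of class `exo_marker`.
#' @export
marker <- function(name, segment, local_position, weight = 1) {
  if (!is.finite(weight) || weight < 0)
    stopf("marker '%s': weight must be >= 0", name)
  structure(list(name = name, segment = segment,
                 local_position = as.numeric(local_position),
                 weight = as.numeric(weight)),
            class = "exo_marker")
}

coupling_is_zero <- function(joint) {
  is.null(joint$coupling) ||
    (all(joint$coupling$tx == 0) && all(joint$coupling$ty == 0) &&
       all(joint$coupling$tz == 0))
}

coord_names_for_joint <- function(j) {
  switch(j$type,
    pin = paste0(j$name, "_angle"),
    coupled_knee = paste0(j$name, "_angle"),
    ball = paste0(j$name, c("_flexion", "_adduction", "_rotation")),
    universal2 = paste0(j$name, c("_flexion", "_deviation")),
    universal6 = paste0(j$name, c("_tx", "_ty", "_tz",
                                  "_flexion", "_adduction", "_rotation")),
    weld = character(0))
}

coord_kinds_for_joint <- function(j) {
  switch(j$type,
    pin = "rotation", coupled_knee = "rotation",
    ball = rep("rotation", 3L), universal2 = rep("rotation", 2L),
    universal6 = c(rep("translation", 3L), rep("rotation", 3L)),
    weld = character(0))
}

#' Assemble a multibody model
#'
#' Builds the kinematic tree, checks invariants (tree topology, unique
#' names, unit axes, PSD inertias) and compiles the generalized-coordinate
#' layout.
#'
#' @param segments list of [segment()] objects.
#' @param joints list of [joint()] objects; exactly one joint per segment
#'   (as child); the tree is rooted at the virtual `"ground"` frame.
#' @param markers list of [marker()] objects.
#' @param gravity gravity vector in the global frame, m/s^2
#'   (default `c(0, 0, -9.81)`: Z-up).
#' @param name optional model name.
#' @return an object of class `multibody_model` with the compiled
#'   coordinate layout in `$coords` (a data frame with columns `name`,
#'   `joint`, `kind`).
#' @export
multibody_model <- function(segments, joints, markers = list(),
                            gravity = c(0, 0, -9.81), name = "model") {
  seg_names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(seg_names))
    stopf("duplicate segment names: %s",
          paste(unique(seg_names[duplicated(seg_names)]), collapse = ", "))
  if ("ground" %in% seg_names) stopf("'ground' is reserved for the root frame")
  names(segments) <- seg_names
  jnt_names <- vapply(joints, `[[`, "", "name")
  if (anyDuplicated(jnt_names))
    stopf("duplicate joint names: %s",
          paste(unique(jnt_names[duplicated(jnt_names)]), collapse = ", "))
  names(joints) <- jnt_names

  children <- vapply(joints, `[[`, "", "child")
  parents <- vapply(joints, `[[`, "", "parent")
  if (anyDuplicated(children))
    stopf("non-tree topology: segment(s) %s have more than one parent joint",
          paste(unique(children[duplicated(children)]), collapse = ", "))
  missing_child <- setdiff(seg_names, children)
  if (length(missing_child))
    stopf("segment(s) without a parent joint: %s",
          paste(missing_child, collapse = ", "))
  bad_parent <- setdiff(parents, c("ground", seg_names))
  if (length(bad_parent))
    stopf("unknown parent segment(s): %s", paste(bad_parent, collapse = ", "))
  bad_child <- setdiff(children, seg_names)
  if (length(bad_child))
    stopf("unknown child segment(s): %s", paste(bad_child, collapse = ", "))

  # topological order from ground; detects cycles / unreachable subtrees
  parent_of <- stats::setNames(parents, children)
  order <- character(0)
  frontier <- "ground"
  while (length(frontier)) {
    nxt <- children[parents %in% frontier]
    order <- c(order, nxt)
    frontier <- nxt
  }
  if (length(order) != length(seg_names))
    stopf("non-tree topology: segment(s) not reachable from ground: %s",
          paste(setdiff(seg_names, order), collapse = ", "))

  mk_names <- vapply(markers, `[[`, "", "name")
  if (anyDuplicated(mk_names))
    stopf("duplicate marker names: %s",
          paste(unique(mk_names[duplicated(mk_names)]), collapse = ", "))
  bad_seg <- setdiff(vapply(markers, `[[`, "", "segment"), seg_names)
  if (length(bad_seg))
    stopf("marker(s) on unknown segment(s): %s", paste(bad_seg, collapse = ", "))
  names(markers) <- mk_names

  # joints indexed by child segment, in topological order
  joint_of <- stats::setNames(joints[match(order, children)], order)

  coords <- do.call(rbind, c(list(
    data.frame(name = character(0), joint = character(0),
               kind = character(0), stringsAsFactors = FALSE)),
    lapply(joint_of, function(j) {
      nm <- coord_names_for_joint(j)
      if (!length(nm)) return(NULL)
      data.frame(name = nm, joint = j$name, kind = coord_kinds_for_joint(j),
                 stringsAsFactors = FALSE)
    })))
  rownames(coords) <- NULL

  model <- structure(list(
    name = name, segments = segments, joints = joint_of,
    markers = markers, order = order, gravity = as.numeric(gravity),
    coords = coords), class = "multibody_model")
  model <- compile_model(model)
  model
}

# Precompute per-coordinate joint bookkeeping and the body/coordinate
# ancestry matrix used by Jacobians and inverse dynamics.
compile_model <- function(model) {
  nq <- nrow(model$coords)
  nb <- length(model$order)
  anc <- matrix(FALSE, nb, nq, dimnames = list(model$order, model$coords$name))
  for (b in seq_len(nb)) {
    seg <- model$order[b]
    repeat {
      j <- model$joints[[seg]]
      idx <- which(model$coords$joint == j$name)
      if (length(idx)) anc[b, idx] <- TRUE
      if (j$parent == "ground") break
      seg <- j$parent
    }
  }
  model$ancestry <- anc
  model$n_q <- nq
  model$n_segments <- nb
  # per-segment coordinate indices of the parent joint
  model$jidx <- lapply(model$joints, function(j)
    which(model$coords$joint == j$name))
  # coupled-knee prescribed-translation splines (only when non-zero)
  model$cspl <- lapply(model$joints, function(j) {
    if (j$type != "coupled_knee" || coupling_is_zero(j)) return(NULL)
    cp <- j$coupling
    list(fx = stats::splinefun(cp$angle, cp$tx, method = "natural"),
         fy = stats::splinefun(cp$angle, cp$ty, method = "natural"),
         fz = stats::splinefun(cp$angle, cp$tz, method = "natural"))
  })
  # marker lookup tables
  if (length(model$markers)) {
    model$marker_segment <- vapply(model$markers, `[[`, "", "segment")
    model$marker_local <- vapply(model$markers, `[[`, numeric(3L),
                                 "local_position")
    model$marker_weight <- vapply(model$markers, `[[`, 0, "weight")
  } else {
    model$marker_segment <- character(0)
    model$marker_local <- matrix(0, 3L, 0L)
    model$marker_weight <- numeric(0)
  }
  model$marker_segidx <- match(model$marker_segment, model$order)
  model
}

#' Number of generalized coordinates of a model
#' @param model a `multibody_model`.
#' @return integer count.
#' @export
n_coordinates <- function(model) model$n_q

#' Number of segments of a model
#' @param model a `multibody_model`.
#' @return integer count.
#' @export
n_segments <- function(model) model$n_segments

#' Coordinate names of a model
#' @param model a `multibody_model`.
#' @return character vector, in coordinate order.
#' @export
coordinate_names <- function(model) model$coords$name

#' Total mass of a model
#' @param model a `multibody_model`.
#' @return total mass, kg.
#' @export
total_mass <- function(model) {
  sum(vapply(model$segments, `[[`, 0, "mass"))
}

#' @export
print.multibody_model <- function(x, ...) {
  cat(sprintf("<multibody_model '%s'>\n", x$name))
  cat(sprintf("  segments:    %d (total mass %.3f kg)\n",
              x$n_segments, total_mass(x)))
  cat(sprintf("  coordinates: %d\n", x$n_q))
  cat(sprintf("  markers:     %d\n", length(x$markers)))
  tb <- table(vapply(x$joints, `[[`, "", "type"))
  cat("  joints:      ", paste(sprintf("%s=%d", names(tb), tb),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Look up a joint by name
#' @param model a `multibody_model`.
#' @param name joint name.
#' @return the `exo_joint` object.
#' @export
get_joint <- function(model, name) {
  for (j in model$joints) if (j$name == name) return(j)
  stopf("no joint named '%s'", name)
}

#' Indices of the coordinates of one joint
#' @param model a `multibody_model`.
#' @param joint_name joint name.
#' @return integer vector of coordinate indices.
#' @export
joint_coord_indices <- function(model, joint_name) {
  which(model$coords$joint == joint_name)
}

#' Neutral (all-zero) coordinate vector
#' @param model a `multibody_model`.
#' @return named numeric vector of zeros.
#' @export
neutral_pose <- function(model) {
  stats::setNames(numeric(model$n_q), model$coords$name)
}
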