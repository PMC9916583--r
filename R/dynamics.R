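#' External load on a body
#'
#' A ground-reaction-style wrench: a force applied at a centre of
#' pressure plus a free moment, all in the global frame.
#'
#' @param body segment name the load acts on.
#' @param time time stamps, s (aligned to the motion on use; resampled
#'   linearly if bases differ).
#' @param force n x 3 force, N.
#' @param cop n x 3 centre of pressure, m.
#' @param free_moment n x 3 free moment, N m (default zero).
#' @return an object of class `external_load`.
#' @export
external_load <- function(body, time, force, cop, free_moment = NULL) {
  force <- as.matrix(force); cop <- as.matrix(cop)
  n <- length(time)
  if (is.null(free_moment)) free_moment <- matrix(0, n, 3L)
  free_moment <- as.matrix(free_moment)
  stopifnot(nrow(force) == n, nrow(cop) == n, nrow(free_moment) == n,
            ncol(force) == 3L, ncol(cop) == 3L, ncol(free_moment) == 3L)
  if (!all(is.finite(force)) || !all(is.finite(free_moment)))
    stopf("external load contains non-finite values")
  structure(list(body = body, time = as.numeric(time), force = force,
                 cop = cop, free_moment = free_moment),
            class = "external_load")
}

# resample a load onto a motion time base (linear, rule 2 at the edges)
resample_load <- function(load, time) {
  if (length(load$time) == length(time) &&
      max(abs(load$time - time)) < 1e-9) return(load)
  re <- function(M) apply(M, 2L, function(col)
    stats::approx(load$time, col, xout = time, rule = 2L)$y)
  external_load(load$body, time, re(load$force), re(load$cop),
                re(load$free_moment))
}

# inverse dynamics for one frame by virtual work over the exact body
# kinematics: tau_k = sum_i J_ik . (inertial wrench_i) - J_ext . F_ext
id_frame <- function(model, kin, loads_f = NULL) {
  nq <- model$n_q
  nb <- model$n_segments
  g <- model$gravity
  masses <- vapply(model$segments, `[[`, 0, "mass")[model$order]
  # body COM kinematics and inertial wrenches
  Fi <- matrix(0, 3L, nb); Mi <- matrix(0, 3L, nb); Xc <- matrix(0, 3L, nb)
  for (b in seq_len(nb)) {
    seg <- model$segments[[model$order[b]]]
    Rb <- kin$R[[b]]
    c_g <- as.numeric(Rb %*% seg$com)
    Xc[, b] <- kin$p[, b] + c_g
    w <- kin$w[, b]; al <- kin$al[, b]
    a_com <- kin$a[, b] + cross3(al, c_g) + cross3(w, cross3(w, c_g))
    Ig <- Rb %*% seg$inertia %*% t(Rb)
    Fi[, b] <- seg$mass * (a_com - g)
    Mi[, b] <- as.numeric(Ig %*% al) + cross3(w, as.numeric(Ig %*% w))
  }
  kinds <- model$coords$kind
  tau <- numeric(nq)
  for (k in seq_len(nq)) {
    aff <- which(model$ancestry[, k])
    if (!length(aff)) next
    if (kinds[k] == "rotation") {
      u <- kin$ax[, k]; pk <- kin$org[, k]
      arm <- Xc[, aff, drop = FALSE] - pk
      mom <- cross3_mat_cols(arm, Fi[, aff, drop = FALSE]) +
        Mi[, aff, drop = FALSE]
      tau[k] <- sum(u * rowSums(mom))
      td <- kin$tdir[, k]
      if (any(td != 0)) tau[k] <- tau[k] + sum(td * rowSums(Fi[, aff, drop = FALSE]))
    } else {
      tau[k] <- sum(kin$ax[, k] * rowSums(Fi[, aff, drop = FALSE]))
    }
  }
  if (!is.null(loads_f)) {
    for (ld in loads_f) {
      b <- match(ld$body, model$order)
      if (is.na(b)) stopf("unknown load body '%s'", ld$body)
      F <- ld$force; P <- ld$cop; M <- ld$free_moment
      for (k in seq_len(nq)) {
        if (!model$ancestry[b, k]) next
        if (kinds[k] == "rotation") {
          u <- kin$ax[, k]; pk <- kin$org[, k]
          tau[k] <- tau[k] - sum(u * (cross3(P - pk, F) + M))
          td <- kin$tdir[, k]
          if (any(td != 0)) tau[k] <- tau[k] - sum(td * F)
        } else {
          tau[k] <- tau[k] - sum(kin$ax[, k] * F)
        }
      }
    }
  }
  tau
}

# columnwise cross product of two 3 x n matrices
cross3_mat_cols <- function(A, B) {
  rbind(A[2L, ] * B[3L, ] - A[3L, ] * B[2L, ],
        A[3L, ] * B[1L, ] - A[1L, ] * B[3L, ],
        A[1L, ] * B[2L, ] - A[2L, ] * B[1L, ])
}

#' Inverse dynamics
#'
#' Computes the net generalized forces tau(t) = M(q) qdd + c(q, qd) -
#' J_ext' F_ext - tau_gravity per frame by a Newton-Euler pass over the
#' tree: exact propagation of angular/linear velocity and acceleration,
#' inertial wrenches per body, and projection onto each coordinate's
#' instantaneous axis (virtual work). External wrenches are applied at
#' their centre of pressure with the free moment added. The six base
#' coordinates of the ground joint receive the whole-body residual
#' wrench, reported separately.
#'
#' @param model a `multibody_model` (for human-robot analyses: the lumped
#'   model from [lump_exoskeleton_inertia()]).
#' @param traj a `coordinate_trajectory` with `qdot` and `qddot` (see
#'   [differentiate_trajectory()]).
#' @param loads list of [external_load()]s.
#' @return an object of class `generalized_forces`: `time`, `tau`
#'   (n x n_q matrix; N m for rotations, N for translations),
#'   `residual_idx` (base-coordinate columns), `kinds`.
#' @export
inverse_dynamics <- function(model, traj, loads = list()) {
  if (is.null(traj$qddot) || is.null(traj$qdot))
    stopf("trajectory has no accelerations; run differentiate_trajectory() first")
  if (inherits(loads, "external_load")) loads <- list(loads)
  nms <- coordinate_names(model)
  missing <- setdiff(nms, colnames(traj$q))
  if (length(missing))
    stopf("trajectory lacks coordinate(s): %s", paste(missing, collapse = ", "))
  for (ld in loads)
    if (!ld$body %in% model$order) stopf("unknown load body '%s'", ld$body)
  loads <- lapply(loads, resample_load, time = traj$time)
  nt <- length(traj$time)
  ci <- match(nms, colnames(traj$q))
  tau <- matrix(0, nt, model$n_q, dimnames = list(NULL, nms))
  for (i in seq_len(nt)) {
    kin <- fk_pass(model, traj$q[i, ci], traj$qdot[i, ci],
                   traj$qddot[i, ci])
    lf <- lapply(loads, function(ld)
      list(body = ld$body, force = ld$force[i, ], cop = ld$cop[i, ],
           free_moment = ld$free_moment[i, ]))
    tau[i, ] <- id_frame(model, kin, if (length(lf)) lf else NULL)
  }
  base <- base_joint(model)
  structure(list(time = traj$time, tau = tau,
                 kinds = model$coords$kind,
                 residual_idx = if (is.null(base)) integer(0)
                 else joint_coord_indices(model, base)),
            class = "generalized_forces")
}

#' Inverse dynamics for a single state
#'
#' One-frame convenience around the Newton-Euler pass: the generalized
#' forces that realize `(q, qdot, qddot)` under the model's gravity and
#' optional external loads. Useful for computed-torque drives and
#' verification work.
#'
#' @param model a `multibody_model`.
#' @param q,qdot,qddot state vectors (length [n_coordinates()]).
#' @param loads optional list of per-frame loads, each a list with
#'   `body`, `force`, `cop`, `free_moment` (3-vectors).
#' @return named numeric vector of generalized forces.
#' @export
inverse_dynamics_frame <- function(model, q, qdot, qddot, loads = NULL) {
  kin <- fk_pass(model, q, qdot, qddot)
  stats::setNames(id_frame(model, kin, loads), coordinate_names(model))
}

# name of the 6-DoF ground joint (base), if any
base_joint <- function(model) {
  for (j in model$joints)
    if (j$parent == "ground" && j$type == "universal6") return(j$name)
  NULL
}

#' @export
print.generalized_forces <- function(x, ...) {
  cat(sprintf("<generalized_forces: %d frames x %d coordinates (%d residual)>\n",
              nrow(x$tau), ncol(x$tau), length(x$residual_idx)))
  invisible(x)
}

#' Forward-dynamics oracle
#'
#' Integrates M(q) qdd = tau - c(q, qd) - g(q) + J' F_ext for small
#' models (verification only; the mass matrix is assembled column-wise by
#' unit-acceleration inverse dynamics every derivative evaluation).
#'
#' @param model a `multibody_model` (intended for <= ~10 coordinates).
#' @param q0,qdot0 initial state.
#' @param tau function(t) returning the applied generalized forces, or
#'   `NULL` for none.
#' @param loads list of [external_load()]s (time-resampled as needed), or
#'   `NULL`.
#' @param t_eval output times, s.
#' @param rtol,atol integrator tolerances (default 1e-10).
#' @return a `coordinate_trajectory` with exact `qdot`/`qddot` at the
#'   output times.
#' @export
forward_dynamics_oracle <- function(model, q0, qdot0, tau = NULL,
                                    loads = NULL, t_eval,
                                    rtol = 1e-10, atol = 1e-10) {
  nq <- model$n_q
  stopifnot(length(q0) == nq, length(qdot0) == nq)
  model_nog <- model
  model_nog$gravity <- c(0, 0, 0)
  zero <- numeric(nq)
  loads_at <- function(t) {
    if (is.null(loads)) return(NULL)
    lapply(loads, function(ld) {
      i <- stats::approx(ld$time, seq_along(ld$time), xout = t, rule = 2L)$y
      lo <- floor(i); hi <- ceiling(i); f <- i - lo
      mix <- function(M) (1 - f) * M[lo, ] + f * M[hi, ]
      list(body = ld$body, force = mix(ld$force), cop = mix(ld$cop),
           free_moment = mix(ld$free_moment))
    })
  }
  accel <- function(t, q, qd) {
    kin0 <- fk_pass(model, q, qd, zero)
    bias <- id_frame(model, kin0, loads_at(t))
    M <- matrix(0, nq, nq)
    for (j in seq_len(nq)) {
      ej <- zero; ej[j] <- 1
      M[, j] <- id_frame(model_nog, fk_pass(model_nog, q, zero, ej))
    }
    tj <- if (is.null(tau)) zero else tau(t)
    solve(M, tj - bias)
  }
  deriv <- function(t, y, parms) {
    q <- y[seq_len(nq)]; qd <- y[nq + seq_len(nq)]
    list(c(qd, accel(t, q, qd)))
  }
  times <- sort(unique(c(t_eval[1L], t_eval)))
  sol <- deSolve::ode(y = c(q0, qdot0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) stopf("forward-dynamics integration failed")
  keep <- match(t_eval, sol[, 1L])
  Q <- sol[keep, 1L + seq_len(nq), drop = FALSE]
  Qd <- sol[keep, 1L + nq + seq_len(nq), drop = FALSE]
  Qdd <- t(matrix(vapply(seq_along(t_eval), function(i)
    accel(t_eval[i], Q[i, ], Qd[i, ]), numeric(nq)), nrow = nq))
  colnames(Q) <- colnames(Qd) <- colnames(Qdd) <- coordinate_names(model)
  coordinate_trajectory(t_eval, Q, Qd, Qdd)
}

#' Total mechanical energy of a model state
#'
#' @param model a `multibody_model`.
#' @param q,qdot state vectors.
#' @return kinetic + gravitational potential energy, J.
#' @export
total_energy <- function(model, q, qdot) {
  kin <- fk_pass(model, q, qdot, numeric(model$n_q))
  E <- 0
  g <- model$gravity
  for (b in seq_len(model$n_segments)) {
    seg <- model$segments[[model$order[b]]]
    Rb <- kin$R[[b]]
    c_g <- as.numeric(Rb %*% seg$com)
    v_com <- kin$v[, b] + cross3(kin$w[, b], c_g)
    Ig <- Rb %*% seg$inertia %*% t(Rb)
    w <- kin$w[, b]
    E <- E + 0.5 * seg$mass * sum(v_com^2) + 0.5 * sum(w * (Ig %*% w)) -
      seg$mass * sum(g * (kin$p[, b] + c_g))
  }
  E
}

#' Whole-body residual check
#'
#' Quality control for inverse dynamics: the base residual force must
#' equal total_mass * (a_com - g) - sum(F_ext) each frame. Reports the
#' largest absolute base residual force and its fraction of model weight,
#' plus the largest mismatch between the base residuals and the
#' independently computed whole-body balance.
#'
#' @param gf a `generalized_forces` from [inverse_dynamics()].
#' @param model,traj,loads the inputs used for the ID run.
#' @return list with `max_force` (N), `frac_weight`, `max_mismatch` (N),
#'   and the per-frame residual force matrix `residual_force`.
#' @export
check_residuals <- function(gf, model, traj, loads = list()) {
  if (!length(gf$residual_idx)) stopf("model has no 6-DoF base joint")
  if (inherits(loads, "external_load")) loads <- list(loads)
  loads <- lapply(loads, resample_load, time = traj$time)
  kinds <- gf$kinds[gf$residual_idx]
  fidx <- gf$residual_idx[kinds == "translation"]
  resF <- gf$tau[, fidx, drop = FALSE]
  nt <- length(traj$time)
  masses <- vapply(model$segments, `[[`, 0, "mass")[model$order]
  mtot <- sum(masses)
  g <- model$gravity
  expected <- matrix(0, nt, 3L)
  ci <- match(coordinate_names(model), colnames(traj$q))
  for (i in seq_len(nt)) {
    kin <- fk_pass(model, traj$q[i, ci], traj$qdot[i, ci],
                   traj$qddot[i, ci])
    acc <- c(0, 0, 0)
    for (b in seq_len(model$n_segments)) {
      seg <- model$segments[[model$order[b]]]
      c_g <- as.numeric(kin$R[[b]] %*% seg$com)
      a_com <- kin$a[, b] + cross3(kin$al[, b], c_g) +
        cross3(kin$w[, b], cross3(kin$w[, b], c_g))
      acc <- acc + seg$mass * a_com
    }
    fe <- c(0, 0, 0)
    for (ld in loads) fe <- fe + ld$force[i, ]
    expected[i, ] <- acc - mtot * g - fe
  }
  weight <- mtot * sqrt(sum(g^2))
  list(max_force = max(abs(resF)),
       frac_weight = max(abs(resF)) / weight,
       max_mismatch = max(abs(resF - expected)),
       residual_force = resF)
}

#' Normalize joint moments to body (or body + device) mass
#'
#' Assisted-locomotion moments are normalized to the combined mass of
#' the participant and the exoskeleton; unassisted moments to the
#' participant's mass alone.
#'
#' @param gf a `generalized_forces`.
#' @param condition `"assisted"` or `"unassisted"`.
#' @param subject_mass participant mass, kg.
#' @param exo_mass device mass, kg (ignored when unassisted).
#' @return an object of class `normalized_moments`: `tau_norm` (N m/kg),
#'   `normalizing_mass`, `condition`, plus the original fields.
#' @export
normalize_moments <- function(gf, condition = c("assisted", "unassisted"),
                              subject_mass, exo_mass = 0) {
  condition <- match.arg(condition)
  if (!is.finite(subject_mass) || subject_mass <= 0)
    stopf("subject_mass must be > 0")
  if (condition == "assisted" && (!is.finite(exo_mass) || exo_mass < 0))
    stopf("exo_mass must be >= 0")
  m <- if (condition == "assisted") subject_mass + exo_mass else subject_mass
  structure(list(time = gf$time, tau_norm = gf$tau / m,
                 normalizing_mass = m, condition = condition,
                 kinds = gf$kinds, residual_idx = gf$residual_idx),
            class = "normalized_moments")
}

#' @rdname normalize_moments
#' @param nm a `normalized_moments`.
#' @return `denormalize_moments()` returns the `generalized_forces`.
#' @export
denormalize_moments <- function(nm) {
  structure(list(time = nm$time, tau = nm$tau_norm * nm$normalizing_mass,
                 kinds = nm$kinds, residual_idx = nm$residual_idx),
            class = "generalized_forces")
}
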