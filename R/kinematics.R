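# Forward kinematics over the joint tree.
#
# All segment frames are propagated in the global frame. For every
# generalized coordinate the pass records its instantaneous global axis,
# point of application and (for the coupled knee) the prescribed
# translation direction; these drive the analytic marker Jacobian for IK
# and the virtual-work sums for inverse dynamics. With `qd`/`qdd`
# supplied, angular velocity/acceleration and frame-origin linear
# velocity/acceleration are propagated alongside (exact, no numerical
# differentiation).
fk_pass <- function(model, q, qd = NULL, qdd = NULL) {
  nq <- model$n_q
  nb <- model$n_segments
  if (length(q) != nq)
    stopf("coordinate vector has length %d, model has %d coordinates",
          length(q), nq)
  want_dyn <- !is.null(qd)
  if (want_dyn && is.null(qdd)) qdd <- numeric(nq)

  R <- vector("list", nb)
  p <- matrix(0, 3L, nb)
  ax <- matrix(0, 3L, nq)
  org <- matrix(0, 3L, nq)
  tdir <- matrix(0, 3L, nq)
  if (want_dyn) {
    W <- matrix(0, 3L, nb); AL <- matrix(0, 3L, nb)
    V <- matrix(0, 3L, nb); A <- matrix(0, 3L, nb)
  }

  for (b in seq_len(nb)) {
    segname <- model$order[[b]]
    j <- model$joints[[segname]]
    if (j$parent == "ground") {
      Rp <- diag(3L); pp <- c(0, 0, 0)
      w <- al <- v <- a <- c(0, 0, 0)
    } else {
      ip <- match(j$parent, model$order)
      Rp <- R[[ip]]; pp <- p[, ip]
      if (want_dyn) { w <- W[, ip]; al <- AL[, ip]; v <- V[, ip]; a <- A[, ip] }
      else w <- al <- v <- a <- NULL
    }
    # fixed offset: joint location + orientation in the parent frame
    D <- as.numeric(Rp %*% j$location)
    pc <- pp + D
    Rc <- Rp %*% j$orientation
    if (want_dyn) {
      v <- v + cross3(w, D)
      a <- a + cross3(al, D) + cross3(w, cross3(w, D))
    }

    idx <- model$jidx[[segname]]
    type <- j$type
    if (type != "weld") {
      if (type == "universal6") {
        for (i in 1:3) {
          k <- idx[i]; u <- Rc[, i]
          ax[, k] <- u
          qk <- q[k]
          pc <- pc + qk * u
          if (want_dyn) {
            Du <- qk * u
            v <- v + qd[k] * u + cross3(w, Du)
            a <- a + qdd[k] * u + 2 * qd[k] * cross3(w, u) +
              cross3(al, Du) + cross3(w, cross3(w, Du))
          }
        }
        rot_idx <- idx[4:6]
      } else if (type == "coupled_knee") {
        k <- idx[1L]
        if (!is.null(model$cspl[[segname]])) {
          sp <- model$cspl[[segname]]
          qk <- q[k]
          tau <- c(sp$fx(qk), sp$fy(qk), sp$fz(qk))
          dtau <- c(sp$fx(qk, 1L), sp$fy(qk, 1L), sp$fz(qk, 1L))
          Dt <- as.numeric(Rc %*% tau)
          td <- as.numeric(Rc %*% dtau)
          tdir[, k] <- td
          pc <- pc + Dt
          if (want_dyn) {
            d2tau <- c(sp$fx(qk, 2L), sp$fy(qk, 2L), sp$fz(qk, 2L))
            v <- v + cross3(w, Dt) + qd[k] * td
            a <- a + cross3(al, Dt) + cross3(w, cross3(w, Dt)) +
              2 * qd[k] * cross3(w, td) +
              as.numeric(Rc %*% (d2tau * qd[k]^2 + dtau * qdd[k]))
          }
        }
        rot_idx <- idx
      } else {
        rot_idx <- idx
      }
      if (length(rot_idx)) {
        axes <- j$axes
        for (i in seq_along(rot_idx)) {
          k <- rot_idx[i]
          e <- axes[[i]]
          u <- as.numeric(Rc %*% e)
          ax[, k] <- u
          org[, k] <- pc
          if (want_dyn) {
            al <- al + qdd[k] * u + qd[k] * cross3(w, u)
            w <- w + qd[k] * u
          }
          Rc <- Rc %*% rot3(e, q[k])
        }
      }
    }
    R[[b]] <- Rc
    p[, b] <- pc
    if (want_dyn) { W[, b] <- w; AL[, b] <- al; V[, b] <- v; A[, b] <- a }
  }
  out <- list(R = R, p = p, ax = ax, org = org, tdir = tdir)
  if (want_dyn) { out$w <- W; out$al <- AL; out$v <- V; out$a <- A }
  out
}

# global marker positions (3 x n_markers) from an fk_pass result
marker_positions <- function(model, fk) {
  n <- length(model$markers)
  X <- matrix(0, 3L, n, dimnames = list(NULL, names(model$markers)))
  for (i in seq_len(n)) {
    b <- model$marker_segidx[i]
    X[, i] <- fk$p[, b] + as.numeric(fk$R[[b]] %*% model$marker_local[, i])
  }
  X
}

#' Forward kinematics
#'
#' Composes body poses along the joint tree and places the model markers
#' in the global frame.
#'
#' @param model a `multibody_model`.
#' @param q coordinate vector (length [n_coordinates()]).
#' @return list with `segments` (per-segment list of `R` 3x3 rotation and
#'   `p` origin, m) and `markers` (n x 3 matrix of global positions, m).
#' @export
forward_kinematics <- function(model, q) {
  fk <- fk_pass(model, q)
  segs <- stats::setNames(lapply(seq_along(model$order), function(b)
    list(R = fk$R[[b]], p = as.numeric(fk$p[, b]))), model$order)
  list(segments = segs, markers = t(marker_positions(model, fk)))
}

# Analytic Jacobian of marker positions w.r.t. the generalized
# coordinates: 3*m x nq, rows grouped per marker (x, y, z).
marker_jacobian <- function(model, fk, mk_idx = seq_along(model$markers),
                            X = NULL) {
  nq <- model$n_q
  m <- length(mk_idx)
  if (is.null(X)) X <- marker_positions(model, fk)[, mk_idx, drop = FALSE]
  segb <- model$marker_segidx[mk_idx]
  J <- matrix(0, 3L * m, nq)
  kinds <- model$coords$kind
  for (k in seq_len(nq)) {
    aff <- which(model$ancestry[segb, k])
    if (!length(aff)) next
    rows <- as.vector(outer(-2:0, 3L * aff, `+`))
    if (kinds[k] == "rotation") {
      blk <- cross3_mat(fk$ax[, k], X[, aff, drop = FALSE] - fk$org[, k])
      td <- fk$tdir[, k]
      if (any(td != 0)) blk <- blk + td
      J[rows, k] <- as.vector(blk)
    } else {
      J[rows, k] <- rep(fk$ax[, k], times = length(aff))
    }
  }
  J
}
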