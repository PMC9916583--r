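# shared fixtures, built in code

# uniform-rod pendulum: pin at the origin, rod hanging along -Z
make_pendulum <- function(mass = 2, length = 1, axis = c(0, -1, 0)) {
  multibody_model(
    list(segment("rod", mass, com = c(0, 0, -length / 2),
                 inertia = diag(c(mass * length^2 / 12,
                                  mass * length^2 / 12, 1e-6)))),
    list(joint("hinge", "pin", "ground", "rod", axes = list(axis))))
}

# random serial chain of pin joints with mixed axes, hanging under gravity
make_random_chain <- function(seed, n_links = 3L) {
  set.seed(seed)
  axes <- list(c(0, -1, 0), c(1, 0, 0), c(0, 1, 0))
  L <- stats::runif(n_links, 0.3, 0.6)
  m <- stats::runif(n_links, 0.8, 3)
  cfrac <- stats::runif(n_links, 0.3, 0.7)
  segs <- list(); jnts <- list()
  parent <- "ground"
  for (i in seq_len(n_links)) {
    nm <- paste0("link", i)
    segs[[i]] <- segment(nm, m[i], com = c(0, 0, -cfrac[i] * L[i]),
                         inertia = diag(c(m[i] * L[i]^2 / 12,
                                          m[i] * L[i]^2 / 12,
                                          m[i] * L[i]^2 / 50)))
    jnts[[i]] <- joint(paste0("j", i), "pin", parent, nm,
                       location = if (i == 1L) c(0, 0, 0)
                       else c(0, 0, -L[i - 1L]),
                       axes = list(axes[[1L + (i - 1L) %% 3L]]))
    parent <- nm
  }
  multibody_model(segs, jnts)
}

# smooth multi-sine torque drive, bounded below ~1.5 Hz
make_chain_torque <- function(seed, nq) {
  set.seed(seed + 1000L)
  amp <- stats::runif(nq, 0.3, 2)
  freq <- stats::runif(nq, 0.3, 1.4)
  phase <- stats::runif(nq, 0, 2 * pi)
  function(t) amp * sin(2 * pi * freq * t + phase)
}

# computed-torque drive: a smooth band-limited reference motion (gait
# band, <= 1.5 Hz) realized exactly through inverse dynamics, so the
# forward-dynamics oracle reproduces a bounded trajectory
make_reference_drive <- function(seed, model) {
  nq <- n_coordinates(model)
  set.seed(seed + 500L)
  A <- stats::runif(nq, 0.15, 0.4)
  f <- stats::runif(nq, 0.4, 1.5)
  ph <- stats::runif(nq, 0, 2 * pi)
  off <- stats::runif(nq, -0.2, 0.2)
  qref <- function(t) off + A * sin(2 * pi * f * t + ph)
  qdref <- function(t) A * 2 * pi * f * cos(2 * pi * f * t + ph)
  qddref <- function(t) -A * (2 * pi * f)^2 * sin(2 * pi * f * t + ph)
  tau <- function(t) inverse_dynamics_frame(model, qref(t), qdref(t),
                                            qddref(t))
  list(qref = qref, qdref = qdref, tau = tau)
}

# study models are expensive enough to share across test files
study_models_cache <- new.env(parent = emptyenv())
study_models <- function() {
  if (is.null(study_models_cache$m))
    study_models_cache$m <- build_study_models()
  study_models_cache$m
}

# relative RMS error between two matrices over a row window
rel_rms <- function(est, ref, rows = seq_len(nrow(ref))) {
  sqrt(mean((est[rows, ] - ref[rows, ])^2)) / sqrt(mean(ref[rows, ]^2))
}
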