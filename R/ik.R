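# Marker-based inverse kinematics: damped Gauss-Newton (Levenberg-style
# lambda adaptation) on the weighted marker residual.

ik_control <- function(tol_step = 1e-8, tol_obj = 1e-12, max_iter = 100L,
                       lambda0 = 1e-3) {
  list(tol_step = tol_step, tol_obj = tol_obj, max_iter = max_iter,
       lambda0 = lambda0)
}

#' Solve inverse kinematics for a single frame
#'
#' Finds the coordinates minimizing the weighted sum of squared distances
#' between observed and model marker positions by damped Gauss-Newton
#' with an analytic Jacobian. Occluded markers (`NA` positions) are
#' dropped from the objective. Coordinates whose subtree carries no
#' observed marker are unobservable for the frame: they are held at
#' `q_init` and reported in `underdetermined`.
#'
#' @param model a `multibody_model`.
#' @param observed n x 3 matrix of global marker positions (m) with marker
#'   names as rownames; `NA` marks occlusion.
#' @param weights optional named non-negative weights (default: the model
#'   marker weights).
#' @param q_init starting coordinates (default neutral pose).
#' @param control solver settings, see source of `ik_control()`.
#' @return list with `q`, `rms` (weighted marker RMS, m), `errors`
#'   (per-marker distances), `worst_marker`, `iterations`, `converged`,
#'   `underdetermined` (coordinate names).
#' @export
solve_ik_frame <- function(model, observed, weights = NULL, q_init = NULL,
                           control = list()) {
  ctrl <- do.call(ik_control, control)
  q <- q_init %||% neutral_pose(model)
  obs_names <- intersect(rownames(observed), names(model$markers))
  if (!length(obs_names)) stopf("no observed markers match the model")
  mk_idx <- match(obs_names, names(model$markers))
  Xobs <- t(observed[obs_names, , drop = FALSE])    # 3 x m
  ok <- !apply(is.na(Xobs), 2L, any)
  mk_idx <- mk_idx[ok]
  Xobs <- Xobs[, ok, drop = FALSE]
  if (!ncol(Xobs)) stopf("all observed markers are occluded in this frame")
  w <- if (is.null(weights)) model$marker_weight[mk_idx]
  else {
    ww <- weights[names(model$markers)[mk_idx]]
    ww[is.na(ww)] <- 1
    as.numeric(ww)
  }
  keepw <- w > 0
  mk_idx <- mk_idx[keepw]; Xobs <- Xobs[, keepw, drop = FALSE]; w <- w[keepw]

  # observability: a coordinate is determined only if some weighted
  # marker lies in its subtree
  segb <- model$marker_segidx[mk_idx]
  observable <- colSums(model$ancestry[segb, , drop = FALSE]) > 0
  free <- which(observable)
  under <- model$coords$name[!observable]
  sw <- sqrt(w)
  wsum <- sum(w)

  obj <- function(fk) {
    X <- marker_positions(model, fk)[, mk_idx, drop = FALSE]
    r <- Xobs - X
    list(f = sum(w * colSums(r^2)), r = r, X = X)
  }
  fk <- fk_pass(model, q)
  cur <- obj(fk)
  lambda <- ctrl$lambda0
  it <- 0L
  converged <- FALSE
  while (it < ctrl$max_iter) {
    it <- it + 1L
    J <- marker_jacobian(model, fk, mk_idx, X = cur$X)[, free, drop = FALSE]
    Jw <- J * rep(sw, each = 3L)
    rw <- as.vector(cur$r) * rep(sw, each = 3L)
    H <- crossprod(Jw)
    g <- crossprod(Jw, rw)
    accepted <- FALSE
    for (tries in 1:25) {
      step <- tryCatch(
        solve(H + lambda * diag(nrow(H)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        qn <- q
        qn[free] <- qn[free] + as.numeric(step)
        fkn <- fk_pass(model, qn)
        new <- obj(fkn)
        if (new$f <= cur$f) {
          df <- cur$f - new$f
          q <- qn; fk <- fkn; cur <- new
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          if (max(abs(step)) < ctrl$tol_step || df < ctrl$tol_obj)
            converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- cur$f < 1e-18 || it > 1L; break }
    if (converged) break
  }
  errors <- sqrt(colSums(cur$r^2))
  names(errors) <- names(model$markers)[mk_idx]
  list(q = q, rms = sqrt(cur$f / (wsum)), errors = errors,
       worst_marker = names(errors)[which.max(errors)],
       iterations = it, converged = converged, underdetermined = under)
}

#' Solve inverse kinematics over a marker trajectory
#'
#' Frame-sequential damped Gauss-Newton with previous-frame warm start.
#' The first frame starts from a neutral pose shifted by a coarse global
#' translation fit (observed-vs-model marker centroid). The result
#' records the mean +/- SD marker RMS and a pass/fail flag against the
#' 2 cm tracking tolerance used in practice for marker-driven simulators.
#'
#' @param model a `multibody_model`.
#' @param mts a [marker_trajectory_set()].
#' @param weights optional named marker weights.
#' @param q0 starting coordinates for the first frame.
#' @param tolerance acceptable mean marker RMS, m (default 0.02).
#' @param control solver settings.
#' @return an object of class `ik_result`: `trajectory`
#'   (`coordinate_trajectory`), `per_frame_rms`, `mean_rms`, `sd_rms`,
#'   `worst_marker` (name + error), `pass`, `failed_frames`,
#'   `underdetermined`.
#' @export
solve_ik <- function(model, mts, weights = NULL, q0 = NULL,
                     tolerance = 0.02, control = list()) {
  nt <- length(mts$time)
  if (!nt) stopf("empty marker trajectory")
  q <- q0 %||% neutral_pose(model)
  if (is.null(q0)) {
    # coarse global-pose init: match marker centroids via base translation
    obs1 <- mts_frame(mts, 1L)
    common <- intersect(rownames(obs1), names(model$markers))
    obs_ok <- obs1[common, , drop = FALSE]
    obs_ok <- obs_ok[stats::complete.cases(obs_ok), , drop = FALSE]
    base_t <- model$coords$name[model$coords$kind == "translation"]
    base_t <- base_t[seq_len(min(3L, length(base_t)))]
    if (nrow(obs_ok) && length(base_t) == 3L) {
      Xm <- marker_positions(model, fk_pass(model, q))
      shift <- colMeans(obs_ok) -
        rowMeans(Xm[, rownames(obs_ok), drop = FALSE])
      q[base_t] <- q[base_t] + shift
    }
  }
  nq <- model$n_q
  Q <- matrix(0, nt, nq, dimnames = list(NULL, model$coords$name))
  rms <- numeric(nt)
  worst_err <- -Inf; worst_name <- NA_character_
  failed <- integer(0)
  under <- character(0)
  for (i in seq_len(nt)) {
    res <- solve_ik_frame(model, mts_frame(mts, i), weights = weights,
                          q_init = q, control = control)
    q <- res$q
    Q[i, ] <- q
    rms[i] <- res$rms
    if (length(res$errors) && max(res$errors) > worst_err) {
      worst_err <- max(res$errors); worst_name <- res$worst_marker
    }
    if (!res$converged) failed <- c(failed, i)
    under <- union(under, res$underdetermined)
  }
  structure(list(
    trajectory = coordinate_trajectory(mts$time, Q),
    per_frame_rms = rms, mean_rms = mean(rms),
    sd_rms = if (nt > 1L) stats::sd(rms) else 0,
    worst_marker = list(name = worst_name, error = worst_err),
    tolerance = tolerance, pass = mean(rms) < tolerance,
    failed_frames = failed, underdetermined = under),
    class = "ik_result")
}

#' @export
print.ik_result <- function(x, ...) {
  cat(sprintf("<ik_result: %d frames, marker RMS %.2f +/- %.2f mm (%s %.0f mm tolerance)>\n",
              length(x$per_frame_rms), 1000 * x$mean_rms, 1000 * x$sd_rms,
              if (x$pass) "PASS, <" else "FAIL, >=", 1000 * x$tolerance))
  if (length(x$failed_frames))
    cat(sprintf("  non-converged frames: %s\n",
                paste(utils::head(x$failed_frames, 10L), collapse = ", ")))
  if (length(x$underdetermined))
    cat(sprintf("  under-determined coordinates: %s\n",
                paste(x$underdetermined, collapse = ", ")))
  invisible(x)
}
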