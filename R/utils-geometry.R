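# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# cross product of one 3-vector against the columns of a 3 x n matrix
cross3_mat <- function(a, B) {
  rbind(a[2L] * B[3L, ] - a[3L] * B[2L, ],
        a[3L] * B[1L, ] - a[1L] * B[3L, ],
        a[1L] * B[2L, ] - a[2L] * B[1L, ])
}

# skew-symmetric matrix of a 3-vector
skew3 <- function(a) {
  matrix(c(0, -a[3L], a[2L],
           a[3L], 0, -a[1L],
           -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
}

# Rodrigues rotation about a unit axis
rot3 <- function(axis, angle) {
  ca <- cos(angle); sa <- sin(angle)
  K <- skew3(axis)
  diag(3L) * ca + sa * K + (1 - ca) * (axis %o% axis)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length axis vector")
  v / n
}

#' Degree/radian conversion
#' @param x angle(s).
#' @return converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

is_symmetric_psd <- function(M, tol = 1e-8) {
  if (any(abs(M - t(M)) > tol)) return(FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1L])))
}

# parallel-axis transfer of an inertia tensor about the COM to a point
# displaced by d (tensor and d in the same frame)
parallel_axis <- function(I_com, mass, d) {
  I_com + mass * (sum(d^2) * diag(3L) - d %o% d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# format numbers for file output: 8 significant digits, deterministic
fmt_num <- function(x) {
  out <- sprintf("%.8g", x)
  out[is.na(x)] <- ""
  out
}
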