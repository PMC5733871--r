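#' Quaternion arithmetic for EEG signal analysis
#'
#' Quaternions are represented as numeric vectors `c(w, x, y, z)` (scalar
#' part first) and quaternion series as m-by-4 numeric matrices, one
#' quaternion per row. The Hamilton convention is used throughout:
#' `i^2 = j^2 = k^2 = ijk = -1`, so `ij = k` and `ji = -k` (right-handed).
#'
#' @name quaternion-arithmetic
NULL

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(as.numeric(q), nrow = 1L)
  }
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("quaternions must have 4 components (w, x, y, z)")
  storage.mode(q) <- "double"
  q
}

#' Hamilton product of quaternions
#'
#' Multiplies quaternions elementwise by row. Both arguments may be a
#' single quaternion (length-4 vector) or an m-by-4 matrix; a single
#' quaternion is recycled against a series.
#'
#' @param p,q quaternions as length-4 vectors `c(w, x, y, z)` or m-by-4
#'   matrices.
#' @return the product, in the same shape as the longer argument.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0)) # i * j = k
#' @export
quat_multiply <- function(p, q) {
  p <- as_quat_matrix(p)
  q <- as_quat_matrix(q)
  if (nrow(p) != nrow(q)) {
    if (nrow(p) == 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
    else if (nrow(q) == 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
    else stop("incompatible quaternion series lengths")
  }
  w1 <- p[, 1L]; x1 <- p[, 2L]; y1 <- p[, 3L]; z1 <- p[, 4L]
  w2 <- q[, 1L]; x2 <- q[, 2L]; y2 <- q[, 3L]; z2 <- q[, 4L]
  out <- cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
  colnames(out) <- c("w", "x", "y", "z")
  if (nrow(out) == 1L) drop(out) else out
}

#' Quaternion conjugate
#'
#' @param q a quaternion or m-by-4 series.
#' @return the conjugate(s), same shape as the input.
#' @export
quat_conjugate <- function(q) {
  m <- as_quat_matrix(q)
  m[, 2:4] <- -m[, 2:4]
  if (is.null(dim(q))) drop(m) else m
}

#' Quaternion norm
#'
#' @param q a quaternion or m-by-4 series.
#' @return Euclidean 4-norm(s) as a numeric vector.
#' @export
quat_norm <- function(q) {
  m <- as_quat_matrix(q)
  sqrt(rowSums(m^2))
}

#' Unit quaternion from an axis-angle rotation
#'
#' Builds `cos(theta/2) + (ax*i + ay*j + az*k) * sin(theta/2)`, the unit
#' quaternion encoding a rotation of `angle` radians about the unit
#' vector `axis`.
#'
#' @param axis unit 3-vector (checked to within 1e-9).
#' @param angle rotation angle in radians.
#' @return a unit quaternion `c(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  stopifnot(length(axis) == 3L, length(angle) == 1L, is.finite(angle))
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) {
    stop("rotation axis must be a unit vector")
  }
  c(w = cos(angle / 2), sin(angle / 2) * c(x = axis[1L], y = axis[2L], z = axis[3L]))
}

#' Rotate 3-vectors by quaternions (sandwich product)
#'
#' Computes the vector part of `q * (0, r) * q^-1` row by row, with the
#' full inverse `q^-1 = conjugate(q) / |q|^2`, so the map is a proper
#' rotation (an isometry) for any nonzero `q`, not only unit quaternions.
#' Rows with `|q| = 0` map to the zero vector (degenerate-input policy:
#' four simultaneously flat channels carry no orientation).
#'
#' @param q a quaternion (length-4) or m-by-4 series.
#' @param r a 3-vector or m-by-3 matrix of vectors to rotate.
#' @return rotated vector(s), same shape as `r`.
#' @export
quat_rotate <- function(q, r) {
  qm <- as_quat_matrix(q)
  if (is.null(dim(r))) {
    stopifnot(length(r) == 3L)
    rm <- matrix(as.numeric(r), nrow = 1L)
  } else {
    rm <- as.matrix(r)
    if (ncol(rm) != 3L) stop("vectors to rotate must have 3 components")
  }
  if (nrow(qm) != nrow(rm)) {
    if (nrow(qm) == 1L) qm <- qm[rep(1L, nrow(rm)), , drop = FALSE]
    else if (nrow(rm) == 1L) rm <- rm[rep(1L, nrow(qm)), , drop = FALSE]
    else stop("quaternion and vector series lengths differ")
  }
  n2 <- rowSums(qm^2)
  pure <- cbind(0, rm)
  qinv <- cbind(qm[, 1L], -qm[, 2L], -qm[, 3L], -qm[, 4L]) / ifelse(n2 > 0, n2, 1)
  out <- quat_multiply(quat_multiply(qm, pure), qinv)
  out <- as_quat_matrix(out)
  out[n2 == 0, ] <- 0
  res <- out[, 2:4, drop = FALSE]
  colnames(res) <- c("x", "y", "z")
  if (is.null(dim(r))) drop(res) else res
}

#' Build the quaternion and displaced-vector streams from a 4-channel window
#'
#' The first channel becomes the scalar part and the remaining three the
#' imaginary parts of a quaternion per sample; the vector stream takes
#' the three imaginary channels displaced forward by `dt` samples. Both
#' streams have length `m = ns - dt`, where `ns` is the window length.
#'
#' @param window numeric ns-by-4 matrix, one column per channel, the
#'   scalar channel first.
#' @param dt positive integer rotation displacement in samples
#'   (default 4).
#' @return a list with `q` (m-by-4 quaternion series), `r` (m-by-3 vector
#'   series) and `m`.
#' @export
build_quaternion_streams <- function(window, dt = 4L) {
  window <- as.matrix(window)
  if (ncol(window) != 4L) stop("window must have exactly 4 channels")
  dt <- as.integer(dt)
  if (dt < 1L) stop("dt must be a positive integer")
  ns <- nrow(window)
  if (ns <= dt) stop("window length (", ns, ") must exceed dt (", dt, ")")
  m <- ns - dt
  q <- window[seq_len(m), , drop = FALSE]
  colnames(q) <- c("w", "x", "y", "z")
  r <- window[seq_len(m) + dt, 2:4, drop = FALSE]
  colnames(r) <- c("x", "y", "z")
  list(q = q, r = r, m = m)
}

#' Modulus of the rotated quaternion stream
#'
#' Rotates each displaced vector `r_t` by the quaternion `q_t` and takes
#' the Euclidean norm of the rotated vector part. This scalar series
#' (`q_mod`) is the descriptor from which window features are computed.
#'
#' @param q m-by-4 quaternion series.
#' @param r m-by-3 vector series.
#' @return numeric vector of length m, all values >= 0.
#' @export
rotation_modulus <- function(q, r) {
  q <- as_quat_matrix(q)
  r <- as.matrix(r)
  if (nrow(q) != nrow(r)) stop("quaternion and vector series lengths differ")
  rot <- quat_rotate(q, r)
  rot <- matrix(rot, ncol = 3L)
  sqrt(rowSums(rot^2))
}
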