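# Quaternion algebra --------------------------------------------------------
#
# Quaternions are stored as n x 4 numeric matrices in scalar-first order
# (w, x, y, z), Hamilton convention. Orientation quaternions rotate vectors
# expressed in the sensor frame into the global frame: v_global = q (0,v) q*.
# The global frame is right-handed with +Z up.

as_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != 4) stop("quaternions must have 4 components (w, x, y, z)")
  q
}

#' Quaternion norms
#' @param q n x 4 quaternion matrix (scalar-first)
#' @return numeric vector of row norms
#' @keywords internal
quat_norm <- function(q) sqrt(rowSums(as_quat(q)^2))

#' Normalize quaternions to unit norm
#' @param q n x 4 quaternion matrix
#' @return matrix of unit quaternions
#' @export
quat_normalize <- function(q) {
  q <- as_quat(q)
  q / quat_norm(q)
}

#' Canonicalize quaternion sign
#'
#' `q` and `-q` encode the same rotation (double cover); the canonical
#' representative has non-negative scalar part.
#' @param q n x 4 quaternion matrix
#' @return matrix with `q[,1] >= 0` row-wise
#' @export
quat_canonical <- function(q) {
  q <- as_quat(q)
  s <- ifelse(q[, 1] < 0, -1, 1)
  q * s
}

#' Quaternion conjugate
#' @param q n x 4 quaternion matrix
#' @return conjugated matrix
#' @export
quat_conjugate <- function(q) {
  q <- as_quat(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a * b`; a single-row argument is recycled.
#' @param a,b quaternion matrices (n x 4 or 1 x 4)
#' @return n x 4 matrix
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat(a); b <- as_quat(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

#' Rotate vectors by unit quaternions
#'
#' Applies `v' = q (0, v) q*` row-wise, i.e. expresses sensor-frame vectors in
#' the global frame when `q` is a sensor-to-global orientation.
#' @param q n x 4 unit quaternion matrix (a single row is recycled)
#' @param v n x 3 matrix of vectors (a single row is recycled)
#' @return n x 3 matrix of rotated vectors
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1 && n > 1) q <- q[rep(1, n), , drop = FALSE]
  if (nrow(v) == 1 && n > 1) v <- v[rep(1, n), , drop = FALSE]
  qv <- q[, 2:4, drop = FALSE]
  t <- 2 * cross3(qv, v)
  v + q[, 1] * t + cross3(qv, t)
}

#' Rotation matrix of a single unit quaternion
#' @param q length-4 quaternion (w, x, y, z)
#' @return 3 x 3 rotation matrix (sensor-to-global)
#' @export
quat_to_rotmat <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#' @param axis length-3 axis (normalized internally)
#' @param angle rotation angle(s) in radians
#' @return n x 4 quaternion matrix (one row per angle)
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  cbind(cos(angle / 2), outer(sin(angle / 2), axis))
}

#' Quaternion from intrinsic x-y-z Euler angles
#'
#' Composition `q = qx(roll) * qy(pitch) * qz(yaw)` (intrinsic rotations about
#' the moving sensor axes).
#' @param roll,pitch,yaw angle vectors in radians
#' @return n x 4 quaternion matrix
#' @export
quat_from_euler <- function(roll, pitch, yaw) {
  qx <- quat_from_axis_angle(c(1, 0, 0), roll)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch)
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  quat_multiply(quat_multiply(qx, qy), qz)
}

#' Mean attitude of a quaternion trajectory
#'
#' Chordal mean: canonicalize signs, average component-wise, renormalize.
#' Adequate for the small-dispersion attitudes occurring within a passage.
#' @param q n x 4 unit quaternion matrix
#' @return 1 x 4 unit quaternion
#' @export
quat_mean <- function(q) {
  q <- quat_canonical(as_quat(q))
  m <- matrix(colMeans(q), nrow = 1)
  quat_normalize(m)
}

#' Body-frame angular velocity of a quaternion trajectory
#'
#' Differentiates the orientation stream by central differences and maps the
#' derivative into the body (sensor) frame: `omega = 2 * vec(q* dq/dt)`.
#' @param q n x 4 unit quaternion trajectory
#' @param fs sampling rate in Hz
#' @return n x 3 matrix of angular velocity (rad/s) in the sensor frame
#' @export
quat_angular_velocity <- function(q, fs) {
  q <- as_quat(q)
  n <- nrow(q)
  if (n < 3) stop("need at least 3 samples to differentiate orientation")
  dq <- q
  dq[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) * fs / 2
  dq[1, ] <- (q[2, ] - q[1, ]) * fs
  dq[n, ] <- (q[n, ] - q[n - 1, ]) * fs
  prod <- quat_multiply(quat_conjugate(q), dq)
  2 * prod[, 2:4, drop = FALSE]
}
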