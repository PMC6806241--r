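# Quaternion algebra: scalar-first [q0 q1 q2 q3], Hamilton convention.
# A quaternion stores the body-to-Earth rotation; the Earth frame follows the
# NED (north-east-down) convention, so gravity points along +z_n.

#' Hamilton product of two quaternions
#'
#' Quaternions are numeric vectors `c(q0, q1, q2, q3)` with the scalar part
#' first.  The product `quat_multiply(a, b)` composes rotations so that the
#' result rotates by `b` first, then by `a`.
#'
#' @param a,b Numeric length-4 quaternions, scalar part first.
#' @return Numeric length-4 quaternion.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i * j = k
#' @export
quat_multiply <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L)
  c(a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) c(a[1L], -a[2L], -a[3L], -a[4L])

#' Normalize a quaternion to unit length
#'
#' @param q Numeric length-4 quaternion.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Canonical hemisphere: flip sign so the scalar part is non-negative
#'
#' `q` and `-q` encode the same rotation; output boundaries use the
#' representative with `q0 >= 0`.
#'
#' @param q Numeric length-4 quaternion.
#' @return Quaternion with non-negative scalar part.
#' @export
quat_canonical <- function(q) if (q[1L] < 0) -q else q

#' Rotation matrix of a quaternion
#'
#' Returns the 3x3 body-to-Earth rotation matrix \eqn{R(q)} such that
#' `R %*% v_body` expresses a body-frame vector in the Earth frame.
#'
#' @param q Unit quaternion.
#' @return 3x3 orthonormal matrix.
#' @export
quat_to_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Rotate a vector by a quaternion
#'
#' `quat_rotate(q, v)` maps a body-frame vector to the Earth frame
#' (`q (0,v) q*`); `quat_rotate_inverse(q, v)` maps an Earth-frame vector to
#' the body frame, which is what a strapped-down sensor observes.
#'
#' @param q Unit quaternion (body-to-Earth).
#' @param v Numeric length-3 vector.
#' @return Rotated length-3 vector.
#' @export
quat_rotate <- function(q, v) {
  p <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  p[2:4]
}

#' @rdname quat_rotate
#' @export
quat_rotate_inverse <- function(q, v) {
  p <- quat_multiply(quat_multiply(quat_conjugate(q), c(0, v)), q)
  p[2:4]
}

#' Rotation angle between two attitudes, in radians
#'
#' The geodesic rotation angle separating the attitudes encoded by `a` and
#' `b`, insensitive to the sign ambiguity of unit quaternions.
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians, in `[0, pi]`.
#' @export
quat_angle <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

#' Axis-angle construction of a quaternion
#'
#' @param axis Rotation axis (need not be unit length; zero axis gives
#'   identity).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0 || angle == 0) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Convert a unit quaternion to ZYX (yaw-pitch-roll) Euler angles
#'
#' Intrinsic ZYX convention: yaw about z, then pitch about y, then roll about
#' x.  Ranges are roll, yaw in `(-pi, pi]` and pitch in `[-pi/2, pi/2]`.
#' At gimbal lock (`|pitch| = pi/2`) roll and yaw are indistinguishable; the
#' fallback sets `roll = 0` and folds the free angle into yaw, so the result
#' is always finite.
#'
#' @param q Unit quaternion (norm within `1e-6` of 1).
#' @return Named numeric vector `c(roll, pitch, yaw)` in radians.
#' @export
quat_to_euler <- function(q) {
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6)
    stop("quat_to_euler() requires a unit quaternion")
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  s <- 2 * (w * y - z * x)
  if (abs(s) >= 1 - 1e-12) {
    # gimbal lock: only roll +/- yaw is observable; put it all in yaw
    pitch <- sign(s) * pi / 2
    roll  <- 0
    yaw   <- 2 * atan2(x, w) * -sign(s)
    # map into (-pi, pi]
    yaw <- atan2(sin(yaw), cos(yaw))
  } else {
    roll  <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
    pitch <- asin(s)
    yaw   <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  }
  c(roll = roll, pitch = pitch, yaw = yaw)
}

#' Convert ZYX Euler angles to a unit quaternion
#'
#' @param roll,pitch,yaw Angles in radians (intrinsic ZYX convention).
#' @return Unit quaternion with non-negative scalar part.
#' @export
euler_to_quat <- function(roll, pitch, yaw) {
  cr <- cos(roll / 2);  sr <- sin(roll / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cy <- cos(yaw / 2);   sy <- sin(yaw / 2)
  q <- c(cy * cp * cr + sy * sp * sr,
         cy * cp * sr - sy * sp * cr,
         cy * sp * cr + sy * cp * sr,
         sy * cp * cr - cy * sp * sr)
  quat_canonical(quat_normalize(q))
}
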