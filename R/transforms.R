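#' Rigid-body transforms and angle utilities
#'
#' All gait-level parameters (hip swing, lift swing, joint angles) are in
#' degrees; all rigid transforms work in radians. Conversion between the two
#' is confined to [deg2rad()] / [rad2deg()].
#'
#' @name transforms
NULL

#' Degrees to radians
#' @param deg angle in degrees.
#' @return angle in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' Radians to degrees
#' @param rad angle in radians.
#' @return angle in degrees.
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Wrap an angle to (-pi, pi]
#' @param a angle in radians (vectorised).
#' @return wrapped angle.
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; keep the (+pi] end of the interval
  w[w == -pi] <- pi
  w
}

rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Homogeneous rigid transform from Euler angles and a translation
#'
#' Composes intrinsic rotations in fixed roll-pitch-yaw order
#' (about x, then y, then z: `R = Rz %*% Ry %*% Rx`) followed by a
#' translation, returning the 4x4 homogeneous matrix.
#'
#' @param rotation numeric length-3, Euler angles (x, y, z) in radians.
#' @param translation numeric length-3 translation.
#' @return a 4x4 homogeneous transform matrix.
#' @examples
#' homogeneous_transform(c(0, 0, pi / 2), c(0, 0, 0)) %*% c(1, 0, 0, 1)
#' @export
homogeneous_transform <- function(rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  H <- diag(4)
  H[1:3, 1:3] <- rot_z(rotation[3]) %*% rot_y(rotation[2]) %*% rot_x(rotation[1])
  H[1:3, 4] <- translation
  H
}

#' Apply a homogeneous transform to one or more 3-D points
#' @param H 4x4 homogeneous matrix.
#' @param p numeric length-3 point, or 3-row matrix of points.
#' @return transformed point(s), same shape as `p`.
#' @export
transform_point <- function(H, p) {
  if (is.matrix(p)) {
    H[1:3, 1:3] %*% p + H[1:3, 4]
  } else {
    drop(H[1:3, 1:3] %*% p) + H[1:3, 4]
  }
}
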