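# Rigid 6-DOF geometry about the isocenter.
#
# Axis convention (right-handed): x = LR (+x toward patient left),
# y = AP (+y anterior), z = SI (+z superior). Pitch rotates about x,
# yaw about y, roll about z. Rotations are extrinsic with fixed order
# R = Rz(roll) %*% Rx(pitch) %*% Ry(yaw); translation is applied after
# rotation. A transform maps patient-frame points to their displaced
# position: p' = R (p - iso) + iso + t.

.deg2rad <- function(d) d * pi / 180

.rotX <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rotY <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rotZ <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix of a rigid transform
#'
#' @param t a [RigidTransform6D-class].
#' @return 3x3 rotation matrix `Rz(roll) Rx(pitch) Ry(yaw)`.
#' @export
rotationMatrix <- function(t) {
  .rotZ(.deg2rad(t@roll)) %*% .rotX(.deg2rad(t@pitch)) %*%
    .rotY(.deg2rad(t@yaw))
}

#' Homogeneous 4x4 matrix of a rigid transform about an isocenter
#'
#' Maps patient-frame points to their displaced position,
#' `p' = R (p - iso) + iso + t`, with the rotation applied about the
#' isocenter and the translation applied after the rotation.
#'
#' @param t a [RigidTransform6D-class]; all components must be finite.
#' @param isocenter numeric(3), mm.
#' @return 4x4 homogeneous matrix.
#' @examples
#' transformMatrix(rigidTransform(), c(0, 0, 0))  # identity
#' @export
transformMatrix <- function(t, isocenter = c(0, 0, 0)) {
  if (!is(t, "RigidTransform6D")) stop("t must be a RigidTransform6D")
  validObject(t)
  iso <- as.numeric(isocenter)
  if (length(iso) != 3L || !all(is.finite(iso)))
    stop("isocenter must be finite numeric(3)")
  R <- rotationMatrix(t)
  b <- iso + c(t@tx, t@ty, t@tz) - R %*% iso
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- b
  m
}

#' Compose two homogeneous transforms
#'
#' `composeTransforms(a, b)` applies `b` first, then `a` (matrix product
#' `a %*% b`), the convention used to combine a systematic setup error with
#' a per-fraction random draw (systematic applied last).
#'
#' @param a,b 4x4 homogeneous matrices.
#' @export
composeTransforms <- function(a, b) {
  stopifnot(is.matrix(a), all(dim(a) == 4L), is.matrix(b), all(dim(b) == 4L))
  a %*% b
}

#' Invert a rigid homogeneous transform
#'
#' Uses the rigid structure (`R^T`, `-R^T b`) rather than a general solve.
#' @param m 4x4 rigid homogeneous matrix.
#' @export
invertTransform <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4L))
  Rt <- t(m[1:3, 1:3])
  out <- diag(4)
  out[1:3, 1:3] <- Rt
  out[1:3, 4] <- -Rt %*% m[1:3, 4]
  out
}

#' Apply a homogeneous transform to points
#'
#' @param m 4x4 matrix.
#' @param pts numeric(3) or an n x 3 matrix of points (mm).
#' @return Points in the same shape as the input.
#' @export
applyTransform <- function(m, pts) {
  if (is.null(dim(pts))) {
    as.numeric(m[1:3, 1:3] %*% pts + m[1:3, 4])
  } else {
    t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
  }
}

#' Recover 6-DOF parameters from a rigid matrix
#'
#' Inverse of [transformMatrix()] for the package's Euler convention
#' (`R = Rz(roll) Rx(pitch) Ry(yaw)`); valid away from the pitch = +/-90
#' degree gimbal lock, far beyond any clinically plausible setup error.
#'
#' @param m 4x4 rigid matrix.
#' @param isocenter numeric(3) used when the matrix was built.
#' @return A [RigidTransform6D-class].
#' @export
decomposeTransform <- function(m, isocenter = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  pitch <- asin(max(-1, min(1, R[3, 2])))
  yaw <- atan2(-R[3, 1], R[3, 3])
  roll <- atan2(-R[1, 2], R[2, 2])
  iso <- as.numeric(isocenter)
  tvec <- m[1:3, 4] - iso + R %*% iso
  rigidTransform(tx = tvec[1], ty = tvec[2], tz = tvec[3],
                 pitch = pitch * 180 / pi, yaw = yaw * 180 / pi,
                 roll = roll * 180 / pi)
}

#' Serialize / deserialize a transform for JSON interchange
#'
#' Field names follow the report schema: `tx_mm`, `ty_mm`, `tz_mm`,
#' `pitch_deg`, `yaw_deg`, `roll_deg`.
#' @param t a `RigidTransform6D`.
#' @export
transformToList <- function(t) {
  list(tx_mm = t@tx, ty_mm = t@ty, tz_mm = t@tz,
       pitch_deg = t@pitch, yaw_deg = t@yaw, roll_deg = t@roll)
}

#' @rdname transformToList
#' @param x a named list with the serialized fields.
#' @export
transformFromList <- function(x) {
  rigidTransform(tx = x$tx_mm, ty = x$ty_mm, tz = x$tz_mm,
                 pitch = x$pitch_deg, yaw = x$yaw_deg, roll = x$roll_deg)
}
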