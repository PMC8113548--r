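## Rigid transforms: construction, group operations, quaternion utilities.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric (mm).
#' @param source,target names of the source and target frames.
#' @return a [RigidTransform-class].
#' @examples
#' Tz <- rigidTransform(rotationAboutZ(pi / 2), c(0, 0, 0), "a", "b")
#' applyTransform(Tz, c(1, 0, 0))
#' @export
rigidTransform <- function(rotation, translation = c(0, 0, 0),
                           source = "a", target = "b") {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation),
      sourceFrame = source, targetFrame = target)
}

#' Identity transform between two frames
#' @param source,target frame names (identical frames by default).
#' @return a [RigidTransform-class] with identity rotation and zero translation.
#' @export
identityTransform <- function(source = "a", target = source) {
  rigidTransform(diag(3), c(0, 0, 0), source, target)
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(T_ab, T_bc)} maps the source frame of \code{T_ab}
#' to the target frame of \code{T_bc}: the result applies \code{T_ab} first.
#'
#' @param T_ab,T_bc [RigidTransform-class] objects with
#'   \code{targetFrame(T_ab) == sourceFrame(T_bc)}.
#' @return the chained [RigidTransform-class].
#' @export
composeTransforms <- function(T_ab, T_bc) {
  if (!identical(T_ab@targetFrame, T_bc@sourceFrame))
    stop(sprintf("frame mismatch: cannot chain %s->%s with %s->%s",
                 T_ab@sourceFrame, T_ab@targetFrame,
                 T_bc@sourceFrame, T_bc@targetFrame))
  rigidTransform(T_bc@rotation %*% T_ab@rotation,
                 as.vector(T_bc@rotation %*% T_ab@translation) + T_bc@translation,
                 source = T_ab@sourceFrame, target = T_bc@targetFrame)
}

#' Invert a rigid transform
#' @param T a [RigidTransform-class].
#' @return the inverse transform, with source and target frames swapped.
#' @export
invertTransform <- function(T) {
  Rt <- t(T@rotation)
  rigidTransform(Rt, as.vector(-Rt %*% T@translation),
                 source = T@targetFrame, target = T@sourceFrame)
}

#' Apply a rigid transform to points
#' @param T a [RigidTransform-class].
#' @param points length-3 vector or n x 3 matrix of points (mm).
#' @return points in the target frame, same shape as the input.
#' @export
applyTransform <- function(T, points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    return(as.vector(T@rotation %*% points) + T@translation)
  }
  sweep(points %*% t(T@rotation), 2, T@translation, "+")
}

#' Rotation about a coordinate axis
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotationAboutZ <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' @rdname rotationAboutZ
#' @export
rotationAboutX <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rotationAboutZ
#' @export
rotationAboutY <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' Rotation angle of a rotation matrix
#' @param R a 3x3 rotation matrix.
#' @return the rotation angle in radians, in [0, pi].
#' @export
rotationAngle <- function(R) {
  # atan2 of the skew part against the trace: accurate for small angles,
  # where the acos form loses half the significant digits
  s <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
              (R[2, 1] - R[1, 2])^2) / 2
  c_ <- (sum(diag(R)) - 1) / 2
  atan2(s, c_)
}

#' Axis-angle rotation matrix (Rodrigues)
#' @param axis rotation axis (normalized internally).
#' @param angle angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotationAxisAngle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rigid transform
#'
#' Uniform random rotation (via random quaternion) with a random translation;
#' uses R's RNG, so set the seed for reproducibility.
#'
#' @param maxTranslation translations drawn uniformly in
#'   \code{[-maxTranslation, maxTranslation]} per axis (mm).
#' @param source,target frame names.
#' @return a [RigidTransform-class].
#' @export
randomRigidTransform <- function(maxTranslation = 50, source = "a",
                                 target = "b") {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  rigidTransform(matrixFromQuaternion(q),
                 runif(3, -maxTranslation, maxTranslation), source, target)
}

## -- quaternions ------------------------------------------------------------
## Unit quaternion convention: q = (w, x, y, z), q and -q equivalent.

#' Quaternion/matrix conversions and spherical-linear interpolation
#'
#' Rotations are stored as matrices but serialized and interpolated as unit
#' quaternions \code{(w, x, y, z)}.
#'
#' @param R a 3x3 rotation matrix.
#' @return \code{quaternionFromMatrix}: length-4 unit quaternion.
#' @export
quaternionFromMatrix <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' @rdname quaternionFromMatrix
#' @param q length-4 unit quaternion \code{(w, x, y, z)}.
#' @return \code{matrixFromQuaternion}: 3x3 rotation matrix.
#' @export
matrixFromQuaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' @rdname quaternionFromMatrix
#' @param q0,q1 unit quaternions to interpolate between.
#' @param s interpolation parameter in [0, 1].
#' @return \code{slerpQuaternion}: interpolated unit quaternion.
#' @export
slerpQuaternion <- function(q0, q1, s) {
  d <- sum(q0 * q1)
  if (d < 0) {         # take the short arc
    q1 <- -q1
    d <- -d
  }
  if (d > 1 - 1e-10)   # nearly parallel: linear interpolation is stable
    return({v <- (1 - s) * q0 + s * q1; v / sqrt(sum(v^2))})
  th <- acos(min(1, d))
  (sin((1 - s) * th) * q0 + sin(s * th) * q1) / sin(th)
}
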