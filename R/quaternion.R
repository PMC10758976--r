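## Quaternion algebra for joint-angle kinematics.
##
## Quaternions are stored scalar-first (w, x, y, z), Hamilton convention.
## A single quaternion is a length-4 numeric vector; a frame stream is an
## n x 4 matrix with one row per frame.  q and -q encode the same rotation;
## quat_canonical() fixes the sign ambiguity by forcing w >= 0.

as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns (w,x,y,z)")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion has 4 components (w,x,y,z)")
    matrix(q, nrow = 1L)
  }
}

check_finite_quat <- function(q) {
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  invisible(q)
}

#' Construct a unit quaternion
#'
#' @param w,x,y,z Real components, scalar first (Hamilton convention).
#' @param normalize Normalize to unit length (default `TRUE`).
#' @return Named numeric vector `c(w, x, y, z)`.
#' @export
#' @examples
#' quaternion(1, 0, 0, 0)          # identity rotation
#' rotation_quat("y", 90)          # quarter turn about the Y axis
quaternion <- function(w, x, y, z, normalize = TRUE) {
  q <- c(w = w, x = x, y = y, z = z)
  check_finite_quat(q)
  if (normalize) q <- quat_normalize(q)
  q
}

#' @rdname quaternion
#' @param axis One of `"x"`, `"y"`, `"z"`, or a length-3 axis vector.
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @export
rotation_quat <- function(axis, angle_deg) {
  if (is.character(axis)) {
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be 'x', 'y', 'z' or a length-3 vector"))
  }
  stopifnot(length(axis) == 3L, all(is.finite(axis)), all(is.finite(angle_deg)))
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be non-zero")
  axis <- axis / nrm
  half <- angle_deg * pi / 360
  if (length(half) == 1L) {
    quaternion(cos(half), axis[1] * sin(half), axis[2] * sin(half),
               axis[3] * sin(half), normalize = FALSE)
  } else {
    cbind(w = cos(half), x = axis[1] * sin(half), y = axis[2] * sin(half),
          z = axis[3] * sin(half))
  }
}

#' Quaternion norm, normalization and canonical sign
#'
#' `quat_normalize()` rescales to unit length (error on a zero quaternion);
#' `quat_canonical()` additionally flips the sign so that `w >= 0`, removing
#' the two-to-one ambiguity between `q` and `-q`.
#'
#' @param q Length-4 quaternion or n x 4 frame matrix.
#' @return Object of the same shape as `q`.
#' @export
quat_normalize <- function(q) {
  m <- as_quat_matrix(q)
  check_finite_quat(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a (near-)zero quaternion")
  out <- m / nrm
  if (is.matrix(q)) out else stats::setNames(drop(out), c("w", "x", "y", "z"))
}

#' @rdname quat_normalize
#' @export
quat_canonical <- function(q) {
  m <- as_quat_matrix(quat_normalize(q))
  flip <- m[, 1L] < 0
  m[flip, ] <- -m[flip, ]
  if (is.matrix(q)) m else stats::setNames(drop(m), c("w", "x", "y", "z"))
}

#' Hamilton product of two quaternions
#'
#' Non-commutative quaternion multiplication; the result is renormalized.
#' Inputs may be single quaternions or aligned n x 4 frame matrices (a single
#' quaternion is recycled against a matrix).
#'
#' @param a,b Unit quaternions (length-4 vectors or n x 4 matrices).
#' @return Product quaternion(s), unit norm.
#' @export
quat_multiply <- function(a, b) {
  A <- as_quat_matrix(a); B <- as_quat_matrix(b)
  check_finite_quat(A); check_finite_quat(B)
  if (nrow(A) == 1L && nrow(B) > 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
  if (nrow(B) == 1L && nrow(A) > 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("frame counts differ")
  w <- A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4]
  x <- A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3]
  y <- A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2]
  z <- A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  out <- quat_normalize(cbind(w = w, x = x, y = y, z = z))
  if (is.matrix(a) || is.matrix(b)) out
  else stats::setNames(drop(out), c("w", "x", "y", "z"))
}

#' Inverse of a unit quaternion
#'
#' For unit quaternions the inverse equals the conjugate.
#'
#' @param q Unit quaternion (length-4 vector or n x 4 matrix).
#' @return Inverse quaternion(s).
#' @export
quat_inverse <- function(q) {
  m <- as_quat_matrix(q)
  check_finite_quat(m)
  if (any(rowSums(m^2) < 1e-12)) stop("zero quaternion has no inverse")
  out <- cbind(w = m[, 1], x = -m[, 2], y = -m[, 3], z = -m[, 4])
  out <- quat_normalize(out)
  if (is.matrix(q)) out else stats::setNames(drop(out), c("w", "x", "y", "z"))
}

#' Relative joint quaternion between two segments
#'
#' Computes the rotation carrying the proximal-segment frame onto the
#' distal-segment frame: `q_joint = q_proximal^-1 (x) q_distal`, the standard
#' relative-orientation formula for joint angles from segment orientations.
#' Published descriptions differ on which operand is labelled "rb1"; here the
#' proximal segment is always the inverted operand.  Both inputs must be
#' expressed in the same global reference frame — this cannot be verified from
#' the data and is a documented contract.
#'
#' @param q_proximal,q_distal Unit quaternions (vectors or aligned matrices).
#' @return Joint quaternion(s).
#' @export
joint_quaternion <- function(q_proximal, q_distal) {
  quat_multiply(quat_inverse(q_proximal), q_distal)
}

## 3x3 rotation matrix for a single quaternion (used by tests and the
## gimbal-free decomposition path).
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Intrinsic YXZ Euler decomposition
#'
#' Factors a rotation as an intrinsic Y-X'-Z'' sequence and returns the three
#' angles in degrees.  Under the package's plane mapping the Y channel carries
#' flexion/extension, X abduction/adduction, and Z axial rotation.  Ranges:
#' `angle_y`, `angle_z` in (-180, 180], `angle_x` in [-90, 90].
#'
#' Near gimbal lock (`|angle_x|` within `gimbal_tol` degrees of 90) the Y and
#' Z rotations share an axis; the tie-break sets `angle_z = 0` and folds the
#' full coupled rotation into `angle_y`, and the frame is flagged.
#'
#' @param q Unit quaternion (length-4 vector) or n x 4 frame matrix.
#' @param gimbal_tol Degrees from 90 at which a frame is flagged as
#'   gimbal-proximal (default 0.01).
#' @return For a matrix input, a data frame with columns `angle_y`, `angle_x`,
#'   `angle_z` (degrees) and logical `gimbal`; for a single quaternion a named
#'   numeric vector with a `gimbal` attribute.
#' @export
#' @examples
#' euler_yxz(rotation_quat("y", 45))  # c(45, 0, 0)
euler_yxz <- function(q, gimbal_tol = 0.01) {
  m <- quat_normalize(as_quat_matrix(q))
  w <- m[, 1]; x <- m[, 2]; y <- m[, 3]; z <- m[, 4]
  r11 <- 1 - 2 * (y^2 + z^2); r12 <- 2 * (x * y - w * z)
  r13 <- 2 * (x * z + w * y)
  r21 <- 2 * (x * y + w * z); r22 <- 1 - 2 * (x^2 + z^2)
  r23 <- 2 * (y * z - w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  sx <- pmin(1, pmax(-1, -r23))
  angle_x <- asin(sx) * 180 / pi
  gimbal <- abs(angle_x) >= 90 - gimbal_tol
  angle_y <- atan2(r13, r33) * 180 / pi
  angle_z <- atan2(r21, r22) * 180 / pi
  if (any(gimbal)) {
    ## fold the coupled Y-Z rotation into Y, zero out Z
    up <- gimbal & sx > 0
    dn <- gimbal & sx <= 0
    angle_y[up] <- atan2(r12[up], r11[up]) * 180 / pi
    angle_y[dn] <- atan2(-r12[dn], r11[dn]) * 180 / pi
    angle_z[gimbal] <- 0
  }
  if (is.matrix(q)) {
    data.frame(angle_y = angle_y, angle_x = angle_x, angle_z = angle_z,
               gimbal = gimbal)
  } else {
    out <- c(angle_y = angle_y, angle_x = angle_x, angle_z = angle_z)
    attr(out, "gimbal") <- gimbal
    out
  }
}

#' Compose a quaternion from intrinsic YXZ angles
#'
#' Inverse of [euler_yxz()]: builds `q = q_y (x) q_x (x) q_z` from the three
#' elemental rotations.  Vectorized over angles.
#'
#' @param angle_y,angle_x,angle_z Angles in degrees.
#' @return Unit quaternion (vector for scalar input, matrix otherwise).
#' @export
euler_yxz_quat <- function(angle_y, angle_x, angle_z) {
  n <- max(length(angle_y), length(angle_x), length(angle_z))
  ay <- rep_len(angle_y, n) * pi / 360
  ax <- rep_len(angle_x, n) * pi / 360
  az <- rep_len(angle_z, n) * pi / 360
  cy <- cos(ay); sy <- sin(ay); cx <- cos(ax); sx <- sin(ax)
  cz <- cos(az); sz <- sin(az)
  ## qy (x) qx (x) qz expanded
  w <- cy * cx * cz + sy * sx * sz
  x <- cy * sx * cz + sy * cx * sz
  y <- sy * cx * cz - cy * sx * sz
  z <- cy * cx * sz - sy * sx * cz
  out <- quat_normalize(cbind(w = w, x = x, y = y, z = z))
  if (n == 1L && length(angle_y) == 1L && length(angle_x) == 1L &&
      length(angle_z) == 1L) {
    stats::setNames(drop(out), c("w", "x", "y", "z"))
  } else out
}

#' Sign-align consecutive frames of a quaternion stream
#'
#' Antipodal continuity: flips the sign of frames so that consecutive
#' quaternions have a non-negative dot product, a prerequisite for filtering
#' quaternion components as ordinary signals.
#'
#' @param qmat n x 4 quaternion frame matrix.
#' @return Sign-aligned matrix.
#' @export
sign_align <- function(qmat) {
  m <- as_quat_matrix(qmat)
  if (nrow(m) < 2L) return(m)
  d <- rowSums(m[-1L, , drop = FALSE] * m[-nrow(m), , drop = FALSE])
  ## cumulative flip state: frame i is negated when an odd number of sign
  ## reversals occurred up to i
  flips <- cumsum(d < 0) %% 2L == 1L
  m[c(FALSE, flips), ] <- -m[c(FALSE, flips), ]
  m
}

#' Frame-to-frame angular speed of an orientation stream
#'
#' Geodesic angle between consecutive unit quaternions times the sample rate,
#' in degrees per second.  The first sample duplicates the second so the
#' output has the same length as the stream.
#'
#' @param qmat n x 4 quaternion frame matrix (n >= 2).
#' @param sample_rate Sampling frequency in Hz.
#' @return Numeric vector of length n, degrees/second.
#' @export
angular_speed <- function(qmat, sample_rate) {
  m <- quat_normalize(as_quat_matrix(qmat))
  if (nrow(m) < 2L) stop("angular speed needs at least 2 frames")
  d <- abs(rowSums(m[-1L, , drop = FALSE] * m[-nrow(m), , drop = FALSE]))
  ang <- 2 * acos(pmin(1, d)) * 180 / pi
  c(ang[1L], ang) * sample_rate
}
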