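# Minimal 3-D rotation algebra: rotation matrices, unit quaternions, and the
# matrix log map. Conventions: a quaternion q = (w, x, y, z) maps body-frame
# vectors into the global frame, v_g = R(q) v_b.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the x, y, or z axis.
#'
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Compose intrinsic x-y-z rotations
#'
#' Composes three rotations about the body x, then (new) y, then (new) z axes.
#' Used for sensor mounting perturbations.
#'
#' @param angles_deg Numeric triplet (x, y, z) in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_xyz_intrinsic <- function(angles_deg) {
  rot_x(angles_deg[1]) %*% rot_y(angles_deg[2]) %*% rot_z(angles_deg[3])
}

#' Quaternion to rotation matrix
#'
#' @param q Numeric length-4 vector (w, x, y, z); need not be exactly unit norm
#'   (it is normalized internally).
#' @return A 3x3 rotation matrix mapping body-frame to global-frame vectors.
#' @keywords internal
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rotation matrix to rotation vector (log map)
#'
#' Returns the axis-angle vector (axis times angle, radians). Robust to small
#' angles via a first-order expansion.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric length-3 rotation vector in radians.
#' @keywords internal
rotmat_to_rotvec <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  cos_theta <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cos_theta)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (theta < 1e-7) {
    # sin(theta)/theta -> 1; v = 2 sin(theta) * axis
    return(v / 2)
  }
  if (theta > pi - 1e-6) {
    # near pi the off-diagonal difference degenerates; recover axis from the
    # symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs from the largest component
    i <- which.max(axis)
    s <- sign(c(B[1, i], B[2, i], B[3, i]))
    s[s == 0] <- 1
    axis <- axis * s * sign(axis[i])
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  v / (2 * sin(theta)) * theta
}

#' Check that a matrix is a proper rotation
#'
#' @param R Matrix to test.
#' @param tol Orthonormality tolerance.
#' @return TRUE or FALSE.
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}
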