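#' Rigid-body transforms
#'
#' Rigid transforms are represented throughout as plain 4x4 homogeneous
#' matrices: a 3x3 rotation block, a 3x1 translation (mm) and last row
#' `(0, 0, 0, 1)`.  [rigid_transform()] builds and validates one;
#' [is_rigid_transform()] checks the invariants (orthonormal rotation with
#' determinant +1, tolerance 1e-9 by default).
#'
#' The Euler-angle parameterization used everywhere in the package is
#' intrinsic x-y-z: `R = Rx(a) %*% Ry(b) %*% Rz(c)`, angles in degrees.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return `rigid_transform()`: a 4x4 matrix.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  if (!is_rigid_transform(m, tol = 1e-6)) {
    stop("rotation block is not a proper rotation (R'R = I, det = +1)")
  }
  m
}

#' @param m a 4x4 matrix.
#' @param tol numerical tolerance on orthonormality and the determinant.
#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || any(dim(m) != c(4, 4)) || any(!is.finite(m))) return(FALSE)
  r <- m[1:3, 1:3]
  ok_orth <- max(abs(crossprod(r) - diag(3))) <= tol
  ok_det <- abs(det(r) - 1) <= tol
  ok_row <- max(abs(m[4, ] - c(0, 0, 0, 1))) <= tol
  ok_orth && ok_det && ok_row
}

#' Re-orthonormalize the rotation block of a near-rigid transform
#'
#' Projects the 3x3 block onto the closest proper rotation (polar
#' decomposition via SVD) and zeroes the last row drift.  Used as a guard on
#' optimizer output.
#'
#' @param m 4x4 near-rigid matrix.
#' @return a valid 4x4 rigid transform.
#' @export
orthonormalize_transform <- function(m) {
  s <- svd(m[1:3, 1:3])
  d <- diag(c(1, 1, det(s$u %*% t(s$v))))
  r <- s$u %*% d %*% t(s$v)
  rigid_transform(r, m[1:3, 4])
}

# elementary rotations, angle in degrees
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Intrinsic x-y-z Euler angles
#'
#' `euler_to_rotmat()` composes `Rx(a) Ry(b) Rz(c)` (degrees);
#' `rotmat_to_euler()` inverts it.  For the sub-degree error magnitudes this
#' package reports, all common conventions agree to first order; the intrinsic
#' x-y-z choice is fixed and documented here.
#'
#' @param angles length-3 vector of degrees about x, y, z.
#' @return a 3x3 rotation matrix, or a length-3 vector of degrees.
#' @export
euler_to_rotmat <- function(angles) {
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  rot_x(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
}

#' @param r 3x3 rotation matrix.
#' @rdname euler_to_rotmat
#' @export
rotmat_to_euler <- function(r) {
  # R = Rx Ry Rz  =>  R[1,3] = sin(b); gimbal lock at |b| = 90 deg
  b <- asin(max(-1, min(1, r[1, 3])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(-r[2, 3], r[3, 3])
    c <- atan2(-r[1, 2], r[1, 1])
  } else {
    a <- atan2(r[2, 1], r[2, 2])
    c <- 0
  }
  c(a, b, c) * 180 / pi
}

#' Convert a 6-vector of pose parameters to a rigid transform
#'
#' The six degrees of freedom are three intrinsic x-y-z Euler angles
#' (degrees) followed by three translations (mm).  The rotation is applied
#' about `center` (typically the bone region's centroid, which decouples the
#' rotational and translational parameters), then the translation is added:
#' `p -> R (p - center) + center + t`.
#'
#' @param params numeric length 6: `(rx, ry, rz, tx, ty, tz)`.
#' @param center length-3 rotation center (mm); default the origin.
#' @return 4x4 rigid transform.
#' @export
pose_to_transform <- function(params, center = c(0, 0, 0)) {
  stopifnot(length(params) == 6, all(is.finite(params)))
  r <- euler_to_rotmat(params[1:3])
  t <- params[4:6] + center - r %*% center
  rigid_transform(r, t)
}

#' @param transform 4x4 rigid transform.
#' @rdname pose_to_transform
#' @export
transform_to_pose <- function(transform, center = c(0, 0, 0)) {
  stopifnot(is_rigid_transform(transform, tol = 1e-6))
  r <- transform[1:3, 1:3]
  ang <- rotmat_to_euler(r)
  t <- transform[1:3, 4] - center + r %*% center
  c(ang, t)
}

#' Apply a rigid transform to 3D points
#'
#' @param transform 4x4 rigid transform.
#' @param points length-3 vector or n x 3 matrix (mm).
#' @return same shape as `points`.
#' @export
transform_points <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  out <- p %*% t(transform[1:3, 1:3]) + rep(transform[1:3, 4], each = nrow(p))
  if (vec) drop(out) else out
}

#' @rdname rigid_transform
#' @export
transform_invert <- function(m) {
  r <- t(m[1:3, 1:3])
  rigid_transform(r, -r %*% m[1:3, 4])
}
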