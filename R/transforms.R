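# Rigid 3-D transforms as 4x4 homogeneous matrices. Angles are degrees
# throughout the package; positive rotations follow the right-hand rule.

deg2rad <- function(x) x * pi / 180

#' Elementary rotation matrices (degrees)
#'
#' 3x3 right-handed rotation matrices about the coordinate axes. In joint
#' coordinates the x-axis is the series long-axis (roll), y dorso-ventral
#' (yaw) and z latero-lateral (pitch).
#'
#' @param deg rotation angle in degrees
#' @return 3x3 rotation matrix
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Build a rigid transform
#'
#' @param R 3x3 rotation matrix
#' @param t length-3 translation
#' @return 4x4 homogeneous rigid transform
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' Joint rotation composed intrinsically as roll, then yaw, then pitch
#'
#' The package-wide rotation order: roll about the joint x-axis first, then
#' yaw about the rotated y-axis, then pitch about the rotated z-axis, i.e.
#' `R = Rx(roll) %*% Ry(yaw) %*% Rz(pitch)` in the joint frame. At
#' yaw = +/-90 deg the roll and pitch axes align (the degeneracy the cosine
#' correction compensates for).
#'
#' @param roll,yaw,pitch angles in degrees
#' @return 3x3 rotation matrix in joint-frame coordinates
#' @export
joint_rotation <- function(roll, yaw, pitch) {
  rot_x(roll) %*% rot_y(yaw) %*% rot_z(pitch)
}

#' Apply a 4x4 rigid transform to points
#'
#' @param T 4x4 transform
#' @param P n x 3 matrix of points
#' @return transformed n x 3 matrix
#' @export
transform_points <- function(T, P) {
  P <- as_points(P)
  sweep(P %*% t(T[1:3, 1:3]), 2, T[1:3, 4], `+`)
}

as_points <- function(P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3, byrow = TRUE)
  storage.mode(P) <- "double"
  P
}

# rotation about an arbitrary fixed point, given a 3x3 rotation
rotation_about <- function(R, center) {
  rigid_transform(R, as.numeric(center) - as.numeric(R %*% center))
}

# pose transform for one joint: rotation about the joint COR, axes given as
# columns (x, y, z) of `axes`
joint_pose_transform <- function(cor, axes, roll, yaw, pitch) {
  R <- axes %*% joint_rotation(roll, yaw, pitch) %*% t(axes)
  rotation_about(R, cor)
}

# numerically re-orthonormalise a rotation (Gram-Schmidt via SVD)
orthonormalize <- function(R) {
  s <- svd(R)
  R2 <- s$u %*% t(s$v)
  if (det(R2) < 0) {
    s$u[, 3] <- -s$u[, 3]
    R2 <- s$u %*% t(s$v)
  }
  R2
}
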