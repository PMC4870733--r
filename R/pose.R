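# Rigid-body pose algebra and the joint coordinate system (JCS).
#
# A pose maps body-frame coordinates to world millimetres: p_world = R p + t.
# Displacements between two bodies are reported in an anatomical joint axis
# frame, differenced against the neutral configuration, with an intrinsic
# x-y-z Euler decomposition for the rotational part.

ORTHO_TOL <- 1e-9

#' Construct a rigid pose
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1).
#' @param translation length-3 numeric, world millimetres.
#' @return object of class `rigid_pose` with elements `rotation`, `translation`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L ||
      !all(is.finite(rotation)) || !all(is.finite(translation)))
    stop_mrikin("rigid_pose needs a finite 3x3 rotation and length-3 translation",
                "mrikin_pose_error")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6 || abs(det(rotation) - 1) > 1e-6)
    stop_mrikin(sprintf("rotation is not a proper orthonormal matrix (drift %.3g)", err),
                "mrikin_pose_error")
  if (err > 1e-12) rotation <- orthonormalize(rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("Rigid pose (mm):\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}

# Nearest rotation matrix (polar factor via SVD).
orthonormalize <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  Q
}

pose_identity <- function() rigid_pose()

is_rigid_pose <- function(x) inherits(x, "rigid_pose")

check_pose <- function(p, what = "pose") {
  if (!is_rigid_pose(p))
    stop_mrikin(paste(what, "is not a rigid_pose"), "mrikin_pose_error")
  err <- max(abs(crossprod(p$rotation) - diag(3)))
  if (err > 1e-6)
    stop_mrikin(sprintf("%s rotation not orthonormal (drift %.3g)", what, err),
                "mrikin_pose_error")
  invisible(p)
}

#' Elementary rotation matrices (degrees)
#' @param deg angle in degrees; positive follows the right-hand rule.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg); c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Compose two poses
#'
#' `compose_poses(a, b)` applies `b` first, then `a`:
#' x -> a.R (b.R x + b.t) + a.t.
#' @param a,b `rigid_pose` objects.
#' @return composed `rigid_pose`; the rotation is re-orthonormalized if
#'   numerical drift exceeds 1e-12.
#' @export
compose_poses <- function(a, b) {
  check_pose(a, "a"); check_pose(b, "b")
  R <- a$rotation %*% b$rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-12) R <- orthonormalize(R)
  rigid_pose(R, as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a pose
#' @param p a `rigid_pose`.
#' @export
pose_inverse <- function(p) {
  check_pose(p)
  Rt <- t(p$rotation)
  rigid_pose(Rt, as.numeric(-Rt %*% p$translation))
}

#' Apply a pose to points
#' @param p a `rigid_pose`.
#' @param pts numeric vector of length 3 or an n x 3 matrix of points.
#' @return transformed points, same shape as the input.
#' @export
pose_apply <- function(p, pts) {
  check_pose(p)
  if (is.null(dim(pts))) return(as.numeric(p$rotation %*% pts) + p$translation)
  sweep(pts %*% t(p$rotation), 2, p$translation, "+")
}

#' Rotation about an arbitrary axis through a point
#'
#' Convenience constructor for the trial geometry: rotation of `deg` degrees
#' about the line through `center` with direction `axis`.
#' @param axis length-3 direction (normalized internally).
#' @param deg angle in degrees.
#' @param center point on the rotation axis (mm).
#' @export
pose_rotation_about <- function(axis, deg, center = c(0, 0, 0)) {
  u <- unit3(axis)
  a <- deg2rad(deg); c_ <- cos(a); s <- sin(a)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + s * K + (1 - c_) * (K %*% K)
  rigid_pose(orthonormalize(R), center - as.numeric(R %*% center))
}

#' Anatomical joint axes (AJX)
#'
#' A right-handed orthonormal frame in which relative displacements between
#' two bodies are expressed: by convention here x is the rotation-trial axis,
#' z the translation-trial axis and y the coil-bore axis.
#' @param origin frame origin in world mm.
#' @param x_axis,y_axis,z_axis unit axis directions (world frame).
#' @return object of class `joint_axes`.
#' @export
joint_axes <- function(origin = c(0, 0, 0),
                       x_axis = c(1, 0, 0),
                       y_axis = c(0, 1, 0),
                       z_axis = c(0, 0, 1)) {
  origin <- as.numeric(origin)
  R <- cbind(unit3(x_axis), unit3(y_axis), unit3(z_axis))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop_mrikin("joint axes must be mutually orthogonal unit vectors",
                "mrikin_axes_error")
  if (sum(cross3(R[, 1], R[, 2]) * R[, 3]) < 0)
    stop_mrikin("joint axes must be right-handed", "mrikin_axes_error")
  structure(list(origin = origin, rotation = orthonormalize(R)),
            class = "joint_axes")
}

axes_as_pose <- function(axes) rigid_pose(axes$rotation, axes$origin)

#' Intrinsic x-y-z Euler angles of a rotation matrix
#'
#' Decomposes R = Rx(a) Ry(b) Rz(c); angles returned in degrees. The middle
#' (y) angle is the arcsine branch in \[-90, 90\] degrees; configurations with
#' |b| close to 90 degrees are gimbal-degenerate and flagged.
#' @param R 3x3 rotation matrix.
#' @return list with `angles` (named length-3, degrees) and logical `gimbal`.
#' @export
euler_xyz <- function(R) {
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  gimbal <- abs(sb) > sin(deg2rad(85))
  if (!gimbal) {
    a <- atan2(-R[2, 3], R[3, 3])
    c_ <- atan2(-R[1, 2], R[1, 1])
  } else {
    # x and z rotations are not separable; push everything into x.
    a <- atan2(R[3, 2], R[2, 2])
    c_ <- 0
  }
  list(angles = c(x = rad2deg(a), y = rad2deg(b), z = rad2deg(c_)),
       gimbal = gimbal)
}

euler_to_rotation <- function(deg_xyz) {
  rot_x(deg_xyz[1]) %*% rot_y(deg_xyz[2]) %*% rot_z(deg_xyz[3])
}

#' Joint-coordinate-system displacement between two bodies
#'
#' The relative pose of body B with respect to body A is expressed in the
#' joint axes and differenced against the neutral configuration: axes copies
#' are rigidly attached to each body at neutral, and the transform between the
#' two copies at the current configuration is the joint displacement (identity
#' at neutral by construction).
#'
#' @param neutral_a,neutral_b neutral poses of bodies A and B.
#' @param current_a,current_b current poses.
#' @param axes `joint_axes` defined in world coordinates at neutral.
#' @param frame_index integer stored in the record.
#' @return a `displacement_record`: list with `frame_index`,
#'   `translation_x/y/z` (mm), `rotation_about_x/y/z` (deg), `full_6dof`
#'   (named length-6), and `gimbal` flag.
#' @export
jcs_displacement <- function(neutral_a, neutral_b, current_a, current_b,
                             axes, frame_index = NA_integer_) {
  for (p in list(neutral_a, neutral_b, current_a, current_b)) check_pose(p)
  E <- axes_as_pose(axes)
  ea <- compose_poses(pose_inverse(neutral_a), E)  # axes in A's body frame
  eb <- compose_poses(pose_inverse(neutral_b), E)  # axes in B's body frame
  J <- compose_poses(pose_inverse(compose_poses(current_a, ea)),
                     compose_poses(current_b, eb))
  eu <- euler_xyz(J$rotation)
  tr <- J$translation
  full <- c(tx = tr[1], ty = tr[2], tz = tr[3],
            rx = eu$angles[["x"]], ry = eu$angles[["y"]], rz = eu$angles[["z"]])
  structure(list(frame_index = frame_index,
                 translation_x = tr[1], translation_y = tr[2],
                 translation_z = tr[3],
                 rotation_about_x = full[["rx"]],
                 rotation_about_y = full[["ry"]],
                 rotation_about_z = full[["rz"]],
                 full_6dof = full, gimbal = eu$gimbal),
            class = "displacement_record")
}

#' Rebuild the relative pose encoded by a displacement record
#'
#' Inverse of the extraction in [jcs_displacement()]: returns the current pose
#' of body B implied by a record, given the neutral poses and axes (used for
#' round-trip verification).
#' @inheritParams jcs_displacement
#' @param record a `displacement_record`.
#' @export
jcs_reconstruct_b <- function(record, neutral_a, neutral_b, current_a, axes) {
  E <- axes_as_pose(axes)
  ea <- compose_poses(pose_inverse(neutral_a), E)
  eb <- compose_poses(pose_inverse(neutral_b), E)
  J <- rigid_pose(euler_to_rotation(record$full_6dof[c("rx", "ry", "rz")]),
                  record$full_6dof[c("tx", "ty", "tz")])
  # current_b = current_a ea J eb^-1
  compose_poses(compose_poses(compose_poses(current_a, ea), J),
                pose_inverse(eb))
}

#' @export
print.displacement_record <- function(x, ...) {
  cat(sprintf("frame %s: tz = %.4f mm, tx = %.4f mm, rx = %.4f deg%s\n",
              x$frame_index, x$translation_z, x$translation_x,
              x$rotation_about_x,
              if (isTRUE(x$gimbal)) " [gimbal-degenerate]" else ""))
  invisible(x)
}

#' @export
as.data.frame.displacement_record <- function(x, ...) {
  data.frame(frame_index = x$frame_index,
             translation_x = x$translation_x,
             translation_y = x$translation_y,
             translation_z = x$translation_z,
             rotation_about_x = x$rotation_about_x,
             rotation_about_y = x$rotation_about_y,
             rotation_about_z = x$rotation_about_z,
             gimbal = x$gimbal)
}

# --- serialization -----------------------------------------------------------

#' Serialize poses and joint axes to/from JSON
#'
#' Rotations are stored as 9 row-major floats, translations in mm.
#' @param p a `rigid_pose`.
#' @export
pose_to_list <- function(p) {
  check_pose(p)
  list(rotation = as.numeric(t(p$rotation)), translation = p$translation)
}

#' @rdname pose_to_list
#' @param x list with `rotation` (9 row-major floats) and `translation`.
#' @export
pose_from_list <- function(x) {
  rigid_pose(matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE),
             as.numeric(x$translation))
}

#' @rdname pose_to_list
#' @param axes a `joint_axes`.
#' @param path file path for JSON output.
#' @export
axes_save <- function(axes, path) {
  jsonlite::write_json(list(origin = axes$origin,
                            rotation = as.numeric(t(axes$rotation))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pose_to_list
#' @export
axes_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- matrix(as.numeric(x$rotation), 3, 3, byrow = TRUE)
  joint_axes(as.numeric(x$origin), R[, 1], R[, 2], R[, 3])
}
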