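#' Rigid 6-DoF pose track
#'
#' Per-frame pose of one surgical tool: 3D position plus rotation as a unit
#' quaternion, with a detection mask. Quaternions are scalar-first
#' `(qw, qx, qy, qz)`, right-handed.
#'
#' @param positions T x 3 numeric matrix.
#' @param rotations T x 4 numeric matrix of unit quaternions.
#' @param detected Logical vector of length T.
#' @param tool_id Identifier tag.
#' @param imputed Logical vector marking frames filled by imputation
#'   (default all `FALSE`).
#' @return An object of class `rigid_pose_track`.
#' @export
rigid_pose_track <- function(positions, rotations, detected, tool_id = "tool",
                             imputed = rep(FALSE, length(detected))) {
  positions <- as.matrix(positions)
  rotations <- as.matrix(rotations)
  detected <- as.logical(detected)
  t_len <- length(detected)
  if (nrow(positions) != t_len || nrow(rotations) != t_len || length(imputed) != t_len) {
    stop("positions, rotations, detected and imputed must share length T")
  }
  if (ncol(positions) != 3L) stop("positions must be T x 3")
  if (ncol(rotations) != 4L) stop("rotations must be T x 4 quaternions")
  nrm <- sqrt(rowSums(rotations^2))
  if (any(detected & abs(nrm - 1) > 1e-9)) {
    stop("rotations at detected frames must be unit quaternions")
  }
  structure(list(positions = positions, rotations = rotations,
                 detected = detected, imputed = as.logical(imputed),
                 tool_id = tool_id),
            class = "rigid_pose_track")
}

#' @export
length.rigid_pose_track <- function(x) length(x$detected)

#' @export
print.rigid_pose_track <- function(x, ...) {
  cat("<rigid_pose_track> '", x$tool_id, "': ", length(x$detected), " frames, ",
      sum(x$detected), " detected\n", sep = "")
  invisible(x)
}

#' Two-hand 21-joint track
#'
#' @param joints T x 2 x 21 x 3 array (hand order L, R).
#' @param detected T x 2 logical matrix.
#' @param imputed T x 2 logical matrix marking interpolated frames.
#' @return An object of class `hand_joint_track`.
#' @export
hand_joint_track <- function(joints, detected,
                             imputed = matrix(FALSE, nrow(detected), 2)) {
  if (length(dim(joints)) != 4L || !all(dim(joints)[2:4] == c(2L, 21L, 3L))) {
    stop("joints must be a T x 2 x 21 x 3 array")
  }
  detected <- as.matrix(detected)
  if (nrow(detected) != dim(joints)[1] || ncol(detected) != 2L) {
    stop("detected must be T x 2")
  }
  structure(list(joints = joints, detected = detected, imputed = as.matrix(imputed)),
            class = "hand_joint_track")
}

#' @export
length.hand_joint_track <- function(x) nrow(x$detected)

#' @export
print.hand_joint_track <- function(x, ...) {
  cat("<hand_joint_track> ", nrow(x$detected), " frames; detected L/R: ",
      sum(x$detected[, 1]), "/", sum(x$detected[, 2]), "\n", sep = "")
  invisible(x)
}

# ---- quaternion helpers (scalar-first, Hamilton product) ----

#' Quaternion utilities
#'
#' Scalar-first `(w, x, y, z)` unit quaternions. `quat_multiply` is the
#' Hamilton product; `quat_geodesic` returns the rotation angle (radians, in
#' `[0, pi]`) between two orientations; `quat_rotate` rotates row vectors.
#'
#' @param q,q1,q2 Length-4 quaternions (or n x 4 matrices where documented).
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_normalize <- function(q) q / sqrt(sum(q^2))

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  c(q1[1] * q2[1] - q1[2] * q2[2] - q1[3] * q2[3] - q1[4] * q2[4],
    q1[1] * q2[2] + q1[2] * q2[1] + q1[3] * q2[4] - q1[4] * q2[3],
    q1[1] * q2[3] - q1[2] * q2[4] + q1[3] * q2[1] + q1[4] * q2[2],
    q1[1] * q2[4] + q1[2] * q2[3] - q1[3] * q2[2] + q1[4] * q2[1])
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) c(q[1], -q[2:4])

#' @rdname quaternions
#' @export
quat_geodesic <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

#' @rdname quaternions
#' @param axis Unit 3-vector rotation axis.
#' @param angle Rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' @rdname quaternions
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' @rdname quaternions
#' @param v n x 3 matrix of row vectors to rotate.
#' @export
quat_rotate <- function(q, v) {
  v <- rbind(v)
  v %*% t(quat_to_matrix(q))
}

#' Tool symmetry group
#'
#' Default ambiguity group of the tool pose estimator: the identity and a
#' 180-degree rotation about the tool's own y-axis. A 180-degree flip about
#' both the x- and z-axes composes to the same global rotation, so the
#' smallest group consistent with the observed flips has order two; a larger
#' group can be supplied wherever a `symmetry` argument is accepted.
#'
#' @return 2 x 4 matrix of quaternions (rows).
#' @export
tool_symmetry_group <- function() {
  rbind(c(1, 0, 0, 0),
        quat_from_axis_angle(c(0, 1, 0), pi))
}
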