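#' Pose preprocessing configuration
#'
#' Bundles the tunable parameters of the pose-cleaning pipeline.
#'
#' @param max_gap_frames Largest missing-frame gap filled by imputation /
#'   interpolation (default 10 frames, i.e. 1/3 s at 30 FPS).
#' @param savgol_window Odd Savitzky-Golay window length in frames (default 9).
#' @param savgol_order Polynomial order of the filter (default 2).
#' @param tool_noise_sigma Std. dev. of augmentation noise, in track units for
#'   positions and radians for rotations (default 0.01).
#' @param hand_rotation_axis Axis for the hand rotation augmentation
#'   (default the vertical axis).
#' @param flip_probability Probability of each whole-video flip augmentation
#'   (default 0.5).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_gap_frames = 10L,
                              savgol_window = 9L,
                              savgol_order = 2L,
                              tool_noise_sigma = 0.01,
                              hand_rotation_axis = c(0, 1, 0),
                              flip_probability = 0.5) {
  savgol_window <- as.integer(savgol_window)
  savgol_order <- as.integer(savgol_order)
  if (savgol_window %% 2L == 0L || savgol_window <= savgol_order) {
    stop("savgol_window must be odd and greater than savgol_order")
  }
  if (max_gap_frames < 0L) stop("max_gap_frames must be >= 0")
  if (flip_probability < 0 || flip_probability > 1) {
    stop("flip_probability must lie in [0, 1]")
  }
  structure(list(max_gap_frames = as.integer(max_gap_frames),
                 savgol_window = savgol_window, savgol_order = savgol_order,
                 tool_noise_sigma = tool_noise_sigma,
                 hand_rotation_axis = hand_rotation_axis / sqrt(sum(hand_rotation_axis^2)),
                 flip_probability = flip_probability),
            class = "preprocess_config")
}

# maximal runs of a logical vector: 1-based inclusive [start, end]
logical_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' Resolve symmetry-flip ambiguities in a tool rotation track
#'
#' Pose estimators for (near-)symmetric tools may return, at any frame, the
#' true rotation composed with an element of the tool's symmetry group,
#' producing 180-degree jumps between consecutive frames. Walking the detected
#' frames in order, each rotation is replaced by `R_t * S` for the symmetry
#' element `S` minimizing the geodesic angle to the previously corrected
#' detected frame; the first detected frame is left unchanged.
#'
#' @param track A [rigid_pose_track()].
#' @param symmetry n x 4 matrix of symmetry quaternions (rows); must contain
#'   the identity. Default [tool_symmetry_group()].
#' @return The corrected [rigid_pose_track()]; positions and masks unchanged.
#' @export
disambiguate_tool_rotations <- function(track, symmetry = tool_symmetry_group()) {
  stopifnot(inherits(track, "rigid_pose_track"))
  symmetry <- rbind(symmetry)
  if (nrow(symmetry) == 0L) stop("symmetry set must be non-empty")
  if (!any(apply(symmetry, 1L, function(s) abs(abs(sum(s * c(1, 0, 0, 0))) - 1) < 1e-9))) {
    stop("symmetry set must contain the identity")
  }
  idx <- which(track$detected)
  if (length(idx) <= 1L) return(track)
  rot <- track$rotations
  prev <- rot[idx[1L], ]
  for (t in idx[-1L]) {
    q <- rot[t, ]
    best <- NULL
    best_ang <- Inf
    for (s in seq_len(nrow(symmetry))) {
      cand <- quat_multiply(q, symmetry[s, ])
      ang <- quat_geodesic(prev, cand)
      if (ang < best_ang - 1e-12) {
        best_ang <- ang
        best <- cand
      }
    }
    rot[t, ] <- quat_normalize(best)
    prev <- rot[t, ]
  }
  track$rotations <- rot
  track
}

#' Gap-limited last-observation-carried-forward imputation
#'
#' Fills each maximal run of undetected frames of length at most
#' `max_gap_frames` that immediately follows a detected frame with that
#' frame's pose, marking the filled frames as imputed. Longer gaps and frames
#' before the first detection are left missing; detected frames are untouched.
#'
#' @param track A [rigid_pose_track()].
#' @param max_gap_frames Largest gap length filled (default 10).
#' @return The imputed [rigid_pose_track()].
#' @export
impute_locf <- function(track, max_gap_frames = 10L) {
  stopifnot(inherits(track, "rigid_pose_track"), max_gap_frames >= 0L)
  if (!any(track$detected) || max_gap_frames == 0L) return(track)
  runs <- logical_runs(track$detected)
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] || i == 1L) next  # detected run, or leading gap
    len <- runs$end[i] - runs$start[i] + 1L
    if (len > max_gap_frames) next
    src <- runs$start[i] - 1L  # last detected frame before the gap
    span <- runs$start[i]:runs$end[i]
    track$positions[span, ] <- matrix(track$positions[src, ], len, 3, byrow = TRUE)
    track$rotations[span, ] <- matrix(track$rotations[src, ], len, 4, byrow = TRUE)
    track$imputed[span] <- TRUE
  }
  track
}

#' Gap-limited linear interpolation for hand joints
#'
#' Per hand, per joint, per coordinate: linearly interpolates across interior
#' gaps of length at most `max_gap_frames` (a detected frame is required on
#' both sides); boundary gaps are left missing.
#'
#' @param track A [hand_joint_track()].
#' @param max_gap_frames Largest gap length filled (default 10).
#' @return The interpolated [hand_joint_track()].
#' @export
interpolate_gaps_linear <- function(track, max_gap_frames = 10L) {
  stopifnot(inherits(track, "hand_joint_track"), max_gap_frames >= 0L)
  if (max_gap_frames == 0L) return(track)
  for (h in 1:2) {
    det <- track$detected[, h]
    if (sum(det) < 2L) next
    runs <- logical_runs(det)
    for (i in seq_len(nrow(runs))) {
      if (runs$value[i] || i == 1L || i == nrow(runs)) next
      len <- runs$end[i] - runs$start[i] + 1L
      if (len > max_gap_frames) next
      lo <- runs$start[i] - 1L
      hi <- runs$end[i] + 1L
      w <- (runs$start[i]:runs$end[i] - lo) / (hi - lo)
      a <- track$joints[lo, h, , ]
      b <- track$joints[hi, h, , ]
      for (k in seq_along(w)) {
        track$joints[lo + k, h, , ] <- (1 - w[k]) * a + w[k] * b
      }
      track$imputed[runs$start[i]:runs$end[i], h] <- TRUE
    }
  }
  track
}

sg_filter_span <- function(mat, window, order) {
  # columns filtered independently; exact for polynomials of degree <= order
  apply(mat, 2L, function(col) signal::sgolayfilt(col, p = order, n = window))
}

#' Savitzky-Golay smoothing of pose tracks
#'
#' Applies a Savitzky-Golay filter per coordinate within each contiguous
#' observed span (detected or imputed frames); spans shorter than the filter
#' window pass through unchanged, and missing frames never enter the filter.
#' For rotations, quaternion sign continuity is enforced first (a quaternion
#' is negated when its dot product with the previous one is negative), the
#' four components are filtered, and the result is renormalized to unit
#' length. The filter reproduces polynomials up to `savgol_order` exactly.
#'
#' @param track A [rigid_pose_track()] or [hand_joint_track()].
#' @param cfg A [preprocess_config()].
#' @return Track of the same class, smoothed.
#' @export
smooth_savitzky_golay <- function(track, cfg = preprocess_config()) {
  UseMethod("smooth_savitzky_golay")
}

#' @export
smooth_savitzky_golay.rigid_pose_track <- function(track, cfg = preprocess_config()) {
  obs <- track$detected | track$imputed
  runs <- logical_runs(obs)
  for (i in which(runs$value)) {
    span <- runs$start[i]:runs$end[i]
    if (length(span) < cfg$savgol_window) next
    track$positions[span, ] <- sg_filter_span(track$positions[span, , drop = FALSE],
                                              cfg$savgol_window, cfg$savgol_order)
    q <- track$rotations[span, , drop = FALSE]
    for (t in seq_len(nrow(q))[-1L]) {
      if (sum(q[t, ] * q[t - 1L, ]) < 0) q[t, ] <- -q[t, ]
    }
    q <- sg_filter_span(q, cfg$savgol_window, cfg$savgol_order)
    track$rotations[span, ] <- q / sqrt(rowSums(q^2))
  }
  track
}

#' @export
smooth_savitzky_golay.hand_joint_track <- function(track, cfg = preprocess_config()) {
  for (h in 1:2) {
    obs <- track$detected[, h] | track$imputed[, h]
    runs <- logical_runs(obs)
    for (i in which(runs$value)) {
      span <- runs$start[i]:runs$end[i]
      if (length(span) < cfg$savgol_window) next
      flat <- matrix(track$joints[span, h, , ], nrow = length(span))
      flat <- sg_filter_span(flat, cfg$savgol_window, cfg$savgol_order)
      track$joints[span, h, , ] <- array(flat, dim = c(length(span), 21, 3))
    }
  }
  track
}

#' Training-time tool pose augmentation
#'
#' With probability `flip_probability` each, applies (1) a 180-degree rotation
#' about the y-axis and (2) a 180-degree rotation about both the x- and
#' z-axes to the whole video (positions rotated, rotations composed on the
#' left, consistently for all frames); then adds i.i.d. Gaussian noise of
#' standard deviation `tool_noise_sigma` to every position coordinate and
#' perturbs each rotation about a random axis by an angle of the same
#' magnitude in radians. Deterministic given `seed`.
#'
#' @param track A [rigid_pose_track()].
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed.
#' @return Augmented [rigid_pose_track()].
#' @export
augment_tool_pose <- function(track, cfg = preprocess_config(), seed = 1L) {
  stopifnot(inherits(track, "rigid_pose_track"))
  withr::with_seed(seed, {
    t_len <- length(track$detected)
    flips <- stats::runif(2) < cfg$flip_probability
    qy <- quat_from_axis_angle(c(0, 1, 0), pi)
    qxz <- quat_multiply(quat_from_axis_angle(c(1, 0, 0), pi),
                         quat_from_axis_angle(c(0, 0, 1), pi))
    for (k in 1:2) {
      if (!flips[k]) next
      qf <- if (k == 1L) qy else qxz
      track$positions <- quat_rotate(qf, track$positions)
      track$rotations <- t(apply(track$rotations, 1L, function(q) quat_multiply(qf, q)))
    }
    if (cfg$tool_noise_sigma > 0) {
      track$positions <- track$positions +
        matrix(stats::rnorm(t_len * 3, sd = cfg$tool_noise_sigma), t_len, 3)
      ang <- stats::rnorm(t_len, sd = cfg$tool_noise_sigma)
      ax <- matrix(stats::rnorm(t_len * 3), t_len, 3)
      ax <- ax / sqrt(rowSums(ax^2))
      for (t in seq_len(t_len)) {
        dq <- quat_from_axis_angle(ax[t, ], ang[t])
        track$rotations[t, ] <- quat_normalize(quat_multiply(dq, track$rotations[t, ]))
      }
    }
  })
  track
}

#' Training-time hand pose augmentation
#'
#' Draws one rotation angle uniformly in `[0, 2*pi)` about
#' `cfg$hand_rotation_axis` and applies it to all joints of all frames.
#' Deterministic given `seed`.
#'
#' @inheritParams augment_tool_pose
#' @param track A [hand_joint_track()].
#' @return Augmented [hand_joint_track()].
#' @export
augment_hand_pose <- function(track, cfg = preprocess_config(), seed = 1L) {
  stopifnot(inherits(track, "hand_joint_track"))
  withr::with_seed(seed, {
    ang <- stats::runif(1, 0, 2 * pi)
    q <- quat_from_axis_angle(cfg$hand_rotation_axis, ang)
    n <- dim(track$joints)[1]
    for (h in 1:2) {
      flat <- matrix(track$joints[, h, , ], nrow = n * 21, ncol = 3)
      track$joints[, h, , ] <- array(quat_rotate(q, flat), dim = c(n, 21, 3))
    }
  })
  track
}

#' Flatten pose tracks into a per-frame feature sequence
#'
#' Tools modality: per frame, per tool (sorted by tool id), 3 position
#' coordinates + 4 quaternion components + 1 validity flag; frames that are
#' neither detected nor imputed are zero-filled with flag 0. Hands modality:
#' the 2 x 21 x 3 = 126 joint coordinates followed by 2 per-hand validity
#' flags (D = 128).
#'
#' @param tools Named list of [rigid_pose_track()] (for `modality = "tools"`).
#' @param hands A [hand_joint_track()] (for `modality = "hands"`).
#' @param modality `"tools"` or `"hands"`.
#' @param include_validity Include validity flag columns (default `TRUE`).
#' @return A [feature_sequence()].
#' @export
tracks_to_features <- function(tools = NULL, hands = NULL,
                               modality = c("tools", "hands"),
                               include_validity = TRUE) {
  modality <- match.arg(modality)
  if (modality == "tools") {
    if (is.null(tools) || length(tools) == 0L) stop("tools tracks required")
    lens <- vapply(tools, length, 1L)
    if (length(unique(lens)) != 1L) stop("tool tracks must share length T")
    t_len <- lens[[1L]]
    blocks <- lapply(tools[order(names(tools))], function(tr) {
      valid <- tr$detected | tr$imputed
      pos <- tr$positions
      rot <- tr$rotations
      pos[!valid, ] <- 0
      rot[!valid, ] <- 0
      b <- cbind(pos, rot)
      if (include_validity) b <- cbind(b, as.numeric(valid))
      b
    })
    feature_sequence(do.call(cbind, blocks), modality = "tools")
  } else {
    if (is.null(hands)) stop("hand track required")
    t_len <- nrow(hands$detected)
    valid <- hands$detected | hands$imputed
    blocks <- lapply(1:2, function(h) {
      flat <- matrix(hands$joints[, h, , ], nrow = t_len)  # T x 63
      flat[!valid[, h], ] <- 0
      flat
    })
    m <- do.call(cbind, blocks)
    if (include_validity) m <- cbind(m, valid[, 1] * 1, valid[, 2] * 1)
    feature_sequence(m, modality = "hands")
  }
}
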