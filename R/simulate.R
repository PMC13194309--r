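#' Synthetic operating-room simulator configuration
#'
#' Defaults reproduce the printed structure of the study dataset: four
#' gesture classes with mean durations 138 / 41 / 66 / 259 frames
#' (entering / gripping / passing / other) at 30 FPS, an 'other' segment
#' after roughly 30% of suturing cycles (matching the 259 'other' per ~850
#' cycles ratio), five surgeons with individual style offsets, two tools
#' (needle driver and tweezers) with occasional symmetry flips and detection
#' dropouts, and per-modality independent noise controlled by a single
#' signal-to-noise ratio.
#'
#' @param n_surgeons Number of surgeons (>= 3; default 5).
#' @param videos_per_surgeon Videos per surgeon (default 3).
#' @param cycles_per_video Suturing cycles per video (default 9, roughly
#'   3,000 frames at the default durations).
#' @param mean_durations Named per-class mean segment durations in frames.
#' @param duration_dispersion Negative-binomial size parameter controlling
#'   duration spread (default 5).
#' @param p_other_per_cycle Probability of an 'other' segment after each
#'   cycle (default 0.3).
#' @param fps Frames per second (default 30).
#' @param tool_count Number of tools (fixed at 2).
#' @param detection_dropout_rate Expected fraction of frames with a missed
#'   detection (default 0.05).
#' @param mean_gap_length Mean detection-gap length in frames (default 4).
#' @param flip_rate Per-frame probability of a symmetry flip in the simulated
#'   tool rotations (default 0.05).
#' @param video_feature_dim Dimension of the synthetic video embeddings
#'   (default 64).
#' @param snr Signal-to-noise ratio scaling all modality noises (default 4).
#' @param surgeon_style_sigma Std. dev. of per-surgeon additive style offsets
#'   in trajectory and feature space (default 0.25).
#' @param seed Integer master seed.
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(n_surgeons = 5L, videos_per_surgeon = 3L,
                             cycles_per_video = 9L,
                             mean_durations = c(entering = 138, gripping = 41,
                                                passing = 66, other = 259),
                             duration_dispersion = 5,
                             p_other_per_cycle = 0.3, fps = 30,
                             tool_count = 2L,
                             detection_dropout_rate = 0.05,
                             mean_gap_length = 4,
                             flip_rate = 0.05,
                             video_feature_dim = 64L,
                             snr = 4, surgeon_style_sigma = 0.25, seed = 1L) {
  if (n_surgeons < 3L) stop("n_surgeons must be >= 3")
  if (any(mean_durations <= 0)) stop("mean durations must be positive")
  rates <- c(p_other_per_cycle, detection_dropout_rate, flip_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_surgeons = as.integer(n_surgeons),
                 videos_per_surgeon = as.integer(videos_per_surgeon),
                 cycles_per_video = as.integer(cycles_per_video),
                 mean_durations = mean_durations,
                 duration_dispersion = duration_dispersion,
                 p_other_per_cycle = p_other_per_cycle, fps = fps,
                 tool_count = as.integer(tool_count),
                 detection_dropout_rate = detection_dropout_rate,
                 mean_gap_length = mean_gap_length, flip_rate = flip_rate,
                 video_feature_dim = as.integer(video_feature_dim),
                 snr = snr, surgeon_style_sigma = surgeon_style_sigma,
                 seed = as.integer(seed)),
            class = "simulator_config")
}

draw_duration <- function(n, mean, size) {
  1L + stats::rnbinom(n, size = size, mu = mean - 1)
}

#' Simulate a gesture label sequence
#'
#' Repeats the suturing cycle entering -> gripping -> passing, inserting one
#' 'other' segment after each cycle with probability `p_other_per_cycle`.
#' Segment durations are negative-binomial with the configured per-class
#' means (minimum one frame). Uses the ambient RNG state; wrap in
#' [withr::with_seed()] or call `set.seed()` for reproducibility.
#'
#' @param cfg A [simulator_config()].
#' @param n_cycles Number of suturing cycles (>= 1).
#' @return A [label_sequence()].
#' @export
simulate_label_sequence <- function(cfg, n_cycles = cfg$cycles_per_video) {
  if (n_cycles < 1L) stop("at least one cycle required")
  md <- cfg$mean_durations
  sz <- cfg$duration_dispersion
  dur_e <- draw_duration(n_cycles, md[["entering"]], sz)
  dur_g <- draw_duration(n_cycles, md[["gripping"]], sz)
  dur_p <- draw_duration(n_cycles, md[["passing"]], sz)
  has_o <- stats::rbinom(n_cycles, 1L, cfg$p_other_per_cycle) == 1L
  dur_o <- draw_duration(n_cycles, md[["other"]], sz)
  ids <- integer(0)
  for (i in seq_len(n_cycles)) {
    ids <- c(ids, rep.int(1L, dur_e[i]), rep.int(2L, dur_g[i]),
             rep.int(3L, dur_p[i]),
             if (has_o[i]) rep.int(4L, dur_o[i]) else integer(0))
  }
  label_sequence(ids, gesture_vocabulary(), cfg$fps)
}

#' Draw a surgeon style
#'
#' Additive offsets a surgeon imposes on trajectories and features; held
#' fixed across that surgeon's videos so leave-one-user-out folds face a
#' genuine distribution shift.
#'
#' @param cfg A [simulator_config()].
#' @return List of style offsets.
#' @export
surgeon_style <- function(cfg) {
  list(tool_offset = stats::rnorm(3, sd = cfg$surgeon_style_sigma),
       hand_offset = stats::rnorm(3, sd = cfg$surgeon_style_sigma),
       video_offset = stats::rnorm(cfg$video_feature_dim,
                                   sd = cfg$surgeon_style_sigma),
       articulation = stats::rnorm(1, sd = 0.1))
}

tool_ids <- function() c("needle_driver", "tweezers")

# class-specific position bases (tool x class x xyz) and motion amplitudes
tool_base_positions <- function() {
  b <- array(0, dim = c(2, 4, 3))
  b[1, , ] <- rbind(c(0.0, 0.0, 0.5), c(0.6, 0.2, 0.3),
                    c(1.1, 0.1, 0.1), c(0.3, 0.9, 0.8))
  b[2, , ] <- rbind(c(0.4, 0.5, 0.0), c(-0.3, 0.3, 0.6),
                    c(0.8, -0.4, 0.4), c(-0.2, 1.0, 0.9))
  b
}

# smooth class-conditioned template path for one tool (no noise)
tool_template_positions <- function(ids, tool, style) {
  t_len <- length(ids)
  base <- tool_base_positions()[tool, , , drop = TRUE]  # 4 x 3
  seg <- labels_to_segments(ids)
  phase <- numeric(t_len)
  for (i in seq_len(nrow(seg))) {
    span <- (seg$start[i] + 1L):seg$end[i]
    phase[span] <- seq(0, 1, length.out = length(span))
  }
  pos <- base[ids, , drop = FALSE]
  amp <- 0.3
  wob <- cbind(sin(2 * pi * phase), cos(2 * pi * phase), sin(4 * pi * phase))
  pos + amp * wob + matrix(style$tool_offset, t_len, 3, byrow = TRUE)
}

insert_detection_gaps <- function(t_len, rate, mean_gap) {
  detected <- rep(TRUE, t_len)
  if (rate <= 0) return(detected)
  p_start <- min(1, rate / mean_gap)
  starts <- which(stats::rbinom(t_len, 1L, p_start) == 1L)
  lens <- 1L + stats::rgeom(length(starts), prob = 1 / mean_gap)
  for (k in seq_along(starts)) {
    span <- starts[k]:min(t_len, starts[k] + lens[k] - 1L)
    detected[span] <- FALSE
  }
  detected
}

#' Simulate tool pose tracks
#'
#' Per tool, positions follow a class-specific smooth template (phase
#' parameterized within each segment) plus the surgeon's style offset plus
#' Gaussian noise; rotations follow a class-conditioned exponentially
#' smoothed angle path. Each frame is independently corrupted by a symmetry
#' flip with probability `flip_rate`, and detection gaps of geometric length
#' are inserted at the configured dropout rate.
#'
#' @param labels A [label_sequence()].
#' @param cfg A [simulator_config()].
#' @param style A [surgeon_style()].
#' @return Named list of [rigid_pose_track()] objects.
#' @export
simulate_tool_tracks <- function(labels, cfg, style = surgeon_style(cfg)) {
  ids <- labels$labels
  t_len <- length(ids)
  pos_sigma <- if (is.finite(cfg$snr)) 2.0 / cfg$snr else 0
  rot_sigma <- if (is.finite(cfg$snr)) 0.8 / cfg$snr else 0
  axes <- list(c(0, 0, 1), c(1, 0, 0))
  targets <- rbind(c(0, 0.8, 1.6, 2.4), c(2.2, 1.4, 0.6, -0.2))
  tracks <- list()
  for (k in 1:2) {
    pos <- tool_template_positions(ids, k, style)
    if (pos_sigma > 0) {
      pos <- pos + matrix(stats::rnorm(t_len * 3, sd = pos_sigma), t_len, 3)
    }
    theta <- numeric(t_len)
    theta[1] <- targets[k, ids[1]]
    for (t in seq_len(t_len)[-1L]) {
      theta[t] <- theta[t - 1L] + 0.1 * (targets[k, ids[t]] - theta[t - 1L])
    }
    if (rot_sigma > 0) theta <- theta + stats::rnorm(t_len, sd = rot_sigma)
    rot <- t(vapply(theta, function(a) quat_from_axis_angle(axes[[k]], a),
                    numeric(4)))
    flip <- stats::rbinom(t_len, 1L, cfg$flip_rate) == 1L
    if (any(flip)) {
      s <- tool_symmetry_group()[2L, ]
      rot[flip, ] <- t(apply(rot[flip, , drop = FALSE], 1L,
                             function(q) quat_multiply(q, s)))
    }
    detected <- insert_detection_gaps(t_len, cfg$detection_dropout_rate,
                                      cfg$mean_gap_length)
    tr <- rigid_pose_track(pos, rot, detected, tool_id = tool_ids()[k])
    attr(tr, "flipped") <- flip  # diagnostic: which frames were flip-corrupted
    tracks[[tool_ids()[k]]] <- tr
  }
  tracks
}

hand_joint_template <- function() {
  dirs <- rbind(c(1, 0, 0.2), c(0.8, 0.5, 0.1), c(0.4, 0.9, 0),
                c(0, 1, 0.1), c(-0.4, 0.9, 0.2))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tpl <- matrix(0, 21, 3)
  for (f in 1:5) {
    for (j in 1:4) {
      tpl[1L + (f - 1L) * 4L + j, ] <- dirs[f, ] * 0.3 * j
    }
  }
  tpl
}

#' Simulate two-hand joint tracks
#'
#' Each wrist follows the clean template path of its tool (left hand: needle
#' driver; right hand: tweezers) with a fixed offset; a class-dependent
#' articulation scale modulates the canonical 21-joint hand template around
#' the wrist. Noise and detection dropout as configured.
#'
#' @inheritParams simulate_tool_tracks
#' @return A [hand_joint_track()].
#' @export
simulate_hand_tracks <- function(labels, cfg, style = surgeon_style(cfg)) {
  ids <- labels$labels
  t_len <- length(ids)
  sigma <- if (is.finite(cfg$snr)) 1.2 / cfg$snr else 0
  artic <- c(0.5, 1.0, 1.6, 0.75) + style$articulation
  tpl <- hand_joint_template()
  joints <- array(0, dim = c(t_len, 2, 21, 3))
  detected <- matrix(FALSE, t_len, 2)
  wrist_off <- rbind(c(0, -0.25, 0.1), c(0, -0.25, -0.1))
  for (h in 1:2) {
    wrist <- tool_template_positions(ids, h, style) +
      matrix(wrist_off[h, ], t_len, 3, byrow = TRUE) +
      matrix(style$hand_offset, t_len, 3, byrow = TRUE)
    scale <- artic[ids]
    for (a in 1:3) {
      joints[, h, , a] <- wrist[, a] + outer(scale, tpl[, a])
    }
    if (sigma > 0) {
      joints[, h, , ] <- joints[, h, , ] +
        array(stats::rnorm(t_len * 21 * 3, sd = sigma), dim = c(t_len, 21, 3))
    }
    detected[, h] <- insert_detection_gaps(t_len, cfg$detection_dropout_rate,
                                           cfg$mean_gap_length)
  }
  hand_joint_track(joints, detected)
}

#' Class prototype vectors for synthetic video embeddings
#'
#' Fixed per-class prototypes in `video_feature_dim` dimensions, drawn
#' deterministically from `cfg$seed` so every video of a dataset shares them.
#'
#' @param cfg A [simulator_config()].
#' @return 4 x D numeric matrix.
#' @export
class_prototypes <- function(cfg) {
  withr::with_seed(cfg$seed + 7919L,
                   matrix(stats::rnorm(4L * cfg$video_feature_dim), 4L))
}

#' Simulate per-frame video embeddings
#'
#' Stands in for a fine-tuned frame-wise feature extractor: each frame's
#' embedding is its class prototype plus the surgeon's style offset plus
#' temporally smoothed Gaussian noise whose scale is `sqrt(D) / snr`.
#'
#' @inheritParams simulate_tool_tracks
#' @param prototypes Prototype matrix from [class_prototypes()].
#' @return A [feature_sequence()] with modality `"video"`.
#' @export
simulate_video_features <- function(labels, cfg, style = surgeon_style(cfg),
                                    prototypes = class_prototypes(cfg)) {
  ids <- labels$labels
  t_len <- length(ids)
  d <- cfg$video_feature_dim
  vals <- prototypes[ids, , drop = FALSE] +
    matrix(style$video_offset, t_len, d, byrow = TRUE)
  if (is.finite(cfg$snr)) {
    sigma <- 0.5 * sqrt(d) / cfg$snr
    noise <- matrix(stats::rnorm(t_len * d), t_len, d)
    if (t_len >= 5L) {
      sm <- stats::filter(noise, rep(1 / 5, 5), sides = 2)
      sm[is.na(sm)] <- noise[is.na(sm)]
      noise <- sqrt(5) * as.matrix(sm)  # restore unit variance after smoothing
    }
    vals <- vals + sigma * noise
  }
  feature_sequence(vals, modality = "video")
}

#' Simulate a full multi-surgeon dataset in memory
#'
#' Draws one style per surgeon and, per video, a label sequence plus
#' independently noised tool tracks, hand tracks and video embeddings.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulator_config()].
#' @return List with `videos` (each: `id`, `surgeon`, `labels`, `tools`,
#'   `hands`, `video_features`) and `cfg`.
#' @export
simulate_dataset <- function(cfg = simulator_config()) {
  protos <- class_prototypes(cfg)
  withr::with_seed(cfg$seed, {
    videos <- list()
    for (s in seq_len(cfg$n_surgeons)) {
      style <- surgeon_style(cfg)
      for (v in seq_len(cfg$videos_per_surgeon)) {
        labels <- simulate_label_sequence(cfg)
        videos[[length(videos) + 1L]] <- list(
          id = sprintf("s%02d_v%02d", s, v),
          surgeon = sprintf("surgeon%02d", s),
          labels = labels,
          tools = simulate_tool_tracks(labels, cfg, style),
          hands = simulate_hand_tracks(labels, cfg, style),
          video_features = simulate_video_features(labels, cfg, style, protos))
      }
    }
    list(videos = videos, cfg = cfg)
  })
}

#' Clean pose tracks and assemble per-modality features for one video
#'
#' Tools: symmetry disambiguation, gap-limited LOCF imputation,
#' Savitzky-Golay smoothing, then flattening to position + quaternion +
#' validity features. Hands: gap-limited linear interpolation, smoothing,
#' flattening. Video embeddings pass through.
#'
#' @param video One element of `simulate_dataset()$videos` (or an equivalent
#'   list with `tools`, `hands`, `video_features`).
#' @param pcfg A [preprocess_config()].
#' @return Named list of [feature_sequence()]: `tools`, `hands`, `video`.
#' @export
prepare_modalities <- function(video, pcfg = preprocess_config()) {
  tools <- lapply(video$tools, function(tr) {
    tr <- disambiguate_tool_rotations(tr)
    tr <- impute_locf(tr, pcfg$max_gap_frames)
    smooth_savitzky_golay(tr, pcfg)
  })
  hands <- interpolate_gaps_linear(video$hands, pcfg$max_gap_frames)
  hands <- smooth_savitzky_golay(hands, pcfg)
  list(tools = tracks_to_features(tools = tools, modality = "tools"),
       hands = tracks_to_features(hands = hands, modality = "hands"),
       video = video$video_features)
}

#' Write a simulated dataset to disk
#'
#' Emits, per video, a frame-label CSV, a tool-pose CSV, a hand-pose CSV and
#' a video-feature matrix (with JSON sidecar), plus a JSON manifest mapping
#' video ids to files and surgeon ids. Byte-identical across runs for a
#' fixed `cfg$seed`.
#'
#' @param cfg A [simulator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
make_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(cfg)
  entries <- lapply(ds$videos, function(v) {
    base <- file.path(out_dir, v$id)
    write_frame_labels(v$labels, paste0(base, "_labels.csv"))
    write_tool_pose_table(v$tools, paste0(base, "_tools.csv"))
    write_hand_pose_table(v$hands, paste0(base, "_hands.csv"))
    write_feature_matrix(v$video_features, paste0(base, "_video.tsv"))
    list(id = v$id, surgeon = v$surgeon,
         labels = paste0(v$id, "_labels.csv"),
         tools = paste0(v$id, "_tools.csv"),
         hands = paste0(v$id, "_hands.csv"),
         video = paste0(v$id, "_video.tsv"))
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(fps = cfg$fps, n_surgeons = cfg$n_surgeons,
                            videos = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
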