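#' Frame-wise label sequence
#'
#' A `label_sequence` holds one gesture class per video frame. Class ids are
#' 1-based integer indices into `vocabulary` (the R convention; on-disk frame
#' indices remain 0-based).
#'
#' @param labels Integer vector of class ids, one per frame.
#' @param vocabulary Ordered character vector of class names.
#' @param fps Frames per second of the source video (default 30).
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels, vocabulary = gesture_vocabulary(), fps = 30) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("label sequence must contain at least one frame")
  if (anyNA(labels) || any(labels < 1L) || any(labels > length(vocabulary))) {
    stop("label ids must lie in [1, |vocabulary|]")
  }
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  structure(list(labels = labels, vocabulary = vocabulary, fps = fps),
            class = "label_sequence")
}

#' @export
length.label_sequence <- function(x) length(x$labels)

#' @export
print.label_sequence <- function(x, ...) {
  cat("<label_sequence> ", length(x$labels), " frames @ ", x$fps, " FPS, ",
      length(x$vocabulary), " classes\n", sep = "")
  invisible(x)
}

#' Per-frame feature matrix
#'
#' @param values Numeric T x D matrix of per-frame features.
#' @param modality One of `"video"`, `"tools"`, `"hands"`, `"concat"`.
#' @param stride Source-frame step the rows correspond to (default 1).
#' @return An object of class `feature_sequence`.
#' @export
feature_sequence <- function(values, modality, stride = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("feature matrix must be at least 1 x 1")
  if (!all(is.finite(values))) stop("feature matrix contains non-finite entries")
  modality <- match.arg(modality, c("video", "tools", "hands", "concat"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(values = values, modality = modality, stride = stride),
            class = "feature_sequence")
}

#' @export
dim.feature_sequence <- function(x) dim(x$values)

#' @export
print.feature_sequence <- function(x, ...) {
  cat("<feature_sequence> ", nrow(x$values), " x ", ncol(x$values),
      " [", x$modality, ", stride ", x$stride, "]\n", sep = "")
  invisible(x)
}

#' BORIS-style event records
#'
#' Builds a validated event table in the tabular dialect used by the toolkit:
#' one behaviour per row with start/stop times in seconds.
#'
#' @param behavior Character vector of class names.
#' @param start_s,stop_s Numeric vectors of event start/stop times (seconds).
#' @param vocabulary Allowed class names.
#' @return A `data.frame` with columns `behavior`, `start_s`, `stop_s`.
#' @export
event_records <- function(behavior, start_s, stop_s,
                          vocabulary = gesture_vocabulary()) {
  if (length(behavior) != length(start_s) || length(behavior) != length(stop_s)) {
    stop("behavior, start_s and stop_s must have equal length")
  }
  match_class(behavior, vocabulary)
  if (any(start_s < 0)) stop("event start times must be >= 0")
  if (any(stop_s <= start_s)) stop("event stop times must exceed start times")
  data.frame(behavior = as.character(behavior),
             start_s = as.numeric(start_s),
             stop_s = as.numeric(stop_s))
}

#' Read frame-wise labels from CSV
#'
#' Expects a header `frame,label` with 0-based consecutive frame indices
#' starting at 0 and label strings drawn from `vocabulary`.
#'
#' @param path CSV file path.
#' @param vocabulary Ordered class names.
#' @param fps Frames per second recorded in the returned sequence.
#' @return A [label_sequence()].
#' @export
read_frame_labels <- function(path, vocabulary = gesture_vocabulary(), fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "label") %in% names(df))) {
    stop("expected header 'frame,label' in ", path)
  }
  if (nrow(df) == 0L) stop("empty label file: ", path)
  df <- df[order(df$frame), , drop = FALSE]
  if (anyDuplicated(df$frame)) stop("duplicate frame index in ", path)
  if (!identical(as.integer(df$frame), seq_len(nrow(df)) - 1L)) {
    stop("non-consecutive frames in ", path, " (expected 0..T-1)")
  }
  label_sequence(match_class(df$label, vocabulary), vocabulary, fps)
}

#' Write frame-wise labels to CSV
#'
#' @param x A [label_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_labels <- function(x, path) {
  stopifnot(inherits(x, "label_sequence"))
  df <- data.frame(frame = seq_along(x$labels) - 1L,
                   label = x$vocabulary[x$labels])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert timed behaviour events to frame-wise labels
#'
#' Frame `f` (0-based) receives the class of the event whose half-open time
#' interval `[start_s, stop_s)` covers `f / fps`; frames covered by no event
#' receive `fill_class`.
#'
#' @param events Event table from [event_records()] or [read_boris_events()].
#' @param fps Frames per second (the dataset rate is 30).
#' @param n_frames Total number of frames to label.
#' @param fill_class Class name for uncovered frames (default `"other"`).
#' @param vocabulary Ordered class names.
#' @param clip If `TRUE`, events extending beyond `n_frames / fps` are clipped
#'   with a warning; the default (`FALSE`) raises an error.
#' @return A [label_sequence()] of length `n_frames`.
#' @export
events_to_frame_labels <- function(events, fps, n_frames,
                                   fill_class = "other",
                                   vocabulary = gesture_vocabulary(),
                                   clip = FALSE) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  fill_id <- match_class(fill_class, vocabulary)
  labels <- rep.int(fill_id, n_frames)
  if (nrow(events) > 0L) {
    ids <- match_class(events$behavior, vocabulary)
    o <- order(events$start_s)
    ev <- events[o, , drop = FALSE]
    ids <- ids[o]
    if (nrow(ev) > 1L && any(ev$start_s[-1L] < ev$stop_s[-nrow(ev)])) {
      stop("overlapping events")
    }
    horizon <- n_frames / fps
    if (any(ev$stop_s > horizon + 1e-9)) {
      if (clip) {
        warning("clipping events extending beyond ", signif(horizon, 6), " s")
        ev$stop_s <- pmin(ev$stop_s, horizon)
      } else {
        stop("event extends beyond the video horizon (", signif(horizon, 6),
             " s); set clip = TRUE to truncate")
      }
    }
    for (i in seq_len(nrow(ev))) {
      first <- ceiling(ev$start_s[i] * fps - 1e-9)
      last <- ceiling(ev$stop_s[i] * fps - 1e-9) - 1
      if (last >= first && last >= 0 && first < n_frames) {
        labels[(max(first, 0) + 1L):(min(last, n_frames - 1L) + 1L)] <- ids[i]
      }
    }
  }
  label_sequence(labels, vocabulary, fps)
}

#' Read a BORIS-style tabular event export
#'
#' @param path CSV with header `behavior,start_s,stop_s`.
#' @param vocabulary Allowed class names.
#' @return Validated event `data.frame`.
#' @export
read_boris_events <- function(path, vocabulary = gesture_vocabulary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("behavior", "start_s", "stop_s")
  if (!all(need %in% names(df))) {
    stop("expected header 'behavior,start_s,stop_s' in ", path)
  }
  event_records(df$behavior, df$start_s, df$stop_s, vocabulary)
}

#' Write events to a BORIS-style CSV
#' @param events Event `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boris_events <- function(events, path) {
  utils::write.csv(events[, c("behavior", "start_s", "stop_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tool pose table
#'
#' Expects header `frame,tool_id,x,y,z,qw,qx,qy,qz,detected`. Quaternions are
#' scalar-first `(qw,qx,qy,qz)`, right-handed, and renormalized to unit
#' length on read (a zero or non-finite quaternion on a detected row is an
#' error). Supplying a finite `tol` enables a strict mode in which detected
#' rows whose norm deviates from 1 by more than `tol` raise an error instead.
#' Frames with `detected = 0` are treated as missing regardless of their
#' coordinate values. Each tool's track spans frames `0..max(frame)`; frames
#' without a row are missing.
#'
#' @param path CSV file path.
#' @param tol Optional strict unit-norm tolerance (default `Inf`:
#'   renormalize any valid quaternion).
#' @return Named list of [rigid_pose_track()] objects, one per `tool_id`.
#' @export
read_tool_pose_table <- function(path, tol = Inf) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "tool_id", "x", "y", "z", "qw", "qx", "qy", "qz", "detected")
  if (!all(need %in% names(df))) {
    stop("expected header 'frame,tool_id,x,y,z,qw,qx,qy,qz,detected' in ", path)
  }
  if (!all(df$detected %in% c(0L, 1L))) stop("detected must be 0 or 1")
  if (anyDuplicated(df[, c("frame", "tool_id")])) {
    stop("duplicate (frame, tool_id) row in ", path)
  }
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  det <- df$detected == 1L
  nrm <- sqrt(rowSums(q^2))
  if (any(det & (!is.finite(nrm) | nrm < 1e-8))) {
    stop("degenerate quaternion on a detected row")
  }
  if (is.finite(tol) && any(det & abs(nrm - 1) > tol)) {
    stop("non-unit quaternion beyond tolerance (", tol, ")")
  }
  q[det, ] <- q[det, , drop = FALSE] / nrm[det]
  n_frames <- max(df$frame) + 1L
  tracks <- list()
  for (tid in sort(unique(df$tool_id))) {
    sel <- df$tool_id == tid
    fr <- df$frame[sel] + 1L
    pos <- matrix(0, n_frames, 3)
    rot <- matrix(c(1, 0, 0, 0), n_frames, 4, byrow = TRUE)
    dd <- rep(FALSE, n_frames)
    pos[fr, ] <- as.matrix(df[sel, c("x", "y", "z")])
    rot[fr, ] <- q[sel, , drop = FALSE]
    dd[fr] <- det[sel]
    rot[!dd, ] <- rep(c(1, 0, 0, 0), each = sum(!dd))
    tracks[[as.character(tid)]] <- rigid_pose_track(pos, rot, dd, tool_id = as.character(tid))
  }
  tracks
}

#' Write tool pose tracks to a pose table CSV
#' @param tracks Named list of [rigid_pose_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tool_pose_table <- function(tracks, path) {
  rows <- lapply(names(tracks), function(tid) {
    tr <- tracks[[tid]]
    data.frame(frame = seq_along(tr$detected) - 1L, tool_id = tid,
               x = tr$positions[, 1], y = tr$positions[, 2], z = tr$positions[, 3],
               qw = tr$rotations[, 1], qx = tr$rotations[, 2],
               qy = tr$rotations[, 3], qz = tr$rotations[, 4],
               detected = as.integer(tr$detected))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hand_coord_names <- function() {
  jj <- sprintf("%02d", 0:20)
  as.vector(t(outer(jj, c("x", "y", "z"), function(j, a) paste0(a, j))))
}

#' Read a hand joint table
#'
#' Expects header `frame,hand,detected,x00,y00,z00,...,x20,y20,z20` (63
#' coordinate columns per row, one row per frame per hand, hand in `{L,R}`).
#'
#' @param path CSV file path.
#' @return A [hand_joint_track()].
#' @export
read_hand_pose_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- hand_coord_names()
  n_coord <- sum(grepl("^[xyz][0-9]{2}$", names(df)))
  if (n_coord != 63L) stop("expected 63 coordinates, found ", n_coord)
  need <- c("frame", "hand", "detected", coords)
  if (!all(need %in% names(df))) stop("missing columns in ", path)
  if (!all(df$hand %in% c("L", "R"))) stop("hand must be 'L' or 'R'")
  if (anyDuplicated(df[, c("frame", "hand")])) stop("duplicate (frame, hand) row")
  n_frames <- max(df$frame) + 1L
  joints <- array(0, dim = c(n_frames, 2, 21, 3))
  detected <- matrix(FALSE, n_frames, 2)
  for (h in 1:2) {
    sel <- df$hand == c("L", "R")[h]
    fr <- df$frame[sel] + 1L
    mat <- as.matrix(df[sel, coords, drop = FALSE])  # T x 63, joint-major xyz
    for (j in 1:21) {
      for (a in 1:3) {
        joints[fr, h, j, a] <- mat[, (j - 1L) * 3L + a]
      }
    }
    detected[fr, h] <- df$detected[sel] == 1L
  }
  hand_joint_track(joints, detected)
}

#' Write a hand joint track to CSV
#' @param track A [hand_joint_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hand_pose_table <- function(track, path) {
  n <- dim(track$joints)[1]
  rows <- lapply(1:2, function(h) {
    flat <- matrix(0, n, 63)  # T x 63, joint-major xyz
    for (j in 1:21) {
      for (a in 1:3) {
        flat[, (j - 1L) * 3L + a] <- track$joints[, h, j, a]
      }
    }
    df <- data.frame(frame = seq_len(n) - 1L, hand = c("L", "R")[h],
                     detected = as.integer(track$detected[, h]))
    df[hand_coord_names()] <- flat
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-frame feature matrices
#'
#' The matrix is stored as a headerless tab-delimited text table (T rows, D
#' columns); `modality` and `stride` live in a JSON sidecar at
#' `paste0(path, ".json")`. Values are printed with 17 significant digits so a
#' write/read round trip is exact.
#'
#' @param path Matrix file path.
#' @return [read_feature_matrix()] returns a [feature_sequence()].
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty feature matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  d <- length(parts[[1L]])
  if (any(lengths(parts) != d)) stop("ragged rows in ", path)
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals) || any(!is.finite(vals))) stop("non-numeric or non-finite entry in ", path)
  m <- matrix(vals, ncol = d, byrow = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(modality = "concat", stride = 1L)
  feature_sequence(m, modality = meta$modality, stride = meta$stride)
}

#' @rdname read_feature_matrix
#' @param seq A [feature_sequence()] to write.
#' @export
write_feature_matrix <- function(seq, path) {
  stopifnot(inherits(seq, "feature_sequence"))
  txt <- apply(seq$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  jsonlite::write_json(list(modality = seq$modality, stride = seq$stride),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
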