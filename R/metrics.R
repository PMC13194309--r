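#' Run-length segmentation of a label sequence
#'
#' Converts frame-wise labels to maximal constant runs as half-open frame
#' intervals `[start, end)` (0-based starts, matching on-disk frame indices).
#'
#' @param labels A [label_sequence()] or integer vector of class ids.
#' @return A `data.frame` with columns `class_id`, `start`, `end`.
#' @export
labels_to_segments <- function(labels) {
  ids <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  r <- rle(ids)
  end <- cumsum(r$lengths)
  data.frame(class_id = r$values, start = end - r$lengths, end = end)
}

#' Reconstruct frame labels from segments
#'
#' Inverse of [labels_to_segments()]: expands contiguous half-open segments
#' back to one class id per frame.
#'
#' @param segments `data.frame` with `class_id`, `start`, `end` (half-open,
#'   contiguous, first start 0).
#' @param vocabulary Ordered class names.
#' @param fps Frames per second.
#' @return A [label_sequence()].
#' @export
segments_to_labels <- function(segments, vocabulary = gesture_vocabulary(), fps = 30) {
  if (nrow(segments) == 0L) stop("empty segmentation")
  if (segments$start[1L] != 0L) stop("first segment must start at frame 0")
  if (any(segments$end <= segments$start)) stop("segments must satisfy end > start")
  if (nrow(segments) > 1L &&
      !all(segments$start[-1L] == segments$end[-nrow(segments)])) {
    stop("segments must be contiguous")
  }
  label_sequence(rep.int(segments$class_id, segments$end - segments$start),
                 vocabulary, fps)
}

#' Convert segments to timed events
#'
#' @param segments Output of [labels_to_segments()].
#' @param fps Frames per second.
#' @param vocabulary Ordered class names.
#' @param drop_class Optional class name whose segments are omitted (e.g. the
#'   fill class when inverting [events_to_frame_labels()]).
#' @return Event `data.frame` with `behavior`, `start_s`, `stop_s`.
#' @export
segments_to_events <- function(segments, fps = 30,
                               vocabulary = gesture_vocabulary(),
                               drop_class = NULL) {
  ev <- data.frame(behavior = vocabulary[segments$class_id],
                   start_s = segments$start / fps,
                   stop_s = segments$end / fps)
  if (!is.null(drop_class)) ev <- ev[ev$behavior != drop_class, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

check_paired_labels <- function(pred, gt) {
  p <- if (inherits(pred, "label_sequence")) pred$labels else as.integer(pred)
  g <- if (inherits(gt, "label_sequence")) gt$labels else as.integer(gt)
  if (length(p) != length(g)) stop("prediction and ground truth lengths differ")
  list(p = p, g = g)
}

#' Frame-wise accuracy
#'
#' @param pred,gt [label_sequence()] objects (or id vectors) of equal length.
#' @return Percent of frames where prediction equals ground truth.
#' @export
frame_accuracy <- function(pred, gt) {
  x <- check_paired_labels(pred, gt)
  100 * mean(x$p == x$g)
}

#' Frame-wise macro-averaged F1
#'
#' Per class occurring in prediction or ground truth, computes frame-wise
#' precision, recall and F1 (zero-division within an occurring class gives 0);
#' classes absent from both are excluded. Returns the unweighted mean x 100.
#'
#' @inheritParams frame_accuracy
#' @return Macro F1 in percent.
#' @export
f1_macro_framewise <- function(pred, gt) {
  x <- check_paired_labels(pred, gt)
  classes <- sort(unique(c(x$p, x$g)))
  f1 <- vapply(classes, function(c) {
    tp <- sum(x$p == c & x$g == c)
    fp <- sum(x$p == c & x$g != c)
    fn <- sum(x$p != c & x$g == c)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1.0)
  100 * mean(f1)
}

# Levenshtein distance between two integer vectors (unit costs), iterative DP
levenshtein_ids <- function(a, b) {
  n <- length(a); m <- length(b)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1,
                         cur[j] + 1,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Segmental edit score
#'
#' 100 x (1 - Levenshtein distance between the segment-class strings of
#' prediction and ground truth, normalized by the larger segment count),
#' floored at 0. Penalizes over-segmentation independently of segment
#' durations.
#'
#' @inheritParams frame_accuracy
#' @return Edit score in percent.
#' @export
edit_score <- function(pred, gt) {
  x <- check_paired_labels(pred, gt)
  sp <- rle(x$p)$values
  sg <- rle(x$g)$values
  d <- levenshtein_ids(sp, sg)
  max(0, 100 * (1 - d / max(length(sp), length(sg))))
}

#' Segmental overlap F1 (F1@k)
#'
#' Segments of all classes are pooled. Each predicted segment, in temporal
#' order, is matched to the unmatched same-class ground-truth segment of
#' maximal IoU (intersection over union of frame intervals) and counts as a
#' true positive when that IoU is at least `k`, otherwise a false positive;
#' ground-truth segments left unmatched are false negatives.
#'
#' @inheritParams frame_accuracy
#' @param k IoU threshold in (0, 1]; the standard operating points are
#'   0.10, 0.25 and 0.50.
#' @return F1 in percent.
#' @export
f1_at_k <- function(pred, gt, k) {
  if (k <= 0 || k > 1) stop("k must lie in (0, 1]")
  x <- check_paired_labels(pred, gt)
  ps <- labels_to_segments(x$p)
  gs <- labels_to_segments(x$g)
  used <- rep(FALSE, nrow(gs))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(ps))) {
    cand <- which(!used & gs$class_id == ps$class_id[i])
    if (length(cand) == 0L) { fp <- fp + 1L; next }
    inter <- pmax(0, pmin(ps$end[i], gs$end[cand]) - pmax(ps$start[i], gs$start[cand]))
    uni <- pmax(ps$end[i], gs$end[cand]) - pmin(ps$start[i], gs$start[cand])
    iou <- inter / uni
    j <- cand[which.max(iou)]
    if (max(iou) >= k) { tp <- tp + 1L; used[j] <- TRUE } else fp <- fp + 1L
  }
  fn <- sum(!used)
  if (2 * tp + fp + fn == 0) return(100)
  100 * 2 * tp / (2 * tp + fp + fn)
}

#' Full metrics report for one video
#'
#' @inheritParams frame_accuracy
#' @return Named list with `accuracy`, `edit`, `f1_macro`, `f1_10`, `f1_25`,
#'   `f1_50`, all in percent.
#' @export
metrics_report <- function(pred, gt) {
  list(accuracy = frame_accuracy(pred, gt),
       edit = edit_score(pred, gt),
       f1_macro = f1_macro_framewise(pred, gt),
       f1_10 = f1_at_k(pred, gt, 0.10),
       f1_25 = f1_at_k(pred, gt, 0.25),
       f1_50 = f1_at_k(pred, gt, 0.50))
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties. For n <= 20 without ties the p-value comes from exact
#' enumeration of the null distribution of the positive-rank sum; otherwise
#' a normal approximation with tie correction is used.
#' `alternative = "greater"` tests whether `x` tends to exceed `y`.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return List with `statistic` (positive-rank sum W), `p_value`, `n`
#'   (pairs after dropping zeros), and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 20L && !ties) {
    # exact null: counts of rank-subset sums via polynomial convolution
    maxw <- n * (n + 1) / 2
    counts <- numeric(maxw + 1L)
    counts[1L] <- 1
    for (rr in seq_len(n)) {
      shifted <- c(numeric(rr), counts[seq_len(maxw + 1L - rr)])
      counts <- counts + shifted
    }
    total <- 2^n
    p_ge <- sum(counts[(w + 1L):(maxw + 1L)]) / total
    p_le <- sum(counts[seq_len(w + 1L)]) / total
    p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Aggregate per-fold metric reports
#'
#' Computes mean and standard deviation of each metric across folds. A fold's
#' value is the unweighted mean over its test videos when a report carries
#' multiple videos.
#'
#' @param per_fold List of per-fold reports ([metrics_report()] lists, or
#'   data.frames of per-video rows with metric columns).
#' @param std `"sample"` (n-1 denominator, default) or `"population"`.
#' @return `data.frame` with columns `metric`, `mean`, `std`.
#' @export
aggregate_folds <- function(per_fold, std = c("sample", "population")) {
  std <- match.arg(std)
  metrics <- c("accuracy", "edit", "f1_macro", "f1_10", "f1_25", "f1_50")
  fold_vals <- vapply(per_fold, function(rep) {
    if (is.data.frame(rep)) {
      vapply(metrics, function(m) mean(rep[[m]]), 1.0)
    } else {
      vapply(metrics, function(m) mean(unlist(rep[[m]])), 1.0)
    }
  }, numeric(length(metrics)))
  fold_vals <- matrix(fold_vals, nrow = length(metrics))
  mu <- rowMeans(fold_vals)
  n <- ncol(fold_vals)
  dev <- if (n > 1L) {
    s <- apply(fold_vals, 1L, stats::sd)
    if (std == "population") s * sqrt((n - 1) / n) else s
  } else rep(0, length(metrics))
  data.frame(metric = metrics, mean = mu, std = dev, row.names = NULL)
}
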