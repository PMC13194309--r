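#' Per-frame class logits
#'
#' Unnormalized class scores, one row per frame; the object averaged by the
#' model ensemble.
#'
#' @param values T x C numeric matrix.
#' @param stride Source-frame step (default 1).
#' @return An object of class `logit_sequence`.
#' @export
logit_sequence <- function(values, stride = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("logits must be finite")
  structure(list(values = values, stride = as.integer(stride)),
            class = "logit_sequence")
}

#' @export
dim.logit_sequence <- function(x) dim(x$values)

#' @export
print.logit_sequence <- function(x, ...) {
  cat("<logit_sequence> ", nrow(x$values), " frames x ", ncol(x$values),
      " classes (stride ", x$stride, ")\n", sep = "")
  invisible(x)
}

#' Concatenate per-frame features across modalities
#'
#' Column-binds the feature matrices of several modalities into the single
#' per-frame vector used by the straightforward multimodal approach.
#'
#' @param seqs List of [feature_sequence()] objects sharing T and stride.
#' @return A [feature_sequence()] with modality `"concat"`.
#' @export
concat_modalities <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence list")
  t_len <- vapply(seqs, function(s) nrow(s$values), 1L)
  strides <- vapply(seqs, function(s) s$stride, 1L)
  if (length(unique(t_len)) != 1L) stop("length mismatch across modalities")
  if (length(unique(strides)) != 1L) stop("stride mismatch across modalities")
  if (length(seqs) == 1L) return(seqs[[1L]])
  feature_sequence(do.call(cbind, lapply(seqs, `[[`, "values")),
                   modality = "concat", stride = strides[1L])
}

#' Logit-averaging ensemble
#'
#' Element-wise arithmetic mean of the logits of several model runs. Averaging
#' logits (rather than softmax probabilities) lets a confident model -- one
#' whose logits have large norm -- dominate the combined prediction.
#'
#' @param runs List of [logit_sequence()] objects sharing T and C.
#' @return The averaged [logit_sequence()].
#' @export
average_logits <- function(runs) {
  if (length(runs) == 0L) stop("empty ensemble")
  dims <- vapply(runs, function(r) dim(r$values), integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("logit shape mismatch across runs")
  }
  logit_sequence(Reduce(`+`, lapply(runs, `[[`, "values")) / length(runs),
                 stride = runs[[1L]]$stride)
}

#' Frame-wise argmax of logits
#'
#' Ties are broken toward the lowest class index.
#'
#' @param logits A [logit_sequence()].
#' @param vocabulary Ordered class names.
#' @param fps Frames per second attached to the result.
#' @return A [label_sequence()].
#' @export
logits_to_labels <- function(logits, vocabulary = gesture_vocabulary(), fps = 30) {
  label_sequence(max.col(logits$values, ties.method = "first"), vocabulary, fps)
}

#' Neighbour-based prediction smoothing
#'
#' Replaces every maximal run of identical predictions that is shorter than
#' `min_run` frames -- excluding runs touching either end of the sequence --
#' with the label of the longer adjacent run (ties go to the left neighbour),
#' iterating until no interior run is shorter than `min_run`. Removes the
#' isolated flicker frames that logit averaging can introduce.
#'
#' @param labels A [label_sequence()].
#' @param min_run Minimum interior run length in frames (default 3).
#' @return The smoothed [label_sequence()].
#' @export
smooth_predictions <- function(labels, min_run = 3L) {
  stopifnot(inherits(labels, "label_sequence"), min_run >= 1L)
  ids <- labels$labels
  repeat {
    r <- rle(ids)
    k <- length(r$lengths)
    if (k <= 2L) break
    interior <- 2:(k - 1L)
    short <- interior[r$lengths[interior] < min_run]
    if (length(short) == 0L) break
    new_vals <- r$values
    for (i in short) {
      left <- r$lengths[i - 1L]
      right <- r$lengths[i + 1L]
      new_vals[i] <- if (right > left) r$values[i + 1L] else r$values[i - 1L]
    }
    ids <- rep.int(new_vals, r$lengths)
  }
  labels$labels <- ids
  labels
}

logit_norm_bin_index <- function(n, n_bins) {
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep.int(base, n_bins) + c(rep.int(1L, extra), rep.int(0L, n_bins - extra))
  rep.int(seq_len(n_bins), sizes)
}

#' Accuracy binned by logit norm
#'
#' Frames are sorted by the Euclidean norm of their logit vector and split
#' into `n_bins` contiguous, (near-)equal-sized groups (any remainder goes to
#' the lowest-norm bins, so bin sizes differ by at most one). Confident
#' models produce large-norm logits, so accuracy typically rises with the
#' bin's mean norm.
#'
#' @param logits A [logit_sequence()].
#' @param labels Ground-truth [label_sequence()] of matching length.
#' @param n_bins Number of bins (default 10).
#' @return `data.frame` with columns `bin`, `mean_norm`, `accuracy`
#'   (percent), `count`, ordered from lowest to highest norm.
#' @export
logit_norm_accuracy_bins <- function(logits, labels, n_bins = 10L) {
  t_len <- nrow(logits$values)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > t_len) stop("n_bins exceeds number of frames")
  gt <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  if (length(gt) != t_len) stop("labels and logits length mismatch")
  nrm <- sqrt(rowSums(logits$values^2))
  pred <- max.col(logits$values, ties.method = "first")
  o <- order(nrm)
  bin <- logit_norm_bin_index(t_len, n_bins)
  data.frame(bin = seq_len(n_bins),
             mean_norm = as.numeric(tapply(nrm[o], bin, mean)),
             accuracy = as.numeric(tapply((pred == gt)[o], bin, mean)) * 100,
             count = as.integer(table(bin)))
}

#' Per-bin accuracy difference between two runs
#'
#' Bins are defined by the logit norms of the reference run `logits_a`; the
#' returned delta is `accuracy(b) - accuracy(a)` within each bin, showing
#' where (in confidence) a second run, e.g. an ensemble, helps.
#'
#' @param logits_a Reference [logit_sequence()] (defines the bins).
#' @param logits_b Comparison [logit_sequence()].
#' @param labels Ground-truth labels.
#' @param n_bins Number of bins (default 10).
#' @return `data.frame` with `bin`, `mean_norm`, `accuracy_a`, `accuracy_b`,
#'   `delta` (percentage points), `count`.
#' @export
ensemble_delta_bins <- function(logits_a, logits_b, labels, n_bins = 10L) {
  t_len <- nrow(logits_a$values)
  if (nrow(logits_b$values) != t_len) stop("run length mismatch")
  if (n_bins < 1L || n_bins > t_len) stop("invalid n_bins")
  gt <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  nrm <- sqrt(rowSums(logits_a$values^2))
  pa <- max.col(logits_a$values, ties.method = "first")
  pb <- max.col(logits_b$values, ties.method = "first")
  o <- order(nrm)
  bin <- logit_norm_bin_index(t_len, n_bins)
  acc_a <- as.numeric(tapply((pa == gt)[o], bin, mean)) * 100
  acc_b <- as.numeric(tapply((pb == gt)[o], bin, mean)) * 100
  data.frame(bin = seq_len(n_bins),
             mean_norm = as.numeric(tapply(nrm[o], bin, mean)),
             accuracy_a = acc_a, accuracy_b = acc_b, delta = acc_b - acc_a,
             count = as.integer(table(bin)))
}
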