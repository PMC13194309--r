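#' Temporal model configuration
#'
#' Hyperparameters of the MS-TCN++ segmentation model. The experiment grids
#' explored are `L` in {3, 5, 8, 12}, `S` in {2, 3, 5} and `lr` in
#' {1e-3, 1e-4, 1e-5}; the prediction-generation and refinement stages share
#' the layer count (`L_PG = L_R = L`).
#'
#' @param L Dilated layers per stage.
#' @param S Total stages: one prediction-generation stage plus `S - 1`
#'   refinement stages (so `S >= 2`).
#' @param lr Adam learning rate.
#' @param hidden_width Channels of every stage (the "feature size", default 128).
#' @param lambda_smooth Weight of the truncated-MSE smoothing loss (default 0.15).
#' @param tau Truncation threshold of the smoothing loss (default 4).
#' @param input_batchnorm Apply 1D batch normalization to the input features
#'   (default `FALSE`; performance is typically higher without it).
#' @param stride Frame subsampling stride applied before the model (default 1;
#'   2 halves sequence length, i.e. every 2nd frame).
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation frame accuracy.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(L = 5L, S = 2L, lr = 1e-3, hidden_width = 128L,
                         lambda_smooth = 0.15, tau = 4.0,
                         input_batchnorm = FALSE, stride = 1L,
                         epochs = 50L, patience = 5L, seed = 1L) {
  if (L < 1L) stop("L must be >= 1")
  if (S < 2L) stop("S must be >= 2 (prediction generation + >= 1 refinement)")
  if (hidden_width < 1L) stop("hidden_width must be >= 1")
  if (tau <= 0) stop("tau must be positive")
  if (lambda_smooth < 0) stop("lambda_smooth must be >= 0")
  if (stride < 1L) stop("stride must be >= 1")
  structure(list(L = as.integer(L), S = as.integer(S), lr = lr,
                 hidden_width = as.integer(hidden_width),
                 lambda_smooth = lambda_smooth, tau = tau,
                 input_batchnorm = isTRUE(input_batchnorm),
                 stride = as.integer(stride), epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# flat ordered parameter list; order must match src/mstcn.cpp
init_mstcn_params <- function(cfg, input_dim, n_classes) {
  h <- cfg$hidden_width
  params <- list()
  add <- function(p) params[[length(params) + 1L]] <<- p
  if (cfg$input_batchnorm) {
    add(matrix(1, input_dim, 1))   # gamma
    add(matrix(0, input_dim, 1))   # beta
  }
  add(he_init(h, input_dim, input_dim)); add(matrix(0, h, 1))
  for (l in seq_len(cfg$L)) {
    for (branch in 1:2) {
      for (tap in 1:3) add(he_init(h, h, 3 * h))
      add(matrix(0, h, 1))
    }
    add(he_init(h, 2 * h, 2 * h)); add(matrix(0, h, 1))
  }
  add(he_init(n_classes, h, h)); add(matrix(0, n_classes, 1))
  for (s in seq_len(cfg$S - 1L)) {
    add(he_init(h, n_classes, n_classes)); add(matrix(0, h, 1))
    for (l in seq_len(cfg$L)) {
      for (tap in 1:3) add(he_init(h, h, 3 * h))
      add(matrix(0, h, 1))
      add(he_init(h, h, h)); add(matrix(0, h, 1))
    }
    add(he_init(n_classes, h, h)); add(matrix(0, n_classes, 1))
  }
  params
}

#' Build an MS-TCN++ model
#'
#' Constructs the multi-stage temporal convolutional network: a
#' prediction-generation stage of `L` dual-dilated residual layers (layer `l`
#' runs two kernel-3 convolutions with dilations `2^l` and `2^(L-1-l)`, whose
#' concatenated outputs pass through a 1x1 convolution, ReLU and residual
#' add), followed by `S - 1` refinement stages that consume the softmax
#' probabilities of the previous stage through `L` kernel-3 dilated residual
#' layers (dilation `2^l`). Every stage emits frame-wise class logits through
#' a 1x1 output head. Weight initialization is deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @param input_dim Feature dimension D.
#' @param n_classes Number of classes C.
#' @param vocabulary Optional class names stored with the model.
#' @return An object of class `mstcn_pp`.
#' @export
build_mstcn_pp <- function(cfg, input_dim, n_classes,
                           vocabulary = gesture_vocabulary()) {
  stopifnot(inherits(cfg, "model_config"))
  if (input_dim < 1L || n_classes < 1L) stop("input_dim and n_classes must be >= 1")
  params <- withr::with_seed(cfg$seed,
                             init_mstcn_params(cfg, input_dim, n_classes))
  structure(list(cfg = cfg, input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes), params = params,
                 run_mean = rep(0, input_dim), run_var = rep(1, input_dim),
                 vocabulary = vocabulary, trained = FALSE, log = NULL),
            class = "mstcn_pp")
}

#' @export
print.mstcn_pp <- function(x, ...) {
  cat("<mstcn_pp> L=", x$cfg$L, " S=", x$cfg$S, " width=", x$cfg$hidden_width,
      " D=", x$input_dim, " C=", x$n_classes,
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

cpp_cfg <- function(model) {
  c(model$cfg[c("L", "S", "hidden_width", "lr", "lambda_smooth", "tau",
                "epochs", "patience")],
    list(n_classes = model$n_classes, input_dim = model$input_dim,
         input_batchnorm = model$cfg$input_batchnorm,
         run_mean = model$run_mean, run_var = model$run_var))
}

#' Run the model over a feature sequence
#'
#' Deterministic evaluation-mode forward pass.
#'
#' @param model An [build_mstcn_pp()] model.
#' @param features A [feature_sequence()] with `D = input_dim`.
#' @return List of `S` [logit_sequence()] objects, one per stage; the last
#'   element is the model's prediction output.
#' @export
predict_logits <- function(model, features) {
  stopifnot(inherits(model, "mstcn_pp"), inherits(features, "feature_sequence"))
  if (ncol(features$values) != model$input_dim) {
    stop("feature dimension ", ncol(features$values),
         " does not match model input_dim ", model$input_dim)
  }
  out <- cpp_mstcn_forward(model$params, cpp_cfg(model), t(features$values),
                           model$run_mean, model$run_var)
  lapply(out, logit_sequence, stride = features$stride)
}

#' Multi-stage segmentation loss
#'
#' Sum over stages of frame-mean cross-entropy plus `lambda_smooth` times the
#' truncated mean-squared difference of adjacent log-probabilities: the mean
#' over frames `t >= 2` and classes of `min(tau, |log p[t, c] -
#' log p[t-1, c]|)^2` (the previous frame is treated as constant for
#' gradients). The smoothing term discourages over-segmentation.
#'
#' @param stage_logits List of [logit_sequence()] objects (one per stage).
#' @param labels Ground-truth [label_sequence()] of matching length.
#' @param cfg A [model_config()] supplying `lambda_smooth` and `tau`.
#' @return Non-negative scalar loss.
#' @export
segmentation_loss <- function(stage_logits, labels, cfg = model_config()) {
  y <- if (inherits(labels, "label_sequence")) labels$labels else as.integer(labels)
  total <- 0
  for (sl in stage_logits) {
    v <- sl$values
    if (nrow(v) != length(y)) stop("stage logits and labels length mismatch")
    mx <- apply(v, 1L, max)
    logp <- v - mx - log(rowSums(exp(v - mx)))
    ce <- -mean(logp[cbind(seq_along(y), y)])
    tmse <- 0
    if (nrow(v) >= 2L) {
      d <- abs(logp[-1L, , drop = FALSE] - logp[-nrow(v), , drop = FALSE])
      tmse <- mean(pmin(cfg$tau, d)^2)
    }
    total <- total + ce + cfg$lambda_smooth * tmse
  }
  total
}

#' Train an MS-TCN++ model
#'
#' Adam optimization with one full video per step, iterating videos in the
#' given order each epoch. After each epoch the mean frame accuracy over the
#' validation videos is evaluated; training stops when it has failed to
#' improve for more than `cfg$patience` consecutive epochs, and the
#' best-validation parameters are returned. With no validation videos the
#' best (lowest) training loss plays the same role. Fully deterministic.
#'
#' @param model An [build_mstcn_pp()] model.
#' @param train_videos List of `list(features =, labels =)` pairs.
#' @param val_videos Same structure; may be empty.
#' @return The trained model; `$log` holds per-epoch training loss and
#'   validation accuracy, `$best_epoch` the selected epoch.
#' @export
train_mstcn <- function(model, train_videos, val_videos = list()) {
  stopifnot(inherits(model, "mstcn_pp"))
  if (length(train_videos) == 0L) stop("empty training set")
  prep <- function(v) {
    if (ncol(v$features$values) != model$input_dim) stop("feature dimension mismatch")
    t_f <- nrow(v$features$values)
    y <- if (inherits(v$labels, "label_sequence")) v$labels$labels else as.integer(v$labels)
    if (length(y) != t_f) stop("features and labels length mismatch")
    list(X = t(v$features$values), y = y - 1L)
  }
  tr <- lapply(train_videos, prep)
  va <- lapply(val_videos, prep)
  res <- cpp_mstcn_train(model$params, cpp_cfg(model),
                         lapply(tr, `[[`, "X"), lapply(tr, `[[`, "y"),
                         lapply(va, `[[`, "X"), lapply(va, `[[`, "y"))
  model$params <- res$params
  model$run_mean <- as.numeric(res$run_mean)
  model$run_var <- as.numeric(res$run_var)
  model$trained <- TRUE
  model$best_epoch <- res$best_epoch
  model$log <- data.frame(epoch = seq_along(res$train_loss),
                          train_loss = res$train_loss,
                          val_accuracy = res$val_accuracy)
  model
}

#' Receptive-field radius of the architecture
#'
#' Number of frames on each side of a frame that can influence its logits.
#' Each kernel-3 convolution of dilation d reaches d frames to each side; a
#' dual-dilated layer's two branches run in parallel, so it contributes the
#' larger of its two dilations. The radius is the sum over all layers of all
#' stages.
#'
#' @param cfg A [model_config()].
#' @return Integer radius in frames.
#' @export
receptive_field_radius <- function(cfg) {
  l <- 0:(cfg$L - 1L)
  pg <- sum(pmax(2^l, 2^(cfg$L - 1L - l)))
  as.integer(pg + (cfg$S - 1L) * (2^cfg$L - 1L))
}

#' Subsample frames at a fixed stride
#'
#' Keeps frames 0, `stride`, `2*stride`, ... and records the stride; long
#' operative videos are typically subsampled at stride 2 (every 2nd frame).
#'
#' @param x A [feature_sequence()] or [label_sequence()].
#' @param stride Integer step (>= 1).
#' @return Object of the same class.
#' @export
subsample_frames <- function(x, stride) {
  UseMethod("subsample_frames")
}

#' @export
subsample_frames.feature_sequence <- function(x, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride == 1L) return(x)
  keep <- seq(1L, nrow(x$values), by = stride)
  feature_sequence(x$values[keep, , drop = FALSE], x$modality,
                   stride = x$stride * stride)
}

#' @export
subsample_frames.label_sequence <- function(x, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride == 1L) return(x)
  x$labels <- x$labels[seq(1L, length(x$labels), by = stride)]
  x
}

#' Expand stride-s predictions back to the original frame rate
#'
#' Repeats each prediction `stride` times and truncates to `original_t`
#' frames, inverting [subsample_frames()] for metric computation at the
#' source frame rate.
#'
#' @param labels A [label_sequence()] predicted at a coarser stride.
#' @param stride The subsampling stride used.
#' @param original_t Original sequence length in frames.
#' @return A [label_sequence()] of length `original_t`.
#' @export
upsample_labels <- function(labels, stride, original_t) {
  stopifnot(inherits(labels, "label_sequence"))
  ids <- rep(labels$labels, each = stride)[seq_len(original_t)]
  label_sequence(ids, labels$vocabulary, labels$fps)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration, the
#' vocabulary, input dimensions and all parameters at full precision.
#'
#' @param model An [build_mstcn_pp()] model.
#' @param path Output `.json` path.
#' @return `path`, invisibly; `read_checkpoint()` returns the model.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mstcn_pp"))
  obj <- list(cfg = unclass(model$cfg), input_dim = model$input_dim,
              n_classes = model$n_classes, vocabulary = model$vocabulary,
              run_mean = model$run_mean, run_var = model$run_var,
              trained = model$trained,
              params = lapply(model$params, function(m) list(dim = dim(m),
                                                             data = as.numeric(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$cfg[setdiff(names(obj$cfg), character(0))])
  model <- build_mstcn_pp(cfg, obj$input_dim, obj$n_classes, obj$vocabulary)
  model$params <- lapply(seq_len(nrow(obj$params)), function(i) {
    matrix(obj$params$data[[i]], obj$params$dim[[i]][1], obj$params$dim[[i]][2])
  })
  model$run_mean <- obj$run_mean
  model$run_var <- obj$run_var
  model$trained <- isTRUE(obj$trained)
  model
}
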