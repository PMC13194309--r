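#' Enumerate leave-one-user-out folds
#'
#' One fold per ordered pair of distinct surgeons: one surgeon's videos form
#' the validation set, another's the test set, and the remainder the training
#' set, so five surgeons give 5 * 4 = 20 folds. Folds are ordered by
#' validation surgeon, then test surgeon.
#'
#' @param surgeons Character (or coercible) vector of distinct surgeon ids.
#' @return `data.frame` with columns `val` and `test`.
#' @export
make_louo_folds <- function(surgeons) {
  surgeons <- as.character(surgeons)
  if (anyDuplicated(surgeons)) stop("duplicate surgeon ids")
  if (length(surgeons) < 3L) {
    stop("need at least 3 surgeons (training set would be empty)")
  }
  s <- sort(surgeons)
  g <- expand.grid(test = s, val = s, stringsAsFactors = FALSE)
  g <- g[g$val != g$test, c("val", "test")]
  g <- g[order(g$val, g$test), , drop = FALSE]
  rownames(g) <- NULL
  g
}

resolve_cfg <- function(model_cfgs, name) {
  if (inherits(model_cfgs, "model_config")) return(model_cfgs)
  if (!is.null(model_cfgs[[name]])) return(model_cfgs[[name]])
  stop("no model_config supplied for '", name, "'")
}

#' Run the full LOUO experiment matrix
#'
#' For every fold, trains one MS-TCN++ per single modality and one on the
#' concatenated features; reports, per test video, the metrics of each
#' single-modality model, of the concatenated ("straightforward") model, and
#' of the logit-averaging ensemble (the single-modality models plus,
#' by default, the concatenated model, followed by neighbour-based
#' prediction smoothing). Per-(video, fold) values are retained so paired
#' significance tests can be run on the output. Fully seeded and
#' deterministic.
#'
#' @param videos List of per-video records: `id`, `surgeon`, `labels`
#'   (a [label_sequence()]), and `features` (named list of
#'   [feature_sequence()] per modality), e.g. [simulate_dataset()] videos
#'   passed through [prepare_modalities()].
#' @param modalities Modalities to use (default `c("tools","hands","video")`).
#' @param model_cfg A single [model_config()] used for every model, or a
#'   named list with one config per modality plus `"concat"`.
#' @param min_run Minimum interior run length for ensemble prediction
#'   smoothing (default 3 frames).
#' @param ensemble_with_concat Include the concatenated model in the ensemble
#'   (default `TRUE`).
#' @param seed Base seed; per-fold, per-model seeds are derived from it.
#' @param verbose Print per-fold progress.
#' @return List with `folds`, `per_video` (long data.frame: one row per test
#'   video x method with the six metrics) and `summary` (mean and sd across
#'   folds per method and metric).
#' @export
run_experiment <- function(videos, modalities = c("tools", "hands", "video"),
                           model_cfg = model_config(), min_run = 3L,
                           ensemble_with_concat = TRUE, seed = 1L,
                           verbose = FALSE) {
  if (length(videos) == 0L) stop("no videos supplied")
  for (v in videos) {
    if (!all(modalities %in% names(v$features))) {
      stop("video ", v$id, " is missing a requested modality")
    }
  }
  surgeons <- unique(vapply(videos, `[[`, "", "surgeon"))
  folds <- make_louo_folds(surgeons)
  model_names <- c(modalities, "concat")

  base_cfg <- resolve_cfg(model_cfg, model_names[1L])
  stride <- base_cfg$stride
  # subsample once; all model configs must share the stride
  prepped <- lapply(videos, function(v) {
    feats <- lapply(v$features[modalities], subsample_frames, stride = stride)
    feats$concat <- concat_modalities(unname(feats[modalities]))
    list(id = v$id, surgeon = v$surgeon,
         labels = subsample_frames(v$labels, stride), features = feats)
  })

  rows <- list()
  for (f in seq_len(nrow(folds))) {
    val_s <- folds$val[f]
    test_s <- folds$test[f]
    idx_test <- which(vapply(prepped, `[[`, "", "surgeon") == test_s)
    idx_val <- which(vapply(prepped, `[[`, "", "surgeon") == val_s)
    idx_train <- setdiff(seq_along(prepped), c(idx_test, idx_val))
    if (length(idx_test) == 0L) stop("fold with no test videos")

    test_logits <- list()  # model name -> list over test videos
    for (m in seq_along(model_names)) {
      name <- model_names[m]
      cfg <- resolve_cfg(model_cfg, name)
      if (cfg$stride != stride) stop("all model configs must share the stride")
      cfg$seed <- as.integer((seed + 7919 * f + 97 * m) %% .Machine$integer.max)
      pick <- function(i) list(features = prepped[[i]]$features[[name]],
                               labels = prepped[[i]]$labels)
      model <- build_mstcn_pp(cfg, ncol(prepped[[idx_train[1L]]]$features[[name]]$values),
                              length(videos[[1L]]$labels$vocabulary))
      model <- train_mstcn(model, lapply(idx_train, pick), lapply(idx_val, pick))
      test_logits[[name]] <- lapply(idx_test, function(i) {
        out <- predict_logits(model, prepped[[i]]$features[[name]])
        out[[length(out)]]
      })
    }

    members <- if (ensemble_with_concat) model_names else modalities
    for (j in seq_along(idx_test)) {
      gt <- prepped[[idx_test[j]]]$labels
      vid <- prepped[[idx_test[j]]]$id
      preds <- list()
      for (name in model_names) {
        preds[[name]] <- logits_to_labels(test_logits[[name]][[j]],
                                          gt$vocabulary, gt$fps)
      }
      ens_logits <- average_logits(lapply(members, function(n) test_logits[[n]][[j]]))
      preds$ensemble <- smooth_predictions(
        logits_to_labels(ens_logits, gt$vocabulary, gt$fps), min_run)
      for (method in names(preds)) {
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, val_surgeon = val_s, test_surgeon = test_s, video = vid,
          method = method, as.data.frame(metrics_report(preds[[method]], gt)))
      }
    }
    if (verbose) {
      message("fold ", f, "/", nrow(folds), " (val=", val_s,
              ", test=", test_s, ") done")
    }
  }
  per_video <- do.call(rbind, rows)
  methods <- unique(per_video$method)
  summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_video[per_video$method == m, , drop = FALSE]
    agg <- aggregate_folds(split(sub, sub$fold))
    cbind(method = m, agg)
  }))
  rownames(summary) <- NULL
  list(folds = folds, per_video = per_video, summary = summary)
}

#' Paired comparison of two methods across folds
#'
#' Pairs the per-(video, fold) metric values of two methods from a
#' [run_experiment()] result -- one pair for each video and each fold in
#' which that video sits in the test set -- and applies the Wilcoxon
#' signed-rank test to every metric.
#'
#' @param result A [run_experiment()] result.
#' @param method_a,method_b Method names as they appear in
#'   `result$per_video$method` (e.g. `"ensemble"`, `"video"`).
#' @param alternative `"greater"` (a tends to beat b) or `"two_sided"`.
#' @return `data.frame` with one row per metric: statistic, p-value, n pairs.
#' @export
compare_methods <- function(result, method_a, method_b,
                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  pv <- result$per_video
  a <- pv[pv$method == method_a, , drop = FALSE]
  b <- pv[pv$method == method_b, , drop = FALSE]
  key <- function(d) paste(d$video, d$fold)
  b <- b[match(key(a), key(b)), , drop = FALSE]
  metrics <- c("accuracy", "edit", "f1_macro", "f1_10", "f1_25", "f1_50")
  do.call(rbind, lapply(metrics, function(m) {
    w <- tryCatch(wilcoxon_signed_rank(a[[m]], b[[m]], alternative),
                  error = function(e) list(statistic = NA_real_,
                                           p_value = NA_real_, n = 0L,
                                           method = "degenerate"))
    data.frame(metric = m, statistic = w$statistic, p_value = w$p_value,
               n = w$n, method = w$method)
  }))
}
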