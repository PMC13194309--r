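test_that("model config enforces the architecture invariants", {
  expect_error(model_config(S = 1), "S must be")
  expect_error(model_config(L = 0), "L must be")
  expect_error(model_config(tau = 0), "tau")
  expect_error(model_config(lambda_smooth = -1), "lambda")
  cfg <- model_config(L = 3, S = 2)
  expect_s3_class(cfg, "model_config")
})

test_that("forward pass honours shape and determinism contracts across the grid", {
  set.seed(2)
  t_len <- 50L
  fs <- feature_sequence(matrix(rnorm(t_len * 16), t_len, 16), "concat")
  for (spec in list(c(3, 2), c(5, 3), c(3, 5))) {
    cfg <- model_config(L = spec[1], S = spec[2], hidden_width = 8, seed = 4)
    m <- build_mstcn_pp(cfg, 16, 4)
    out <- predict_logits(m, fs)
    expect_length(out, spec[2])
    for (sl in out) expect_identical(dim(sl$values), c(t_len, 4L))
  }
  cfg <- model_config(L = 3, S = 2, hidden_width = 8, seed = 4)
  m <- build_mstcn_pp(cfg, 16, 4)
  a <- predict_logits(m, fs)
  b <- predict_logits(m, fs)
  expect_identical(a[[2]]$values, b[[2]]$values)
})

test_that("all-zero parameters give constant logits and uniform probabilities", {
  cfg <- model_config(L = 3, S = 2, hidden_width = 8, seed = 1)
  m <- build_mstcn_pp(cfg, 5, 4)
  m$params <- lapply(m$params, function(p) p * 0)
  fs <- feature_sequence(matrix(rnorm(30 * 5), 30, 5), "video")
  out <- predict_logits(m, fs)
  for (sl in out) {
    expect_equal(max(abs(sl$values)), 0)
    p <- exp(sl$values) / rowSums(exp(sl$values))
    expect_equal(p, matrix(0.25, 30, 4), ignore_attr = TRUE)
  }
})

test_that("perturbations beyond the receptive field leave logits unchanged", {
  set.seed(11)
  cfg <- model_config(L = 3, S = 2, hidden_width = 8, seed = 6)
  radius <- receptive_field_radius(cfg)  # 10 + 7 for L=3, S=2
  expect_identical(radius, as.integer(sum(pmax(2^(0:2), 2^(2:0))) + 7))
  t_len <- 2L * radius + 41L
  X <- matrix(rnorm(t_len * 6), t_len, 6)
  m <- build_mstcn_pp(cfg, 6, 4)
  base <- predict_logits(m, feature_sequence(X, "video"))[[2]]$values
  mid <- radius + 21L
  X2 <- X
  X2[mid + radius + 1L, ] <- X2[mid + radius + 1L, ] + 100
  X2[mid - radius - 1L, ] <- X2[mid - radius - 1L, ] - 50
  pert <- predict_logits(m, feature_sequence(X2, "video"))[[2]]$values
  expect_equal(pert[mid, ], base[mid, ], tolerance = 1e-10)
  # and a perturbation inside the field does change the frame
  X3 <- X
  X3[mid + 1L, ] <- X3[mid + 1L, ] + 100
  pert3 <- predict_logits(m, feature_sequence(X3, "video"))[[2]]$values
  expect_gt(max(abs(pert3[mid, ] - base[mid, ])), 1e-6)
})

test_that("segmentation loss matches closed forms", {
  t_len <- 20
  y <- label_sequence(rep(c(1, 2, 3, 4), 5))
  cfg <- model_config(lambda_smooth = 0.15, tau = 4)

  # uniform logits: cross-entropy = ln(4) per stage, smoothing term 0
  zero <- logit_sequence(matrix(0, t_len, 4))
  expect_equal(segmentation_loss(list(zero), y, cfg), log(4), tolerance = 1e-12)
  expect_equal(segmentation_loss(list(zero, zero), y, cfg), 2 * log(4),
               tolerance = 1e-12)

  # time-constant logits: truncated MSE is exactly 0
  const <- logit_sequence(matrix(rep(c(3, 1, -2, 0), each = t_len), t_len, 4))
  cfg0 <- model_config(lambda_smooth = 0)
  ce_only <- segmentation_loss(list(const), y, cfg0)
  expect_equal(segmentation_loss(list(const), y, cfg), ce_only, tolerance = 1e-12)

  # a jump of 10 in adjacent log-probabilities is truncated at tau^2 = 16
  v <- matrix(0, 2, 2)
  v[2, ] <- c(10, 0)  # logp difference roughly (5, -5) -> both clipped at 4
  lg <- logit_sequence(v)
  y2 <- label_sequence(c(1, 1), vocabulary = c("a", "b"))
  cfgt <- model_config(lambda_smooth = 1, tau = 4)
  mx <- apply(v, 1, max)
  logp <- v - mx - log(rowSums(exp(v - mx)))
  d <- abs(logp[2, ] - logp[1, ])
  expected_tmse <- mean(pmin(4, d)^2)
  ce <- -mean(logp[cbind(1:2, c(1, 1))])
  expect_equal(segmentation_loss(list(lg), y2, cfgt), ce + expected_tmse,
               tolerance = 1e-12)
  expect_true(any(d > 4))  # the clip is active
  expect_equal(pmin(4, d[d > 4])^2, rep(16, sum(d > 4)))
})

test_that("loss is invariant under consistent class relabeling", {
  set.seed(14)
  t_len <- 30
  v <- matrix(rnorm(t_len * 4), t_len, 4)
  y <- sample(1:4, t_len, replace = TRUE)
  cfg <- model_config()
  perm <- c(3, 1, 4, 2)
  l1 <- segmentation_loss(list(logit_sequence(v)), label_sequence(y), cfg)
  l2 <- segmentation_loss(list(logit_sequence(v[, order(perm)])),
                          label_sequence(perm[y]), cfg)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("training reduces loss on separable data and is reproducible", {
  set.seed(33)
  t_len <- 300
  y <- random_label_ids(t_len, 4, min_run = 8)
  protos <- matrix(rnorm(4 * 10, sd = 3), 4, 10)
  X <- protos[y, ] + matrix(rnorm(t_len * 10, sd = 0.3), t_len, 10)
  vids <- list(list(features = feature_sequence(X, "video"),
                    labels = label_sequence(y)))
  cfg <- model_config(L = 3, S = 2, hidden_width = 16, lr = 1e-3,
                      epochs = 5, patience = 10, seed = 8)
  m <- build_mstcn_pp(cfg, 10, 4)
  m1 <- train_mstcn(m, vids)
  expect_lte(min(m1$log$train_loss), m1$log$train_loss[1])
  expect_lt(m1$log$train_loss[5], m1$log$train_loss[1])

  m2 <- train_mstcn(build_mstcn_pp(cfg, 10, 4), vids)
  expect_identical(m1$log, m2$log)
  expect_equal(m1$params, m2$params)

  expect_error(train_mstcn(m, list()), "empty training set")
})

test_that("early stopping halts after patience non-improving epochs", {
  set.seed(40)
  t_len <- 100
  y <- random_label_ids(t_len, 4, min_run = 5)
  X <- matrix(rnorm(t_len * 6), t_len, 6)  # pure noise: no real improvement
  vids <- list(list(features = feature_sequence(X, "video"),
                    labels = label_sequence(y)))
  val <- list(list(features = feature_sequence(matrix(rnorm(t_len * 6), t_len, 6), "video"),
                   labels = label_sequence(random_label_ids(t_len, 4, min_run = 5))))
  cfg <- model_config(L = 2, S = 2, hidden_width = 4, lr = 1e-5,
                      epochs = 50, patience = 0, seed = 2)
  m <- train_mstcn(build_mstcn_pp(cfg, 6, 4), vids, val)
  # stops at the first epoch that fails to improve validation accuracy
  first_bad <- which(diff(c(-Inf, cummax(m$log$val_accuracy))) == 0)[1]
  expect_identical(nrow(m$log), first_bad)
})

test_that("input batch normalization is frozen in evaluation and guards zero variance", {
  set.seed(17)
  t_len <- 60
  X <- matrix(rnorm(t_len * 5), t_len, 5)
  X[, 3] <- 1  # zero-variance feature
  y <- random_label_ids(t_len, 4)
  cfg <- model_config(L = 2, S = 2, hidden_width = 4, epochs = 2,
                      input_batchnorm = TRUE, seed = 5)
  m <- build_mstcn_pp(cfg, 5, 4)
  m <- train_mstcn(m, list(list(features = feature_sequence(X, "video"),
                                labels = label_sequence(y))))
  out1 <- predict_logits(m, feature_sequence(X, "video"))
  out2 <- predict_logits(m, feature_sequence(X, "video"))
  expect_identical(out1[[2]]$values, out2[[2]]$values)
  expect_true(all(is.finite(out1[[2]]$values)))
})

test_that("frame subsampling keeps every stride-th frame and inverts approximately", {
  fs <- feature_sequence(matrix(1:14, 7, 2), "video")
  expect_identical(subsample_frames(fs, 1), fs)
  s2 <- subsample_frames(fs, 2)
  expect_identical(nrow(s2$values), 4L)  # frames 0,2,4,6
  expect_identical(s2$values[, 1], c(1, 3, 5, 7))
  expect_identical(s2$stride, 2L)
  expect_error(subsample_frames(fs, 0), "stride")

  ls <- label_sequence(c(1, 1, 2, 2, 3, 3, 4))
  d <- subsample_frames(ls, 2)
  expect_identical(d$labels, c(1L, 2L, 3L, 4L))
  up <- upsample_labels(d, 2, 7)
  expect_identical(length(up$labels), 7L)

  # exhaustive: all 4-class sequences of length <= 8 with min run 2 keep
  # >= 50% frame agreement after a stride-2 round trip
  seqs <- list()
  gen <- function(prefix, remaining) {
    if (remaining == 0) { seqs[[length(seqs) + 1L]] <<- prefix; return() }
    if (remaining < 2) return()
    for (c in 1:4) {
      for (run in 2:remaining) gen(c(prefix, rep(c, run)), remaining - run)
    }
  }
  for (t_len in c(4, 6, 7, 8)) gen(integer(0), t_len)
  for (s in seqs) {
    ls <- label_sequence(s)
    rt <- upsample_labels(subsample_frames(ls, 2), 2, length(s))
    expect_gte(mean(rt$labels == s), 0.5)
  }
})

test_that("checkpoints round-trip through JSON", {
  cfg <- model_config(L = 2, S = 2, hidden_width = 4, seed = 9)
  m <- build_mstcn_pp(cfg, 6, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, f)
  m2 <- read_checkpoint(f)
  expect_equal(m2$params, m$params)
  fs <- feature_sequence(matrix(rnorm(60), 10, 6), "video")
  expect_equal(predict_logits(m2, fs)[[2]]$values,
               predict_logits(m, fs)[[2]]$values)
})

test_that("dimension mismatches are rejected", {
  cfg <- model_config(L = 2, S = 2, hidden_width = 4)
  m <- build_mstcn_pp(cfg, 6, 4)
  expect_error(predict_logits(m, feature_sequence(matrix(0, 5, 7), "video")),
               "does not match")
  expect_error(build_mstcn_pp(cfg, 0, 4), ">= 1")
})
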