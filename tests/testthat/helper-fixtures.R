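# Shared fixture builders; everything is generated in code.

# smooth, frame-to-frame consistent rotation track about a fixed axis
make_smooth_rotation_track <- function(t_len = 40, axis = c(0, 0, 1),
                                       step = 0.05, detected = rep(TRUE, t_len)) {
  ang <- cumsum(rep(step, t_len))
  rot <- t(vapply(ang, function(a) quat_from_axis_angle(axis, a), numeric(4)))
  rigid_pose_track(matrix(0, t_len, 3), rot, detected)
}

# corrupt each frame independently with a random element of the symmetry group
flip_corrupt <- function(track, flip_mask,
                         s = tool_symmetry_group()[2L, ]) {
  for (t in which(flip_mask)) {
    track$rotations[t, ] <- quat_multiply(track$rotations[t, ], s)
  }
  track
}

make_hand_track <- function(t_len = 20, detected = matrix(TRUE, t_len, 2)) {
  joints <- array(0, dim = c(t_len, 2, 21, 3))
  for (h in 1:2) {
    for (a in 1:3) {
      joints[, h, , a] <- outer(seq_len(t_len) / t_len, seq_len(21) * 0.1)
    }
  }
  hand_joint_track(joints, detected)
}

random_label_ids <- function(t_len, n_classes = 4, min_run = 1) {
  ids <- integer(0)
  while (length(ids) < t_len) {
    len <- sample(min_run:max(min_run, 5), 1)
    ids <- c(ids, rep(sample.int(n_classes, 1), len))
  }
  ids[seq_len(t_len)]
}

# independent naive segmental-overlap F1 (loop-over-everything style)
naive_f1_at_k <- function(pred_ids, gt_ids, k) {
  seg <- function(v) {
    r <- rle(v)
    e <- cumsum(r$lengths)
    list(cls = r$values, s = e - r$lengths, e = e)
  }
  p <- seg(pred_ids); g <- seg(gt_ids)
  used <- rep(FALSE, length(g$cls))
  tp <- 0; fp <- 0
  for (i in seq_along(p$cls)) {
    best <- 0; best_j <- 0
    for (j in seq_along(g$cls)) {
      if (used[j] || g$cls[j] != p$cls[i]) next
      inter <- max(0, min(p$e[i], g$e[j]) - max(p$s[i], g$s[j]))
      uni <- max(p$e[i], g$e[j]) - min(p$s[i], g$s[j])
      iou <- inter / uni
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0 && best >= k) { tp <- tp + 1; used[best_j] <- TRUE }
    else fp <- fp + 1
  }
  fn <- sum(!used)
  if (2 * tp + fp + fn == 0) 100 else 100 * 2 * tp / (2 * tp + fp + fn)
}

# plain matrix-DP Levenshtein oracle on segment class strings
naive_edit_score <- function(pred_ids, gt_ids) {
  a <- rle(pred_ids)$values
  b <- rle(gt_ids)$values
  n <- length(a); m <- length(b)
  dp <- matrix(0, n + 1, m + 1)
  dp[, 1] <- 0:n
  dp[1, ] <- 0:m
  for (i in 1:n) for (j in 1:m) {
    dp[i + 1, j + 1] <- min(dp[i, j + 1] + 1, dp[i + 1, j] + 1,
                            dp[i, j] + (a[i] != b[j]))
  }
  max(0, 100 * (1 - dp[n + 1, m + 1] / max(n, m)))
}

# exact Wilcoxon p by enumerating all 2^n sign assignments (tie-free ranks)
enumerate_wilcoxon_p <- function(d, alternative = "greater") {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

# tiny in-memory dataset for experiment harness tests
make_tiny_experiment_videos <- function(n_surgeons = 3, videos_per_surgeon = 1,
                                        cycles = 2, snr = 8, seed = 5) {
  cfg <- simulator_config(n_surgeons = n_surgeons,
                          videos_per_surgeon = videos_per_surgeon,
                          cycles_per_video = cycles,
                          mean_durations = c(entering = 20, gripping = 10,
                                             passing = 14, other = 25),
                          snr = snr, seed = seed)
  ds <- simulate_dataset(cfg)
  pcfg <- preprocess_config(savgol_window = 5)
  lapply(ds$videos, function(v) {
    list(id = v$id, surgeon = v$surgeon, labels = v$labels,
         features = prepare_modalities(v, pcfg))
  })
}
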