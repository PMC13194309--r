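test_that("quaternion helpers satisfy basic rotation algebra", {
  qy <- quat_from_axis_angle(c(0, 1, 0), pi)
  expect_equal(quat_rotate(qy, c(1, 2, 3))[1, ], c(-1, 2, -3), tolerance = 1e-12)
  # x-flip composed with z-flip equals the y-flip as a global rotation
  qxz <- quat_multiply(quat_from_axis_angle(c(1, 0, 0), pi),
                       quat_from_axis_angle(c(0, 0, 1), pi))
  expect_equal(quat_to_matrix(qxz), quat_to_matrix(qy), tolerance = 1e-12)
  # geodesic angle of a known rotation
  q1 <- quat_from_axis_angle(c(0, 0, 1), 0.3)
  q2 <- quat_from_axis_angle(c(0, 0, 1), 1.1)
  expect_equal(quat_geodesic(q1, q2), 0.8, tolerance = 1e-12)
})

test_that("rotation disambiguation corrects isolated symmetry flips", {
  tr <- make_smooth_rotation_track(8)
  expect_equal(disambiguate_tool_rotations(tr)$rotations, tr$rotations)

  # constant rotation except frame 5 stored flipped
  q <- quat_from_axis_angle(c(1, 1, 0), 0.4)
  rot <- matrix(q, 8, 4, byrow = TRUE)
  corrupted <- rot
  corrupted[5, ] <- quat_multiply(q, tool_symmetry_group()[2, ])
  trc <- rigid_pose_track(matrix(0, 8, 3), corrupted, rep(TRUE, 8))
  fixed <- disambiguate_tool_rotations(trc)
  expect_equal(abs(sum(fixed$rotations[5, ] * q)), 1, tolerance = 1e-9)

  # single frame untouched; empty / identity-free symmetry sets rejected
  tr1 <- make_smooth_rotation_track(1)
  expect_equal(disambiguate_tool_rotations(tr1)$rotations, tr1$rotations)
  expect_error(disambiguate_tool_rotations(tr, matrix(numeric(0), 0, 4)),
               "non-empty")
  expect_error(disambiguate_tool_rotations(tr, tool_symmetry_group()[2, , drop = FALSE]),
               "identity")
})

test_that("greedy disambiguation matches brute-force minimal geodesic path", {
  # enumerate all 2^T symmetry assignments on a short corrupted track and
  # minimize the summed geodesic path; the greedy result must match
  set.seed(21)
  t_len <- 8
  tr <- make_smooth_rotation_track(t_len, step = 0.07)
  flip <- sample(c(TRUE, FALSE), t_len, replace = TRUE)
  corrupted <- flip_corrupt(tr, flip)
  s2 <- tool_symmetry_group()[2, ]
  grids <- expand.grid(rep(list(c(0, 1)), t_len - 1))
  best_cost <- Inf
  best_assign <- NULL
  for (g in seq_len(nrow(grids))) {
    assign <- c(0, as.numeric(grids[g, ]))
    qs <- corrupted$rotations
    for (t in which(assign == 1)) qs[t, ] <- quat_multiply(qs[t, ], s2)
    cost <- sum(vapply(2:t_len, function(t) quat_geodesic(qs[t - 1, ], qs[t, ]),
                       1.0))
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_assign <- qs }
  }
  greedy <- disambiguate_tool_rotations(corrupted)
  for (t in 1:t_len) {
    expect_equal(abs(sum(greedy$rotations[t, ] * best_assign[t, ])), 1,
                 tolerance = 1e-9)
  }
})

test_that("flip-recovery property: corrupted smooth tracks are restored up to a global flip", {
  s2 <- tool_symmetry_group()[2, ]
  ok <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    t_len <- 30
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    tr <- make_smooth_rotation_track(t_len, axis = axis, step = runif(1, 0.02, 0.1))
    flip <- runif(t_len) < 0.3
    fixed <- disambiguate_tool_rotations(flip_corrupt(tr, flip))
    # compare to original up to one global symmetry element
    agree_id <- all(vapply(1:t_len, function(t)
      abs(sum(fixed$rotations[t, ] * tr$rotations[t, ])), 1.0) > 1 - 1e-6)
    flipped_all <- t(apply(tr$rotations, 1, function(q) quat_multiply(q, s2)))
    agree_flip <- all(vapply(1:t_len, function(t)
      abs(sum(fixed$rotations[t, ] * flipped_all[t, ])), 1.0) > 1 - 1e-6)
    if (agree_id || agree_flip) ok <- ok + 1L
  }
  expect_identical(ok, 100L)
})

test_that("LOCF fills gaps up to the limit and never touches detected frames", {
  t_len <- 40
  det <- rep(TRUE, t_len)
  det[6:15] <- FALSE   # gap of exactly 10
  det[20:30] <- FALSE  # gap of 11
  tr <- make_smooth_rotation_track(t_len, detected = det)
  tr$positions <- matrix(seq_len(t_len), t_len, 3)
  out <- impute_locf(tr, 10)
  expect_true(all(out$imputed[6:15]))
  expect_equal(out$positions[6:15, 1], rep(5, 10))
  expect_equal(out$rotations[10, ], tr$rotations[5, ])
  expect_false(any(out$imputed[20:30]))
  # detected frames untouched
  expect_equal(out$positions[det, ], tr$positions[det, ])

  # fully detected track is unchanged
  tr2 <- make_smooth_rotation_track(10)
  expect_equal(impute_locf(tr2, 10), tr2)

  # leading gap stays missing
  det3 <- rep(TRUE, 10); det3[1:3] <- FALSE
  tr3 <- make_smooth_rotation_track(10, detected = det3)
  out3 <- impute_locf(tr3, 10)
  expect_false(any(out3$imputed[1:3]))

  # all-missing track unchanged
  tr4 <- make_smooth_rotation_track(5, detected = rep(FALSE, 5))
  expect_equal(impute_locf(tr4, 10), tr4)
})

test_that("linear interpolation fills interior gaps only, up to the limit", {
  t_len <- 30
  det <- matrix(TRUE, t_len, 2)
  det[2:3, 1] <- FALSE
  tr <- make_hand_track(t_len, det)
  tr$joints[1, 1, 1, 1] <- 0
  tr$joints[4, 1, 1, 1] <- 3
  out <- interpolate_gaps_linear(tr, 10)
  expect_equal(out$joints[2, 1, 1, 1], 1, tolerance = 1e-12)
  expect_equal(out$joints[3, 1, 1, 1], 2, tolerance = 1e-12)
  expect_true(all(out$imputed[2:3, 1]))

  # gap of 11 with limit 10 untouched
  det2 <- matrix(TRUE, t_len, 2)
  det2[5:15, 2] <- FALSE
  tr2 <- make_hand_track(t_len, det2)
  out2 <- interpolate_gaps_linear(tr2, 10)
  expect_false(any(out2$imputed[5:15, 2]))

  # boundary gap untouched even when short
  det3 <- matrix(TRUE, t_len, 2)
  det3[(t_len - 2):t_len, 1] <- FALSE
  out3 <- interpolate_gaps_linear(make_hand_track(t_len, det3), 10)
  expect_false(any(out3$imputed[, 1]))

  # no gaps: identity
  tr4 <- make_hand_track(10)
  expect_equal(interpolate_gaps_linear(tr4, 10), tr4)
})

test_that("Savitzky-Golay smoothing is exact on quadratics and reduces noise", {
  cfg <- preprocess_config(savgol_window = 9, savgol_order = 2)
  t_len <- 60
  tt <- seq_len(t_len)
  quad <- cbind(1 + 0.5 * tt - 0.01 * tt^2, 2 - 0.2 * tt + 0.003 * tt^2, 0.1 * tt)
  tr <- make_smooth_rotation_track(t_len)
  tr$positions <- quad
  out <- smooth_savitzky_golay(tr, cfg)
  interior <- 5:(t_len - 4)
  expect_equal(out$positions[interior, ], quad[interior, ], tolerance = 1e-9)

  # constant signal unchanged
  trc <- make_smooth_rotation_track(20)
  trc$positions <- matrix(3, 20, 3)
  expect_equal(smooth_savitzky_golay(trc, cfg)$positions,
               trc$positions, tolerance = 1e-12)

  # white noise variance shrinks
  set.seed(9)
  trn <- make_smooth_rotation_track(200)
  trn$positions <- matrix(rnorm(600), 200, 3)
  outn <- smooth_savitzky_golay(trn, cfg)
  expect_lt(var(outn$positions[, 1]), var(trn$positions[, 1]))

  # quaternions stay unit and short spans pass through
  expect_equal(sqrt(rowSums(out$rotations^2)), rep(1, t_len), tolerance = 1e-9)
  det <- rep(TRUE, 20); det[8:20] <- FALSE
  short <- make_smooth_rotation_track(20, detected = det)
  outs <- smooth_savitzky_golay(short, cfg)
  expect_equal(outs$positions, short$positions)
})

test_that("smoothing handles quaternion sign flips without jumps", {
  t_len <- 30
  tr <- make_smooth_rotation_track(t_len, step = 0.04)
  tr$rotations[10:20, ] <- -tr$rotations[10:20, ]  # same rotations, flipped sign
  out <- smooth_savitzky_golay(tr, preprocess_config())
  ref <- smooth_savitzky_golay(make_smooth_rotation_track(t_len, step = 0.04),
                               preprocess_config())
  for (t in 1:t_len) {
    expect_equal(abs(sum(out$rotations[t, ] * ref$rotations[t, ])), 1,
                 tolerance = 1e-9)
  }
})

test_that("tool augmentation flips whole videos rigidly and is seeded", {
  t_len <- 12
  tr <- make_smooth_rotation_track(t_len, step = 0.06)
  tr$positions <- matrix(rnorm(3 * t_len), t_len, 3)

  # sigma 0 and flip probability 0: identity
  cfg0 <- preprocess_config(tool_noise_sigma = 0, flip_probability = 0)
  expect_equal(augment_tool_pose(tr, cfg0, seed = 1), tr)

  # forced flips: positions follow Ry(180) = diag(-1, 1, -1)
  cfg1 <- preprocess_config(tool_noise_sigma = 0, flip_probability = 1)
  out <- augment_tool_pose(tr, cfg1, seed = 1)
  # both flips applied; their composition is the identity rotation globally
  expect_equal(out$positions, tr$positions, tolerance = 1e-9)

  tr13 <- tr
  tr13$positions <- matrix(c(1, 2, 3), 1, 3)
  tr13$rotations <- tr$rotations[1, , drop = FALSE]
  tr13$detected <- TRUE
  tr13$imputed <- FALSE
  # a single y-flip on position (1,2,3) gives (-1,2,-3)
  qy <- quat_from_axis_angle(c(0, 1, 0), pi)
  expect_equal(quat_rotate(qy, c(1, 2, 3))[1, ], c(-1, 2, -3))

  # determinism and rigidity: inter-frame geodesics preserved before noise
  cfg2 <- preprocess_config(tool_noise_sigma = 0, flip_probability = 0.5)
  a <- augment_tool_pose(tr, cfg2, seed = 7)
  b <- augment_tool_pose(tr, cfg2, seed = 7)
  expect_equal(a, b)
  rel <- function(x) vapply(2:t_len, function(t)
    quat_geodesic(x$rotations[t - 1, ], x$rotations[t, ]), 1.0)
  expect_equal(rel(a), rel(tr), tolerance = 1e-9)
})

test_that("hand augmentation is a seeded rigid rotation of all joints", {
  tr <- make_hand_track(10)
  cfg <- preprocess_config()
  a <- augment_hand_pose(tr, cfg, seed = 3)
  b <- augment_hand_pose(tr, cfg, seed = 3)
  expect_equal(a, b)
  # pairwise inter-joint distances preserved
  d0 <- dist(tr$joints[5, 1, , ])
  d1 <- dist(a$joints[5, 1, , ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(a$joints, tr$joints)))
})

test_that("track flattening yields the documented feature layout", {
  t_len <- 6L
  tr1 <- make_smooth_rotation_track(t_len)
  tr2 <- make_smooth_rotation_track(t_len)
  fs <- tracks_to_features(tools = list(b_tool = tr2, a_tool = tr1),
                           modality = "tools")
  expect_identical(ncol(fs$values), 16L)  # 2 tools x (3 + 4 + 1)
  expect_identical(nrow(fs$values), t_len)

  # missing-and-unimputed frame is zero-filled with validity 0
  det <- rep(TRUE, t_len); det[3] <- FALSE
  trm <- make_smooth_rotation_track(t_len, detected = det)
  fsm <- tracks_to_features(tools = list(t = trm), modality = "tools")
  expect_equal(fsm$values[3, ], rep(0, 8))
  expect_equal(fsm$values[2, 8], 1)

  hands <- make_hand_track(t_len)
  fh <- tracks_to_features(hands = hands, modality = "hands")
  expect_identical(ncol(fh$values), 128L)  # 126 coordinates + 2 flags
  fh2 <- tracks_to_features(hands = hands, modality = "hands",
                            include_validity = FALSE)
  expect_identical(ncol(fh2$values), 126L)

  expect_error(tracks_to_features(tools = list(a = tr1,
                                               b = make_smooth_rotation_track(3)),
                                  modality = "tools"), "share length")
})

test_that("preprocess config validates filter parameters", {
  expect_error(preprocess_config(savgol_window = 8), "odd")
  expect_error(preprocess_config(savgol_window = 3, savgol_order = 3), "odd|greater")
  expect_error(preprocess_config(max_gap_frames = -1), "max_gap")
})
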