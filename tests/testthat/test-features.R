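test_that("cornerness is zero on constant images and step edges", {
  expect_true(all(shi_tomasi_score_map(matrix(0.5, 20, 20)) == 0))
  edge <- matrix(0, 20, 20)
  edge[, 11:20] <- 1  # vertical step: rank-1 structure tensor
  score <- shi_tomasi_score_map(edge)
  expect_lt(max(score[5:16, 5:16]), 1e-10)
  expect_error(shi_tomasi_score_map(matrix(0, 4, 4)), class = "tv_degenerate_error")
})

test_that("cornerness equals the eigendecomposition oracle", {
  # checkerboard corner: a genuinely 2-D structure
  img <- matrix(0, 15, 15)
  img[1:7, 1:7] <- 1
  img[8:15, 8:15] <- 1
  score <- shi_tomasi_score_map(img, window = 5)
  expect_equal(score[8, 8], brute_min_eig(img, 8, 8, 5), tolerance = 1e-10)
  expect_gt(score[8, 8], 0)

  set.seed(21)
  for (rep in 1:50) {
    img <- matrix(runif(225), 15, 15)
    score <- shi_tomasi_score_map(img, window = 5)
    r <- sample(5:11, 1)
    c <- sample(5:11, 1)
    expect_equal(score[r, c], brute_min_eig(img, r, c, 5), tolerance = 1e-8)
  }
  expect_true(all(score >= 0))
})

test_that("feature selection ranks, masks and spaces candidates", {
  score <- matrix(0, 40, 40)
  score[10, 10] <- 5
  score[10, 30] <- 3
  score[30, 10] <- 4
  roi <- rect_roi(0, 0, 40, 40)
  top2 <- select_features(score, roi, max_n = 2, min_dist = 3)
  expect_equal(nrow(top2), 2)
  expect_equal(sort(top2$score), c(4, 5))

  # a peak inside the exclusion rectangle is never returned
  excl <- rect_roi(8, 8, 5, 5)
  kept <- select_features(score, roi, exclusion = excl, max_n = 10, min_dist = 3)
  expect_false(any(kept$x == 9 & kept$y == 9))

  # greedy suppression enforces the minimum pairwise distance
  set.seed(3)
  dense <- matrix(runif(1600), 40, 40)
  pts <- select_features(dense, roi, max_n = 50, min_dist = 5)
  d <- as.matrix(dist(pts[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 5)
  expect_lte(nrow(pts), 50)

  expect_error(select_features(matrix(0, 40, 40), roi), class = "tv_feature_error")
})

test_that("tracking is exact on a static scene and follows commanded motion", {
  sc <- cached_scene("static64", rows = 64, cols = 64, duration = 4,
                     bcg_amp_px = 0, nostril_amp_k = 0, noise_sd_k = 0, seed = 9)
  pp <- preprocess_video(sc$video)
  seeds <- select_features(shi_tomasi_score_map(pp$frames[1, , ]),
                           test_face_roi(), max_n = 15)
  tr <- track_features(pp$frames, seeds, 50)
  disp <- sqrt((tr$positions[, , 1] - tr$positions[, 1, 1])^2 +
               (tr$positions[, , 2] - tr$positions[, 1, 2])^2)
  expect_lt(max(disp), 0.02)
})

test_that("tracking recovers a sub-pixel vertical sinusoid below 0.05 px RMS", {
  sc <- cached_scene("sine64", rows = 64, cols = 64, duration = 6,
                     hr_bpm = 70, bcg_amp_px = 0.3, noise_sd_k = 0, seed = 4)
  pp <- preprocess_video(sc$video)
  seeds <- select_features(shi_tomasi_score_map(pp$frames[1, , ]),
                           test_face_roi(), max_n = 20)
  tr <- track_features(pp$frames, seeds, 50)
  vt <- vertical_trajectories(tr)
  t_s <- (seq_len(nrow(vt$mat)) - 1) / 50
  cmd <- 0.3 * sin(2 * pi * 70 / 60 * t_s)
  cmd <- cmd - mean(cmd)
  rms <- apply(vt$mat, 2, function(col) sqrt(mean((col - cmd)^2)))
  expect_lt(median(rms), 0.05)
})

test_that("sub-pixel accuracy holds across amplitudes 0.1 to 2 px", {
  # rigid vertical translation of a textured template, rendered directly
  set.seed(31)
  tmpl <- matrix(runif(64 * 64), 64, 64)
  tmpl <- 0.2 + 0.6 * (tmpl + tmpl[c(1, 1:63), ] + tmpl[, c(1, 1:63)]) / 3
  for (amp in c(0.1, 0.5, 2)) {
    nf <- 120
    t_s <- (seq_len(nf) - 1) / 50
    dy <- amp * sin(2 * pi * 1.2 * t_s)
    frames <- array(0, c(nf, 64, 64))
    for (t in seq_len(nf))
      frames[t, , ] <- thermovitals:::shift_rows_bilinear(tmpl, dy[t], 0.2)
    seeds <- select_features(shi_tomasi_score_map(frames[1, , ]),
                             rect_roi(16, 16, 32, 32), max_n = 10)
    tr <- track_features(frames, seeds, 50)
    vt <- vertical_trajectories(tr)
    cmd <- dy - mean(dy)
    rms <- apply(vt$mat, 2, function(col) sqrt(mean((col - cmd)^2)))
    expect_lt(median(rms), 0.05)
  }
})

test_that("points that exit the frame are flagged invalid and stay invalid", {
  nf <- 40
  frames <- array(0, c(nf, 80, 48))
  set.seed(12)
  tmpl <- matrix(runif(80 * 48), 80, 48)
  for (t in seq_len(nf))
    frames[t, , ] <- thermovitals:::shift_rows_bilinear(tmpl, 0.5 * (t - 1), 0)
  # one point rides off the bottom border, one stays comfortably inside
  seeds <- data.frame(id = 1:2, x = c(24, 24), y = c(62, 30), score = 1)
  tr <- track_features(frames, seeds, 50)
  expect_true(any(!tr$valid[1, ]))
  first_bad <- which(!tr$valid[1, ])[1]
  expect_true(all(!tr$valid[1, first_bad:nf]))
  expect_true(all(tr$valid[2, ]))
})

test_that("vertical trajectories isolate centred row motion", {
  pos <- array(0, c(2, 10, 2))
  pos[1, , 1] <- seq(5, 14)        # pure horizontal motion
  pos[1, , 2] <- 7
  pos[2, , 1] <- 3
  pos[2, , 2] <- 10 + sin(1:10)
  tr <- structure(list(positions = pos, valid = matrix(TRUE, 2, 10),
                       fps = 50, ids = 1:2), class = "feature_tracks")
  vt <- vertical_trajectories(tr)
  expect_equal(vt$mat[, 1], rep(0, 10))  # constant row: zero after centring
  expect_equal(vt$mat[, 2], sin(1:10) - mean(sin(1:10)))
})

test_that("erratic-point pruning drops jumpers but respects ties and bounds", {
  nf <- 30
  n <- 15
  pos <- array(0, c(n, nf, 2))
  for (i in seq_len(n)) {
    pos[i, , 1] <- 10 + i
    pos[i, , 2] <- 20 + 0.1 * sin(seq_len(nf) / 3)
  }
  valid <- matrix(TRUE, n, nf)
  tracks <- structure(list(positions = pos, valid = valid, fps = 50, ids = 1:n),
                      class = "feature_tracks")
  # identical motion: ties sit at the pooled percentile, none dropped
  expect_equal(dim(prune_erratic(tracks, 95)$positions)[1], n)

  jump <- tracks
  jump$positions[4, 16:nf, 2] <- jump$positions[4, 16:nf, 2] + 10
  pruned <- prune_erratic(jump, 95)
  expect_false(4 %in% pruned$ids)
  expect_equal(dim(prune_erratic(jump, 100)$positions)[1], n)
})
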