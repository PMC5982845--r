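test_that("estimators reproduce hand-computed values on a 5-sample window", {
  w <- c(1, 2, 3, 2, 1)  # w[-2..2]
  expect_equal(estimator_ac(w, 2), 5.0)             # (1/2)(3*1 + 2*2 + 1*3)
  expect_equal(estimator_amdf(w, 2), 1 / (2 + 1e-12))  # mean |diff| = 2
  expect_equal(estimator_map(w, 2), 4)              # max(3+1, 2+2, 1+3)
})

test_that("estimator edge behaviours match their definitions", {
  z <- rep(0, 9)
  expect_equal(estimator_ac(z, 4), 0)
  # exactly periodic window: AMDF denominator collapses to the epsilon guard
  p <- rep(c(1, -1), length.out = 9)
  expect_equal(estimator_amdf(p, 2), 1e12, tolerance = 1e-3)
  # homogeneity: doubling the signal halves the AMDF estimator
  w <- c(0.3, 1.1, -0.4, 0.8, -1.0, 0.2, 0.9)
  expect_equal(estimator_amdf(2 * w, 3), estimator_amdf(w, 3) / 2,
               tolerance = 1e-9)
  # two unit impulses m apart maximize MAP at exactly 2
  imp <- rep(0, 11); imp[6] <- 1; imp[6 - 4] <- 1
  expect_equal(estimator_map(imp, 4), 2)
  # monotone window: the best pairing is the right-most one (v = m)
  mono <- seq(-1, 1, length.out = 9)
  expect_equal(estimator_map(mono, 3), mono[5 + 3] + mono[5])
  expect_error(estimator_ac(w, 5), class = "tv_degenerate_error")
})

test_that("a cosine of period m scores highest essentially at its own lag", {
  m_true <- 25
  v <- -60:60
  w <- cos(2 * pi * v / m_true)
  lags <- 10:50
  vals <- vapply(lags, function(m) estimator_ac(w[(61 - m):(61 + m)], m), numeric(1))
  # finite-sum edge terms can push the argmax by one sample, never more
  expect_lte(abs(lags[which.max(vals)] - m_true), 1)
  expect_gte(vals[lags == m_true], 0.99 * max(vals))
})

test_that("estimators agree with literal brute-force loops on random cases", {
  set.seed(22)
  for (i in 1:100) {
    m <- sample(2:40, 1)
    w <- rnorm(2 * m + 1 + 2 * sample(0:5, 1))
    if (length(w) %% 2 == 0) w <- c(w, rnorm(1))
    expect_equal(estimator_ac(w, m), brute_ac(w, m), tolerance = 1e-10)
    expect_equal(estimator_amdf(w, m), brute_amdf(w, m), tolerance = 1e-10)
    expect_equal(estimator_map(w, m), brute_map(w, m), tolerance = 1e-10)
  }
})

test_that("posterior conversion shifts, normalizes and handles flat input", {
  expect_equal(to_posterior(c(1, 1, 1))$probs, rep(1 / 3, 3))
  expect_equal(to_posterior(c(0, 2, 6))$probs, c(0, 0.25, 0.75))
  set.seed(23)
  for (i in 1:20) expect_equal(sum(to_posterior(rnorm(30))$probs), 1, tolerance = 1e-9)
  expect_error(to_posterior(c(1, NA, 2)), class = "tv_degenerate_error")
})

test_that("Bayesian fusion multiplies posteriors with documented tie handling", {
  lags <- 5:7
  u <- to_posterior(c(1, 1, 1), lags)
  peaked <- to_posterior(c(0, 0, 4), lags)
  f1 <- fuse_bayes(u, u, u)
  expect_equal(f1$m_hat, 5)  # uniform: tie goes to the smallest lag
  f2 <- fuse_bayes(u, u, peaked)
  expect_equal(f2$posterior$probs, peaked$probs)
  expect_equal(f2$m_hat, 7)
  pA <- structure(list(lags = lags, probs = c(0.5, 0.5, 0)), class = "lag_posterior")
  pB <- structure(list(lags = lags, probs = c(0, 0.5, 0.5)), class = "lag_posterior")
  f3 <- fuse_bayes(pA, pB, u)
  expect_equal(f3$posterior$probs, c(0, 1, 0))
  expect_equal(f3$m_hat, 6)
  # disjoint supports: degenerate fusion falls back to the AC argmax
  pC <- structure(list(lags = lags, probs = c(0, 0, 1)), class = "lag_posterior")
  pD <- structure(list(lags = lags, probs = c(1, 0, 0)), class = "lag_posterior")
  f4 <- fuse_bayes(pD, pC, pC)
  expect_true(f4$degenerate)
  expect_equal(f4$m_hat, 5)
})

test_that("ROI tracking recovers commanded integer shifts and flags flat templates", {
  set.seed(24)
  tmpl <- matrix(runif(48 * 48, 22, 34), 48, 48)
  nf <- 20
  frames <- array(0, c(nf, 48, 48))
  for (t in seq_len(nf)) frames[t, , ] <- tmpl
  # shift content by (3, -2) from frame 10 on
  for (t in 10:nf) {
    shifted <- matrix(22, 48, 48)
    shifted[4:48, 1:46] <- tmpl[1:45, 3:48]
    frames[t, , ] <- shifted
  }
  video <- thermal_video(frames, 50)
  roi <- rect_roi(15, 15, 12, 12)
  off <- track_roi(video, roi, search_radius = 6)
  expect_equal(off[5, ], c(0, 0))
  expect_equal(off[15, ], c(3, -2))

  flat <- thermal_video(array(25, c(5, 32, 32)), 50)
  expect_error(track_roi(flat, rect_roi(10, 10, 8, 8)),
               class = "tv_tracking_error")
})

test_that("ROM averaging reproduces closed-form means", {
  frames <- array(30, c(3, 20, 20))
  video <- thermal_video(frames, 50)
  tr <- rom_waveform(video, rect_roi(4, 4, 10, 10))
  expect_equal(tr$values, rep(30, 3))

  # checkerboard of 20/40 averages to exactly 30
  chk <- matrix(rep(c(20, 40), 200), 20, 20)
  arr <- array(0, c(2, 20, 20))
  arr[1, , ] <- chk
  arr[2, , ] <- chk
  video2 <- thermal_video(arr, 50)
  tr2 <- rom_waveform(video2, rect_roi(2, 2, 8, 8), NULL, rr_config(rom_frac = 1))
  expect_equal(tr2$values, rep(30, 2))
})

test_that("respiratory rate is recovered from a synthetic scene within 1 breath/min", {
  sc <- cached_scene("rr15", rows = 96, cols = 96, duration = 30,
                     rr_bpm = 15, seed = 26)
  nroi <- sc$config$nostril_roi
  roi <- rect_roi(nroi$row0 - 2, nroi$col0 - 3, nroi$height + 4, nroi$width + 6)
  est <- estimate_rr_series(sc$video, roi)
  expect_gt(length(est$rates), 3)
  expect_lte(mean(abs(est$rates - 15)), 1)
})

test_that("the fused lag equals the arithmetic interval of the true rate", {
  sc <- cached_scene("rr15", rows = 96, cols = 96, duration = 30,
                     rr_bpm = 15, seed = 26)
  nroi <- sc$config$nostril_roi
  roi <- rect_roi(nroi$row0 - 2, nroi$col0 - 3, nroi$height + 4, nroi$width + 6)
  est <- estimate_rr_series(sc$video, roi)
  m_hat <- 60 * 50 / est$rates
  expect_lt(median(abs(m_hat - 200)), 3)  # 60 * 50 / 15 = 200 samples
})

test_that("traces without full lag support are rejected", {
  sc <- cached_scene("static64", rows = 64, cols = 64, duration = 4,
                     bcg_amp_px = 0, nostril_amp_k = 0, noise_sd_k = 0, seed = 9)
  nroi <- sc$config$nostril_roi
  expect_error(estimate_rr_series(sc$video, nroi),  # 200 samples < 2*500+1
               class = "tv_degenerate_error")
})
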