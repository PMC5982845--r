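test_that("series alignment interpolates the reference onto estimate times", {
  est <- rate_series(c(0, 1, 2), c(70, 71, 72), "heart")
  ref <- rate_series(c(0, 1, 2), c(70, 71, 72), "heart")
  p <- align_series(est, ref)
  expect_equal(p$est, p$ref)

  ref_const <- rate_series(c(0, 2), c(70, 70), "heart")
  expect_equal(align_series(est, ref_const)$ref, rep(70, 3))

  est_mid <- rate_series(1.5, 65, "heart")
  ref2 <- rate_series(c(1, 2), c(60, 70), "heart")
  expect_equal(align_series(est_mid, ref2)$ref, 65)

  late <- rate_series(c(10, 11), c(70, 70), "heart")
  expect_error(align_series(est, late), class = "tv_alignment_error")
})

test_that("error statistics reproduce hand-computed cases", {
  same <- data.frame(est = c(70, 71), ref = c(70, 71))
  expect_equal(rmse(same), 0)
  expect_equal(relative_errors(same), c(0, 0))
  expect_equal(eps90(relative_errors(same)), 0)

  two <- data.frame(est = c(72, 68), ref = c(70, 70))
  expect_equal(rmse(two), 2)
  expect_equal(relative_errors(two), c(2 / 70, 2 / 70))
  expect_equal(eps90(relative_errors(two)), 2 / 70)

  # order-statistic interpolation applied by hand: 0.9*(10-1)+1 = 9.1
  expect_equal(eps90(seq(0.01, 0.10, by = 0.01)), 0.091)
  expect_error(rmse(data.frame(est = numeric(0), ref = numeric(0))),
               class = "tv_degenerate_error")
})

test_that("CAND matches direct arithmetic and complements relative error", {
  expect_equal(cand(70, 70), 1.0)
  expect_equal(cand(90.46, 85.22), 0.9421, tolerance = 5e-5)
  expect_error(cand(0, 70), class = "tv_domain_error")

  set.seed(31)
  gt <- runif(20, 50, 100)
  ti <- gt + rnorm(20, 0, 5)
  pairs <- data.frame(est = ti, ref = gt)
  expect_equal(cand(gt, ti) + relative_errors(pairs), rep(1, 20))
})

test_that("Bland-Altman reproduces hand-computed limits", {
  same <- data.frame(est = c(70, 80), ref = c(70, 80))
  expect_equal(unlist(bland_altman(same)[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))

  offset <- data.frame(est = c(72, 82), ref = c(70, 80))
  ba <- bland_altman(offset)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_high - ba$loa_low, 0)

  pm1 <- data.frame(est = c(69, 71), ref = c(70, 70))  # diffs {-1, 1}
  ba2 <- bland_altman(pm1)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa_low, -1.96 * sqrt(2))
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))
  expect_error(bland_altman(same[1, ]), class = "tv_degenerate_error")

  # the bias always equals the difference of the means
  set.seed(32)
  pairs <- data.frame(est = runif(15, 60, 90), ref = runif(15, 60, 90))
  expect_equal(bland_altman(pairs)$bias, mean(pairs$est) - mean(pairs$ref))
})

test_that("table aggregation equals a spreadsheet-style recomputation", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    tab <- data.frame(subject_id = seq_len(n),
                      mean_gt = runif(n, 50, 100), mean_irt = runif(n, 50, 100),
                      rmse = runif(n, 0, 8), eps_mean = runif(n, 0, 0.1),
                      eps90 = runif(n, 0, 0.2))
    agg <- aggregate_validation(tab)
    for (col in c("mean_gt", "mean_irt", "rmse", "eps_mean", "eps90")) {
      x <- tab[[col]]
      m <- sum(x) / n
      s <- sqrt(sum((x - m)^2) / (n - 1))
      expect_equal(agg[["mean", col]], m)
      expect_equal(agg[["sd", col]], s)
    }
  }
  tab1 <- data.frame(subject_id = 1:3, mean_gt = 70, mean_irt = 71,
                     rmse = 2, eps_mean = 0.02, eps90 = 0.05)
  expect_equal(unname(unlist(aggregate_validation(tab1)["sd", ])), rep(0, 5))
})

test_that("bundled pilot tables reproduce their published summary rows", {
  frontal <- load_validation_table("hr_frontal")
  side <- load_validation_table("hr_side")
  expect_equal(nrow(frontal), 18)
  expect_equal(nrow(side), 16)
  expect_equal(mean(frontal$rmse), 3.53, tolerance = 0.005 / 3.53)
  expect_equal(mean(side$rmse), 3.43, tolerance = 0.005 / 3.43)
  expect_equal(mean_rate_relative_error(frontal), 0.021, tolerance = 0.03)
  expect_equal(mean_rate_relative_error(side), 0.023, tolerance = 0.03)
  expect_equal(mean(cand(frontal$mean_gt, frontal$mean_irt)), 0.9787,
               tolerance = 5e-5)
  expect_equal(mean(cand(side$mean_gt, side$mean_irt)), 0.9766,
               tolerance = 5e-5)

  rr <- load_validation_table("rr_frontal")
  expect_equal(nrow(rr), 16)
  expect_equal(mean(rr$mean_gt), 15.36, tolerance = 0.01)
})

test_that("validate_series assembles all statistics coherently", {
  est <- rate_series(seq(0, 9), 70 + sin(seq(0, 9)), "heart")
  ref <- rate_series(seq(0, 9), rep(70, 10), "heart")
  v <- validate_series(est, ref)
  expect_equal(v$n, 10)
  expect_equal(v$rmse, sqrt(mean(sin(seq(0, 9))^2)))
  expect_equal(v$bias, mean(sin(seq(0, 9))))
  expect_equal(v$cand_mean, mean(cand(rep(70, 10), est$rates)))
})
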