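test_that("MSE, PSNR and MAE match closed forms and brute-force oracles", {
  set.seed(21)
  G <- matrix(runif(64), 8, 8)
  expect_equal(mse_metric(G, G), 0)
  expect_equal(mse_metric(G + 0.5, G), 0.25)
  expect_equal(mae_metric(G, G), 0)
  expect_equal(mae_metric(G + 0.2, G), 0.2, tolerance = 1e-12)
  # PSNR closed form: max 1, MSE 0.01 -> 20 dB
  G1 <- matrix(0, 8, 8); G1[1, 1] <- 1
  y1 <- G1; y1[2, 1] <- 0.8 # one pixel off by 0.8 -> MSE = 0.64/64 = 0.01
  expect_equal(psnr_metric(y1, G1), 20, tolerance = 1e-12)
  # scale invariance of the PSNR ratio
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(psnr_metric(2 * a, 2 * b), psnr_metric(a, b))
  # identical images signal infinite PSNR distinctly
  expect_identical(psnr_metric(G, G), Inf)
  # brute-force elementwise loop oracles
  loop_mse <- 0; loop_mae <- 0
  for (i in seq_along(a)) {
    loop_mse <- loop_mse + (a[i] - b[i])^2
    loop_mae <- loop_mae + abs(a[i] - b[i])
  }
  expect_equal(mse_metric(a, b), loop_mse / 64, tolerance = 1e-9)
  expect_equal(mae_metric(a, b), loop_mae / 64, tolerance = 1e-9)
  expect_equal(psnr_metric(a, b), 10 * log10(max(a, b)^2 / (loop_mse / 64)),
               tolerance = 1e-9)
  expect_error(mse_metric(a, matrix(0, 4, 4)), "shape")
})

test_that("SSIM follows the literal product form with c1 = 0.01, c2 = 0.03", {
  set.seed(22)
  y <- matrix(runif(64), 8, 8)
  expect_identical(ssim_metric(y, y, mode = "global"), 1)
  expect_identical(ssim_metric(y, y, mode = "windowed", window = 3), 1)
  # constant images: variance terms vanish, covariance term cancels to 1
  a <- 0.8; b <- 0.3
  expect_equal(ssim_metric(matrix(a, 8, 8), matrix(b, 8, 8), mode = "global"),
               (2 * a * b + 0.01) / (a^2 + b^2 + 0.01), tolerance = 1e-12)
  # global mode against brute-force statistics
  G <- matrix(runif(64), 8, 8)
  muy <- sum(y) / 64; mug <- sum(G) / 64
  vy <- sum((y - muy)^2) / 64; vg <- sum((G - mug)^2) / 64
  cyg <- sum((y - muy) * (G - mug)) / 64
  expect_equal(ssim_metric(y, G, mode = "global"),
               (2 * muy * mug + 0.01) * (2 * cyg + 0.03) /
                 ((muy^2 + mug^2 + 0.01) * (vy + vg + 0.03)),
               tolerance = 1e-9)
  # standard-constants compatibility mode
  expect_equal(ssim_metric(y, G, mode = "global", constants = "standard"),
               (2 * muy * mug + 1e-4) * (2 * cyg + 9e-4) /
                 ((muy^2 + mug^2 + 1e-4) * (vy + vg + 9e-4)),
               tolerance = 1e-9)
})

test_that("metric bounds hold on random image pairs", {
  set.seed(23)
  for (i in 1:1000) {
    y <- matrix(runif(64), 8, 8)
    G <- matrix(runif(64), 8, 8)
    expect_lte(ssim_metric(y, G, mode = "global"), 1)
    expect_lte(mae_metric(y, G)^2, mse_metric(y, G)) # Jensen
  }
  # PSNR positive whenever max >= 1 and MSE < 1
  for (i in 1:50) {
    y <- matrix(runif(64), 8, 8); y[1] <- 1
    G <- matrix(runif(64), 8, 8)
    if (mse_metric(y, G) < 1) expect_gt(psnr_metric(y, G), 0)
  }
})

test_that("metrics reports aggregate per-image rows with population SD", {
  set.seed(24)
  pred <- array(runif(32 * 32 * 5), c(32, 32, 5))
  targ <- array(runif(32 * 32 * 5), c(32, 32, 5))
  rep <- metrics_report(pred, targ, ssim_mode = "windowed")
  expect_equal(nrow(rep$per_image), 5)
  expect_setequal(rep$summary$metric, c("ssim", "psnr", "mae", "mse"))
  # mean/sd recomputed by hand from the per-image rows
  for (m in rep$summary$metric) {
    v <- rep$per_image[[m]]
    i <- which(rep$summary$metric == m)
    expect_equal(rep$summary$mean[i], mean(v))
    expect_equal(rep$summary$sd[i], sqrt(mean((v - mean(v))^2)))
  }
  # identical stacks: perfect scores
  perf <- metrics_report(targ, targ)
  expect_equal(perf$summary$mean[perf$summary$metric == "ssim"], 1)
  expect_equal(perf$summary$mean[perf$summary$metric == "mae"], 0)
  expect_error(metrics_report(array(0, c(4, 4, 0)), array(0, c(4, 4, 0))), "empty")
})
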