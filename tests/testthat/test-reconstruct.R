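test_that("time reversal of silence is silence and geometry is validated", {
  g <- small_grid(); m <- pat_medium()
  sa <- build_sensor_array(16, g)
  z <- simulate_forward(matrix(0, 64, 64), g, m, sa)
  expect_equal(time_reversal(z, g, m, sa), matrix(0, 64, 64))
  sa8 <- build_sensor_array(8, g)
  expect_error(time_reversal(z, g, m, sa8), "disagree")
})

test_that("dense-view noiseless TR approximately inverts the forward operator", {
  g <- small_grid(); m <- pat_medium()
  sa <- build_sensor_array(128, g)
  disc <- matrix(0, 64, 64)
  disc[(row(disc) - 32.5)^2 + (col(disc) - 32.5)^2 < 7^2] <- 1
  rec <- time_reversal(simulate_forward(disc, g, m, sa), g, m, sa)
  expect_gte(stats::cor(as.vector(rec), as.vector(disc)), 0.9)
  # sparse view is strictly worse (streak artifacts)
  sa8 <- build_sensor_array(8, g)
  rec8 <- time_reversal(simulate_forward(disc, g, m, sa8), g, m, sa8)
  expect_lt(ssim_metric(rec8, disc), ssim_metric(rec, disc))
})

test_that("paired datasets are normalized, split 8:1:1 and reproducible", {
  g <- small_grid(); m <- pat_medium()
  scenes <- generate_scenes(10, seed = 77, nx = 64L)
  ds <- make_paired_dataset(scenes, n_sensors = 16, grid = g, medium = m,
                            seed = 5)
  expect_s3_class(ds, "pat_dataset")
  expect_equal(lengths(ds$split), c(train = 8, val = 1, test = 1))
  expect_length(unique(unlist(ds$split)), 10)
  for (i in 1:10) {
    expect_equal(min(ds$inputs[, , i]), 0)
    expect_equal(max(ds$inputs[, , i]), 1)
  }
  ds2 <- make_paired_dataset(scenes, n_sensors = 16, grid = g, medium = m,
                             seed = 5)
  expect_identical(ds$split, ds2$split)
  expect_equal(ds$inputs, ds2$inputs)
})
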