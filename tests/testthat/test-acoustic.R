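# Solver physics at reduced geometry (64 x 64 imaging region, 2 mm ring);
# the full study geometry is exercised by the acceptance checks.

test_that("sensor arrays are validated, uniform, and on the ring", {
  g <- pat_grid()
  expect_error(build_sensor_array(4, g), "between 8 and 512")
  expect_error(build_sensor_array(1000, g), "between 8 and 512")
  sa8 <- build_sensor_array(8, g)
  expect_equal(diff(sa8$angles), rep(pi / 4, 7))
  sa512 <- build_sensor_array(512, g)
  ctr <- (g$nx + 1) / 2 + g$offset
  r_px <- sa512$ring_radius / g$dx
  # snapped nodes lie within half a pixel of the nominal ring
  gr <- (sa512$idx0 %% g$n_full) + 1
  gc <- (sa512$idx0 %/% g$n_full) + 1
  d <- sqrt((gr - ctr)^2 + (gc - ctr)^2)
  expect_true(all(abs(d - r_px) <= sqrt(0.5) + 1e-9))
})

test_that("the forward operator is linear and zero maps to zero", {
  g <- small_grid(); m <- pat_medium()
  sa <- build_sensor_array(16, g)
  z <- simulate_forward(matrix(0, 64, 64), g, m, sa)
  expect_equal(max(abs(z$series)), 0)
  p0 <- generate_scene(2, seed = 5, nx = 64L)
  s1 <- simulate_forward(p0, g, m, sa)$series
  s2 <- simulate_forward(2.5 * p0, g, m, sa)$series
  expect_lt(max(abs(s2 - 2.5 * s1)) / max(abs(s2)), 1e-6)
  # superposition
  q0 <- generate_scene(2, seed = 6, nx = 64L)
  s3 <- simulate_forward(q0, g, m, sa)$series
  s4 <- simulate_forward(p0 + q0, g, m, sa)$series
  expect_lt(max(abs(s4 - s1 - s3)) / max(abs(s4)), 1e-6)
})

test_that("acoustic energy is conserved without the PML and absorbed with it", {
  g <- small_grid(); m <- pat_medium()
  sa <- build_sensor_array(16, g)
  disc <- matrix(0, 64, 64)
  disc[(row(disc) - 32.5)^2 + (col(disc) - 32.5)^2 < 6^2] <- 1
  e_off <- attr(simulate_forward(disc, g, m, sa, pml = FALSE,
                                 record_energy = TRUE), "energy")
  expect_lt((max(e_off) - min(e_off)) / max(e_off), 0.005)
  e_on <- attr(simulate_forward(disc, g, m, sa, pml = TRUE,
                                record_energy = TRUE), "energy")
  expect_lt(e_on[length(e_on)] / e_on[1], 0.1) # mostly absorbed in this window
  expect_lte(max(diff(e_on)), 1e-9 * e_on[1]) # monotone decay
})

test_that("swapping a point source and point sensor preserves the trace", {
  g <- small_grid(); m <- pat_medium()
  a <- c(22L, 30L); b <- c(44L, 38L)
  mk <- function(px) { z <- matrix(0, 64, 64); z[px[1], px[2]] <- 1; z }
  sens <- function(px) {
    sa <- build_sensor_array(8, g)
    sa$idx0 <- as.integer((px[1] + g$offset - 1) + g$n_full * (px[2] + g$offset - 1))
    sa$n_sensors <- 1L
    sa
  }
  t_ab <- simulate_forward(mk(a), g, m, sens(b))$series
  t_ba <- simulate_forward(mk(b), g, m, sens(a))$series
  expect_lt(sqrt(sum((t_ab - t_ba)^2) / sum(t_ab^2)), 0.01)
})

test_that("sensor noise is calibrated to the requested SNR", {
  g <- small_grid(); m <- pat_medium()
  sa <- build_sensor_array(16, g)
  p0 <- generate_scene(3, seed = 8, nx = 64L)
  clean <- simulate_forward(p0, g, m, sa)
  expect_error(add_gaussian_noise(simulate_forward(matrix(0, 64, 64), g, m, sa)),
               "zero")
  # fixed 50 dB target: SNR recomputed from the stored clean/noisy pair
  noisy <- add_gaussian_noise(clean, c(50, 50), seed = 3)
  realized <- 10 * log10(mean(noisy$clean^2) / mean((noisy$series - noisy$clean)^2))
  expect_equal(realized, 50, tolerance = 0.5)
  # infinite-SNR limit leaves the data untouched
  inf_noise <- add_gaussian_noise(clean, c(Inf, Inf), seed = 4)
  expect_equal(inf_noise$series, clean$series)
  # drawn targets are uniform over [40, 60] dB
  targets <- vapply(1:300, function(s)
    add_gaussian_noise(clean, c(40, 60), seed = s)$snr_db, 0)
  expect_true(all(targets >= 40 & targets <= 60))
  ks <- suppressWarnings(stats::ks.test(targets, "punif", 40, 60))
  expect_gt(ks$p.value, 0.01)
})
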