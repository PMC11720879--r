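# Shared helpers: a reduced simulation geometry for fast unit tests, an
# independent point-in-polygon oracle, and a lazily built corpus shared by
# the acceptance checks.

# Reduced geometry: 64 x 64 imaging region, 2 mm ring. Same solver, PML and
# CFL settings as the study geometry, about 4x cheaper per run.
small_grid <- function() pat_grid(nx = 64L, ring_radius = 2e-3)

# Ray-casting point-in-polygon test (independent of the half-plane
# rasterizer used by the package).
oracle_inside <- function(row, col, v) {
  n <- nrow(v)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    r1 <- v[i, 1]; c1 <- v[i, 2]; r2 <- v[j, 1]; c2 <- v[j, 2]
    if ((r1 > row) != (r2 > row)) {
      xint <- c1 + (row - r1) / (r2 - r1) * (c2 - c1)
      if (col < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

oracle_raster <- function(spec, nx = 128L) {
  v <- sparsepat:::phantom_vertices(spec)
  out <- matrix(0, nx, nx)
  for (r in seq_len(nx)) for (c in seq_len(nx)) {
    if (oracle_inside(r, c, v)) out[r, c] <- spec$intensity
  }
  out
}

# training-mode batch loss without an optimizer step
batch_loss <- function(model, xb, yb) {
  sp <- asNamespace("sparsepat")
  tp <- sp$new_tape(model$ps, training = TRUE, grad = FALSE)
  sp$tp_value(tp, sp$tp_mse(tp, model$fwd(tp, sp$tp_input(tp, xb)), yb))
}

# ---- shared corpus for the acceptance checks -------------------------------
# 200 random scenes acquired at 50 transducers with 40-60 dB noise (the
# training corpus), plus clean 512-channel recordings of the first 20 scenes
# used for the sensor-count degradation curve. Built once per test run.
.acc_env <- new.env(parent = emptyenv())

acceptance_corpus <- function() {
  if (!is.null(.acc_env$ds)) return(.acc_env)
  grid <- pat_grid()
  medium <- pat_medium()
  scenes <- generate_scenes(200, seed = 2024)
  .acc_env$ds <- make_paired_dataset(scenes, n_sensors = 50, seed = 2025)
  sa512 <- build_sensor_array(512, grid)
  .acc_env$clean512 <- lapply(1:20, function(i) {
    simulate_forward(scenes[, , i], grid, medium, sa512)
  })
  .acc_env$scenes <- scenes
  .acc_env$grid <- grid
  .acc_env$medium <- medium
  .acc_env
}
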