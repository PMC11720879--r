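#' Time-reversal reconstruction
#'
#' Re-emits the recorded sensor series in reversed time order as enforced
#' (Dirichlet) pressure values at the sensor grid nodes while the same
#' k-space solver steps the wave field; the interior pressure after the last
#' step is the reconstruction. Sensors that snapped to the same grid node
#' are averaged before enforcement. The image is min-max normalized to
#' \[0, 1\] (a constant field maps to all zeros).
#'
#' @param data A `sensor_data` recorded with the same geometry.
#' @param grid,medium,sensors The acquisition geometry.
#' @param normalize Min-max normalize the output (the default).
#' @return An `nx` x `nx` reconstruction matrix.
#' @export
time_reversal <- function(data, grid = pat_grid(), medium = pat_medium(),
                          sensors, normalize = TRUE) {
  stop_if(!inherits(data, "sensor_data"), "data must be sensor_data")
  stop_if(nrow(data$series) != sensors$n_sensors,
          "sensor_data and sensor_array disagree on the number of channels")
  stop_if(abs(data$dt - grid$dt) > 1e-15, "sensor_data dt does not match grid dt")
  ops <- solver_ops(grid, medium)
  rev_series <- data$series[, ncol(data$series):1, drop = FALSE]
  # average coincident sensors (possible after snapping dense rings)
  uidx <- unique(sensors$idx0)
  if (length(uidx) < length(sensors$idx0)) {
    grp <- match(sensors$idx0, uidx)
    agg <- matrix(0, length(uidx), ncol(rev_series))
    cnt <- tabulate(grp, nbins = length(uidx))
    for (m in seq_along(grp)) agg[grp[m], ] <- agg[grp[m], ] + rev_series[m, ]
    rev_series <- agg / cnt
  }
  zero <- matrix(0, grid$n_full, grid$n_full)
  res <- kspace_run_cpp(
    zero, ops$C1, ops$A, ops$B, ops$flipidx,
    ops$PX, ops$PXS, ops$PY, ops$PYS,
    grid$dt, medium$density, medium$sound_speed^2, grid$nt,
    uidx, FALSE, rev_series, TRUE, FALSE)
  img <- crop_field(res$p, grid)
  if (normalize) img <- minmax_norm(img) # negatives kept until this point
  img
}

minmax_norm <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] == 0) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Build a paired (reconstruction, ground truth) dataset
#'
#' For each scene: simulate forward propagation onto a sparse circular
#' array, add Gaussian sensor noise with a random 40-60 dB SNR, reconstruct
#' by time reversal and min-max normalize. Pairs are split into train /
#' validation / test sets 8:1:1 by a seeded shuffle.
#'
#' @param scenes `nx` x `nx` x N array (or list of matrices) of ground-truth
#'   initial-pressure scenes.
#' @param n_sensors Transducer count (scalar, or vector recycled per scene).
#' @param snr_db_range Sensor-noise SNR range in dB; NULL for noiseless data.
#' @param grid,medium Simulation geometry.
#' @param seed Integer seed controlling noise draws and the split shuffle.
#' @param split Ratios for train/validation/test.
#' @param progress Print a line every 25 scenes.
#' @return A `pat_dataset`: list with `inputs`, `targets`
#'   (nx x nx x N arrays), `split` (index vectors), and `n_sensors`.
#' @export
make_paired_dataset <- function(scenes, n_sensors = 50, snr_db_range = c(40, 60),
                                grid = pat_grid(), medium = pat_medium(),
                                seed = NULL, split = c(8, 1, 1),
                                progress = FALSE) {
  if (is.list(scenes)) scenes <- simplify2array(scenes)
  if (length(dim(scenes)) == 2) dim(scenes) <- c(dim(scenes), 1)
  n <- dim(scenes)[3]
  stop_if(n < 1, "no scenes supplied")
  n_sensors <- rep_len(n_sensors, n)
  arrays <- lapply(unique(n_sensors), build_sensor_array, grid = grid)
  names(arrays) <- as.character(unique(n_sensors))
  inputs <- array(0, dim(scenes))
  with_seed(seed, {
    for (i in seq_len(n)) {
      sa <- arrays[[as.character(n_sensors[i])]]
      sd_ <- simulate_forward(scenes[, , i], grid, medium, sa)
      if (!is.null(snr_db_range)) {
        sd_ <- add_gaussian_noise(sd_, snr_db_range, keep_clean = FALSE)
      }
      inputs[, , i] <- time_reversal(sd_, grid, medium, sa)
      if (progress && i %% 25 == 0) message("  scene ", i, "/", n)
    }
    idx <- sample.int(n)
    n_tr <- floor(n * split[1] / sum(split))
    n_val <- floor(n * split[2] / sum(split))
    structure(list(
      inputs = inputs, targets = scenes,
      split = list(train = sort(idx[seq_len(n_tr)]),
                   val = sort(idx[n_tr + seq_len(n_val)]),
                   test = sort(idx[seq(n_tr + n_val + 1, length.out = n - n_tr - n_val)])),
      n_sensors = n_sensors
    ), class = "pat_dataset")
  })
}

#' @export
print.pat_dataset <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<pat_dataset> %d pairs of %dx%d images (train/val/test = %d/%d/%d)\n",
              d[3], d[1], d[2], length(x$split$train), length(x$split$val),
              length(x$split$test)))
  invisible(x)
}

# subset helper used by training / evaluation
dataset_subset <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  idx <- ds$split[[which]]
  list(inputs = ds$inputs[, , idx, drop = FALSE],
       targets = ds$targets[, , idx, drop = FALSE])
}
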