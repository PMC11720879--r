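#' Acoustic medium description
#'
#' Homogeneous 2D medium; defaults are typical soft-tissue values.
#'
#' @param sound_speed Speed of sound in m/s.
#' @param density Mass density in kg/m^3.
#' @return An object of class `pat_medium`.
#' @export
pat_medium <- function(sound_speed = 1500, density = 1000) {
  stop_if(sound_speed <= 0, "sound_speed must be positive")
  stop_if(density <= 0, "density must be positive")
  structure(list(sound_speed = sound_speed, density = density),
            class = "pat_medium")
}

#' Simulation grid
#'
#' The imaging region is a 10 x 10 mm square sampled on `nx` x `nx` points
#' (78.125 um pixels by default), surrounded by a perfectly matched layer
#' (PML) of `pml_width` grid points. The computational grid is padded with a
#' few inert cells beyond the PML up to a size with small prime factors,
#' which speeds up the FFTs substantially without changing the physics. The
#' time step is set from the CFL number (dt = cfl * dx / c) and the window
#' length covers 1.2 ring diameters of propagation.
#'
#' @param nx Imaging-region side length in grid points.
#' @param dx Grid spacing in meters.
#' @param pml_width PML thickness in grid points.
#' @param cfl CFL number (must be <= 0.3, the solver's stability bound).
#' @param medium A `pat_medium` (determines dt).
#' @param ring_radius Transducer ring radius in meters (determines nt).
#' @param t_factor Window length in units of the ring-diameter crossing time.
#' @return An object of class `pat_grid`.
#' @export
pat_grid <- function(nx = 128L, dx = 10e-3 / 128, pml_width = 20L, cfl = 0.3,
                     medium = pat_medium(), ring_radius = 4e-3,
                     t_factor = 1.2) {
  stop_if(cfl > 0.3 + 1e-12, "cfl exceeds the stability bound 0.3")
  stop_if(pml_width < 0, "pml_width must be >= 0")
  c0 <- medium$sound_speed
  dt <- cfl * dx / c0
  nt <- as.integer(ceiling(t_factor * 2 * ring_radius / (c0 * dt)))
  n_min <- nx + 2L * pml_width
  n_full <- fft_friendly_size(n_min)
  structure(list(
    nx = as.integer(nx), ny = as.integer(nx), dx = dx, dy = dx,
    pml_width = as.integer(pml_width), cfl = cfl, dt = dt, nt = nt,
    ring_radius = ring_radius,
    n_full = n_full,
    offset = as.integer((n_full - nx) %/% 2) # 0-based start of imaging region
  ), class = "pat_grid")
}

#' @export
print.pat_grid <- function(x, ...) {
  cat(sprintf("<pat_grid> %dx%d @ %.3f um, PML %d, full grid %d, dt=%.4g us, nt=%d\n",
              x$nx, x$ny, x$dx * 1e6, x$pml_width, x$n_full, x$dt * 1e6, x$nt))
  invisible(x)
}

# smallest size >= n whose prime factors are all <= 5
fft_friendly_size <- function(n) {
  ok <- function(m) {
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  while (!ok(n)) n <- n + 1L
  n
}

# Precomputed spectral operators and PML profiles for a grid/medium pair.
# Cached since every forward/time-reversal run reuses them.
.solver_cache <- new.env(parent = emptyenv())

solver_ops <- function(grid, medium, pml_alpha = 2) {
  key <- paste(grid$n_full, grid$dx, grid$dt, medium$sound_speed,
               grid$pml_width, pml_alpha, sep = "|")
  hit <- .solver_cache[[key]]
  if (!is.null(hit)) return(hit)

  n <- grid$n_full
  dx <- grid$dx
  c0 <- medium$sound_speed
  dt <- grid$dt
  kv <- 2 * pi / (n * dx) * c(0:(n / 2), -((n / 2 - 1):1))
  KX <- matrix(kv, n, n)
  KY <- matrix(kv, n, n, byrow = TRUE)
  kmag <- sqrt(KX^2 + KY^2)
  arg <- c0 * kmag * dt / 2
  kappa <- ifelse(arg == 0, 1, sin(arg) / arg) # k-space dispersion correction

  mxp <- 1i * KX * kappa * exp(+1i * KX * dx / 2) # p -> dp/dx on staggered grid
  myp <- 1i * KY * kappa * exp(+1i * KY * dx / 2)
  mxu <- 1i * KX * kappa * exp(-1i * KX * dx / 2) # staggered u -> div at centers
  myu <- 1i * KY * kappa * exp(-1i * KY * dx / 2)

  idx <- 0:(n - 1)
  flip1 <- (n - idx) %% n
  flipidx <- outer(flip1, flip1 * n, `+`) # 0-based linear index of -k

  # PML absorption: quartic ramp over the layer, strength pml_alpha * c / dx,
  # applied as exp(-sigma dt / 2) twice per update; the inert padding cells
  # beyond the layer keep full strength.
  prof <- function(stag) {
    x <- idx + if (stag) 0.5 else 0
    lo <- grid$offset # imaging region is [offset, offset + nx - 1]
    inner_lo <- lo # PML occupies [lo - pml, lo)
    d <- pmax(0, pmax((inner_lo - x) / grid$pml_width,
                      (x - (inner_lo + grid$nx - 1)) / grid$pml_width))
    d <- pmin(d, 1)
    exp(-pml_alpha * (c0 / dx) * d^4 * dt / 2)
  }
  px <- prof(FALSE); pxs <- prof(TRUE)
  ops <- list(
    C1 = mxp + 1i * myp,
    A = (mxu + myu) / 2, B = (mxu - myu) / 2,
    flipidx = as.vector(flipidx),
    PX = matrix(px, n, n), PXS = matrix(pxs, n, n),
    PY = matrix(px, n, n, byrow = TRUE), PYS = matrix(pxs, n, n, byrow = TRUE)
  )
  .solver_cache[[key]] <- ops
  ops
}

#' Circular transducer array
#'
#' `n_sensors` point transducers uniformly spaced on a ring of radius
#' `ring_radius` centered on the imaging region, snapped to the nearest grid
#' node (the ring must lie inside the non-PML region).
#'
#' @param n_sensors Number of transducers (8 to 512).
#' @param grid A `pat_grid`.
#' @param ring_radius Ring radius in meters.
#' @return An object of class `sensor_array` with angles, continuous
#'   positions (grid pixels, imaging-region frame) and snapped node indices.
#' @export
build_sensor_array <- function(n_sensors, grid = pat_grid(),
                               ring_radius = grid$ring_radius) {
  stop_if(n_sensors < 8 || n_sensors > 512,
          "n_sensors must be between 8 and 512")
  n_sensors <- as.integer(n_sensors)
  r_px <- ring_radius / grid$dx
  stop_if(r_px >= grid$nx / 2,
          "sensor ring does not fit inside the non-PML region")
  angles <- 2 * pi * (seq_len(n_sensors) - 1L) / n_sensors
  ctr <- (grid$nx + 1) / 2 # imaging-frame center, 1-based continuous
  rows <- ctr + r_px * sin(angles)
  cols <- ctr + r_px * cos(angles)
  gr <- round(rows) + grid$offset # full-grid 1-based
  gc <- round(cols) + grid$offset
  structure(list(
    n_sensors = n_sensors, ring_radius = ring_radius, angles = angles,
    rows = rows, cols = cols,
    idx0 = as.integer((gr - 1) + grid$n_full * (gc - 1)) # 0-based linear
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d transducers on a %.1f mm ring\n",
              x$n_sensors, x$ring_radius * 1e3))
  invisible(x)
}

# Embed the imaging-region field into the full computational grid.
embed_field <- function(p0, grid) {
  full <- matrix(0, grid$n_full, grid$n_full)
  sel <- grid$offset + seq_len(grid$nx)
  full[sel, sel] <- p0
  full
}

crop_field <- function(pfull, grid) {
  sel <- grid$offset + seq_len(grid$nx)
  pfull[sel, sel]
}

# Frequency-domain Blackman smoothing of the initial pressure (suppresses
# Gibbs ringing from sharp-edged phantoms). Kept as a pure spectral
# apodization -- no amplitude restoration -- so the forward operator stays
# exactly linear in p0.
smooth_p0 <- function(pfull) {
  n <- nrow(pfull)
  w <- 0.42 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) +
    0.08 * cos(4 * pi * (0:(n - 1)) / (n - 1))
  wk <- w[(((0:(n - 1)) + n %/% 2) %% n) + 1] # peak moved to the DC bin
  wk <- wk / max(wk) # unit DC gain
  Re(fft(fft(pfull) * outer(wk, wk), inverse = TRUE)) / n^2
}

#' Simulate forward acoustic propagation to a sensor ring
#'
#' Propagates an initial pressure distribution through a homogeneous medium
#' with a first-order k-space pseudospectral solver (spectral spatial
#' derivatives with k-space dispersion correction, staggered leapfrog time
#' stepping of the coupled pressure/velocity equations, split-field PML) and
#' records the pressure time series at each transducer. The discrete forward
#' operator is linear in `p0`.
#'
#' @param p0 Initial pressure: `nx` x `nx` matrix (imaging-region frame).
#' @param grid A `pat_grid`.
#' @param medium A `pat_medium`.
#' @param sensors A `sensor_array` built on the same grid.
#' @param smooth Apply frequency-domain Blackman smoothing to `p0` first.
#' @param pml Enable the perfectly matched layer.
#' @param record_energy Also record the discrete acoustic energy per step.
#' @return An object of class `sensor_data`: list with `series`
#'   (n_sensors x nt), `dt`, `snr_db` (NULL for clean data) and optionally
#'   an `energy` attribute.
#' @export
simulate_forward <- function(p0, grid = pat_grid(), medium = pat_medium(),
                             sensors, smooth = TRUE, pml = TRUE,
                             record_energy = FALSE) {
  stop_if(!is.matrix(p0) || nrow(p0) != grid$nx || ncol(p0) != grid$nx,
          "p0 must be a ", grid$nx, "x", grid$nx, " matrix")
  stop_if(grid$dt > 0.3 * grid$dx / medium$sound_speed + 1e-18,
          "time step violates the CFL stability bound")
  stop_if(!inherits(sensors, "sensor_array"), "sensors must be a sensor_array")
  ops <- solver_ops(grid, medium)
  pfull <- embed_field(p0, grid)
  if (smooth && any(pfull != 0)) pfull <- smooth_p0(pfull)
  one <- matrix(1, 1, 1)
  ident <- matrix(1, grid$n_full, grid$n_full)
  res <- kspace_run_cpp(
    pfull, ops$C1, ops$A, ops$B, ops$flipidx,
    if (pml) ops$PX else ident, if (pml) ops$PXS else ident,
    if (pml) ops$PY else ident, if (pml) ops$PYS else ident,
    grid$dt, medium$density, medium$sound_speed^2, grid$nt,
    sensors$idx0, TRUE, one, FALSE, record_energy)
  out <- structure(list(series = res$series, dt = grid$dt, snr_db = NULL,
                        n_sensors = sensors$n_sensors),
                   class = "sensor_data")
  if (record_energy) attr(out, "energy") <- as.vector(res$energy)
  out
}

#' @export
print.sensor_data <- function(x, ...) {
  cat(sprintf("<sensor_data> %d channels x %d samples, dt=%.4g us%s\n",
              nrow(x$series), ncol(x$series), x$dt * 1e6,
              if (is.null(x$snr_db)) " (clean)"
              else sprintf(", SNR %.1f dB", x$snr_db)))
  invisible(x)
}

#' Add calibrated Gaussian sensor noise
#'
#' Draws a target signal-to-noise ratio uniformly from `snr_db_range` and
#' adds white Gaussian noise whose variance is set from the global mean
#' square of the clean multichannel signal, so that
#' 10*log10(P_signal / P_noise) equals the drawn target.
#'
#' @param data A clean `sensor_data`.
#' @param snr_db_range Length-2 range of target SNR in dB.
#' @param seed Optional integer seed.
#' @param keep_clean Keep the clean series in the `clean` field.
#' @return A `sensor_data` with noisy `series` and realized `snr_db`.
#' @export
add_gaussian_noise <- function(data, snr_db_range = c(40, 60), seed = NULL,
                               keep_clean = TRUE) {
  stop_if(!inherits(data, "sensor_data"), "data must be sensor_data")
  psig <- mean(data$series^2)
  stop_if(psig == 0, "SNR undefined: the signal is identically zero")
  with_seed(seed, {
    target <- if (snr_db_range[1] == snr_db_range[2]) snr_db_range[1]
              else runif(1, snr_db_range[1], snr_db_range[2])
    sdn <- if (is.finite(target)) sqrt(psig / 10^(target / 10)) else 0
    noisy <- data$series + matrix(rnorm(length(data$series), 0, sdn),
                                  nrow(data$series))
    out <- data
    if (keep_clean) out$clean <- data$series
    out$series <- noisy
    out$snr_db <- target
    out
  })
}
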