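#' Sample a random phantom specification
#'
#' Draws one random absorber: shape kind uniform over triangle / square /
#' rectangle, circumradius uniform in \[5, 10\] pixels, peak intensity
#' (dimensionless absorbance) uniform in \[0, 1\], rotation uniform in
#' \[0, 2*pi), and a center placed uniformly so the shape lies inside the
#' grid. Rectangles additionally draw an aspect ratio uniform in \[1.5, 3\]
#' (a square is the aspect-1 case).
#'
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @param nx Grid side length in pixels.
#' @return An object of class `phantom_spec`.
#' @export
sample_phantom_spec <- function(seed = NULL, nx = 128L) {
  with_seed(seed, {
    kind <- sample(c("triangle", "square", "rectangle"), 1L)
    radius <- runif(1, 5, 10)
    spec <- list(
      shape_kind = kind,
      center = c(row = runif(1, 1 + radius, nx - radius),
                 col = runif(1, 1 + radius, nx - radius)),
      radius = radius,
      intensity = runif(1, 0, 1),
      rotation = runif(1, 0, 2 * pi),
      aspect = if (kind == "rectangle") runif(1, 1.5, 3) else 1
    )
    structure(spec, class = "phantom_spec")
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s r=%.2f px I=%.3f rot=%.2f rad at (%.1f, %.1f)\n",
              x$shape_kind, x$radius, x$intensity, x$rotation,
              x$center[1], x$center[2]))
  invisible(x)
}

# Polygon vertices (row, col) of a spec; convex, counter-clockwise.
phantom_vertices <- function(spec) {
  ctr <- spec$center
  rot <- spec$rotation
  r <- spec$radius
  ang <- switch(spec$shape_kind,
    triangle = rot + 2 * pi * (0:2) / 3,
    square = rot + pi / 4 + pi / 2 * (0:3),
    rectangle = NULL)
  if (!is.null(ang)) {
    return(cbind(row = ctr[1] + r * sin(ang), col = ctr[2] + r * cos(ang)))
  }
  a <- spec$aspect
  hw <- r * a / sqrt(1 + a^2) # half-width along the long axis
  hh <- r / sqrt(1 + a^2)
  base <- rbind(c(-hh, -hw), c(-hh, hw), c(hh, hw), c(hh, -hw)) # (row, col)
  R <- rbind(c(cos(rot), -sin(rot)), c(sin(rot), cos(rot)))
  v <- base %*% t(R)
  cbind(row = ctr[1] + v[, 1], col = ctr[2] + v[, 2])
}

#' Rasterize a phantom onto the pressure grid
#'
#' A pixel carries the spec's intensity iff its center (integer row/col
#' coordinates) lies strictly inside the convex polygon defined by the
#' shape's center, circumradius and rotation; all other pixels are zero.
#'
#' @param spec A `phantom_spec`.
#' @param nx Grid side length.
#' @return An `nx` x `nx` matrix (initial pressure, non-negative).
#' @export
rasterize_phantom <- function(spec, nx = 128L) {
  stop_if(!inherits(spec, "phantom_spec"), "rasterize_phantom() needs a phantom_spec")
  stop_if(spec$radius < 1, "degenerate phantom: circumradius below one pixel")
  v <- phantom_vertices(spec)
  n <- nrow(v)
  rows <- matrix(seq_len(nx), nx, nx)
  cols <- matrix(seq_len(nx), nx, nx, byrow = TRUE)
  inside <- matrix(TRUE, nx, nx)
  # half-plane test against each directed edge of the CCW polygon
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    er <- v[j, 1] - v[i, 1]; ec <- v[j, 2] - v[i, 2]
    cr <- (cols - v[i, 2]) * er - (rows - v[i, 1]) * ec
    inside <- inside & (cr < 0)
  }
  out <- matrix(0, nx, nx)
  out[inside] <- spec$intensity
  out
}

#' Generate a random multi-object phantom scene
#'
#' Sums `n_objects` independently sampled rasterized phantoms and clips the
#' result to \[0, 1\], so overlapping absorbers saturate rather than exceed
#' the normalized intensity range.
#'
#' @param n_objects Number of absorbers (>= 0).
#' @param seed Optional integer seed.
#' @param nx Grid side length.
#' @return An `nx` x `nx` matrix with values in \[0, 1\].
#' @export
generate_scene <- function(n_objects, seed = NULL, nx = 128L) {
  stop_if(n_objects < 0, "n_objects must be >= 0")
  with_seed(seed, {
    out <- matrix(0, nx, nx)
    for (i in seq_len(n_objects)) {
      out <- out + rasterize_phantom(sample_phantom_spec(nx = nx), nx = nx)
    }
    pmin(out, 1)
  })
}

#' Generate a vessel-like phantom scene
#'
#' Emulates thin branching vasculature: each branch is a correlated random
#' walk of unit steps whose heading diffuses, stamped with a 1-3 px wide
#' brush at intensity uniform in \[0.5, 1\]; child branches fork off at
#' random points. Values are clipped to \[0, 1\].
#'
#' @param seed Optional integer seed.
#' @param n_branches Number of root branches (0 gives an empty field).
#' @param nx Grid side length.
#' @return An `nx` x `nx` matrix with values in \[0, 1\].
#' @export
generate_vessel_scene <- function(seed = NULL, n_branches = 3L, nx = 128L) {
  stop_if(n_branches < 0, "n_branches must be >= 0")
  with_seed(seed, {
    out <- matrix(0, nx, nx)
    stamp <- function(r, c, wid, val) {
      rad <- (wid - 1) / 2
      rr <- max(1, floor(r - rad)):min(nx, ceiling(r + rad))
      cc <- max(1, floor(c - rad)):min(nx, ceiling(c + rad))
      for (i in rr) for (j in cc) {
        if ((i - r)^2 + (j - c)^2 <= (rad + 0.5)^2 && out[i, j] < val) out[i, j] <<- val
      }
    }
    walk <- function(r, c, heading, len, wid, val, depth) {
      for (s in seq_len(len)) {
        if (r < 2 || r > nx - 1 || c < 2 || c > nx - 1) return(invisible())
        stamp(r, c, wid, val)
        heading <- heading + rnorm(1, 0, 0.25)
        r <- r + sin(heading); c <- c + cos(heading)
        if (depth < 2 && runif(1) < 0.02) {
          walk(r, c, heading + sample(c(-1, 1), 1) * runif(1, 0.5, 1.2),
               round(len * runif(1, 0.3, 0.6)), max(1, wid - 1), val, depth + 1)
        }
      }
    }
    for (b in seq_len(n_branches)) {
      walk(runif(1, 20, nx - 20), runif(1, 20, nx - 20), runif(1, 0, 2 * pi),
           sample(30:80, 1), sample(1:3, 1), runif(1, 0.5, 1), 0)
    }
    pmin(out, 1)
  })
}

#' Generate a stack of random scenes
#'
#' Convenience generator for datasets: each scene draws its object count
#' uniformly from `n_objects_range` (geometric scenes) or uses root-branch
#' count 2-4 (vessel scenes).
#'
#' @param n_scenes Number of scenes.
#' @param seed Optional integer seed.
#' @param vessels Fraction of scenes drawn from the vessel generator.
#' @param n_objects_range Integer range for the per-scene object count.
#' @param nx Grid side length.
#' @return An `nx` x `nx` x `n_scenes` array.
#' @export
generate_scenes <- function(n_scenes, seed = NULL, vessels = 0,
                            n_objects_range = c(1L, 5L), nx = 128L) {
  with_seed(seed, {
    out <- array(0, c(nx, nx, n_scenes))
    for (i in seq_len(n_scenes)) {
      out[, , i] <- if (runif(1) < vessels) {
        generate_vessel_scene(n_branches = sample(2:4, 1), nx = nx)
      } else {
        generate_scene(sample(n_objects_range[1]:n_objects_range[2], 1), nx = nx)
      }
    }
    out
  })
}
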