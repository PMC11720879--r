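test_that("sampled phantom specs satisfy their invariants and are reproducible", {
  specs <- withr::with_seed(42, replicate(300, sample_phantom_spec(), simplify = FALSE))
  radii <- vapply(specs, `[[`, 0, "radius")
  ints <- vapply(specs, `[[`, 0, "intensity")
  rots <- vapply(specs, `[[`, 0, "rotation")
  kinds <- vapply(specs, `[[`, "", "shape_kind")
  expect_true(all(radii >= 5 & radii <= 10))
  expect_true(all(ints >= 0 & ints <= 1))
  expect_true(all(rots >= 0 & rots < 2 * pi))
  expect_setequal(unique(kinds), c("triangle", "square", "rectangle"))
  ctr <- t(vapply(specs, `[[`, c(0, 0), "center"))
  expect_true(all(ctr >= 1 & ctr <= 128))
  # determinism under identical seeds
  expect_identical(sample_phantom_spec(seed = 7), sample_phantom_spec(seed = 7))
})

test_that("sampled radii are uniform on [5, 10]", {
  radii <- vapply(1:10000, function(i) sample_phantom_spec(seed = i)$radius, 0)
  expect_gte(min(radii), 5)
  expect_lte(max(radii), 10)
  ks <- suppressWarnings(stats::ks.test(radii, "punif", 5, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("rasterization matches an exhaustive point-in-polygon oracle", {
  # axis-aligned square (rotation 0 puts the vertices on the diagonals, so
  # the edges align with the grid); off-lattice center and radius keep
  # pixel centers away from the measure-zero boundary case
  sq <- structure(list(shape_kind = "square", center = c(row = 64.2, col = 63.7),
                       radius = 8.3, intensity = 0.7, rotation = 0, aspect = 1),
                  class = "phantom_spec")
  expect_equal(rasterize_phantom(sq), oracle_raster(sq))
  expect_equal(sum(rasterize_phantom(sq) > 0),
               sum(oracle_raster(sq) > 0))
  set.seed(31)
  for (i in 1:3) {
    spec <- sample_phantom_spec()
    expect_equal(rasterize_phantom(spec), oracle_raster(spec))
  }
})

test_that("rasterization handles degenerate and trivial cases", {
  spec <- sample_phantom_spec(seed = 3)
  spec$intensity <- 0
  expect_equal(max(rasterize_phantom(spec)), 0)
  spec2 <- spec
  spec2$radius <- 0.5
  expect_error(rasterize_phantom(spec2), "degenerate")
  # rotation by a full turn leaves the raster unchanged
  spec3 <- sample_phantom_spec(seed = 4)
  spec4 <- spec3
  spec4$rotation <- spec3$rotation + 2 * pi
  expect_equal(rasterize_phantom(spec3), rasterize_phantom(spec4))
})

test_that("scenes compose rasterized phantoms and stay in [0, 1]", {
  expect_equal(generate_scene(0, seed = 1), matrix(0, 128, 128))
  # single-object scene equals rasterizing the first sampled spec
  expect_equal(generate_scene(1, seed = 11),
               rasterize_phantom(sample_phantom_spec(seed = 11)))
  for (s in 1:5) {
    sc <- generate_scene(5, seed = s)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_true(all(is.finite(sc)))
  }
})

test_that("vessel scenes are thin, sparse, reproducible structures", {
  expect_equal(generate_vessel_scene(seed = 1, n_branches = 0),
               matrix(0, 128, 128))
  expect_identical(generate_vessel_scene(seed = 5), generate_vessel_scene(seed = 5))
  frac <- vapply(1:100, function(s) {
    sc <- generate_vessel_scene(seed = s)
    mean(sc > 0)
  }, 0)
  expect_true(all(frac < 0.15))
  sc <- generate_vessel_scene(seed = 9)
  expect_true(all(sc[sc > 0] >= 0.5 & sc[sc > 0] <= 1))
})
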