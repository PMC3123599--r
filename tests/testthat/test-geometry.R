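test_that("empty geometry is fully accessible and has zero excluded volume", {
  g <- cell_geometry(1)
  expect_true(is_accessible(g, matrix(c(0, 0, 0), 1), 0.01))
  expect_false(is_accessible(g, matrix(c(0, 0, 1.2), 1), 0.01))
  # boundary: probe must fit inside the membrane
  expect_false(is_accessible(g, matrix(c(0, 0, 0.995), 1), 0.01))
  ex <- sample_excluded_fraction(g, 0.05, n_samples = 1000, seed = 1)
  expect_identical(ex$fraction, 0)
  # accessibility factor is 1 up to the (tiny) membrane-curvature term
  fa <- sample_access_factor(cell_geometry(50), 0.0025, 0.0025, 200, 50,
                             seed = 1)
  expect_gt(fa$fraction, 0.999)
})

test_that("generation is deterministic in the seed and validates inputs", {
  g1 <- generate_geometry(1, 100, 0.5, 0.02, 200, 0.03, seed = 7)
  g2 <- generate_geometry(1, 100, 0.5, 0.02, 200, 0.03, seed = 7)
  g3 <- generate_geometry(1, 100, 0.5, 0.02, 200, 0.03, seed = 8)
  expect_identical(g1$cylinders, g2$cylinders)
  expect_identical(g1$spheres, g2$spheres)
  expect_false(identical(g1$cylinders, g3$cylinders))
  expect_true(all(sqrt(g1$cylinders$ax^2 + g1$cylinders$ay^2 +
                         g1$cylinders$az^2) - 1 < 1e-9))
  expect_error(generate_geometry(-1, 10, 1, 0.1, 0, 1), "positive")
  expect_error(generate_geometry(1, 10, 0, 0.1, 0, 1), "positive")
})

test_that("single centred obstacle sphere gives the analytic volume ratio", {
  g <- cell_geometry(1, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                             radius = 0.5))
  ex <- sample_excluded_fraction(g, 0, n_samples = 4e4, seed = 3)
  expect_lt(abs(ex$fraction - 0.125), 3 * ex$standard_error)
  # probe inflation: excluded fraction grows to ((a + p)/R)^3 for p = 0.1
  ex2 <- sample_excluded_fraction(g, 0.1, n_samples = 4e4, seed = 4)
  expect_gt(ex2$fraction, ex$fraction)
  expect_lt(abs(ex2$fraction - 0.6^3), 3 * ex2$standard_error + 0.01)
})

test_that("cylinder accessibility respects the capsule boundary exactly", {
  g <- cell_geometry(1, cylinders = data.frame(
    cx = 0, cy = 0, cz = 0, ax = 0, ay = 0, az = 1,
    length = 0.8, radius = 0.05))
  probe <- 0.01
  r_in <- (0.05 + probe) * (1 - 1e-6)
  r_out <- (0.05 + probe) * (1 + 1e-6)
  expect_false(is_accessible(g, matrix(c(r_in, 0, 0), 1), probe))
  expect_true(is_accessible(g, matrix(c(r_out, 0, 0), 1), probe))
  # beyond the end cap the capsule test uses the segment end
  expect_true(is_accessible(g, matrix(c(r_in, 0, 0.45), 1), probe))
  expect_false(is_accessible(g, matrix(c(0, 0, 0.4 + 0.05 + probe - 1e-7), 1),
                             probe))
})

test_that("spatial index agrees with brute force and the R oracle", {
  g <- small_crowded_geometry(seed = 4, cell_radius = 0.8)
  set.seed(11)
  pts <- matrix(runif(3 * 4000, -0.85, 0.85), ncol = 3)
  via_index <- is_accessible(g, pts, 0.0025)
  via_brute <- is_accessible(g, pts, 0.0025, method = "brute")
  expect_identical(via_index, via_brute)
  expect_identical(via_index, r_is_accessible(g, pts, 0.0025))
  # larger probe, still within the index margin
  expect_identical(is_accessible(g, pts, 0.008),
                   is_accessible(g, pts, 0.008, method = "brute"))
})

test_that("excluded fraction is monotone in the probe radius", {
  g <- small_crowded_geometry(seed = 5, cell_radius = 0.8)
  probes <- c(0, 0.0025, 0.005, 0.009)
  fr <- vapply(probes, function(p)
    sample_excluded_fraction(g, p, n_samples = 2e4, seed = 9)$fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("access factor saturates with an impossibly dense geometry", {
  g <- cell_geometry(0.2, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                               radius = 0.199))
  expect_error(
    sample_access_factor(g, 0.0025, 0.0025, 100, 10, seed = 1,
                         max_reject_factor = 5),
    "saturated")
})

test_that("geometry CSV round trip is bit-exact", {
  g <- small_crowded_geometry(seed = 6, cell_radius = 0.6)
  path <- tempfile(fileext = ".csv")
  write_geometry_csv(g, path)
  g2 <- read_geometry_csv(path)
  expect_identical(g$cell_radius, g2$cell_radius)
  expect_equal(as.matrix(g$cylinders), as.matrix(g2$cylinders),
               tolerance = 0)
  expect_equal(as.matrix(g$spheres), as.matrix(g2$spheres), tolerance = 0)
  unlink(path)
})

test_that("surface sampler matches the analytic area of a single sphere", {
  a <- 0.2; probe <- 0.0025
  g <- cell_geometry(1, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                             radius = a))
  sa <- sample_surface_area(g, probe, n_samples = 2e4, seed = 3)
  expect_lt(abs(sa$area - 4 * pi * (a + probe)^2), 3 * sa$standard_error + 1e-9)
  # a sphere buried outside the membrane contributes nothing
  g2 <- cell_geometry(1, spheres = data.frame(cx = c(0, 5), cy = 0, cz = 0,
                                              radius = a))
  sa2 <- sample_surface_area(g2, probe, n_samples = 2e4, seed = 3)
  expect_lt(abs(sa2$area - 4 * pi * (a + probe)^2), 3 * sa2$standard_error + 1e-9)
})
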