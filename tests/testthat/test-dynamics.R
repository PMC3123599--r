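test_that("free-space displacements have the Brownian variance", {
  g <- cell_geometry(50)
  n <- 20000
  cfg <- simulation_config(
    g, species_spec("tracer", 0.0025, 1, n, init = "fixed",
                    positions = matrix(0, n, 3), record = TRUE),
    dt = 1e-3, t_end = 1e-3, observe_every = 1e-3, record_every = 1e-3,
    seed = 3)
  sim <- simulate(cfg)
  d <- sim$positions[, , 2] - sim$positions[, , 1]
  v <- apply(d, 2, var)
  # relative SE of a variance estimate is sqrt(2/n)
  expect_true(all(abs(v / (2 * 1 * 1e-3) - 1) < 3 * sqrt(2 / n)))
  expect_true(all(abs(colMeans(d)) < 3 * sqrt(2e-3 / n)))
})

test_that("immobile and enclosed particles never move", {
  # D = 0
  g <- cell_geometry(1)
  p0 <- matrix(c(0.1, 0.2, 0.3), 1)
  cfg <- simulation_config(
    g, species_spec("x", 0.0025, 0, 1, init = "fixed", positions = p0,
                    record = TRUE),
    dt = 1e-4, t_end = 0.01, observe_every = 1e-3, record_every = 1e-3,
    seed = 4)
  sim <- simulate(cfg)
  expect_true(all(sim$positions[1, 1, ] == 0.1))
  # mobile but fully enclosed: cell barely larger than the probe
  g2 <- cell_geometry(0.0026)
  cfg2 <- simulation_config(
    g2, species_spec("x", 0.0025, 1, 1, init = "fixed",
                     positions = matrix(0, 1, 3), record = TRUE),
    dt = 1e-4, t_end = 0.01, observe_every = 1e-3, record_every = 1e-3,
    seed = 4)
  sim2 <- simulate(cfg2)
  expect_true(all(sim2$positions == 0))
})

test_that("trajectories are reproducible for a fixed seed, distinct otherwise", {
  g <- small_crowded_geometry(seed = 3, cell_radius = 0.6)
  s1 <- diffuse_tracers(g, 20, dt = 1e-5, t_end = 0.005, seed = 9)
  s2 <- diffuse_tracers(g, 20, dt = 1e-5, t_end = 0.005, seed = 9)
  s3 <- diffuse_tracers(g, 20, dt = 1e-5, t_end = 0.005, seed = 10)
  expect_identical(s1$positions, s2$positions)
  expect_false(identical(s1$positions, s3$positions))
})

test_that("no particle is ever observed at an inaccessible position", {
  g <- small_crowded_geometry(seed = 7, cell_radius = 0.6)
  sim <- diffuse_tracers(g, 100, dt = 2e-5, t_end = 0.02,
                         record_every = 2e-4, seed = 12)
  nf <- dim(sim$positions)[3]
  for (f in seq(1, nf, by = 7)) {
    expect_true(all(r_is_accessible(g, sim$positions[, , f], 0.0025)))
  }
})
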