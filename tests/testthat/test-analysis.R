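test_that("MSD of static particles is identically zero", {
  pos <- array(rep(matrix(rnorm(30), 10, 3), 5), dim = c(10, 3, 5))
  m <- compute_msd(pos, times = seq(0, 0.4, by = 0.1))
  expect_true(all(m$msd == 0))
  expect_equal(m$msd[m$lag == 0], 0)
})

test_that("exact linear MSD recovers the diffusion coefficient", {
  # deterministic ballistic construction giving msd = 6 D t exactly
  D <- 0.35
  times <- seq(0, 1, by = 0.05)
  nf <- length(times)
  pos <- array(0, dim = c(4, 3, nf))
  for (f in seq_len(nf)) pos[, , f] <- sqrt(2 * D * times[f])
  m <- compute_msd(pos, times = times, use_multiple_origins = FALSE)
  est <- suppressWarnings(estimate_Deff(m, c(0, 1)))  # perfect-fit lm warning
  expect_equal(est$D, D, tolerance = 1e-10)
  expect_error(estimate_Deff(m, c(0.9, 0.91)), "fewer than 3")
})

test_that("free diffusion is linear and a half-immobile mix halves the slope", {
  g <- cell_geometry(30)
  n <- 1200
  pos0 <- matrix(0, n, 3)
  cfg <- simulation_config(
    g, species_spec("t", 0.0025, 1, n, init = "fixed", positions = pos0,
                    record = TRUE),
    dt = 1e-4, t_end = 0.08, observe_every = 2e-3, record_every = 2e-3,
    seed = 21)
  sim <- simulate(cfg)
  m <- compute_msd(sim)
  fit <- lm(msd ~ lag, data = m[m$lag > 0, ])
  expect_gt(summary(fit)$r.squared, 0.99)
  est <- estimate_Deff(m, c(0.01, 0.08))
  expect_lt(abs(est$D - 1), 0.08)
  # ensemble with half the particles immobile: slope halves
  pos_mix <- sim$positions
  pos_mix[seq_len(n / 2), , ] <- pos_mix[seq_len(n / 2), , 1]
  m2 <- compute_msd(pos_mix, times = sim$record_times)
  est2 <- estimate_Deff(m2, c(0.01, 0.08))
  expect_lt(abs(est2$D - est$D / 2), 0.05)
})

test_that("lags beyond the trajectory are dropped with a warning", {
  pos <- array(rnorm(10 * 3 * 6), dim = c(10, 3, 6))
  expect_warning(m <- compute_msd(pos, times = seq(0, 0.5, by = 0.1),
                                  lags = c(0.1, 0.2, 5)), "dropped")
  expect_true(all(m$lag <= 0.5))
})

test_that("unbound fraction is 1 without binding and decays to 0 without release", {
  g <- cell_geometry(1, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                             radius = 0.3))
  cfg <- simulation_config(
    g, species_spec("T", 0.0025, 1, 150, record = TRUE),
    dt = 1e-4, t_end = 0.05, observe_every = 5e-3, seed = 3)
  sim <- simulate(cfg)
  fu <- unbound_fraction(sim, "T")
  expect_true(all(fu$series$fu == 1))
  cfg2 <- simulation_config(
    g, species_spec("T", 0.0025, 1, 150, record = TRUE),
    reactions = list(rx_adsorption("T", kappa = 20)),
    dt = 1e-4, t_end = 4, observe_every = 0.2, seed = 3)
  sim2 <- simulate(cfg2)
  fu2 <- unbound_fraction(sim2, "T")
  expect_lt(fu2$fu, 0.05)
  expect_true(all(diff(sim2$bound[, 1]) >= 0))
})
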