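test_that("crowding factors reproduce the closed-form values", {
  expect_equal(f_vol(0), 1)
  expect_equal(f_vol(0.5), 2)
  expect_equal(round(f_vol(0.305), 2), 1.44)
  expect_error(f_vol(1), "epsilon")
  expect_equal(f_diff(0.5, 1), 1)
  expect_equal(round(f_diff(0.1, 0.77), 2), 0.97)
  # direct evaluation at beta = 0.3 (sharper than the printed 2 d.p.)
  expect_equal(f_diff(0.3, 0.77), 0.77 / (0.3 + 0.77 * 0.7), tolerance = 1e-12)
  expect_equal(round(f_diff(0.3, 0.77), 3), 0.918)
  cf <- crowding_factors(0.305, 0.1, 0.77, f_access = 0.966)
  expect_equal(round(cf$f_eff, 2), 1.35)
  expect_equal(f_eff(cf), cf$f_vol * cf$f_diff * cf$f_access)
})

test_that("f_diff equals the recomposed micro-rate/collision-rate chain", {
  set.seed(42)
  k_D <- collision_rate_kD(0.0025, 0.0025, 1, 1)
  for (i in 1:25) {
    beta <- runif(1, 0, 0.95)
    delta <- runif(1, 0.05, 1)
    k_macro <- beta * k_D
    k_micro <- micro_rate(k_macro, k_D)
    k_eff <- macro_rate(k_micro, delta * k_D)  # scaled diffusion limit
    expect_equal(k_eff / k_macro, f_diff(beta, delta), tolerance = 1e-12)
  }
})

test_that("well-mixed steady state matches the enzyme bookkeeping", {
  expect_equal(ode_steady_state(0, 7.57e5, 2e-7)$count, 0)
  ss <- ode_steady_state(3.78e-9, 7.57e5, 2e-7)
  expect_equal(ss$count, 2575, tolerance = 2e-3)
  expect_equal(ode_steady_state(2 * 3.78e-9, 7.57e5, 2e-7)$count, 2 * ss$count)
  # the in-vivo variant is exactly the in-vitro one divided by f_eff
  fe <- 1.35
  expect_equal(ode_steady_state(3.78e-9, 7.57e5, 2e-7, f_eff = fe)$count,
               ss$count / fe)
  expect_error(ode_steady_state(1, 0, 1), "positive")
})

test_that("Gillespie birth-death matches the analytic Poisson steady state", {
  # birth lam, per-capita death mu: stationary distribution Poisson(lam/mu)
  lam <- 200; mu <- 4
  g <- gillespie_run(c(S = 50),
                     list(rx_zero_order("S", molecules_per_s = lam),
                          rx_unimolecular("S", character(0), k = mu)),
                     volume = 1, t_end = 30, seed = 11, record_every = 0.05)
  w <- g$times > 3
  m <- mean(g$counts[w, "S"])
  v <- var(g$counts[w, "S"])
  expect_lt(abs(m - lam / mu), 3)
  expect_lt(abs(v / m - 1), 0.35)
  # determinism and constant systems
  g2 <- gillespie_run(c(S = 50),
                      list(rx_zero_order("S", molecules_per_s = lam),
                           rx_unimolecular("S", character(0), k = mu)),
                      volume = 1, t_end = 30, seed = 11, record_every = 0.05)
  expect_identical(g$counts, g2$counts)
  g3 <- gillespie_run(c(S = 7), list(), volume = 1, t_end = 1, seed = 1)
  expect_true(all(g3$counts == 7))
})

test_that("Gillespie bimolecular channel reproduces the ODE steady state", {
  # the test model at reduced scale: source + S + E -> E
  v <- 17.1
  nE <- 2060
  cE <- nE / (v * NA_FACTOR)
  k1 <- 3.78e-9; k2 <- 7.57e5
  g <- gillespie_run(c(S = 257, E = nE),
                     list(rx_zero_order("S", molecules_per_s =
                                          conc_to_count(k1, v)),
                          rx_bimolecular(c("S", "E"), "E", k2)),
                     volume = v, t_end = 150, seed = 5, record_every = 0.5)
  w <- g$times > 30
  pred <- k1 / (k2 * cE) / cE * nE
  m <- mean(g$counts[w, "S"])
  expect_lt(abs(m - pred) / pred, 0.05)
  expect_true(all(g$counts[, "E"] == nE))
})

test_that("homogenized configuration rescales volume and mobility correctly", {
  g <- small_crowded_geometry(seed = 2, cell_radius = 0.7)
  cfg <- simulation_config(
    g, list(species_spec("S", 0.0025, 1, 50),
            species_spec("E", 0.0025, 1, 100)),
    reactions = list(rx_zero_order("S", k_macro = 1e-9),
                     rx_bimolecular(c("S", "E"), "E", 7.57e5)),
    dt = 1e-5, t_end = 0.1, observe_every = 0.01, seed = 2)
  h <- homogenized_cell_config(cfg, epsilon = 0.305, delta = 0.77)
  expect_equal(sphere_volume(h$geometry$cell_radius),
               0.695 * sphere_volume(0.7), tolerance = 1e-12)
  expect_equal(h$species[[1]]$D0, 0.77)
  expect_equal(nrow(h$geometry$cylinders), 0)
  # kernel derived from the in-vitro diffusion: identical k_micro
  expect_equal(h$kernels$k_micro, cfg$kernels$k_micro)
  # the identity transform changes nothing
  id <- homogenized_cell_config(cfg, 0, 1)
  expect_equal(id$geometry$cell_radius, 0.7)
  expect_equal(id$species[[2]]$D0, 1)
  # source strength is preserved in absolute molecules per second
  expect_equal(id$reactions[[1]]$molecules_per_s,
               conc_to_count(1e-9, sphere_volume(0.7)))
})
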