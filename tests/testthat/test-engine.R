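test_that("runs are bit-reproducible and observation cadence is passive", {
  g <- cell_geometry(0.5)
  mk <- function(obs, seed) {
    cfg <- simulation_config(
      g, list(species_spec("A", 0.0025, 1, 50),
              species_spec("B", 0.0025, 1, 50)),
      reactions = list(rx_bimolecular(c("A", "B"), character(0), 1e7)),
      dt = 1e-5, t_end = 0.01, observe_every = obs, seed = seed)
    simulate(cfg)
  }
  s1 <- mk(1e-3, 5)
  s2 <- mk(1e-3, 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$final$positions, s2$final$positions)
  # different observation interval, same dynamics
  s3 <- mk(2e-3, 5)
  expect_identical(s1$final$positions, s3$final$positions)
  # different seed, different trajectory
  s4 <- mk(1e-3, 6)
  expect_false(identical(s1$final$positions, s4$final$positions))
  # counts never negative and monotone events
  expect_true(all(s1$counts >= 0))
  expect_true(all(diff(s1$events[, 1]) >= 0))
})

test_that("mass balance: count changes equal net logged events", {
  g <- cell_geometry(0.5)
  cfg <- simulation_config(
    g, list(species_spec("S", 0.0025, 1, 100),
            species_spec("E", 0.0025, 1, 200),
            species_spec("P", 0.0025, 1, 0)),
    reactions = list(
      rx_zero_order("S", molecules_per_s = 500),
      rx_bimolecular(c("S", "E"), c("P", "E"), 2e7),
      rx_unimolecular("P", character(0), k = 5)),
    dt = 1e-5, t_end = 0.5, observe_every = 0.05, seed = 8)
  sim <- simulate(cfg)
  nt <- length(sim$times)
  births <- sim$events[nt, 1]
  conv <- sim$events[nt, 2]
  decay <- sim$events[nt, 3]
  expect_identical(unname(sim$counts[nt, "S"]), as.integer(100 + births - conv))
  expect_identical(unname(sim$counts[nt, "P"]), as.integer(conv - decay))
  expect_identical(unname(sim$counts[nt, "E"]), 200L)
})

test_that("unimolecular decay follows the exponential law", {
  g <- cell_geometry(1)
  cfg <- simulation_config(
    g, species_spec("X", 0.0025, 1, 10000),
    reactions = list(rx_unimolecular("X", character(0), k = 10)),
    dt = 1e-3, t_end = 0.2, observe_every = 0.02, seed = 3)
  sim <- simulate(cfg)
  expected <- 10000 * exp(-10 * sim$times)
  # binomial-scale tolerance around the closed-form decay
  expect_true(all(abs(sim$counts[, 1] - expected) <
                    4 * sqrt(expected + 1) + 10))
})

test_that("zero-order creation has the right Poisson mean and placement", {
  g <- small_crowded_geometry(seed = 9, cell_radius = 0.6)
  lam <- conc_to_count(2e-7, sphere_volume(0.6))  # molecules per second
  cfg <- simulation_config(
    g, species_spec("S", 0.0025, 0, 0),
    reactions = list(rx_zero_order("S", k_macro = 2e-7)),
    dt = 1e-4, t_end = 2, observe_every = 0.5, seed = 4)
  sim <- simulate(cfg)
  nt <- length(sim$times)
  created <- sim$counts[nt, 1]
  expect_lt(abs(created - lam * 2), 4 * sqrt(lam * 2))
  expect_true(all(r_is_accessible(g, sim$final$positions, 0.0025)))
})

test_that("dissociation restores mobility with the right mean lifetime", {
  # bind everything instantly via a huge adsorption layer target, then watch
  # unbinding statistics
  a <- 0.2
  g <- cell_geometry(1, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                             radius = a))
  k_diss <- 20
  cfg <- simulation_config(
    g, species_spec("T", 0.0025, 1, 400, record = TRUE),
    reactions = list(rx_adsorption("T", kappa = 5),
                     rx_dissociation("T", k_diss)),
    dt = 1e-4, t_end = 1.5, observe_every = 0.01, seed = 6)
  sim <- simulate(cfg)
  nt <- length(sim$times)
  # steady state detailed balance: fu = k_diss / (k_diss + kappa A / V_acc)
  A <- 4 * pi * (a + 0.0025)^2
  v_acc <- 4 / 3 * pi * ((1 - 0.0025)^3 - (a + 0.0025)^3)
  k_bind <- 5 * A / v_acc
  fu_pred <- k_diss / (k_diss + k_bind)
  fu <- unbound_fraction(sim, "T")
  expect_lt(abs(fu$fu - fu_pred), 0.05)
  # mean bound lifetime from event bookkeeping: diss events / mean bound
  w <- sim$times >= 0.5
  diss_rate <- (sim$events[nt, 2] - sim$events[which(w)[1], 2]) /
    (sim$times[nt] - sim$times[which(w)[1]])
  mean_bound <- mean(sim$bound[w, 1])
  expect_lt(abs(diss_rate / mean_bound - k_diss) / k_diss, 0.15)
})

test_that("membrane export decays at the diffusion-controlled rate", {
  R <- 0.5
  g <- cell_geometry(R)
  cfg <- simulation_config(
    g, species_spec("X", 0.0025, 1, 4000),
    reactions = list(rx_membrane_export("X")),
    dt = 1e-5, t_end = 0.06, observe_every = 2e-3, seed = 7)
  sim <- simulate(cfg)
  # late-time survival decays with the slowest mode of an absorbing sphere,
  # lambda_1 = pi^2 D / R_abs^2 (first-passage eigenvalue)
  R_abs <- R - 0.0025 - sqrt(6 * 1 * 1e-5)
  lam1 <- pi^2 * 1 / R_abs^2
  w <- sim$times >= 0.02 & sim$counts[, 1] > 20
  fit <- lm(log(sim$counts[w, 1]) ~ sim$times[w])
  expect_lt(abs(-coef(fit)[2] - lam1) / lam1, 0.15)
})

test_that("membrane influx places molecules in the accessible shell", {
  g <- cell_geometry(0.5)
  cfg <- simulation_config(
    g, species_spec("M", 0.0025, 0, 0),
    reactions = list(rx_membrane_influx("M", 1000, shell_thickness = 0.05)),
    dt = 1e-4, t_end = 0.5, observe_every = 0.1, seed = 8)
  sim <- simulate(cfg)
  nt <- length(sim$times)
  expect_lt(abs(sim$counts[nt, 1] - 500), 4 * sqrt(500))
  r <- sqrt(rowSums(sim$final$positions^2))
  expect_true(all(r >= 0.45 - 1e-12 & r <= 0.5 - 0.0025 + 1e-12))
})

test_that("steady_state_average handles constants and bad windows", {
  x <- rep(42, 100)
  ss <- steady_state_average(x, window = c(10, 90), times = seq_len(100))
  expect_equal(ss$mean, 42)
  expect_equal(ss$sd, 0)
  expect_equal(ss$se, 0)
  expect_error(steady_state_average(x, window = c(200, 300),
                                    times = seq_len(100)), "empty")
})

test_that("configuration validation rejects inconsistent setups", {
  g <- cell_geometry(1)
  sp <- list(species_spec("A", 0.0025, 1, 10))
  expect_error(simulation_config(g, sp, list(
    rx_bimolecular(c("A", "B"), character(0), 1e6)), dt = 1e-5, t_end = 1),
    "unknown species")
  # macroscopic rate above the diffusion limit
  expect_error(simulation_config(g, list(species_spec("A", 0.0025, 1, 1),
                                         species_spec("B", 0.0025, 1, 1)),
    list(rx_bimolecular(c("A", "B"), character(0), 1e9)),
    dt = 1e-5, t_end = 1), "diffusion limit")
  # reaction probability above 1
  expect_error(simulation_config(g, list(species_spec("A", 0.0025, 1, 1),
                                         species_spec("B", 0.0025, 1, 1)),
    list(rx_bimolecular(c("A", "B"), character(0), 7e7)),
    dt = 1e-2, t_end = 1), "dt")
  # recorded species must be inert
  expect_error(simulation_config(g,
    list(species_spec("A", 0.0025, 1, 10, record = TRUE)),
    list(rx_unimolecular("A", character(0), 1)), dt = 1e-5, t_end = 1),
    "recorded")
  # adsorption layer must stay below the obstacle scale
  gs <- cell_geometry(1, spheres = data.frame(cx = 0.5, cy = 0, cz = 0,
                                              radius = 0.01))
  expect_error(simulation_config(gs,
    list(species_spec("A", 0.0025, 1, 10)),
    list(rx_adsorption("A", kappa = 2000)), dt = 1e-4, t_end = 1),
    "r_structure")
})
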