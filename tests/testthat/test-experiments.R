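test_that("in-vitro presets carry the published rate pairs", {
  for (row in list(c(0.01, 3.78e-9, 7.57e5),
                   c(0.1, 3.78e-8, 7.57e6),
                   c(0.3, 1.14e-7, 2.27e7))) {
    cfg <- preset_in_vitro(row[1], volume_scale = 0.01)
    expect_equal(cfg$meta$k1, row[2])
    expect_equal(cfg$meta$k2, row[3])
    expect_equal(cfg$meta$cE, 2e-7)
    # predicted steady state ~2575 per unit volume scale (the published rate
    # pairs are rounded, so the three betas agree only to ~0.5%)
    expect_equal(cfg$meta$prediction / 0.01, 2575, tolerance = 6e-3)
  }
  expect_error(preset_in_vitro(0.2), "beta")
  # species: 2.5 nm, D = 1, enzyme count fixes cE
  cfg <- preset_in_vitro(0.1, volume_scale = 0.05)
  expect_equal(cfg$meta$n_E, round(20600 * 0.05))
  expect_equal(conc_to_count(2e-7, cfg$meta$volume), cfg$meta$n_E,
               tolerance = 1e-3)
  # timestep obeys the probability and step-length bounds
  kern <- cfg$kernels
  expect_lte(kern$P_react, 0.1)
  expect_lte(sqrt(6 * 1 * cfg$dt), kern$R_crit * (1 + 1e-9))
})

test_that("in-vivo preset swaps in the crowded geometry, keeping the model", {
  g <- small_crowded_geometry(seed = 3, cell_radius = 0.5)
  vs <- sphere_volume(0.5) / (20600 / (2e-7 * NA_FACTOR))
  cfg <- preset_in_vivo(0.01, volume_scale = vs, geometry = g)
  expect_gt(nrow(cfg$geometry$cylinders), 0)
  expect_equal(cfg$meta$k2, 7.57e5)
  expect_equal(cfg$geometry$cell_radius, 0.5, tolerance = 1e-6)
})

test_that("binding preset converts the target fu into adsorption rates", {
  g <- small_crowded_geometry(seed = 4, cell_radius = 0.6)
  cfg <- preset_binding(25, 0.5, geometry = g, n_tracers = 10)
  expect_equal(cfg$meta$k_bind, 25)
  expect_gt(cfg$meta$kappa, 0)
  expect_length(cfg$reactions, 2)
  # fu target of 1 disables binding entirely
  cfg1 <- preset_binding(25, 1, geometry = g, n_tracers = 10)
  expect_equal(cfg1$meta$kappa, 0)
  expect_length(cfg1$reactions, 0)
})

test_that("channeling layouts share totals and differ only in placement", {
  cfgs <- lapply(c("channel", "layer", "random", "wellmixed"), function(ly)
    preset_channeling(ly, cell_radius = 0.5, n_enzymes = 40,
                      influx_rate = 50, t_end = 0.1, seed = 5))
  for (cfg in cfgs) {
    counts <- vapply(cfg$species, `[[`, integer(1), "count")
    expect_identical(unname(counts),
                     c(0L, 0L, 0L, 0L, 40L, 40L, 40L))
    # enzymes are immobilized
    d0 <- vapply(cfg$species, `[[`, numeric(1), "D0")
    expect_true(all(d0[5:7] == 0))
    expect_length(cfg$reactions, 5)
  }
  # layer/channel enzymes inside the membrane shell
  shellpos <- cfgs[[2]]$species[[5]]$positions
  r <- sqrt(rowSums(shellpos^2))
  expect_true(all(r >= 0.45 - 1e-9))
  # channel complexes: E2 close to an E1, E3 close to an E2
  e1 <- cfgs[[1]]$species[[5]]$positions
  e2 <- cfgs[[1]]$species[[6]]$positions
  offs <- sqrt(rowSums((e2 - e1)^2))
  expect_true(all(abs(offs - 4 * 0.0025) < 1e-9))
  # well-mixed variant ships a Gillespie-ready reaction set
  wm <- cfgs[[4]]$meta
  expect_length(wm$gillespie_reactions, 5)
  expect_identical(unname(wm$gillespie_counts),
                   c(0L, 0L, 0L, 0L, 40L, 40L, 40L))
})
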