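test_that("collision rate constant reproduces the Smoluchowski values", {
  # two 2.5 nm reactants, D = 1 um^2/s each
  expect_equal(collision_rate_kD(0.0025, 0.0025, 1, 1), 7.57e7,
               tolerance = 2e-3)
  # one partner immobilized
  expect_equal(collision_rate_kD(0.0025, 0.0025, 1, 0), 3.78e7,
               tolerance = 2e-3)
  # linear in the contact radius
  expect_equal(collision_rate_kD(0.005, 0.005, 1, 1),
               2 * collision_rate_kD(0.0025, 0.0025, 1, 1))
  expect_error(collision_rate_kD(0.0025, 0.0025, 0, 0), "positive")
})

test_that("micro and macro rates are exact inverses below the limit", {
  k_D <- collision_rate_kD(0.0025, 0.0025, 1, 1)
  expect_identical(micro_rate(0, k_D), 0)
  # algebraic fixed point: half the limit maps to the limit itself
  expect_equal(micro_rate(0.5 * k_D, k_D), k_D)
  expect_equal(micro_rate(0.3 * k_D, k_D), 3 / 7 * k_D)
  for (f in c(1e-6, 0.01, 0.3, 0.9, 0.99)) {
    expect_equal(macro_rate(micro_rate(f * k_D, k_D), k_D), f * k_D,
                 tolerance = 1e-12)
  }
  expect_error(micro_rate(k_D, k_D), "diffusion limit")
})

test_that("per-step reaction probability matches the hand-derived chain", {
  # beta = 0.01 test setup at dt = 1e-5 s
  k_D <- collision_rate_kD(0.0025, 0.0025, 1, 1)
  k_micro <- micro_rate(7.57e5, k_D)
  p <- reaction_probability(k_micro, 1e-5, 0.0025, 0.0025)
  expect_equal(p, 0.02425, tolerance = 1e-3)
  expect_identical(reaction_probability(0, 1e-5, 0.0025, 0.0025), 0)
  expect_equal(reaction_probability(k_micro, 5e-6, 0.0025, 0.0025), p / 2)
  expect_error(reaction_probability(k_micro, 1, 0.0025, 0.0025),
               "dt must be <=")
})

test_that("volume-derived reaction radius follows the cube-root law", {
  expect_identical(pogson_reaction_radius(0, 1e-5), 0)
  r1 <- pogson_reaction_radius(1e6, 1e-5)
  expect_equal(pogson_reaction_radius(1e6, 8e-5), 2 * r1)
  # unit case: reaction volume 4 pi / 3 um^3 per molecule gives radius 1 um
  k_unit <- 4 / 3 * pi * 6.02214076e8
  expect_equal(pogson_reaction_radius(k_unit, 1), 1)
})

test_that("kernel bundle is internally consistent", {
  kern <- bimolecular_kernel(7.57e6, 0.0025, 0.0025, 1, 1, 2e-6)
  expect_equal(kern$R_crit, 0.005)
  expect_equal(kern$beta, 7.57e6 / kern$k_D)
  expect_equal(macro_rate(kern$k_micro, kern$k_D), 7.57e6, tolerance = 1e-10)
  expect_lte(kern$P_react, 1)
})

test_that("bulk binding rate converts to a surface velocity consistently", {
  a <- 0.2
  g <- cell_geometry(1, spheres = data.frame(cx = 0, cy = 0, cz = 0,
                                             radius = a))
  conv <- kappa_from_kbind(g, k_bind = 10, probe_radius = 0.0025,
                           n_samples = 2e4, seed = 2)
  v_acc <- 4 / 3 * pi * (1^3 - (a + 0.0025)^3)
  kappa_expect <- 10 * v_acc / (4 * pi * (a + 0.0025)^2)
  expect_equal(conv$kappa, kappa_expect, tolerance = 0.05)
})
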