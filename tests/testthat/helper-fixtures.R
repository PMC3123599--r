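# Shared fixtures and independent oracles for the test suite.

NA_FACTOR <- 6.02214076e8  # molecules per (mol/L * um^3)

# small crowded geometry for fast tests
small_crowded_geometry <- function(seed = 2, cell_radius = 1) {
  vs <- (cell_radius / 3.5)^3
  generate_geometry(cell_radius, 25000 * vs, 2.5, 0.0175, 100000 * vs, 0.03,
                    seed = seed, density_multiplier = 0.791)
}

# independent accessibility oracle in plain R: membrane containment plus
# capsule/sphere distance tests straight off the geometry tables
r_is_accessible <- function(geom, points, probe) {
  points <- matrix(points, ncol = 3)
  out <- sqrt(rowSums(points^2)) <= geom$cell_radius - probe
  cyl <- geom$cylinders
  sph <- geom$spheres
  for (i in which(out)) {
    p <- points[i, ]
    if (nrow(cyl)) {
      d <- cbind(p[1] - cyl$cx, p[2] - cyl$cy, p[3] - cyl$cz)
      t_ax <- d[, 1] * cyl$ax + d[, 2] * cyl$ay + d[, 3] * cyl$az
      t_ax <- pmin(pmax(t_ax, -cyl$length / 2), cyl$length / 2)
      e <- d - cbind(t_ax * cyl$ax, t_ax * cyl$ay, t_ax * cyl$az)
      if (any(rowSums(e^2) < (cyl$radius + probe)^2)) {
        out[i] <- FALSE
        next
      }
    }
    if (nrow(sph)) {
      d2 <- (p[1] - sph$cx)^2 + (p[2] - sph$cy)^2 + (p[3] - sph$cz)^2
      if (any(d2 < (sph$radius + probe)^2)) out[i] <- FALSE
    }
  }
  out
}

# full-size calibrated geometry, built once per test session
.acc_env <- new.env()
acceptance_geometry <- function() {
  if (is.null(.acc_env$geom)) {
    .acc_env$geom <- default_cell_geometry(seed = 1)
    build_spatial_index(.acc_env$geom)
  }
  .acc_env$geom
}

# effective bimolecular rate constant and its Poisson standard error from a
# consuming decay run: k = events / (cE * integral N_S dt)
decay_rate_estimate <- function(sim, cE) {
  nt <- length(sim$times)
  events <- sim$events[nt, 2] - sim$events[1, 2]
  int_NS <- sum(diff(sim$times) *
                  (head(sim$counts[, "S"], -1) + tail(sim$counts[, "S"], -1)) / 2)
  k <- events / (cE * int_NS)
  list(k = k, se = k / sqrt(max(events, 1)))
}

# consuming S + E -> E decay run in an empty cell (well-mixed dilute box)
run_decay <- function(k2, dt, n_S = 2000, n_E = 687, volume = 1.1406,
                      t_end = NULL, seed = 1) {
  r_cell <- (3 * volume / (4 * pi))^(1 / 3)
  cE <- n_E / (volume * NA_FACTOR)
  if (is.null(t_end)) t_end <- 1.2 / (k2 * cE)
  obs <- 1000 * dt
  cfg <- simulation_config(
    cell_geometry(r_cell),
    species = list(species_spec("S", 0.0025, 1, n_S),
                   species_spec("E", 0.0025, 1, n_E)),
    reactions = list(rx_zero_order("S", molecules_per_s = 0),
                     rx_bimolecular(c("S", "E"), "E", k2)),
    dt = dt, t_end = ceiling(t_end / obs) * obs, observe_every = obs,
    seed = seed)
  list(sim = simulate(cfg), cE = cE)
}
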