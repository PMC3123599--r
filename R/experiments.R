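# Preset experiment configurations: the source/enzymatic-consumption test
# model in an empty ("in vitro") and crowded ("in vivo") cell, transient
# binding of inert tracers, and the metabolic-channeling enzyme layouts.

# Test-model rate table (k1 mol/(L s), k2 L/(mol s)) per degree of diffusion
# limitation beta = k2 / k_D for 2.5 nm reactants with D = 1 um^2/s.
.test_model_rates <- data.frame(
  beta = c(0.01, 0.1, 0.3),
  k1 = c(3.78e-9, 3.78e-8, 1.14e-7),
  k2 = c(7.57e5, 7.57e6, 2.27e7))

.test_model_cE <- 2e-7    # mol/L
.test_model_nE <- 20600L  # molecules at cE; fixes the volume convention

# Cell volume of the test model: the enzyme count at the stated concentration
# implies V = n_E / (cE * N_A/1e15) ~ 171 um^3 (slightly below the nominal
# 7 um sphere); adopting it reproduces the model's printed steady states.
test_model_volume <- function(volume_scale = 1) {
  .test_model_nE / (.test_model_cE * .NA_FACTOR) * volume_scale
}

#' Timestep selection for a bimolecular experiment
#'
#' The default timestep is the largest `dt` (rounded down to one significant
#' digit) satisfying two bounds: the per-pair reaction probability stays
#' below `p_max`, and - where the reaction is appreciably diffusion limited
#' (`beta >= 0.1`) or obstacles must be resolved - the rms displacement per
#' step `sqrt(6 D dt)` stays below a length scale `step_limit` (the collision
#' radius, or the smallest obstacle radius).
#'
#' @param k_macro macroscopic rate constant, L/(mol s)
#' @param r_i,r_j,D_i,D_j reactant radii (um) and diffusion coefficients
#'   (um^2/s)
#' @param p_max per-pair probability bound
#' @param step_limit rms-step bound, um (`Inf` to disable)
#' @return timestep in s
#' @export
auto_dt <- function(k_macro, r_i, r_j, D_i, D_j, p_max = 0.1,
                    step_limit = Inf) {
  k_D <- collision_rate_kD(r_i, r_j, D_i, D_j)
  k_micro <- micro_rate(k_macro, k_D)
  v_coll <- 4 / 3 * pi * (r_i + r_j)^3
  dt_p <- p_max * v_coll / (k_micro / .NA_FACTOR)
  dt_step <- if (is.finite(step_limit)) {
    step_limit^2 / (6 * max(D_i, D_j))
  } else Inf
  dt <- min(dt_p, dt_step)
  # floor to one significant digit for readable manifests
  e <- 10^floor(log10(dt))
  floor(dt / e) * e
}

lookup_rates <- function(beta) {
  i <- match(beta, .test_model_rates$beta)
  if (is.na(i)) stop("beta must be one of 0.01, 0.1, 0.3")
  .test_model_rates[i, ]
}

#' Preset: well-mixed test model in an empty virtual cell
#'
#' Substrate molecules are created in a zero-order reaction (rate `k1`) and
#' consumed by enzymes in the mass-action channel `S + E -> P + E` (rate
#' `k2`); the inert product is not instantiated. Both species have radius
#' 2.5 nm and `D = 1` um^2/s; the enzyme count is 20,600 at `2e-7` mol/L.
#' The substrate population starts at the deterministic steady state and
#' fluctuates around it. `volume_scale` shrinks the cell at identical
#' concentrations (all counts scale with the volume) to keep run times
#' proportionate.
#'
#' @param beta degree of diffusion limitation `k2 / k_D`: 0.01, 0.1 or 0.3
#' @param volume_scale cell volume multiplier at fixed concentrations
#' @param dt timestep, s (default: [auto_dt()] rule)
#' @param burn_in equilibration time excluded from steady-state windows, s
#'   (default: 2 relaxation times `1/(k2 cE)`)
#' @param window steady-state averaging window length, s (default: 6
#'   relaxation times)
#' @param seed engine seed
#' @return a [simulation_config()] with a `meta` element holding the
#'   analytical prediction, the relaxation time, the burn-in/window and the
#'   rate constants
#' @export
preset_in_vitro <- function(beta = 0.01, volume_scale = 1, dt = NULL,
                            burn_in = NULL, window = NULL, seed = 1) {
  rr <- lookup_rates(beta)
  v <- test_model_volume(volume_scale)
  r_cell <- (3 * v / (4 * pi))^(1 / 3)
  n_E <- as.integer(round(.test_model_nE * volume_scale))
  pred <- ode_steady_state(rr$k1, rr$k2, .test_model_cE,
                           n_E = .test_model_nE)$count * volume_scale
  if (is.null(dt)) {
    dt <- auto_dt(rr$k2, 0.0025, 0.0025, 1, 1,
                  step_limit = if (beta >= 0.1) 0.005 else Inf)
  }
  relax <- 1 / (rr$k2 * .test_model_cE)
  if (is.null(burn_in)) burn_in <- 2 * relax
  if (is.null(window)) window <- 6 * relax
  observe_every <- dt * max(1, round(relax / 50 / dt))
  cfg <- simulation_config(
    geometry = cell_geometry(r_cell),
    species = list(
      species_spec("S", 0.0025, 1, count = round(pred)),
      species_spec("E", 0.0025, 1, count = n_E)),
    reactions = list(
      rx_zero_order("S", k_macro = rr$k1),
      rx_bimolecular(c("S", "E"), products = "E", k_macro = rr$k2)),
    dt = dt, t_end = burn_in + window, observe_every = observe_every,
    seed = seed)
  cfg$meta <- list(beta = beta, k1 = rr$k1, k2 = rr$k2, cE = .test_model_cE,
                   n_E = n_E, volume = v, prediction = pred, relax = relax,
                   burn_in = burn_in, window = c(burn_in, burn_in + window))
  cfg
}

#' Preset: the test model in the crowded model cell
#'
#' Identical to [preset_in_vitro()] except that the cell contains the default
#' crowded geometry (cytoskeleton cylinders plus crowding spheres at the
#' calibrated density). The in-vivo steady-state prediction divides the
#' in-vitro one by `f_eff` computed from this geometry's measured excluded
#' volume fraction, effective diffusion and accessibility factor (see
#' [crowding_factors()]); the measurement itself is left to the caller since
#' the effective diffusion requires a tracer run.
#'
#' @inheritParams preset_in_vitro
#' @param geom_seed seed of the generated geometry
#' @param geometry optionally, a pre-built crowded geometry (overrides
#'   `geom_seed`)
#' @return a [simulation_config()] with `meta` as in [preset_in_vitro()]
#' @export
preset_in_vivo <- function(beta = 0.01, volume_scale = 1, dt = NULL,
                           burn_in = NULL, window = NULL, seed = 1,
                           geom_seed = 1, geometry = NULL) {
  cfg <- preset_in_vitro(beta, volume_scale, dt = dt, burn_in = burn_in,
                         window = window, seed = seed)
  r_cell <- cfg$geometry$cell_radius
  if (is.null(geometry)) {
    geometry <- default_cell_geometry(seed = geom_seed, cell_radius = r_cell)
  }
  meta <- cfg$meta
  cfg <- simulation_config(
    geometry = geometry, species = cfg$species, reactions = cfg$reactions,
    dt = cfg$dt, t_end = cfg$t_end, observe_every = cfg$observe_every,
    seed = seed)
  cfg$meta <- meta
  cfg
}

#' Preset: transient binding of inert tracers to the cytoskeleton
#'
#' Inert tracer molecules (2.5 nm, `D0 = 1` um^2/s) adsorb to the obstacle
#' structures within a reaction layer and dissociate at `k_diss`. The
#' adsorption surface velocity is chosen via the bulk-rate conversion
#' ([kappa_from_kbind()]) so that the steady-state unbound fraction
#' approaches `target_fu`: `k_bind = k_diss (1 - fu) / fu`. All tracers
#' start unbound, so `fu(t)` relaxes from 1 to the plateau at rate
#' `k_bind + k_diss`.
#'
#' @param k_diss dissociation rate, 1/s
#' @param target_fu desired steady-state unbound fraction in (0, 1]
#' @param geometry a crowded `cell_geometry` (default: the calibrated default
#'   cell)
#' @param n_tracers tracer count
#' @param dt timestep, s
#' @param t_end duration, s
#' @param seed engine seed
#' @param geom_seed geometry seed when `geometry` is `NULL`
#' @return a [simulation_config()]; `meta` holds `k_bind` and `kappa`
#' @export
preset_binding <- function(k_diss, target_fu, geometry = NULL,
                           n_tracers = 300, dt = 1e-5, t_end = 1, seed = 1,
                           geom_seed = 1) {
  if (target_fu <= 0 || target_fu > 1) stop("target_fu must be in (0, 1]")
  if (is.null(geometry)) geometry <- default_cell_geometry(seed = geom_seed)
  k_bind <- k_diss * (1 - target_fu) / target_fu
  kappa <- if (k_bind > 0) {
    kappa_from_kbind(geometry, k_bind, 0.0025, seed = geom_seed)$kappa
  } else 0
  reactions <- if (kappa > 0) {
    list(rx_adsorption("tracer", kappa), rx_dissociation("tracer", k_diss))
  } else list()
  cfg <- simulation_config(
    geometry = geometry,
    species = list(species_spec("tracer", 0.0025, 1, count = n_tracers,
                                record = TRUE)),
    reactions = reactions,
    dt = dt, t_end = t_end, observe_every = dt * 50,
    record_every = dt * 50, seed = seed)
  cfg$meta <- list(k_diss = k_diss, target_fu = target_fu, k_bind = k_bind,
                   kappa = kappa)
  cfg
}

# positions at a fixed offset distance from given anchor positions, uniform
# direction, rejection-sampled to stay accessible; used to build the ordered
# enzyme complexes of the channel layout
sample_near_anchors <- function(geom, anchors, probe, offset, seed) {
  out <- matrix(NA_real_, nrow(anchors), 3)
  with_seed(seed, {
    for (i in seq_len(nrow(anchors))) {
      repeat {
        d <- rnorm(3)
        p <- anchors[i, ] + offset * d / sqrt(sum(d^2))
        if (is_accessible(geom, matrix(p, 1), probe)) break
      }
      out[i, ] <- p
    }
  })
  out
}

#' Preset: metabolic-channeling enzyme layouts
#'
#' A linear pathway in an obstacle-free cell: metabolite 1 (extracellular) is
#' transported across the membrane, appearing as metabolite 2 in a
#' membrane-adjacent shell; three immobilized enzymes (E1-E3, `D = 0`)
#' convert metabolite 2 -> 3 -> 4 -> 5 with mass-action rate `k_macro`; the
#' final metabolite 5 is exported through a diffusion-controlled membrane
#' capture layer. Enzyme layouts:
#' * `"channel"` (A): ordered enzyme complexes in the membrane shell: E1
#'   positions are uniform in the shell and each complex places its E2 and E3
#'   a few collision radii from the preceding enzyme, so intermediates are
#'   produced next to the enzyme of the following step (assembly-line
#'   arrangement);
#' * `"layer"` (B): uniform random positions in the membrane shell;
#' * `"random"` (C): uniform random positions in the cell volume;
#' * `"wellmixed"` (D): no positions; the preset is meant to be run with
#'   [gillespie_run()] on the reactions in `meta$gillespie_reactions`
#'   (membrane export becomes the equivalent well-mixed first-order channel
#'   with rate `3 kappa / R`).
#'
#' Influx rate, enzyme counts, cell size and duration are package defaults
#' scaled for tractable runs (see the methods vignette); all layouts share
#' identical totals so differences are attributable to the layout.
#'
#' @param layout one of `"channel"`, `"layer"`, `"random"`, `"wellmixed"`
#' @param D_metabolite metabolite diffusion coefficient, um^2/s (1 or 10 in
#'   the standard comparison)
#' @param cell_radius membrane radius, um
#' @param n_enzymes enzymes per pathway step
#' @param influx_rate membrane influx of metabolite 2, molecules/s
#' @param k_macro enzymatic rate constant, L/(mol s)
#' @param shell_thickness membrane shell thickness, um
#' @param dt timestep, s (default [auto_dt()] rule)
#' @param t_end duration, s
#' @param seed engine seed (also used for enzyme placement)
#' @return a [simulation_config()]; `meta` holds the layout, the well-mixed
#'   reaction set and bookkeeping
#' @export
preset_channeling <- function(layout = c("channel", "layer", "random",
                                         "wellmixed"),
                              D_metabolite = 1, cell_radius = 1.75,
                              n_enzymes = 3600, influx_rate = 1000,
                              k_macro = 3.78e6, shell_thickness = 0.05,
                              dt = NULL, t_end = 1.5, seed = 1) {
  layout <- match.arg(layout)
  r_mol <- 0.0025
  geom <- cell_geometry(cell_radius)
  k_D <- collision_rate_kD(r_mol, r_mol, D_metabolite, 0)
  beta <- k_macro / k_D
  if (is.null(dt)) {
    dt <- auto_dt(k_macro, r_mol, r_mol, D_metabolite, 0,
                  step_limit = if (beta >= 0.1) 2 * r_mol else Inf)
  }
  kappa_exp <- sqrt(6 * D_metabolite * dt) / dt

  mets <- paste0("M", 2:5)
  enz <- paste0("E", 1:3)
  met_species <- lapply(mets, function(m)
    species_spec(m, r_mol, D_metabolite, count = 0))
  enz_pos <- vector("list", 3)
  if (layout == "channel") {
    enz_pos[[1]] <- cpp_sample_accessible(geom_ptr(geom), n_enzymes, r_mol,
                                          1L, shell_thickness,
                                          as.double(seed * 131 + 1), 100000L)
    for (i in 2:3) {
      enz_pos[[i]] <- sample_near_anchors(geom, enz_pos[[i - 1]], r_mol,
                                          offset = 4 * r_mol,
                                          seed = seed * 131 + i)
    }
  } else if (layout == "layer") {
    for (i in 1:3) {
      enz_pos[[i]] <- cpp_sample_accessible(geom_ptr(geom), n_enzymes, r_mol,
                                            1L, shell_thickness,
                                            as.double(seed * 131 + i), 100000L)
    }
  } else if (layout == "random") {
    for (i in 1:3) {
      enz_pos[[i]] <- cpp_sample_accessible(geom_ptr(geom), n_enzymes, r_mol,
                                            0L, 0,
                                            as.double(seed * 131 + i), 100000L)
    }
  }
  enz_species <- lapply(seq_along(enz), function(i) {
    if (layout == "wellmixed") {
      species_spec(enz[i], r_mol, 0, count = n_enzymes)
    } else {
      species_spec(enz[i], r_mol, 0, count = n_enzymes, init = "fixed",
                   positions = enz_pos[[i]])
    }
  })
  reactions <- list(
    rx_membrane_influx("M2", influx_rate, shell_thickness),
    rx_bimolecular(c("M2", "E1"), c("M3", "E1"), k_macro),
    rx_bimolecular(c("M3", "E2"), c("M4", "E2"), k_macro),
    rx_bimolecular(c("M4", "E3"), c("M5", "E3"), k_macro),
    rx_membrane_export("M5", kappa = kappa_exp))
  cfg <- simulation_config(
    geometry = geom, species = c(met_species, enz_species),
    reactions = reactions, dt = dt, t_end = t_end,
    observe_every = dt * max(1, round(t_end / 300 / dt)), seed = seed)
  # well-mixed image of the same mechanism: identical totals and rate
  # constants; the capture layer becomes the first-order rate 3 kappa / R
  gl_reactions <- list(
    rx_membrane_influx("M2", influx_rate, shell_thickness),
    rx_bimolecular(c("M2", "E1"), c("M3", "E1"), k_macro),
    rx_bimolecular(c("M3", "E2"), c("M4", "E2"), k_macro),
    rx_bimolecular(c("M4", "E3"), c("M5", "E3"), k_macro),
    rx_unimolecular("M5", character(0), k = 3 * kappa_exp / cell_radius))
  cfg$meta <- list(layout = layout, D_metabolite = D_metabolite,
                   beta = beta, kappa_exp = kappa_exp,
                   n_enzymes = n_enzymes, influx_rate = influx_rate,
                   gillespie_reactions = gl_reactions,
                   gillespie_counts = setNames(
                     as.integer(c(rep(0, 4), rep(n_enzymes, 3))),
                     c(mets, enz)),
                   volume = sphere_volume(cell_radius))
  cfg
}

#' Run the channeling comparison across layouts
#'
#' Runs the four enzyme layouts with common totals, rates and seed and
#' returns, per layout, the time series of the intracellular final
#' metabolite, its cumulative production (events of the last enzymatic
#' channel) and the cumulative export.
#'
#' @param layouts layouts to run
#' @param D_metabolite metabolite diffusion coefficient, um^2/s
#' @param seed common seed
#' @param ... forwarded to [preset_channeling()]
#' @return named list of data frames (`time`, `M5`, `produced`, `exported`)
#' @export
run_channeling_comparison <- function(layouts = c("channel", "layer",
                                                  "random", "wellmixed"),
                                      D_metabolite = 1, seed = 1, ...) {
  out <- list()
  for (ly in layouts) {
    cfg <- preset_channeling(ly, D_metabolite = D_metabolite, seed = seed,
                             ...)
    if (ly == "wellmixed") {
      g <- gillespie_run(cfg$meta$gillespie_counts,
                         cfg$meta$gillespie_reactions,
                         volume = cfg$meta$volume, t_end = cfg$t_end,
                         seed = seed, record_every = cfg$observe_every)
      out[[ly]] <- data.frame(time = g$times, M5 = g$counts[, "M5"],
                              produced = g$events[, 4],
                              exported = g$events[, 5])
    } else {
      sim <- simulate(cfg)
      out[[ly]] <- data.frame(time = sim$times, M5 = sim$counts[, "M5"],
                              produced = sim$events[, 4],
                              exported = sim$events[, 5])
    }
  }
  out
}
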