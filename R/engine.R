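#' Species definition
#'
#' Physical parameters and initial population of one molecular species.
#'
#' @param name species name
#' @param radius molecule radius, um
#' @param D0 free diffusion coefficient, um^2/s (0 = immobile)
#' @param count initial molecule count
#' @param init initial spatial distribution: uniform over the accessible
#'   volume, uniform over an accessible membrane-adjacent shell, or fixed
#'   positions supplied in `positions`
#' @param positions n x 3 matrix of initial positions (um) for
#'   `init = "fixed"`
#' @param shell_thickness shell thickness for `init = "membrane_layer"`, um
#' @param record record this species' trajectories (positions every
#'   `record_every`); recorded species must not take part in any reaction
#'   that creates, destroys or transforms them
#' @return a `species_spec`
#' @export
species_spec <- function(name, radius, D0, count = 0,
                         init = c("uniform_accessible", "membrane_layer",
                                  "fixed"),
                         positions = NULL, shell_thickness = 0.05,
                         record = FALSE) {
  init <- match.arg(init)
  if (radius <= 0) stop("radius must be positive")
  if (D0 < 0) stop("D0 must be >= 0")
  if (count < 0) stop("count must be >= 0")
  if (init == "fixed") {
    positions <- matrix(as.numeric(positions), ncol = 3)
    if (nrow(positions) != count) stop("positions must have `count` rows")
  }
  structure(list(name = name, radius = radius, D0 = D0,
                 count = as.integer(count), init = init,
                 positions = positions, shell_thickness = shell_thickness,
                 record = isTRUE(record)),
            class = "species_spec")
}

#' Simulation configuration
#'
#' Assembles geometry, species, reaction channels and numerical parameters
#' into a validated configuration. Derived kernel parameters (collision
#' radius, diffusion limit, microscopic rate, per-step reaction probability)
#' are computed here and logged in the `kernels` element; configurations whose
#' per-pair reaction probability would exceed 1, or whose first-order
#' per-step probabilities exceed 1, are rejected before any stepping.
#'
#' @param geometry a `cell_geometry` (use an obstacle-free
#'   [cell_geometry()] for well-mixed "in vitro" cells)
#' @param species list of [species_spec()]
#' @param reactions list of reaction channels (see [reaction_spec])
#' @param dt timestep, s
#' @param t_end simulated duration, s
#' @param observe_every observation interval, s (multiple of `dt`)
#' @param record_every snapshot interval for recorded species, s
#'   (multiple of `dt`; defaults to `observe_every`)
#' @param seed default engine seed (can be overridden in [simulate()])
#' @param max_place_tries rejection-sampling bound for accessible placement
#' @return a `simulation_config`
#' @export
simulation_config <- function(geometry, species, reactions = list(), dt,
                              t_end, observe_every = NULL,
                              record_every = NULL, seed = 1,
                              max_place_tries = 1e5) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (inherits(reactions, "reaction_spec")) reactions <- list(reactions)
  if (dt <= 0) stop("dt must be positive")
  if (t_end < dt) stop("t_end must be >= dt")
  if (is.null(observe_every)) observe_every <- dt
  if (observe_every < dt) stop("observe_every must be >= dt")
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) stop("duplicated species names")
  for (rx in reactions) {
    bad <- setdiff(c(rx$educts, rx$products), sp_names)
    if (length(bad)) stop("reaction references unknown species: ", bad[1])
  }

  cfg <- structure(list(geometry = geometry, species = species,
                        reactions = reactions, dt = dt, t_end = t_end,
                        observe_every = observe_every,
                        record_every = record_every, seed = seed,
                        max_place_tries = max_place_tries),
                   class = "simulation_config")
  lowered <- lower_config(cfg)   # validates; computes kernels
  cfg$kernels <- lowered$kernels
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d species, %d reactions, dt = %g s, t_end = %g s\n",
    length(x$species), length(x$reactions), x$dt, x$t_end))
  if (!is.null(x$kernels) && nrow(x$kernels)) {
    cat("bimolecular kernels:\n")
    print(x$kernels, digits = 4)
  }
  invisible(x)
}

# translate the user-facing config into the flat structure the C++ engine
# consumes: per-step probabilities, Poisson means per step, layer heights
lower_config <- function(cfg) {
  dt <- cfg$dt
  geom <- cfg$geometry
  v_cell <- sphere_volume(geom$cell_radius)
  sp_names <- vapply(cfg$species, `[[`, character(1), "name")
  radius <- vapply(cfg$species, `[[`, numeric(1), "radius")
  D0 <- vapply(cfg$species, `[[`, numeric(1), "D0")
  idx <- function(nm) match(nm, sp_names) - 1L

  min_obs_radius <- suppressWarnings(min(c(geom$cylinders$radius,
                                           geom$spheres$radius, Inf)))
  channels <- list()
  labels <- character(0)
  kern_rows <- list()
  touched <- character(0)   # species whose counts a channel can change

  for (i in seq_along(cfg$reactions)) {
    rx <- cfg$reactions[[i]]
    ch <- switch(
      rx$kind,
      zero_order = {
        lam <- if (!is.null(rx$molecules_per_s)) rx$molecules_per_s
               else conc_to_count(rx$k_macro, v_cell)
        touched <- c(touched, rx$products)
        list(kind = 0L, sp = idx(rx$products),
             lam_step = lam * dt,
             region = if (rx$region == "membrane_shell") 1L else 0L,
             shell = rx$shell_thickness)
      },
      unimolecular = {
        p <- rx$k * dt
        if (p > 1) stop("unimolecular k * dt > 1; reduce dt")
        if (p > 0.1) {
          warning("unimolecular k * dt > 0.1: first-order discretization bias")
        }
        touched <- c(touched, rx$educts, rx$products)
        list(kind = 1L, sp = idx(rx$educts), p = p,
             prods = as.integer(vapply(rx$products, idx, integer(1))))
      },
      bimolecular = {
        ei <- rx$educts[1]; ej <- rx$educts[2]
        Di <- D0[match(ei, sp_names)]; Dj <- D0[match(ej, sp_names)]
        if (!is.null(rx$D_ref)) {
          if (ei %in% names(rx$D_ref)) Di <- rx$D_ref[[ei]]
          if (ej %in% names(rx$D_ref)) Dj <- rx$D_ref[[ej]]
        }
        kern <- bimolecular_kernel(rx$k_macro,
                                   radius[match(ei, sp_names)],
                                   radius[match(ej, sp_names)], Di, Dj, dt)
        prods <- rx$products
        cat_i <- ei %in% prods
        if (cat_i) prods <- prods[-match(ei, prods)]
        cat_j <- ej %in% prods
        if (cat_j) prods <- prods[-match(ej, prods)]
        if (!cat_i) touched <- c(touched, ei)
        if (!cat_j) touched <- c(touched, ej)
        touched <- c(touched, prods)
        kern_rows[[length(kern_rows) + 1]] <-
          data.frame(reaction = paste(ei, "+", ej), k_macro = rx$k_macro,
                     k_D = kern$k_D, k_micro = kern$k_micro,
                     beta = kern$beta, R_crit = kern$R_crit,
                     P_react = kern$P_react)
        list(kind = 2L, spi = idx(ei), spj = idx(ej),
             rcrit = kern$R_crit, P = kern$P_react,
             cat_i = cat_i, cat_j = cat_j,
             prods = as.integer(vapply(prods, idx, integer(1))))
      },
      adsorption = {
        layer <- rx$kappa * dt
        if (rx$structures && layer >= min_obs_radius) {
          stop("adsorption layer kappa * dt >= smallest obstacle radius; ",
               "the flat-layer approximation requires kappa * dt << r_structure")
        }
        list(kind = 3L, sp = idx(rx$educts), layer = layer,
             structures = rx$structures, membrane = rx$membrane)
      },
      dissociation = {
        p <- rx$k_diss * dt
        if (p > 1) stop("k_diss * dt > 1; reduce dt")
        list(kind = 4L, sp = idx(rx$educts), p = p)
      },
      membrane_influx = {
        touched <- c(touched, rx$products)
        list(kind = 5L, sp = idx(rx$products),
             lam_step = rx$molecules_per_s * dt,
             shell = rx$shell_thickness)
      },
      membrane_export = {
        sp_i <- match(rx$educts, sp_names)
        kappa <- rx$kappa
        if (is.null(kappa)) {
          # default: capture layer of one rms step per step => the export is
          # limited by diffusion towards the membrane, not by the layer
          kappa <- sqrt(6 * D0[sp_i] * dt) / dt
        }
        touched <- c(touched, rx$educts)
        list(kind = 6L, sp = idx(rx$educts), layer = kappa * dt)
      },
      stop("unknown reaction kind: ", rx$kind))
    channels[[i]] <- ch
    labels[i] <- paste0(rx$kind, ":",
                        paste(rx$educts, collapse = "+"), ">",
                        paste(rx$products, collapse = "+"))
  }

  recorded <- vapply(cfg$species, `[[`, logical(1), "record")
  if (any(recorded)) {
    clash <- intersect(sp_names[recorded], touched)
    if (length(clash)) {
      stop("recorded species must not be created/destroyed/transformed: ",
           clash[1])
    }
  }

  kernels <- if (length(kern_rows)) do.call(rbind, kern_rows) else
    data.frame(reaction = character(0))
  # immobile catalytic species (fixed positions for the whole run): their
  # bimolecular pair search can use a grid built once instead of per step
  bound_sp <- unlist(lapply(cfg$reactions, function(rx)
    if (rx$kind %in% c("adsorption", "dissociation")) rx$educts else NULL))
  static_sp <- D0 == 0 & !(sp_names %in% touched) & !(sp_names %in% bound_sp)
  list(channels = channels, labels = labels, kernels = kernels,
       radius = radius, D0 = D0, sp_names = sp_names, recorded = recorded,
       static_sp = static_sp)
}

#' Run a simulation
#'
#' Executes the Brownian-dynamics time loop. Each step applies, in fixed
#' order: the rejection-sampled diffusion step, adsorption and dissociation,
#' bimolecular channels (candidate pairs within the collision radius, visited
#' in uniformly random order, each particle reacting at most once per step),
#' unimolecular conversions, zero-order creation, membrane influx, and
#' membrane export; then records observations. Runs are bit-reproducible for
#' a fixed seed.
#'
#' @param config a [simulation_config()]
#' @param seed integer seed overriding `config$seed`
#' @return a `bd_sim`: list with `times`, `counts` (matrix, one column per
#'   species), `bound` (bound-molecule counts), `events` (cumulative events
#'   per channel), `exported` (cumulative export counts), `positions`
#'   (`n x 3 x frames` array for recorded species, else `NULL`),
#'   `record_times`, `kernels`, and the `config`
#' @export
simulate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  low <- lower_config(config)
  geom <- config$geometry
  gp <- geom_ptr(geom)
  dt <- config$dt
  n_steps <- round(config$t_end / dt)
  obs_every <- round(config$observe_every / dt)
  if (abs(obs_every * dt - config$observe_every) > 1e-9 * config$observe_every) {
    stop("observe_every must be a multiple of dt")
  }
  record_every <- if (is.null(config$record_every)) obs_every else
    round(config$record_every / dt)
  n_steps <- obs_every * floor(n_steps / obs_every)

  # assemble initial particles; recorded species first (the engine never
  # compacts the leading block)
  ord <- order(!low$recorded)
  pos_list <- list(); sp_list <- list()
  place_seed <- seed
  for (k in ord) {
    s <- config$species[[k]]
    if (s$count == 0) next
    place_seed <- place_seed + 7919
    pos <- switch(s$init,
      fixed = s$positions,
      uniform_accessible = cpp_sample_accessible(
        gp, s$count, s$radius, 0L, 0, as.double(place_seed),
        as.integer(config$max_place_tries)),
      membrane_layer = cpp_sample_accessible(
        gp, s$count, s$radius, 1L, s$shell_thickness, as.double(place_seed),
        as.integer(config$max_place_tries)))
    pos_list[[length(pos_list) + 1]] <- pos
    sp_list[[length(sp_list) + 1]] <- rep(k - 1L, s$count)
  }
  init_pos <- if (length(pos_list)) do.call(rbind, pos_list) else
    matrix(numeric(0), ncol = 3)
  init_sp <- as.integer(unlist(sp_list))
  n_record <- sum(vapply(config$species[low$recorded], `[[`, integer(1),
                         "count"))

  cpp_cfg <- list(dt = dt, n_steps = as.double(n_steps),
                  obs_every = as.double(obs_every),
                  seed = as.double(seed),
                  radius = low$radius, sigma = sqrt(2 * low$D0 * dt),
                  init_pos = init_pos, init_species = init_sp,
                  init_bound = rep(FALSE, length(init_sp)),
                  n_record = as.integer(n_record),
                  record_every = as.double(record_every),
                  max_place_tries = as.integer(config$max_place_tries),
                  static_species = as.integer(low$static_sp),
                  channels = low$channels)
  raw <- cpp_simulate(gp, cpp_cfg)

  colnames(raw$counts) <- low$sp_names
  colnames(raw$bound) <- low$sp_names
  colnames(raw$events) <- low$labels
  exported <- raw$events[, vapply(config$reactions, function(r)
    identical(r$kind, "membrane_export"), logical(1)), drop = FALSE]
  out <- list(times = raw$times, counts = raw$counts, bound = raw$bound,
              events = raw$events, exported = exported,
              positions = raw$positions,
              record_times = if (!is.null(raw$positions))
                seq(0, by = record_every * dt,
                    length.out = dim(raw$positions)[3]) else NULL,
              final = list(positions = raw$final_pos,
                           species = low$sp_names[raw$final_species + 1],
                           bound = raw$final_bound),
              kernels = config$kernels, seed = seed, config = config)
  class(out) <- "bd_sim"
  out
}

#' @export
print.bd_sim <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("<bd_sim> %d observations over %g s (seed %g)\n",
              nt, x$times[nt], x$seed))
  cat("final counts:\n")
  print(x$counts[nt, ])
  invisible(x)
}

#' Steady-state average of a count series
#'
#' Mean, standard deviation and standard error of one species' molecule count
#' over a time window. Successive observations of a stochastic steady state
#' are autocorrelated, so the standard error is computed from block averages
#' (blocks longer than the correlation time make the block means effectively
#' independent).
#'
#' @param sim a `bd_sim`, or a numeric vector of counts (then `times` must be
#'   given)
#' @param species species name (ignored for a plain vector)
#' @param window numeric length-2: time window `[t0, t1]` in s
#' @param n_blocks number of blocks for the block-averaged standard error
#' @param times observation times when `sim` is a plain vector
#' @return list with `mean`, `sd`, `se`, `n`, `n_blocks`
#' @export
steady_state_average <- function(sim, species = NULL, window, n_blocks = 8,
                                 times = NULL) {
  if (inherits(sim, "bd_sim")) {
    times <- sim$times
    x <- sim$counts[, species]
  } else {
    x <- as.numeric(sim)
    if (is.null(times)) stop("times must be supplied for a plain vector")
  }
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("empty steady-state window")
  x <- x[keep]
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1, n)
  blocks <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- if (n_blocks > 1) stats::sd(bm) / sqrt(n_blocks) else 0
  list(mean = mean(x), sd = stats::sd(x) * (n > 1),
       se = se, n = n, n_blocks = n_blocks)
}

#' Pure-diffusion tracer run
#'
#' Convenience wrapper: simulates `n` inert tracers in a geometry and returns
#' the recorded trajectories, the usual input for [compute_msd()].
#'
#' @param geom a `cell_geometry`
#' @param n number of tracers
#' @param radius tracer radius, um
#' @param D0 free diffusion coefficient, um^2/s
#' @param dt timestep, s
#' @param t_end duration, s
#' @param record_every snapshot interval, s
#' @param seed engine seed
#' @param reactions optional adsorption/dissociation channels acting on the
#'   tracer species (named `"tracer"`)
#' @return a `bd_sim` with `positions` of dimension `n x 3 x frames`
#' @export
diffuse_tracers <- function(geom, n, radius = 0.0025, D0 = 1, dt = 1e-5,
                            t_end = 0.1, record_every = NULL, seed = 1,
                            reactions = list()) {
  if (is.null(record_every)) record_every <- dt * 10
  cfg <- simulation_config(
    geometry = geom,
    species = list(species_spec("tracer", radius, D0, count = n,
                                record = TRUE)),
    reactions = reactions,
    dt = dt, t_end = t_end, observe_every = record_every,
    record_every = record_every, seed = seed)
  simulate(cfg)
}
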