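#' Crowding correction factors for the effective in-vivo reaction rate
#'
#' Three multiplicative factors map an in-vitro macroscopic bimolecular rate
#' constant to crowded-cell conditions:
#' * `f_vol(epsilon) = 1 / (1 - epsilon)`: the excluded volume fraction
#'   `epsilon` concentrates the reactants into the remaining free volume,
#'   raising the effective concentration (applied once per bimolecular
#'   channel, for the partner concentration).
#' * `f_diff(beta, delta)`: the reduced long-time mobility
#'   `delta = D_eff / D0` lowers the collision rate; holding the microscopic
#'   (per-collision) rate fixed while the diffusion limit scales with `delta`
#'   gives `f_diff = delta / (beta + delta (1 - beta))` with
#'   `beta = k_macro / k_D` the degree of diffusion limitation.
#' * `f_access`: steric blocking of the pairwise interaction volume near
#'   obstacles, estimated by Monte-Carlo sampling
#'   ([sample_access_factor()]).
#'
#' The combined effective-rate factor is `f_eff = f_vol * f_diff * f_access`.
#'
#' @param epsilon excluded volume fraction in `[0, 1)`
#' @param beta `k_macro / k_D` in `[0, 1)`
#' @param delta `D_eff / D0` in `(0, 1]`
#' @param f_access accessibility factor in `(0, 1]`
#' @return `f_vol` and `f_diff` return the scalar factor;
#'   `crowding_factors` returns all components and their product `f_eff`
#' @export
f_vol <- function(epsilon) {
  if (any(epsilon < 0) || any(epsilon >= 1)) stop("epsilon must be in [0, 1)")
  1 / (1 - epsilon)
}

#' @rdname f_vol
#' @export
f_diff <- function(beta, delta) {
  if (any(beta < 0) || any(beta >= 1)) stop("beta must be in [0, 1)")
  if (any(delta <= 0) || any(delta > 1)) stop("delta must be in (0, 1]")
  delta / (beta + delta * (1 - beta))
}

#' @rdname f_vol
#' @export
crowding_factors <- function(epsilon, beta, delta, f_access = 1) {
  out <- list(epsilon = epsilon, beta = beta, delta = delta,
              f_vol = f_vol(epsilon), f_diff = f_diff(beta, delta),
              f_access = f_access)
  out$f_eff <- out$f_vol * out$f_diff * out$f_access
  class(out) <- "crowding_factors"
  out
}

#' @rdname f_vol
#' @param factors a `crowding_factors`
#' @export
f_eff <- function(factors) factors$f_vol * factors$f_diff * factors$f_access

#' @export
print.crowding_factors <- function(x, ...) {
  cat(sprintf(paste0(
    "<crowding_factors> epsilon = %.3f, beta = %.3g, delta = %.3f\n",
    "  f_vol = %.3f  f_diff = %.3f  f_access = %.3f  =>  f_eff = %.3f\n"),
    x$epsilon, x$beta, x$delta, x$f_vol, x$f_diff, x$f_access, x$f_eff))
  invisible(x)
}

#' Well-mixed steady state of the source/enzymatic-consumption test model
#'
#' For a substrate created at constant rate `k1` (zero order) and consumed in
#' the enzymatic mass-action channel `S + E -> P + E` with rate constant
#' `k2` and fixed enzyme concentration `cE`, the balance
#' `dcS/dt = k1 - k2 cE cS` has the steady state `cS = k1 / (k2 cE)`. The
#' molecule count follows the enzyme bookkeeping `count = cS / cE * n_E`.
#' `f_eff` applies the crowding correction `k2 -> f_eff k2` for the in-vivo
#' prediction.
#'
#' @param k1 zero-order source rate, mol/(L s)
#' @param k2 bimolecular rate constant, L/(mol s)
#' @param cE enzyme concentration, mol/L
#' @param n_E enzyme molecule count fixing the volume convention
#' @param f_eff crowding correction factor applied to `k2`
#' @return list with `concentration` (mol/L) and `count` (molecules)
#' @export
ode_steady_state <- function(k1, k2, cE, n_E = 20600, f_eff = 1) {
  if (k2 * cE * f_eff <= 0) stop("k2 * cE must be positive")
  cS <- k1 / (f_eff * k2 * cE)
  list(concentration = cS, count = cS / cE * n_E)
}

#' Gillespie stochastic simulation of well-mixed mass-action kinetics
#'
#' Exact SSA over the reaction channels supported by the spatial engine's
#' well-mixed counterpart: zero-order sources, membrane influx (a plain
#' source in a well-mixed model), unimolecular conversions and bimolecular
#' mass-action channels (catalytic educts preserved). Propensities use the
#' molecule-number convention `a = k / (N_A/1e15 * V) * N_i * N_j` for
#' bimolecular channels between distinct species.
#'
#' @param counts named integer vector of initial molecule counts
#' @param reactions list of [reaction_spec] objects
#' @param volume system volume, um^3
#' @param t_end simulated duration, s
#' @param seed RNG seed
#' @param record_every sampling interval of the recorded series, s
#' @return list with `times`, `counts` (matrix), `events` (cumulative per
#'   channel)
#' @export
gillespie_run <- function(counts, reactions, volume, t_end, seed = 1,
                          record_every = t_end / 200) {
  sp <- names(counts)
  nsp <- length(sp)
  nrx <- length(reactions)
  nu <- matrix(0L, nsp, nrx, dimnames = list(sp, NULL))
  rate <- numeric(nrx)
  type <- character(nrx)
  ed <- vector("list", nrx)
  for (i in seq_len(nrx)) {
    rx <- reactions[[i]]
    type[i] <- rx$kind
    for (e in rx$educts) nu[e, i] <- nu[e, i] - 1L
    for (p in rx$products) nu[p, i] <- nu[p, i] + 1L
    rate[i] <- switch(rx$kind,
      zero_order = if (!is.null(rx$molecules_per_s)) rx$molecules_per_s
                   else conc_to_count(rx$k_macro, volume),
      membrane_influx = rx$molecules_per_s,
      unimolecular = rx$k,
      bimolecular = {
        if (rx$educts[1] == rx$educts[2]) {
          stop("same-species bimolecular channels are not supported")
        }
        rx$k_macro / (volume * .NA_FACTOR)
      },
      stop("unsupported channel in the well-mixed reference: ", rx$kind))
    ed[[i]] <- match(rx$educts, sp)
  }

  n_rec <- floor(t_end / record_every) + 1
  times <- seq(0, by = record_every, length.out = n_rec)
  cmat <- matrix(0L, n_rec, nsp, dimnames = list(NULL, sp))
  emat <- matrix(0, n_rec, nrx)
  x <- as.numeric(counts)
  ev <- numeric(nrx)
  with_seed(seed, {
    t <- 0
    irec <- 1
    cmat[1, ] <- x
    repeat {
      a <- vapply(seq_len(nrx), function(i) {
        switch(type[i],
               zero_order = rate[i], membrane_influx = rate[i],
               unimolecular = rate[i] * x[ed[[i]][1]],
               bimolecular = rate[i] * x[ed[[i]][1]] * x[ed[[i]][2]])
      }, numeric(1))
      a0 <- sum(a)
      tau <- if (a0 > 0) stats::rexp(1, a0) else Inf
      tnext <- t + tau
      while (irec < n_rec && times[irec + 1] <= tnext) {
        irec <- irec + 1
        cmat[irec, ] <- x
        emat[irec, ] <- ev
      }
      if (tnext > t_end || !is.finite(tnext)) break
      t <- tnext
      j <- sample.int(nrx, 1, prob = a)
      x <- x + nu[, j]
      ev[j] <- ev[j] + 1
    }
    while (irec < n_rec) {
      irec <- irec + 1
      cmat[irec, ] <- x
      emat[irec, ] <- ev
    }
  })
  list(times = times, counts = cmat, events = emat)
}

#' Homogenized (obstacle-free, mobility-rescaled) counterpart of a config
#'
#' Builds the averaged reference cell for a crowded configuration: the
#' obstacles are removed and the cell volume is multiplied by `1 - epsilon`
#' so that the effective concentrations match the crowded cell; particle
#' mobilities are set to `delta * D0`, while each bimolecular kernel keeps
#' the microscopic rate derived from the original (in-vitro) diffusion
#' coefficients via a `D_ref` override. Molecule counts and rate constants
#' are unchanged. Zero-order channels given as concentrations per total cell
#' volume are converted to absolute rates so the source strength matches the
#' original cell.
#'
#' @param config a [simulation_config()]
#' @param epsilon excluded volume fraction of the crowded geometry
#' @param delta `D_eff / D0` of the crowded geometry
#' @return a new `simulation_config`
#' @export
homogenized_cell_config <- function(config, epsilon, delta) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (delta <= 0 || delta > 1) stop("delta must be in (0, 1]")
  geom0 <- config$geometry
  r_new <- geom0$cell_radius * (1 - epsilon)^(1 / 3)
  geom <- cell_geometry(r_new)
  v_old <- sphere_volume(geom0$cell_radius)
  species <- lapply(config$species, function(s) {
    s$D0 <- s$D0 * delta
    if (s$init == "fixed") s$init <- "uniform_accessible"
    s
  })
  d_orig <- setNames(vapply(config$species, `[[`, numeric(1), "D0"),
                     vapply(config$species, `[[`, character(1), "name"))
  reactions <- lapply(config$reactions, function(rx) {
    if (rx$kind == "bimolecular" && is.null(rx$D_ref)) {
      rx$D_ref <- as.list(d_orig[rx$educts])
    }
    if (rx$kind == "zero_order" && !is.null(rx$k_macro)) {
      # keep the absolute source strength of the original cell
      rx$molecules_per_s <- conc_to_count(rx$k_macro, v_old)
      rx$k_macro <- NULL
    }
    rx
  })
  simulation_config(geometry = geom, species = species,
                    reactions = reactions, dt = config$dt,
                    t_end = config$t_end,
                    observe_every = config$observe_every,
                    record_every = config$record_every,
                    seed = config$seed,
                    max_place_tries = config$max_place_tries)
}
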