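#' Diffusion-limited collision rate constant (Smoluchowski limit)
#'
#' The maximal bimolecular rate constant of two spherical reactants in 3D,
#' `k_D = 4 pi (r_i + r_j) (D_i + D_j)`, converted from um^3 per molecule per
#' second to L/(mol s) via `N_A / 1e15`. It equals the collision rate of the
#' molecules and no macroscopic rate constant may exceed it.
#'
#' @param r_i,r_j reactant radii, um
#' @param D_i,D_j reactant diffusion coefficients, um^2/s
#' @return collision rate constant in L/(mol s)
#' @export
collision_rate_kD <- function(r_i, r_j, D_i, D_j) {
  if (r_i + r_j <= 0) stop("combined radius must be positive")
  if (D_i + D_j <= 0) stop("combined diffusion coefficient must be positive")
  4 * pi * (r_i + r_j) * (D_i + D_j) * .NA_FACTOR
}

#' Microscopic and macroscopic rate constants
#'
#' A macroscopic (bulk, mass-action) bimolecular rate constant `k_macro`
#' composes the collision rate `k_D` with the per-collision reactivity
#' `k_micro` as `k_macro = k_micro k_D / (k_micro + k_D)`. `micro_rate`
#' inverts this relation; `macro_rate` applies it. Both are exact inverses of
#' each other over `0 <= k_macro < k_D`.
#'
#' @param k_macro macroscopic rate constant, L/(mol s); must be `< k_D`
#' @param k_micro microscopic rate constant, L/(mol s)
#' @param k_D collision (diffusion-limit) rate constant, L/(mol s)
#' @return a rate constant in L/(mol s)
#' @export
micro_rate <- function(k_macro, k_D) {
  if (any(k_macro < 0)) stop("k_macro must be >= 0")
  if (any(k_macro >= k_D)) {
    stop("k_macro exceeds the diffusion limit k_D = ",
         format(k_D, digits = 6), " L/(mol s)")
  }
  k_macro * k_D / (k_D - k_macro)
}

#' @rdname micro_rate
#' @export
macro_rate <- function(k_micro, k_D) k_micro * k_D / (k_micro + k_D)

#' Per-step reaction probability inside the collision volume
#'
#' Within one timestep a pair of reactants closer than the collision radius
#' `R_crit = r_i + r_j` reacts with probability
#' `P = k_micro dt / V_coll`, where `V_coll = 4/3 pi R_crit^3`. The
#' probability rescales the collision volume to the reaction volume
#' `k_micro dt` while keeping the physical interaction surface, so the
#' simulated bulk rate reproduces `k_macro` independently of `dt`.
#'
#' @param k_micro microscopic rate constant, L/(mol s)
#' @param dt timestep, s
#' @param r_i,r_j reactant radii, um
#' @return probability in `[0, 1]`; error (reporting the maximal admissible
#'   `dt`) if the combination exceeds 1
#' @export
reaction_probability <- function(k_micro, dt, r_i, r_j) {
  if (dt <= 0) stop("dt must be positive")
  v_coll <- 4 / 3 * pi * (r_i + r_j)^3          # um^3
  k_vol <- k_micro / .NA_FACTOR                 # um^3 / molecule / s
  p <- k_vol * dt / v_coll
  if (any(p > 1)) {
    stop(sprintf(
      "timestep too large: reaction probability %.3g > 1; dt must be <= %.3g s",
      max(p), v_coll / max(k_vol)))
  }
  p
}

#' Volume-derived reaction radius (legacy reference scheme)
#'
#' The radius of the spherical reaction volume `k_macro dt` in which a pair
#' reacts with probability 1, `R = (3 k_macro dt / (4 pi))^(1/3)`. It grows
#' with `dt^(1/3)` and does not match the physical collision radius, which is
#' why the main scheme uses the collision radius plus a probability instead;
#' provided for comparison only.
#'
#' @param k_macro macroscopic rate constant, L/(mol s)
#' @param dt timestep, s
#' @return reaction radius, um
#' @export
pogson_reaction_radius <- function(k_macro, dt) {
  if (dt <= 0) stop("dt must be positive")
  (3 * (k_macro / .NA_FACTOR) * dt / (4 * pi))^(1 / 3)
}

#' Derived bimolecular kernel parameters
#'
#' Combines the rate relations into the per-step simulation parameters of one
#' bimolecular channel: collision radius, diffusion limit, microscopic rate
#' and per-pair reaction probability.
#'
#' @inheritParams collision_rate_kD
#' @param k_macro macroscopic rate constant, L/(mol s)
#' @param dt timestep, s
#' @return list with `R_crit` (um), `k_D`, `k_micro` (L/(mol s)), `P_react`,
#'   `beta = k_macro / k_D`, and `dt`
#' @export
bimolecular_kernel <- function(k_macro, r_i, r_j, D_i, D_j, dt) {
  k_D <- collision_rate_kD(r_i, r_j, D_i, D_j)
  k_micro <- micro_rate(k_macro, k_D)
  list(R_crit = r_i + r_j, k_D = k_D, k_micro = k_micro,
       P_react = reaction_probability(k_micro, dt, r_i, r_j),
       beta = k_macro / k_D, dt = dt)
}

#' Convert a bulk binding rate into an intrinsic surface velocity
#'
#' The adsorption channel binds any unbound molecule whose surface comes
#' within `kappa dt` of a structure surface (reaction layer of height
#' `kappa dt`, probability 1). For a well-mixed population this produces a
#' bulk first-order binding rate `k_bind = kappa * A / V_acc`, where `A` is
#' the accessible contact surface area and `V_acc` the accessible volume, so
#' the inverse conversion is `kappa = k_bind * V_acc / A`. Both `A` and
#' `V_acc` are estimated by Monte-Carlo sampling on the supplied geometry.
#'
#' @param geom a `cell_geometry`
#' @param k_bind desired bulk binding rate constant, 1/s
#' @param probe_radius molecule radius, um
#' @param n_samples Monte-Carlo sample size for area and volume
#' @param seed sampler seed
#' @return list with `kappa` (um/s), `area` (um^2), `V_accessible` (um^3)
#' @export
kappa_from_kbind <- function(geom, k_bind, probe_radius, n_samples = 2e5,
                             seed = 1) {
  if (k_bind < 0) stop("k_bind must be >= 0")
  sa <- sample_surface_area(geom, probe_radius, n_samples, seed = seed)
  ex <- sample_excluded_fraction(geom, probe_radius, n_samples,
                                 seed = seed + 1)
  v_acc <- sphere_volume(geom$cell_radius) * (1 - ex$fraction)
  if (sa$area <= 0) stop("geometry has no structure surface to bind to")
  list(kappa = k_bind * v_acc / sa$area, area = sa$area, V_accessible = v_acc)
}

# ---- reaction channel constructors -----------------------------------------

new_reaction <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  cat(sprintf("<reaction_spec:%s> %s -> %s\n", x$kind,
              paste(x$educts, collapse = " + "),
              if (length(x$products)) paste(x$products, collapse = " + ")
              else "0"))
  invisible(x)
}

#' Reaction channel definitions
#'
#' Constructors for the reaction channels of the simulator. Species are named;
#' rate constants carry the unit of their kind:
#' * `rx_zero_order()`: creation at `k_macro` mol/(L s) over the whole cell
#'   volume (placement uniform over the accessible volume), or alternatively
#'   a direct `molecules_per_s` rate.
#' * `rx_unimolecular()`: first-order conversion/decay at `k` 1/s; each educt
#'   converts with probability `k dt` per step, products inherit the position.
#' * `rx_bimolecular()`: mass-action channel at `k_macro` L/(mol s) using the
#'   collision-radius + probability kernel; educts that also appear among the
#'   products (e.g. the enzyme in S + E -> P + E) are catalytic and are left
#'   untouched. `D_ref` optionally fixes the diffusion coefficients used to
#'   derive the kernel (microscopic rate), e.g. to impose in-vitro reactivity
#'   on a cell with rescaled mobility.
#' * `rx_adsorption()`: transient immobilization on structures and/or the
#'   membrane within a reaction layer of height `kappa dt`; the molecule
#'   species is unchanged, only its mobility is set to zero.
#' * `rx_dissociation()`: release of bound molecules at `k_diss` 1/s
#'   (per-step probability `k_diss dt`).
#' * `rx_membrane_influx()`: zero-order source placing molecules uniformly in
#'   an accessible shell adjacent to the membrane.
#' * `rx_membrane_export()`: capture layer of height `kappa dt` at the
#'   membrane removing molecules of the species with probability 1 (a
#'   diffusion-controlled export when the layer height is of the order of the
#'   step length, the default).
#'
#' @param species,educts,products species names
#' @param k_macro,k,k_diss rate constants (units per kind, see above)
#' @param molecules_per_s direct event rate for source channels
#' @param region placement region for zero-order creation
#' @param shell_thickness membrane shell thickness, um
#' @param D_ref optional named numeric: reference diffusion coefficients for
#'   kernel derivation
#' @param targets adsorption targets: any of `"structures"`, `"membrane"`
#' @param kappa intrinsic surface velocity, um/s (`NULL` for the export
#'   default: one rms step length per step)
#' @name reaction_spec
#' @return a `reaction_spec`
NULL

#' @rdname reaction_spec
#' @export
rx_zero_order <- function(species, k_macro = NULL, molecules_per_s = NULL,
                          region = c("volume", "membrane_shell"),
                          shell_thickness = 0.05) {
  region <- match.arg(region)
  if (is.null(k_macro) == is.null(molecules_per_s)) {
    stop("give exactly one of k_macro [mol/(L s)] or molecules_per_s")
  }
  new_reaction("zero_order",
               list(educts = character(0), products = species,
                    k_macro = k_macro, molecules_per_s = molecules_per_s,
                    region = region, shell_thickness = shell_thickness))
}

#' @rdname reaction_spec
#' @export
rx_unimolecular <- function(educts, products = character(0), k) {
  if (length(educts) != 1) stop("unimolecular channel needs one educt")
  if (k < 0) stop("rate must be >= 0")
  new_reaction("unimolecular",
               list(educts = educts, products = products, k = k))
}

#' @rdname reaction_spec
#' @export
rx_bimolecular <- function(educts, products, k_macro, D_ref = NULL) {
  if (length(educts) != 2) stop("bimolecular channel needs two educts")
  if (k_macro < 0) stop("rate must be >= 0")
  new_reaction("bimolecular",
               list(educts = educts, products = products, k_macro = k_macro,
                    D_ref = D_ref))
}

#' @rdname reaction_spec
#' @export
rx_adsorption <- function(species, kappa, targets = "structures") {
  if (kappa < 0) stop("kappa must be >= 0")
  bad <- setdiff(targets, c("structures", "membrane"))
  if (length(bad)) stop("unknown adsorption target: ", bad[1])
  new_reaction("adsorption",
               list(educts = species, products = species, kappa = kappa,
                    structures = "structures" %in% targets,
                    membrane = "membrane" %in% targets))
}

#' @rdname reaction_spec
#' @export
rx_dissociation <- function(species, k_diss) {
  if (k_diss < 0) stop("rate must be >= 0")
  new_reaction("dissociation",
               list(educts = species, products = species, k_diss = k_diss))
}

#' @rdname reaction_spec
#' @export
rx_membrane_influx <- function(species, molecules_per_s,
                               shell_thickness = 0.05) {
  if (molecules_per_s < 0) stop("rate must be >= 0")
  new_reaction("membrane_influx",
               list(educts = character(0), products = species,
                    molecules_per_s = molecules_per_s,
                    shell_thickness = shell_thickness))
}

#' @rdname reaction_spec
#' @export
rx_membrane_export <- function(species, kappa = NULL) {
  new_reaction("membrane_export",
               list(educts = species, products = character(0), kappa = kappa))
}
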