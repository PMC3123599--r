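#' Construct a virtual-cell obstacle geometry
#'
#' A cell geometry is a closed spherical membrane of radius `cell_radius`
#' containing two kinds of immobile obstacles: cytoskeleton filaments modelled
#' as finite cylinders (capsule distance test) and inert crowding spheres.
#' Obstacle centres may lie anywhere inside the cell ball and obstacles may
#' protrude through the membrane; only the in-cell portion restricts motion,
#' because every accessibility test also enforces membrane containment.
#'
#' @param cell_radius membrane radius in um
#' @param cylinders data frame with columns `cx, cy, cz` (centre, um),
#'   `ax, ay, az` (unit axis), `length` (um), `radius` (um)
#' @param spheres data frame with columns `cx, cy, cz` (centre, um) and
#'   `radius` (um)
#' @param grid_h spatial-index cell edge in um
#' @param margin largest probe radius (molecule radius plus any adsorption
#'   layer) the spatial index guarantees; queries with larger probes fall back
#'   to a full scan
#' @return an object of class `cell_geometry`
#' @export
cell_geometry <- function(cell_radius, cylinders = NULL, spheres = NULL,
                          grid_h = 0.06, margin = 0.01) {
  if (!is.numeric(cell_radius) || cell_radius <= 0) {
    stop("cell_radius must be positive")
  }
  empty_cyl <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                          ax = numeric(0), ay = numeric(0), az = numeric(0),
                          length = numeric(0), radius = numeric(0))
  empty_sph <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                          radius = numeric(0))
  if (is.null(cylinders)) cylinders <- empty_cyl
  if (is.null(spheres)) spheres <- empty_sph
  cylinders <- as.data.frame(cylinders)
  spheres <- as.data.frame(spheres)
  if (nrow(cylinders) > 0) {
    if (any(cylinders$length <= 0) || any(cylinders$radius <= 0)) {
      stop("cylinder length and radius must be positive")
    }
    nrm <- sqrt(cylinders$ax^2 + cylinders$ay^2 + cylinders$az^2)
    if (any(abs(nrm - 1) > 1e-9)) stop("cylinder axes must be unit vectors")
  }
  if (nrow(spheres) > 0 && any(spheres$radius <= 0)) {
    stop("sphere radius must be positive")
  }
  g <- list(cell_radius = cell_radius, cylinders = cylinders,
            spheres = spheres, grid_h = grid_h, margin = margin,
            .cache = new.env(parent = emptyenv()))
  class(g) <- "cell_geometry"
  g
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> radius %.4g um, %d cylinders, %d spheres (V = %.4g um^3)\n",
    x$cell_radius, nrow(x$cylinders), nrow(x$spheres),
    sphere_volume(x$cell_radius)))
  invisible(x)
}

#' Random crowded geometry: uniformly arranged cylinders and spheres
#'
#' Cylinder centres are uniform in the cell ball with orientations uniform on
#' the unit sphere; sphere centres are uniform in the ball. Obstacles may
#' overlap each other and may protrude through the membrane. `density_multiplier`
#' rescales both obstacle counts; the packaged default-cell generator uses it
#' to calibrate the tracer-excluded volume fraction (see
#' [default_cell_geometry()]).
#'
#' @param cell_radius membrane radius, um
#' @param n_cylinders,n_spheres obstacle counts (before rescaling)
#' @param cyl_length,cyl_radius cylinder dimensions, um
#' @param sph_radius crowding-sphere radius, um
#' @param seed integer seed; the same seed reproduces the identical geometry
#' @param density_multiplier common factor applied to both obstacle counts
#' @inheritParams cell_geometry
#' @return a `cell_geometry`
#' @export
generate_geometry <- function(cell_radius, n_cylinders, cyl_length, cyl_radius,
                              n_spheres, sph_radius, seed = 1,
                              density_multiplier = 1,
                              grid_h = 0.06, margin = 0.01) {
  if (cell_radius <= 0) stop("cell_radius must be positive")
  if (n_cylinders > 0 && (cyl_length <= 0 || cyl_radius <= 0)) {
    stop("cylinder dimensions must be positive")
  }
  if (n_spheres > 0 && sph_radius <= 0) stop("sphere radius must be positive")
  nc <- as.integer(round(n_cylinders * density_multiplier))
  ns <- as.integer(round(n_spheres * density_multiplier))
  with_seed(seed, {
    cyl <- if (nc > 0) {
      ctr <- runif_ball(nc, cell_radius)
      ax <- runif_sphere(nc)
      data.frame(cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                 ax = ax[, 1], ay = ax[, 2], az = ax[, 3],
                 length = rep(cyl_length, nc), radius = rep(cyl_radius, nc))
    } else NULL
    sph <- if (ns > 0) {
      ctr <- runif_ball(ns, cell_radius)
      data.frame(cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
                 radius = rep(sph_radius, ns))
    } else NULL
    cell_geometry(cell_radius, cyl, sph, grid_h = grid_h, margin = margin)
  })
}

# n uniform points in the ball of given radius (R RNG)
runif_ball <- function(n, radius) {
  dir <- runif_sphere(n)
  r <- radius * runif(n)^(1 / 3)
  dir * r
}

# n uniform directions on the unit sphere (R RNG)
runif_sphere <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Calibrated obstacle-count multiplier of the default crowded cell: chosen
# once so that the Monte-Carlo excluded volume fraction for a 2.5 nm tracer
# in the full-size default geometry is 30.5% (see the methods vignette).
.default_density_multiplier <- 0.791

#' The default crowded model cell
#'
#' A cell of 7 um diameter containing 25,000 cytoskeleton cylinders
#' (2.5 um long, 35 nm diameter) and 100,000 crowding spheres (60 nm
#' diameter), with obstacle counts rescaled by a fixed calibration multiplier
#' so that the excluded volume fraction for 2.5 nm tracer molecules is 30.5%,
#' the generator's stated operating point. For other cell radii the obstacle
#' counts scale with the cell volume, keeping the obstacle number density.
#'
#' @param seed geometry seed
#' @param cell_radius membrane radius, um
#' @inheritParams cell_geometry
#' @return a `cell_geometry`
#' @export
default_cell_geometry <- function(seed = 1, cell_radius = 3.5,
                                  grid_h = 0.06, margin = 0.01) {
  vol_scale <- (cell_radius / 3.5)^3
  generate_geometry(
    cell_radius = cell_radius,
    n_cylinders = 25000 * vol_scale, cyl_length = 2.5, cyl_radius = 0.0175,
    n_spheres = 100000 * vol_scale, sph_radius = 0.03,
    seed = seed, density_multiplier = .default_density_multiplier,
    grid_h = grid_h, margin = margin)
}

#' Calibrate the obstacle-count multiplier to an excluded-fraction target
#'
#' Because the 2.5 um cytoskeleton cylinders protrude through the membrane,
#' the in-cell excluded volume fraction at fixed obstacle number density
#' depends on the cell radius. This helper bisects the density multiplier of
#' [generate_geometry()] (paper-default obstacle dimensions, counts scaled
#' with cell volume) until the Monte-Carlo excluded fraction for the given
#' probe hits `target`, so reduced-scale cells can be generated at the same
#' crowding operating point as the full-size default cell.
#'
#' @param cell_radius membrane radius, um
#' @param target excluded volume fraction to calibrate to
#' @param probe_radius probe radius, um
#' @param seed geometry/sampling seed
#' @param n_samples Monte-Carlo points per bisection step
#' @param iter bisection iterations
#' @return the calibrated multiplier
#' @export
calibrate_density_multiplier <- function(cell_radius, target = 0.305,
                                         probe_radius = 0.0025, seed = 1,
                                         n_samples = 1e5, iter = 7) {
  vol_scale <- (cell_radius / 3.5)^3
  eval_eps <- function(m) {
    g <- generate_geometry(cell_radius, 25000 * vol_scale, 2.5, 0.0175,
                           100000 * vol_scale, 0.03, seed = seed,
                           density_multiplier = m)
    sample_excluded_fraction(g, probe_radius, n_samples, seed = seed + 1)$fraction
  }
  lo <- 0.2; hi <- 4
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (eval_eps(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# spatial index handle (built lazily, cached; survives reloads by rebuild)
geom_ptr <- function(geom) {
  cache <- geom$.cache
  if (!is.null(cache$ptr) && !cpp_ptr_valid(cache$ptr)) cache$ptr <- NULL
  if (is.null(cache$ptr)) {
    cyl <- as.matrix(geom$cylinders)
    sph <- as.matrix(geom$spheres)
    storage.mode(cyl) <- "double"
    storage.mode(sph) <- "double"
    cache$ptr <- cpp_geom_build(geom$cell_radius, cyl, sph,
                                geom$grid_h, geom$margin)
  }
  cache$ptr
}

#' Build (or rebuild) the spatial index of a geometry
#'
#' The index is a uniform grid storing, per grid cell, every obstacle whose
#' inflated surface could intersect a probe sphere in that cell; queries are
#' then a single-cell lookup and return exactly the brute-force answer for
#' probes up to the index margin. Indexing happens lazily on first use; this
#' function forces it.
#'
#' @param geom a `cell_geometry`
#' @return the geometry, invisibly, with its index cached
#' @export
build_spatial_index <- function(geom) {
  geom_ptr(geom)
  invisible(geom)
}

#' Test accessibility of points for a probe sphere
#'
#' A position is accessible when the probe sphere centred there lies entirely
#' inside the membrane and overlaps no obstacle. This is the same predicate
#' the random walk uses to reject motion steps.
#'
#' @param geom a `cell_geometry`
#' @param points numeric matrix (n x 3) of positions, um
#' @param probe_radius probe sphere radius, um
#' @param method `"index"` (spatial grid) or `"brute"` (scan all obstacles);
#'   both give identical answers
#' @return logical vector of length n
#' @export
is_accessible <- function(geom, points, probe_radius,
                          method = c("index", "brute")) {
  method <- match.arg(method)
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_is_accessible(geom_ptr(geom), points, probe_radius,
                    brute_force = identical(method, "brute"))
}

#' Monte-Carlo excluded volume fraction
#'
#' Fraction of the cell ball volume that is inaccessible to the centre of a
#' probe of the given radius, estimated from uniform sample points with a
#' binomial standard error.
#'
#' @inheritParams is_accessible
#' @param n_samples number of uniform sample points
#' @param seed sampler seed
#' @return a `volume_sample`: list with `fraction`, `standard_error`,
#'   `n_samples`, `seed`
#' @export
sample_excluded_fraction <- function(geom, probe_radius, n_samples = 1e5,
                                     seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  out <- cpp_sample_excluded(geom_ptr(geom), probe_radius,
                             as.integer(n_samples), as.double(seed))
  out$seed <- seed
  class(out) <- "volume_sample"
  out
}

#' Monte-Carlo pairwise accessibility factor
#'
#' Averages, over positions accessible to a molecule of radius `r_i`, the
#' accessible fraction of the interaction ball of radius `r_i + r_j` seen by a
#' reaction partner of radius `r_j`. This is the steric correction factor for
#' bimolecular reactions near obstacles: the interaction volume of a molecule
#' sitting close to a structure is partly blocked, so fewer partner positions
#' can lead to a collision.
#'
#' @inheritParams is_accessible
#' @param r_i,r_j molecule radii, um
#' @param n_centers number of molecule positions sampled (rejection sampling
#'   of accessible positions)
#' @param n_shell sample points in the interaction ball per centre
#' @param seed sampler seed
#' @param max_reject_factor abort with a saturation error after
#'   `max_reject_factor * n_centers` failed placement attempts
#' @return a `volume_sample` whose `fraction` is the accessibility factor
#' @export
sample_access_factor <- function(geom, r_i, r_j, n_centers = 1e4,
                                 n_shell = 100, seed = 1,
                                 max_reject_factor = 1000) {
  if (r_i <= 0 || r_j <= 0) stop("molecule radii must be positive")
  if (n_centers < 1 || n_shell < 1) stop("sample counts must be >= 1")
  out <- cpp_sample_access(geom_ptr(geom), r_i, r_j, as.integer(n_centers),
                           as.integer(n_shell), as.double(seed),
                           max_reject_factor)
  out$seed <- seed
  class(out) <- "volume_sample"
  out
}

#' Monte-Carlo accessible contact surface area of the obstacle structures
#'
#' Total area of the probe-contact surface (obstacle surfaces offset outward
#' by the probe radius) that lies inside the membrane and is not buried in
#' other obstacles. Used to convert a bulk first-order binding rate constant
#' into the intrinsic surface velocity of the adsorption layer (see
#' [kappa_from_kbind()]).
#'
#' @inheritParams is_accessible
#' @param n_samples surface sample points
#' @param seed sampler seed
#' @return list with `area` (um^2), `standard_error`, `nominal_area`,
#'   `n_samples`
#' @export
sample_surface_area <- function(geom, probe_radius, n_samples = 1e5,
                                seed = 1) {
  cpp_sample_surface(geom_ptr(geom), probe_radius, as.integer(n_samples),
                     as.double(seed))
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample> fraction %.4f +/- %.4f (n = %g, seed = %g)\n",
              x$fraction, x$standard_error, x$n_samples, x$seed))
  invisible(x)
}

#' Write / read a geometry as a plain-text CSV table
#'
#' One row per obstacle (`type` is `"cylinder"` or `"sphere"`), preceded by a
#' `"cell"` row holding the membrane radius. Full double precision is kept so
#' a round trip reproduces the geometry bit-exactly.
#'
#' @param geom a `cell_geometry`
#' @param path file path
#' @return `write_geometry_csv` returns `path` invisibly;
#'   `read_geometry_csv` returns a `cell_geometry`
#' @export
write_geometry_csv <- function(geom, path) {
  n_c <- nrow(geom$cylinders)
  n_s <- nrow(geom$spheres)
  rows <- data.frame(
    type = c("cell", rep("cylinder", n_c), rep("sphere", n_s)),
    cx = c(0, geom$cylinders$cx, geom$spheres$cx),
    cy = c(0, geom$cylinders$cy, geom$spheres$cy),
    cz = c(0, geom$cylinders$cz, geom$spheres$cz),
    ax = c(0, geom$cylinders$ax, rep(0, n_s)),
    ay = c(0, geom$cylinders$ay, rep(0, n_s)),
    az = c(0, geom$cylinders$az, rep(0, n_s)),
    length = c(0, geom$cylinders$length, rep(0, n_s)),
    radius = c(geom$cell_radius, geom$cylinders$radius, geom$spheres$radius))
  # format() would round; write full precision explicitly
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(rows), collapse = ","), con)
  num <- vapply(seq_len(nrow(rows)), function(i) {
    paste(c(rows$type[i],
            sprintf("%.17g", as.numeric(rows[i, -1]))), collapse = ",")
  }, character(1))
  writeLines(num, con)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @inheritParams cell_geometry
#' @export
read_geometry_csv <- function(path, grid_h = 0.06, margin = 0.01) {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  cellrow <- rows[rows$type == "cell", , drop = FALSE]
  if (nrow(cellrow) != 1) stop("geometry file must contain one 'cell' row")
  cyl <- rows[rows$type == "cylinder", c("cx", "cy", "cz", "ax", "ay", "az",
                                         "length", "radius"), drop = FALSE]
  sph <- rows[rows$type == "sphere", c("cx", "cy", "cz", "radius"),
              drop = FALSE]
  rownames(cyl) <- NULL
  rownames(sph) <- NULL
  cell_geometry(cellrow$radius,
                if (nrow(cyl)) cyl else NULL,
                if (nrow(sph)) sph else NULL,
                grid_h = grid_h, margin = margin)
}
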