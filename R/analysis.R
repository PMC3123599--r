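#' Mean squared displacement of recorded trajectories
#'
#' Ensemble- (and optionally time-origin-) averaged squared displacement per
#' lag, `<r^2(lag)>`. For free diffusion in 3D the curve is the line
#' `6 D t`; in a crowded cell it bends from an initial slope governed by the
#' free-space `D0` to a reduced long-time slope `6 D_eff t` (transient
#' anomalous diffusion).
#'
#' @param sim a `bd_sim` with recorded positions, or an `n x 3 x frames`
#'   array
#' @param times snapshot times (taken from the `bd_sim` when omitted)
#' @param lags lag times to evaluate, s (defaults to ~60 lags spanning the
#'   trajectory); lags exceeding the trajectory are dropped with a warning
#' @param use_multiple_origins average over shifted time origins (variance
#'   reduction for stationary increments)
#' @param origin_every origin spacing in frames when using multiple origins
#' @return an `msd_curve` data frame with columns `lag`, `msd`, `n_pairs`
#' @export
compute_msd <- function(sim, times = NULL, lags = NULL,
                        use_multiple_origins = TRUE, origin_every = NULL) {
  if (inherits(sim, "bd_sim")) {
    if (is.null(sim$positions)) stop("simulation has no recorded positions")
    pos <- sim$positions
    if (is.null(times)) times <- sim$record_times
  } else {
    pos <- sim
  }
  stopifnot(length(dim(pos)) == 3, dim(pos)[2] == 3)
  nf <- dim(pos)[3]
  n <- dim(pos)[1]
  if (is.null(times)) stop("times must be supplied for a plain array")
  dtf <- times[2] - times[1]

  if (is.null(lags)) {
    lag_frames <- unique(round(exp(seq(log(1), log(nf - 1), length.out = 60))))
  } else {
    lag_frames <- round(lags / dtf)
    drop <- lag_frames >= nf | lag_frames < 0
    if (any(drop)) {
      warning(sum(drop), " lag(s) exceed the trajectory length; dropped")
      lag_frames <- lag_frames[!drop]
    }
    lag_frames <- unique(lag_frames)
  }
  lag_frames <- sort(lag_frames[lag_frames >= 1])

  if (is.null(origin_every)) origin_every <- max(1L, floor(nf / 100))
  msd <- numeric(length(lag_frames))
  npair <- numeric(length(lag_frames))
  for (k in seq_along(lag_frames)) {
    lf <- lag_frames[k]
    origins <- if (use_multiple_origins) {
      seq(1L, nf - lf, by = origin_every)
    } else 1L
    acc <- 0
    for (o in origins) {
      d <- pos[, , o + lf] - pos[, , o]
      acc <- acc + sum(d * d)
    }
    msd[k] <- acc / (n * length(origins))
    npair[k] <- n * length(origins)
  }
  out <- data.frame(lag = c(0, lag_frames * dtf), msd = c(0, msd),
                    n_pairs = c(n, npair))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Effective diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the MSD over a lag window, divided by `2 d = 6`
#' (3D). Reporting the short-lag and the long-lag estimate of the same run
#' exposes the anomalous-diffusion crossover: the short-lag window returns
#' the free-space coefficient, the long-lag window the reduced effective
#' coefficient.
#'
#' @param curve an `msd_curve`
#' @param window numeric length-2 lag window `[lag_min, lag_max]`, s
#' @param method `"slope"` fits a straight line and returns slope/6 (local
#'   derivative of the MSD); `"ratio"` averages `msd/(6 lag)` over the window
#'   (the secant estimate, less sensitive to residual curvature at the ends
#'   of the window)
#' @return list with `D` (um^2/s), `ci` (an approximate 95% interval: from
#'   the fit residuals for `"slope"`, from the per-lag spread for
#'   `"ratio"` - MSD points at nearby lags are correlated, so both are
#'   optimistic), and the `lm` fit (slope method only)
#' @export
estimate_Deff <- function(curve, window, method = c("slope", "ratio")) {
  method <- match.arg(method)
  d <- curve[curve$lag >= window[1] & curve$lag <= window[2] & curve$lag > 0, ]
  if (nrow(d) < 3) stop("fewer than 3 MSD points in the fit window")
  if (method == "ratio") {
    r <- d$msd / (6 * d$lag)
    se <- stats::sd(r) / sqrt(length(r))
    return(list(D = mean(r), ci = mean(r) + c(-2, 2) * se, fit = NULL))
  }
  fit <- lm(msd ~ lag, data = d)
  ci <- suppressMessages(confint(fit)["lag", ] / 6)
  list(D = unname(coef(fit)["lag"]) / 6, ci = unname(ci), fit = fit)
}

#' Unbound fraction time series
#'
#' Fraction of molecules of a species that are not adsorbed to structures,
#' `fu(t) = unbound / total`, plus the plateau estimate over the final part
#' of the run (block-averaged standard error).
#'
#' @param sim a `bd_sim`
#' @param species species name
#' @param plateau_from start of the plateau window as a fraction of the run
#' @return list with `series` (data frame `time`, `fu`), `fu` (plateau mean),
#'   `se`
#' @export
unbound_fraction <- function(sim, species, plateau_from = 0.5) {
  tot <- sim$counts[, species]
  bnd <- sim$bound[, species]
  fu <- ifelse(tot > 0, (tot - bnd) / tot, NA_real_)
  ser <- data.frame(time = sim$times, fu = fu)
  t0 <- plateau_from * max(sim$times)
  ss <- steady_state_average(fu, window = c(t0, max(sim$times)),
                             times = sim$times)
  list(series = ser, fu = ss$mean, se = ss$se)
}
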