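#include <Rcpp.h>
#include "geometry.h"
#include "rng.h"

using namespace Rcpp;
using crowdcell::Geom;
using crowdcell::RNG;

// Build the obstacle world and its uniform-grid index.
// cyl: n x 8 matrix (cx, cy, cz, ax, ay, az, length, radius), axis unit length
// sph: n x 4 matrix (cx, cy, cz, radius)
// margin: largest probe radius (molecule radius plus adsorption layer) the
//         index must serve exactly
// [[Rcpp::export]]
SEXP cpp_geom_build(double cell_radius, NumericMatrix cyl, NumericMatrix sph,
                    double grid_h, double margin) {
  Geom *g = new Geom();
  XPtr<Geom> ptr(g, true);
  g->cellR = cell_radius;
  g->ncyl = cyl.nrow();
  g->nsph = sph.nrow();
  g->cylp.resize(8 * (size_t)g->ncyl);
  for (int k = 0; k < g->ncyl; ++k) {
    double *c = &g->cylp[8 * (size_t)k];
    for (int j = 0; j < 6; ++j) c[j] = cyl(k, j);
    c[6] = 0.5 * cyl(k, 6);  // half-length
    c[7] = cyl(k, 7);
  }
  g->sphp.resize(4 * (size_t)g->nsph);
  for (int k = 0; k < g->nsph; ++k) {
    double *s = &g->sphp[4 * (size_t)k];
    for (int j = 0; j < 4; ++j) s[j] = sph(k, j);
  }

  const int nobs = g->ncyl + g->nsph;
  if (grid_h <= 0.0 || nobs == 0) return ptr;

  g->h = grid_h;
  g->margin = margin;
  g->nx = std::max(1, (int)std::ceil(2.0 * cell_radius / grid_h));
  const int nx = g->nx;
  const size_t ncell = (size_t)nx * nx * nx;
  const double halfdiag = 0.5 * std::sqrt(3.0) * g->h;

  // collect (cell, obstacle) pairs; an obstacle is registered in every grid
  // cell whose centre is within (obstacle radius + margin + half diagonal),
  // so a single-cell lookup is exact for probes up to `margin`
  std::vector<std::pair<int, int>> pairs;
  pairs.reserve((size_t)nobs * 8);

  auto clampi = [&](double v) {
    int i = (int)std::floor((v + cell_radius) / grid_h);
    return std::min(std::max(i, 0), nx - 1);
  };
  const auto cellcoord = [&](int i) {
    return -cell_radius + (i + 0.5) * grid_h;
  };

  for (int id = 0; id < g->ncyl; ++id) {
    const double *c = &g->cylp[8 * (size_t)id];
    const double reach = c[7] + margin + halfdiag;
    const double r2max = reach * reach;
    const double hl = c[6];
    const int nchunk = std::max(1, (int)std::ceil(2.0 * hl / grid_h));
    const double step = 2.0 * hl / nchunk;
    for (int q = 0; q < nchunk; ++q) {
      const double t0 = -hl + q * step;
      const double t1 = (q == nchunk - 1) ? hl + 1.0 : t0 + step;
      const double tl = (q == 0) ? -hl - 1.0 : t0;
      const double tc = t0 + 0.5 * step;
      const double mx = c[0] + tc * c[3], my = c[1] + tc * c[4],
                   mz = c[2] + tc * c[5];
      const double rad = reach + 0.5 * step;
      const int ix0 = clampi(mx - rad), ix1 = clampi(mx + rad);
      const int iy0 = clampi(my - rad), iy1 = clampi(my + rad);
      const int iz0 = clampi(mz - rad), iz1 = clampi(mz + rad);
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double ccx = cellcoord(ix);
        for (int iy = iy0; iy <= iy1; ++iy) {
          const double ccy = cellcoord(iy);
          for (int iz = iz0; iz <= iz1; ++iz) {
            const double ccz = cellcoord(iz);
            // closest-parameter along the axis decides chunk ownership so
            // each cell is registered exactly once per cylinder
            const double dx = ccx - c[0], dy = ccy - c[1], dz = ccz - c[2];
            double t = dx * c[3] + dy * c[4] + dz * c[5];
            if (t < tl || t >= t1) continue;
            double tcl = std::min(std::max(t, -hl), hl);
            const double ex = dx - tcl * c[3], ey = dy - tcl * c[4],
                         ez = dz - tcl * c[5];
            if (ex * ex + ey * ey + ez * ez <= r2max) {
              pairs.emplace_back((ix * nx + iy) * nx + iz, id);
            }
          }
        }
      }
    }
  }
  for (int k = 0; k < g->nsph; ++k) {
    const double *s = &g->sphp[4 * (size_t)k];
    const double reach = s[3] + margin + halfdiag;
    const double r2max = reach * reach;
    const int ix0 = clampi(s[0] - reach), ix1 = clampi(s[0] + reach);
    const int iy0 = clampi(s[1] - reach), iy1 = clampi(s[1] + reach);
    const int iz0 = clampi(s[2] - reach), iz1 = clampi(s[2] + reach);
    for (int ix = ix0; ix <= ix1; ++ix) {
      const double dx = cellcoord(ix) - s[0];
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = cellcoord(iy) - s[1];
        for (int iz = iz0; iz <= iz1; ++iz) {
          const double dz = cellcoord(iz) - s[2];
          if (dx * dx + dy * dy + dz * dz <= r2max) {
            pairs.emplace_back((ix * nx + iy) * nx + iz, g->ncyl + k);
          }
        }
      }
    }
  }

  // counting sort into CSR
  g->cell_start.assign(ncell + 1, 0);
  for (const auto &pr : pairs) ++g->cell_start[pr.first + 1];
  for (size_t c = 0; c < ncell; ++c) g->cell_start[c + 1] += g->cell_start[c];
  g->items.resize(pairs.size());
  std::vector<int> fill(ncell, 0);
  for (const auto &pr : pairs) {
    g->items[g->cell_start[pr.first] + fill[pr.first]++] = pr.second;
  }
  g->indexed = true;
  return ptr;
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr) { return R_ExternalPtrAddr(ptr) != NULL; }

// [[Rcpp::export]]
LogicalVector cpp_is_accessible(SEXP geom_ptr, NumericMatrix points,
                                double probe, bool brute_force = false) {
  XPtr<Geom> g(geom_ptr);
  const int n = points.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    if (brute_force) {
      const double lim = g->cellR - probe;
      out[i] = (lim >= 0.0 && x * x + y * y + z * z <= lim * lim) &&
               !g->hits_any_brute(x, y, z, probe);
    } else {
      out[i] = g->accessible(x, y, z, probe);
    }
  }
  return out;
}

// Monte-Carlo excluded volume fraction for a probe of given radius:
// fraction of uniform points in the cell ball whose probe sphere overlaps an
// obstacle (the membrane is containment, not crowding, and is not scored, so
// an empty cell has exactly zero excluded volume).
// [[Rcpp::export]]
List cpp_sample_excluded(SEXP geom_ptr, double probe, int n_samples,
                         double seed) {
  XPtr<Geom> g(geom_ptr);
  RNG rng((uint64_t)seed);
  double p[3];
  long hits = 0;
  for (int i = 0; i < n_samples; ++i) {
    rng.ball(g->cellR, p);
    if (g->near_structure(p[0], p[1], p[2], probe, 0.0)) ++hits;
  }
  const double frac = (double)hits / (double)n_samples;
  const double se = std::sqrt(std::max(frac * (1.0 - frac), 0.0) / n_samples);
  return List::create(_["fraction"] = frac, _["standard_error"] = se,
                      _["n_samples"] = n_samples);
}

// Pairwise accessibility factor: sample centres accessible to a probe of
// radius r_i (rejection sampling in the cell ball); around each centre sample
// points uniform in the interaction ball of radius (r_i + r_j) and score the
// fraction accessible to a probe of radius r_j. Mean over centres, SE across
// centres.
// [[Rcpp::export]]
List cpp_sample_access(SEXP geom_ptr, double r_i, double r_j, int n_centers,
                       int n_shell, double seed,
                       double max_reject_factor = 1000.0) {
  XPtr<Geom> g(geom_ptr);
  RNG rng((uint64_t)seed);
  double c[3], q[3];
  const double Rint = r_i + r_j;
  long max_tries = (long)(max_reject_factor * (double)n_centers) + 100;
  long tries = 0;
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < n_centers; ++i) {
    for (;;) {
      if (++tries > max_tries)
        stop("geometry too dense: accessible-centre sampling saturated");
      rng.ball(g->cellR, c);
      if (g->accessible(c[0], c[1], c[2], r_i)) break;
    }
    int ok = 0;
    for (int s = 0; s < n_shell; ++s) {
      rng.ball(Rint, q);
      if (g->accessible(c[0] + q[0], c[1] + q[1], c[2] + q[2], r_j)) ++ok;
    }
    const double f = (double)ok / (double)n_shell;
    sum += f;
    sum2 += f * f;
  }
  const double mean = sum / n_centers;
  double var = (sum2 - sum * sum / n_centers) / std::max(1, n_centers - 1);
  const double se = std::sqrt(std::max(var, 0.0) / n_centers);
  return List::create(_["fraction"] = mean, _["standard_error"] = se,
                      _["n_samples"] = n_centers);
}

// Accessible contact surface area of the obstacle structures for a probe of
// given radius: sample points on the probe-offset surfaces proportional to
// nominal area; keep the fraction whose contact position is inside the cell
// and not blocked by any other obstacle. Used to convert a bulk first-order
// binding rate into an intrinsic surface velocity.
// [[Rcpp::export]]
List cpp_sample_surface(SEXP geom_ptr, double probe, int n_samples,
                        double seed) {
  XPtr<Geom> g(geom_ptr);
  RNG rng((uint64_t)seed);
  const int nobs = g->ncyl + g->nsph;
  if (nobs == 0)
    return List::create(_["area"] = 0.0, _["standard_error"] = 0.0,
                        _["nominal_area"] = 0.0, _["n_samples"] = n_samples);

  std::vector<double> cum(nobs);
  double total = 0.0;
  for (int k = 0; k < g->ncyl; ++k) {
    const double *c = &g->cylp[8 * (size_t)k];
    total += 2.0 * M_PI * (c[7] + probe) * (2.0 * c[6]);
    cum[k] = total;
  }
  for (int k = 0; k < g->nsph; ++k) {
    const double r = g->sphp[4 * (size_t)k + 3] + probe;
    total += 4.0 * M_PI * r * r;
    cum[g->ncyl + k] = total;
  }

  long ok = 0;
  double p[3];
  const double eps = 1e-9;
  for (int i = 0; i < n_samples; ++i) {
    const double u = rng.runif() * total;
    const int id =
        (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (id < g->ncyl) {
      const double *c = &g->cylp[8 * (size_t)id];
      const double t = rng.runif(-c[6], c[6]);
      // orthonormal frame (u, v) perpendicular to the axis
      double ux = -c[4], uy = c[3], uz = 0.0;
      double n2 = ux * ux + uy * uy;
      if (n2 < 1e-12) { ux = 1.0; uy = 0.0; n2 = 1.0; }
      const double inv = 1.0 / std::sqrt(n2);
      ux *= inv; uy *= inv;
      const double vx = c[4] * uz - c[5] * uy;
      const double vy = c[5] * ux - c[3] * uz;
      const double vz = c[3] * uy - c[4] * ux;
      const double phi = rng.runif(0.0, 2.0 * M_PI);
      const double r = c[7] + probe;
      const double cp = std::cos(phi), sp = std::sin(phi);
      p[0] = c[0] + t * c[3] + r * (cp * ux + sp * vx);
      p[1] = c[1] + t * c[4] + r * (cp * uy + sp * vy);
      p[2] = c[2] + t * c[5] + r * (cp * uz + sp * vz);
    } else {
      const double *s = &g->sphp[4 * (size_t)(id - g->ncyl)];
      double d[3];
      rng.shell(1.0, 1.0, d);
      const double r = s[3] + probe;
      p[0] = s[0] + r * d[0];
      p[1] = s[1] + r * d[1];
      p[2] = s[2] + r * d[2];
    }
    const double lim = g->cellR - probe;
    if (lim < 0.0 || p[0] * p[0] + p[1] * p[1] + p[2] * p[2] > lim * lim)
      continue;
    // blocked by any obstacle other than its own contact surface? (slightly
    // deflated probe so the own surface does not register)
    bool blocked = false;
    if (g->indexed && probe <= g->margin) {
      const int c = g->cell_of(p[0], p[1], p[2]);
      for (int ii = g->cell_start[c]; ii < g->cell_start[c + 1]; ++ii) {
        const int jd = g->items[ii];
        if (jd == id) continue;
        if (g->hits_obstacle(jd, p[0], p[1], p[2], probe - eps)) {
          blocked = true;
          break;
        }
      }
    } else {
      for (int jd = 0; jd < nobs && !blocked; ++jd) {
        if (jd == id) continue;
        if (g->hits_obstacle(jd, p[0], p[1], p[2], probe - eps)) blocked = true;
      }
    }
    if (!blocked) ++ok;
  }
  const double frac = (double)ok / (double)n_samples;
  const double se_frac = std::sqrt(std::max(frac * (1.0 - frac), 0.0) / n_samples);
  return List::create(_["area"] = frac * total,
                      _["standard_error"] = se_frac * total,
                      _["nominal_area"] = total, _["n_samples"] = n_samples);
}

// Obstacle ids (1-based) registered in the grid cell of a query point; used
// to validate the index against a brute-force scan.
// [[Rcpp::export]]
IntegerVector cpp_index_query(SEXP geom_ptr, NumericVector point) {
  XPtr<Geom> g(geom_ptr);
  if (!g->indexed) return IntegerVector(0);
  const int c = g->cell_of(point[0], point[1], point[2]);
  IntegerVector out(g->cell_start[c + 1] - g->cell_start[c]);
  for (int i = g->cell_start[c], j = 0; i < g->cell_start[c + 1]; ++i, ++j)
    out[j] = g->items[i] + 1;
  return out;
}
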