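// Obstacle world of the virtual cell: bounding membrane sphere, capsule-shaped
// cytoskeleton cylinders (finite-segment distance test) and crowding spheres,
// plus a uniform-grid spatial index over obstacle ids. Obstacle parameters are
// additionally kept packed per obstacle (one cache line) for the hot
// accessibility test of the random walk.
#pragma once
#include <vector>
#include <cmath>
#include <algorithm>

namespace crowdcell {

struct Geom {
  double cellR;
  int ncyl, nsph;
  // packed cylinder records: cx, cy, cz, ax, ay, az, half-length, radius
  std::vector<double> cylp;
  // packed sphere records: cx, cy, cz, radius
  std::vector<double> sphp;

  // uniform grid over the cube [-cellR, cellR]^3
  bool indexed = false;
  double h = 0.0;        // grid cell edge
  double margin = 0.0;   // max probe radius the index guarantees
  int nx = 0;
  std::vector<int> cell_start;  // CSR offsets, nx^3 + 1
  std::vector<int> items;       // obstacle ids (< ncyl: cylinder, else sphere ncyl+k)

  inline int cell_of(double x, double y, double z) const {
    int ix = (int)std::floor((x + cellR) / h);
    int iy = (int)std::floor((y + cellR) / h);
    int iz = (int)std::floor((z + cellR) / h);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), nx - 1);
    iz = std::min(std::max(iz, 0), nx - 1);
    return (ix * nx + iy) * nx + iz;
  }

  // squared distance from point to the finite axis segment of cylinder k
  inline double d2_segment(int k, double x, double y, double z) const {
    const double *c = &cylp[8 * k];
    const double dx = x - c[0], dy = y - c[1], dz = z - c[2];
    double t = dx * c[3] + dy * c[4] + dz * c[5];
    const double hl = c[6];
    if (t > hl) t = hl; else if (t < -hl) t = -hl;
    const double ex = dx - t * c[3], ey = dy - t * c[4], ez = dz - t * c[5];
    return ex * ex + ey * ey + ez * ez;
  }

  inline bool hits_obstacle(int id, double x, double y, double z,
                            double probe) const {
    if (id < ncyl) {
      const double rr = cylp[8 * id + 7] + probe;
      return d2_segment(id, x, y, z) < rr * rr;
    }
    const double *s = &sphp[4 * (id - ncyl)];
    const double dx = x - s[0], dy = y - s[1], dz = z - s[2];
    const double rr = s[3] + probe;
    return dx * dx + dy * dy + dz * dz < rr * rr;
  }

  inline bool hits_any_brute(double x, double y, double z, double probe) const {
    for (int k = 0; k < ncyl; ++k) {
      const double rr = cylp[8 * k + 7] + probe;
      if (d2_segment(k, x, y, z) < rr * rr) return true;
    }
    for (int k = 0; k < nsph; ++k) {
      const double *s = &sphp[4 * k];
      const double dx = x - s[0], dy = y - s[1], dz = z - s[2];
      const double rr = s[3] + probe;
      if (dx * dx + dy * dy + dz * dz < rr * rr) return true;
    }
    return false;
  }

  // true iff a probe sphere centred at p lies fully inside the membrane and
  // overlaps no obstacle; exact for probe <= margin when the index is used
  inline bool accessible(double x, double y, double z, double probe) const {
    const double lim = cellR - probe;
    if (lim < 0.0 || x * x + y * y + z * z > lim * lim) return false;
    if (!indexed || probe > margin) {
      return !hits_any_brute(x, y, z, probe);
    }
    const int c = cell_of(x, y, z);
    const int i1 = cell_start[c + 1];
    for (int i = cell_start[c]; i < i1; ++i) {
      if (hits_obstacle(items[i], x, y, z, probe)) return false;
    }
    return true;
  }

  // adsorption-layer test: does any obstacle surface lie within
  // (probe + layer) of the point? (membrane handled caller-side)
  inline bool near_structure(double x, double y, double z, double probe,
                             double layer) const {
    const double inflated = probe + layer;
    if (!indexed || inflated > margin) return hits_any_brute(x, y, z, inflated);
    const int c = cell_of(x, y, z);
    const int i1 = cell_start[c + 1];
    for (int i = cell_start[c]; i < i1; ++i) {
      if (hits_obstacle(items[i], x, y, z, inflated)) return true;
    }
    return false;
  }
};

}  // namespace crowdcell
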