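// Small self-contained counter-free PRNG (xoshiro256++) so that multi-billion
// draw simulations do not pay the R RNG call overhead and every sampler can be
// seeded explicitly and reproducibly from a single integer.
#pragma once
#include <cstdint>
#include <cmath>

namespace crowdcell {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s[4];
  bool has_cache;
  double cache;

  explicit RNG(uint64_t seed) : has_cache(false), cache(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the (astronomically unlikely) all-zero state
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double runif() { return (next() >> 11) * 0x1.0p-53; }

  inline double runif(double a, double b) { return a + (b - a) * runif(); }

  // standard normal, Marsaglia polar method with caching
  inline double rnorm() {
    if (has_cache) {
      has_cache = false;
      return cache;
    }
    double u, v, s2;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f;
    has_cache = true;
    return u * f;
  }

  // Poisson draw; per-step means in the engine are << 1, but stay correct for
  // large means by recursive thinning into halves.
  inline int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    int n = 0;
    while (lambda > 30.0) {
      // split: X = X1 + X2 with lambda/2 each
      double half = lambda * 0.5;
      n += rpois_small(half);
      lambda -= half;
    }
    return n + rpois_small(lambda);
  }

  inline int rpois_small(double lambda) {
    const double L = std::exp(-lambda);
    int k = 0;
    double p = 1.0;
    do {
      ++k;
      p *= runif();
    } while (p > L);
    return k - 1;
  }

  // uniform point in the ball of radius R (rejection from the cube)
  inline void ball(double R, double *p) {
    double x, y, z;
    do {
      x = 2.0 * runif() - 1.0;
      y = 2.0 * runif() - 1.0;
      z = 2.0 * runif() - 1.0;
    } while (x * x + y * y + z * z > 1.0);
    p[0] = R * x;
    p[1] = R * y;
    p[2] = R * z;
  }

  // uniform point in the spherical shell r0 <= |p| <= r1
  inline void shell(double r0, double r1, double *p) {
    double x, y, z, n2;
    do {
      x = rnorm();
      y = rnorm();
      z = rnorm();
      n2 = x * x + y * y + z * z;
    } while (n2 == 0.0);
    const double inv = 1.0 / std::sqrt(n2);
    const double r03 = r0 * r0 * r0, r13 = r1 * r1 * r1;
    const double r = std::cbrt(runif() * (r13 - r03) + r03);
    p[0] = r * x * inv;
    p[1] = r * y * inv;
    p[2] = r * z * inv;
  }
};

}  // namespace crowdcell
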