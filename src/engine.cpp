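// Time loop of the Brownian-dynamics simulator. Per step (fixed dt):
//   1. rejection-sampled Gaussian random walk of unbound mobile particles
//   2. surface adsorption (reaction layer, P = 1) and dissociation
//   3. bimolecular channels: candidate pairs within the collision radius via
//      spatial hashing, visited in uniformly random order, each particle
//      participating in at most one reaction per step
//   4. unimolecular conversions, zero-order creation, membrane influx/export
//   5. observation (counts, bound counts, cumulative events, snapshots)
// All channel parameters arrive pre-lowered from R (probabilities per step,
// layer heights, Poisson means per step).
#include <Rcpp.h>
#include "geometry.h"
#include "rng.h"

using namespace Rcpp;
using crowdcell::Geom;
using crowdcell::RNG;

namespace {

struct ZeroCh { int sp; double lam; int region; double shell; };
struct UniCh { int sp; double p; std::vector<int> prods; };
struct BiCh {
  int spi, spj;
  double rcrit, r2crit, P;
  bool cati, catj;
  int stat;                // 0: both mobile, 1: spi static, 2: spj static
  std::vector<int> prods;  // products excluding catalytic educts
};
struct AdsCh { int sp; double layer; bool structures, membrane; };
struct DissCh { int sp; double p; };
struct FluxCh { int sp; double lam; double shell; };
struct ExpCh { int sp; double layer; };

struct CandPair { int a, b, ch; };  // b = -(1+k): static partner record k

// dense single-lookup grid over immobile catalytic reactants (enzymes fixed
// in space for the whole run); queries return every static record within the
// channel's collision radius of any point in the queried cell
struct StaticGrid {
  double h, x0;
  int nx = 0;
  std::vector<int> cell_start;
  std::vector<int> items;              // static record ids
  std::vector<double> pos;             // 3 per record
  std::vector<int> spec;               // species per record

  void build(const std::vector<double> &px, const std::vector<double> &py,
             const std::vector<double> &pz, const std::vector<int> &sp,
             const std::vector<char> &is_static_sp, double reach,
             double cellR) {
    for (size_t i = 0; i < px.size(); ++i) {
      if (is_static_sp[sp[i]]) {
        pos.push_back(px[i]); pos.push_back(py[i]); pos.push_back(pz[i]);
        spec.push_back(sp[i]);
      }
    }
    const int n = (int)spec.size();
    h = std::max(4.0 * reach, 1e-3);
    x0 = cellR;
    nx = std::max(1, (int)std::ceil(2.0 * cellR / h));
    const double halfdiag = 0.5 * std::sqrt(3.0) * h;
    const double r2 = (reach + halfdiag) * (reach + halfdiag);
    const size_t ncell = (size_t)nx * nx * nx;
    std::vector<std::pair<int, int>> pairs;
    auto clampi = [&](double v) {
      int i = (int)std::floor((v + x0) / h);
      return std::min(std::max(i, 0), nx - 1);
    };
    for (int k = 0; k < n; ++k) {
      const double qx = pos[3 * k], qy = pos[3 * k + 1], qz = pos[3 * k + 2];
      const int ix0 = clampi(qx - reach - halfdiag), ix1 = clampi(qx + reach + halfdiag);
      const int iy0 = clampi(qy - reach - halfdiag), iy1 = clampi(qy + reach + halfdiag);
      const int iz0 = clampi(qz - reach - halfdiag), iz1 = clampi(qz + reach + halfdiag);
      for (int ix = ix0; ix <= ix1; ++ix)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int iz = iz0; iz <= iz1; ++iz) {
            const double cx = -x0 + (ix + 0.5) * h - qx;
            const double cy = -x0 + (iy + 0.5) * h - qy;
            const double cz = -x0 + (iz + 0.5) * h - qz;
            if (cx * cx + cy * cy + cz * cz <= r2)
              pairs.emplace_back((ix * nx + iy) * nx + iz, k);
          }
    }
    cell_start.assign(ncell + 1, 0);
    for (auto &pr : pairs) ++cell_start[pr.first + 1];
    for (size_t c = 0; c < ncell; ++c) cell_start[c + 1] += cell_start[c];
    items.resize(pairs.size());
    std::vector<int> fill(ncell, 0);
    for (auto &pr : pairs)
      items[cell_start[pr.first] + fill[pr.first]++] = pr.second;
  }

  inline int cell_of(double x, double y, double z) const {
    int ix = (int)std::floor((x + x0) / h);
    int iy = (int)std::floor((y + x0) / h);
    int iz = (int)std::floor((z + x0) / h);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), nx - 1);
    iz = std::min(std::max(iz, 0), nx - 1);
    return (ix * nx + iy) * nx + iz;
  }
};

// open-addressing spatial hash of particle positions (rebuilt each step)
struct PairGrid {
  double inv_h;
  int mask;
  std::vector<int64_t> keys;
  std::vector<int> head;
  std::vector<int> nxt;
  std::vector<int> touched;

  void init(int capacity) {
    int slots = 64;
    while (slots < 4 * capacity) slots <<= 1;
    mask = slots - 1;
    keys.assign(slots, -1);
    head.assign(slots, -1);
    nxt.assign(capacity, -1);
    touched.clear();
    touched.reserve(capacity);
  }
  void reset(int capacity) {
    for (int s : touched) { keys[s] = -1; head[s] = -1; }
    touched.clear();
    if ((int)nxt.size() < capacity) nxt.resize(capacity, -1);
  }
  static inline int64_t pack(int ix, int iy, int iz) {
    return (((int64_t)(ix & 0x1FFFFF)) << 42) |
           (((int64_t)(iy & 0x1FFFFF)) << 21) |
           ((int64_t)(iz & 0x1FFFFF));
  }
  inline int slot_of(int64_t key) const {
    uint64_t hsh = (uint64_t)key * 0x9E3779B97F4A7C15ULL;
    int s = (int)(hsh >> 40) & mask;
    while (keys[s] != -1 && keys[s] != key) s = (s + 1) & mask;
    return s;
  }
  inline void insert(int idx, double x, double y, double z) {
    const int ix = (int)std::floor(x * inv_h);
    const int iy = (int)std::floor(y * inv_h);
    const int iz = (int)std::floor(z * inv_h);
    const int64_t key = pack(ix, iy, iz);
    const int s = slot_of(key);
    if (keys[s] == -1) { keys[s] = key; touched.push_back(s); }
    nxt[idx] = head[s];
    head[s] = idx;
  }
  inline int chain(int ix, int iy, int iz) const {
    const int64_t key = pack(ix, iy, iz);
    const int s = slot_of(key);
    return keys[s] == key ? head[s] : -1;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(SEXP geom_ptr, List cfg) {
  XPtr<Geom> gp(geom_ptr);
  const Geom &G = *gp;
  RNG rng((uint64_t)as<double>(cfg["seed"]));

  const long n_steps = (long)as<double>(cfg["n_steps"]);
  const long obs_every = (long)as<double>(cfg["obs_every"]);
  const double dt = as<double>(cfg["dt"]);

  const NumericVector radius = cfg["radius"];
  const NumericVector sigma = cfg["sigma"];  // per-axis step sd, sqrt(2 D dt)
  const int nsp = radius.size();

  // initial particles
  NumericMatrix init_pos = cfg["init_pos"];
  IntegerVector init_sp = cfg["init_species"];
  LogicalVector init_bd = cfg["init_bound"];
  int n = init_pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> sp(n);
  std::vector<char> bound(n);
  for (int i = 0; i < n; ++i) {
    px[i] = init_pos(i, 0); py[i] = init_pos(i, 1); pz[i] = init_pos(i, 2);
    sp[i] = init_sp[i];
    bound[i] = init_bd[i] ? 1 : 0;
  }

  const int n_record = as<int>(cfg["n_record"]);
  const long record_every = (long)as<double>(cfg["record_every"]);
  const int max_tries = as<int>(cfg["max_place_tries"]);

  // immobile catalytic species (validated in R: D0 = 0, never created,
  // destroyed, transformed or bound); their pair search uses a grid built
  // once at t = 0
  IntegerVector static_in = cfg["static_species"];
  std::vector<char> static_sp(nsp, 0);
  for (int s = 0; s < nsp; ++s) static_sp[s] = static_in[s] != 0;

  // channels
  List chans = cfg["channels"];
  const int nch = chans.size();
  std::vector<ZeroCh> zeros; std::vector<UniCh> unis; std::vector<BiCh> bis;
  std::vector<AdsCh> adss; std::vector<DissCh> disss;
  std::vector<FluxCh> fluxes; std::vector<ExpCh> exps;
  std::vector<int> zero_id, uni_id, bi_id, ads_id, diss_id, flux_id, exp_id;
  double max_rcrit = 0.0, max_static_rcrit = 0.0;
  std::vector<char> sp_hashed(nsp, 0);
  for (int c = 0; c < nch; ++c) {
    List ch = chans[c];
    const int kind = as<int>(ch["kind"]);
    switch (kind) {
      case 0: {
        ZeroCh z; z.sp = as<int>(ch["sp"]); z.lam = as<double>(ch["lam_step"]);
        z.region = as<int>(ch["region"]); z.shell = as<double>(ch["shell"]);
        zeros.push_back(z); zero_id.push_back(c); break;
      }
      case 1: {
        UniCh u; u.sp = as<int>(ch["sp"]); u.p = as<double>(ch["p"]);
        u.prods = as<std::vector<int>>(ch["prods"]);
        unis.push_back(u); uni_id.push_back(c); break;
      }
      case 2: {
        BiCh b; b.spi = as<int>(ch["spi"]); b.spj = as<int>(ch["spj"]);
        b.rcrit = as<double>(ch["rcrit"]); b.r2crit = b.rcrit * b.rcrit;
        b.P = as<double>(ch["P"]);
        b.cati = as<bool>(ch["cat_i"]); b.catj = as<bool>(ch["cat_j"]);
        b.stat = 0;
        if (static_sp[b.spi] && static_sp[b.spj])
          stop("bimolecular channel between two immobile catalytic species");
        if (static_sp[b.spi]) b.stat = 1;
        else if (static_sp[b.spj]) b.stat = 2;
        b.prods = as<std::vector<int>>(ch["prods"]);
        bis.push_back(b); bi_id.push_back(c);
        if (b.stat == 0) {
          max_rcrit = std::max(max_rcrit, b.rcrit);
          sp_hashed[b.spi] = 1; sp_hashed[b.spj] = 1;
        } else {
          max_static_rcrit = std::max(max_static_rcrit, b.rcrit);
        }
        break;
      }
      case 3: {
        AdsCh a; a.sp = as<int>(ch["sp"]); a.layer = as<double>(ch["layer"]);
        a.structures = as<bool>(ch["structures"]);
        a.membrane = as<bool>(ch["membrane"]);
        adss.push_back(a); ads_id.push_back(c); break;
      }
      case 4: {
        DissCh d; d.sp = as<int>(ch["sp"]); d.p = as<double>(ch["p"]);
        disss.push_back(d); diss_id.push_back(c); break;
      }
      case 5: {
        FluxCh f; f.sp = as<int>(ch["sp"]); f.lam = as<double>(ch["lam_step"]);
        f.shell = as<double>(ch["shell"]);
        fluxes.push_back(f); flux_id.push_back(c); break;
      }
      case 6: {
        ExpCh e; e.sp = as<int>(ch["sp"]); e.layer = as<double>(ch["layer"]);
        exps.push_back(e); exp_id.push_back(c); break;
      }
      default: stop("unknown channel kind");
    }
  }

  // per-channel query side: for each bi channel pick the educt species whose
  // particle count is smaller (decided per step)
  const long n_obs = n_steps / std::max(obs_every, (long)1) + 1;
  NumericVector times(n_obs);
  IntegerMatrix counts(n_obs, nsp), boundcounts(n_obs, nsp);
  NumericMatrix events(n_obs, nch);
  std::vector<double> ev(nch, 0.0);

  long n_frames = 0;
  NumericVector positions(0);
  if (n_record > 0) {
    n_frames = n_steps / std::max(record_every, (long)1) + 1;
    positions = NumericVector((R_xlen_t)n_record * 3 * n_frames);
  }

  bool any_mobile_bi = false, any_static_bi = false;
  for (const BiCh &b : bis) {
    if (b.stat == 0) any_mobile_bi = true; else any_static_bi = true;
  }
  PairGrid grid;
  if (any_mobile_bi) {
    grid.inv_h = 1.0 / max_rcrit;
    grid.init(std::max(n, 64));
  }
  StaticGrid sgrid;
  if (any_static_bi) {
    sgrid.build(px, py, pz, sp, static_sp, max_static_rcrit, G.cellR);
  }
  const bool any_bi = !bis.empty();

  std::vector<char> used, dead;
  std::vector<CandPair> cand;
  std::vector<int> spcount(nsp, 0);

  auto place_accessible = [&](int s, int region, double shellth, double *out) {
    const double pr = radius[s];
    const double r0 = region == 1 ? std::max(G.cellR - shellth, 0.0) : 0.0;
    for (int t = 0; t < max_tries; ++t) {
      if (region == 1) rng.shell(r0, G.cellR, out);
      else rng.ball(G.cellR, out);
      if (G.accessible(out[0], out[1], out[2], pr)) return;
    }
    stop("accessible placement sampling saturated");
  };

  auto observe = [&](long iobs, double t) {
    times[iobs] = t;
    std::fill(spcount.begin(), spcount.end(), 0);
    std::vector<int> bc(nsp, 0);
    for (int i = 0; i < n; ++i) {
      ++spcount[sp[i]];
      if (bound[i]) ++bc[sp[i]];
    }
    for (int s = 0; s < nsp; ++s) {
      counts(iobs, s) = spcount[s];
      boundcounts(iobs, s) = bc[s];
    }
    for (int c = 0; c < nch; ++c) events(iobs, c) = ev[c];
  };

  auto snapshot = [&](long frame) {
    for (int i = 0; i < n_record; ++i) {
      positions[i + (R_xlen_t)n_record * (0 + 3 * frame)] = px[i];
      positions[i + (R_xlen_t)n_record * (1 + 3 * frame)] = py[i];
      positions[i + (R_xlen_t)n_record * (2 + 3 * frame)] = pz[i];
    }
  };

  observe(0, 0.0);
  if (n_record > 0) snapshot(0);
  long iobs = 1, iframe = 1;

  for (long step = 1; step <= n_steps; ++step) {
    // --- 1. diffusion ---------------------------------------------------
    for (int i = 0; i < n; ++i) {
      if (bound[i]) continue;
      const double sg = sigma[sp[i]];
      if (sg == 0.0) continue;
      const double qx = px[i] + sg * rng.rnorm();
      const double qy = py[i] + sg * rng.rnorm();
      const double qz = pz[i] + sg * rng.rnorm();
      if (G.accessible(qx, qy, qz, radius[sp[i]])) {
        px[i] = qx; py[i] = qy; pz[i] = qz;
      }
    }

    const int n_pre = n;
    used.assign(n, 0);
    dead.assign(n, 0);

    // --- 2. adsorption / dissociation -----------------------------------
    for (size_t a = 0; a < adss.size(); ++a) {
      const AdsCh &A = adss[a];
      if (A.layer <= 0.0) continue;
      for (int i = 0; i < n_pre; ++i) {
        if (sp[i] != A.sp || bound[i]) continue;
        bool hit = false;
        if (A.structures &&
            G.near_structure(px[i], py[i], pz[i], radius[A.sp], A.layer))
          hit = true;
        if (!hit && A.membrane) {
          const double d = std::sqrt(px[i] * px[i] + py[i] * py[i] +
                                     pz[i] * pz[i]);
          if (G.cellR - d - radius[A.sp] < A.layer) hit = true;
        }
        if (hit) { bound[i] = 1; ev[ads_id[a]] += 1.0; }
      }
    }
    for (size_t d = 0; d < disss.size(); ++d) {
      const DissCh &D = disss[d];
      for (int i = 0; i < n_pre; ++i) {
        if (sp[i] != D.sp || !bound[i]) continue;
        if (rng.runif() < D.p) { bound[i] = 0; ev[diss_id[d]] += 1.0; }
      }
    }

    // --- 3. bimolecular --------------------------------------------------
    if (any_bi) {
      std::fill(spcount.begin(), spcount.end(), 0);
      for (int i = 0; i < n; ++i) ++spcount[sp[i]];
      if (any_mobile_bi) {
        grid.reset(n);
        for (int i = 0; i < n; ++i) {
          if (sp_hashed[sp[i]]) grid.insert(i, px[i], py[i], pz[i]);
        }
      }
      cand.clear();
      for (size_t c = 0; c < bis.size(); ++c) {
        const BiCh &B = bis[c];
        if (B.stat != 0) {
          // mobile educt queries the static (enzyme) grid
          const int msp = (B.stat == 1) ? B.spj : B.spi;
          const int ssp = (B.stat == 1) ? B.spi : B.spj;
          for (int i = 0; i < n_pre; ++i) {
            if (sp[i] != msp) continue;
            const int cidx = sgrid.cell_of(px[i], py[i], pz[i]);
            for (int q = sgrid.cell_start[cidx];
                 q < sgrid.cell_start[cidx + 1]; ++q) {
              const int k = sgrid.items[q];
              if (sgrid.spec[k] != ssp) continue;
              const double dx = sgrid.pos[3 * k] - px[i];
              const double dy = sgrid.pos[3 * k + 1] - py[i];
              const double dz = sgrid.pos[3 * k + 2] - pz[i];
              if (dx * dx + dy * dy + dz * dz < B.r2crit) {
                CandPair cp;
                cp.a = i;
                cp.b = -(1 + k);
                cp.ch = (int)c;
                cand.push_back(cp);
              }
            }
          }
          continue;
        }
        const int qsp = (B.spi == B.spj || spcount[B.spi] <= spcount[B.spj])
                            ? B.spi : B.spj;
        const int psp = (qsp == B.spi) ? B.spj : B.spi;
        for (int i = 0; i < n_pre; ++i) {
          if (sp[i] != qsp) continue;
          const int ix = (int)std::floor(px[i] * grid.inv_h);
          const int iy = (int)std::floor(py[i] * grid.inv_h);
          const int iz = (int)std::floor(pz[i] * grid.inv_h);
          for (int ddx = -1; ddx <= 1; ++ddx)
            for (int ddy = -1; ddy <= 1; ++ddy)
              for (int ddz = -1; ddz <= 1; ++ddz) {
                for (int j = grid.chain(ix + ddx, iy + ddy, iz + ddz); j != -1;
                     j = grid.nxt[j]) {
                  if (j == i || sp[j] != psp) continue;
                  if (qsp == psp && j < i) continue;  // same-species dedupe
                  const double dx = px[j] - px[i], dy = py[j] - py[i],
                               dz = pz[j] - pz[i];
                  if (dx * dx + dy * dy + dz * dz < B.r2crit) {
                    // store as (spi particle, spj particle)
                    CandPair cp;
                    if (qsp == B.spi) { cp.a = i; cp.b = j; }
                    else { cp.a = j; cp.b = i; }
                    cp.ch = (int)c;
                    cand.push_back(cp);
                  }
                }
              }
        }
      }
      // uniformly random visiting order (as-if-random-order pair contract)
      for (int i = (int)cand.size() - 1; i > 0; --i) {
        const int j = (int)(rng.runif() * (i + 1));
        std::swap(cand[i], cand[j]);
      }
      for (const CandPair &cp : cand) {
        const BiCh &B = bis[cp.ch];
        const bool static_partner = cp.b < 0;
        if (used[cp.a] || (!static_partner && used[cp.b])) continue;
        if (rng.runif() >= B.P) continue;
        used[cp.a] = 1;
        if (!static_partner) used[cp.b] = 1;
        ev[bi_id[cp.ch]] += 1.0;
        // consumed educt slots, first educt first; a static partner is
        // catalytic by construction and is never a slot
        int slots[2]; int nslots = 0;
        if (static_partner) {
          const bool mobile_is_i = (B.stat == 2);
          if ((mobile_is_i && !B.cati) || (!mobile_is_i && !B.catj))
            slots[nslots++] = cp.a;
        } else {
          if (!B.cati) slots[nslots++] = cp.a;
          if (!B.catj) slots[nslots++] = cp.b;
        }
        size_t k = 0;
        for (; k < B.prods.size() && (int)k < nslots; ++k)
          sp[slots[k]] = B.prods[k];
        for (int s = (int)k; s < nslots; ++s) dead[slots[s]] = 1;
        for (; k < B.prods.size(); ++k) {
          // extra products appear at the first (or mobile) educt's position
          px.push_back(px[cp.a]); py.push_back(py[cp.a]); pz.push_back(pz[cp.a]);
          sp.push_back(B.prods[k]);
          bound.push_back(0);
          used.push_back(1); dead.push_back(0);
          ++n;
        }
      }
    }

    // --- 4. unimolecular -------------------------------------------------
    for (size_t c = 0; c < unis.size(); ++c) {
      const UniCh &U = unis[c];
      if (U.p <= 0.0) continue;
      for (int i = 0; i < n_pre; ++i) {
        if (sp[i] != U.sp || used[i] || dead[i]) continue;
        if (rng.runif() >= U.p) continue;
        used[i] = 1;
        ev[uni_id[c]] += 1.0;
        if (U.prods.empty()) {
          dead[i] = 1;
        } else {
          sp[i] = U.prods[0];
          for (size_t k = 1; k < U.prods.size(); ++k) {
            px.push_back(px[i]); py.push_back(py[i]); pz.push_back(pz[i]);
            sp.push_back(U.prods[k]);
            bound.push_back(0);
            used.push_back(1); dead.push_back(0);
            ++n;
          }
        }
      }
    }

    // --- 5. zero-order creation -----------------------------------------
    for (size_t c = 0; c < zeros.size(); ++c) {
      const ZeroCh &Z = zeros[c];
      const int k = rng.rpois(Z.lam);
      for (int m = 0; m < k; ++m) {
        double p[3];
        place_accessible(Z.sp, Z.region, Z.shell, p);
        px.push_back(p[0]); py.push_back(p[1]); pz.push_back(p[2]);
        sp.push_back(Z.sp);
        bound.push_back(0);
        used.push_back(1); dead.push_back(0);
        ++n;
        ev[zero_id[c]] += 1.0;
      }
    }

    // --- 6. membrane influx ----------------------------------------------
    for (size_t c = 0; c < fluxes.size(); ++c) {
      const FluxCh &F = fluxes[c];
      const int k = rng.rpois(F.lam);
      for (int m = 0; m < k; ++m) {
        double p[3];
        place_accessible(F.sp, 1, F.shell, p);
        px.push_back(p[0]); py.push_back(p[1]); pz.push_back(p[2]);
        sp.push_back(F.sp);
        bound.push_back(0);
        used.push_back(1); dead.push_back(0);
        ++n;
        ev[flux_id[c]] += 1.0;
      }
    }

    // --- 7. membrane export (capture layer, probability 1) ---------------
    for (size_t c = 0; c < exps.size(); ++c) {
      const ExpCh &E = exps[c];
      for (int i = 0; i < n; ++i) {
        if (sp[i] != E.sp || dead[i]) continue;
        const double d =
            std::sqrt(px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i]);
        if (G.cellR - d - radius[E.sp] < E.layer) {
          dead[i] = 1;
          ev[exp_id[c]] += 1.0;
        }
      }
    }

    // --- compaction -------------------------------------------------------
    {
      int i = n_record;  // recorded particles are never removed (validated in R)
      while (i < n) {
        if (dead[i]) {
          const int last = n - 1;
          px[i] = px[last]; py[i] = py[last]; pz[i] = pz[last];
          sp[i] = sp[last];
          bound[i] = bound[last];
          dead[i] = dead[last];
          used[i] = used[last];
          --n;
        } else {
          ++i;
        }
      }
      px.resize(n); py.resize(n); pz.resize(n);
      sp.resize(n); bound.resize(n);
      used.resize(n); dead.resize(n);
    }

    // --- observation ------------------------------------------------------
    if (obs_every > 0 && step % obs_every == 0 && iobs < n_obs) {
      observe(iobs, step * dt);
      ++iobs;
    }
    if (n_record > 0 && record_every > 0 && step % record_every == 0 &&
        iframe < n_frames) {
      snapshot(iframe);
      ++iframe;
    }
    if ((step & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_pos(n, 3);
  IntegerVector final_sp(n);
  LogicalVector final_bd(n);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = px[i]; final_pos(i, 1) = py[i]; final_pos(i, 2) = pz[i];
    final_sp[i] = sp[i];
    final_bd[i] = bound[i] != 0;
  }

  List out = List::create(
      _["times"] = times, _["counts"] = counts, _["bound"] = boundcounts,
      _["events"] = events, _["final_pos"] = final_pos,
      _["final_species"] = final_sp, _["final_bound"] = final_bd);
  if (n_record > 0) {
    positions.attr("dim") =
        IntegerVector::create(n_record, 3, (int)n_frames);
    out["positions"] = positions;
  }
  return out;
}

// Rejection-sample points accessible to a probe, uniform over the accessible
// part of the ball (region = 0) or of a membrane-adjacent shell (region = 1).
// [[Rcpp::export]]
NumericMatrix cpp_sample_accessible(SEXP geom_ptr, int n, double probe,
                                    int region, double shell_thickness,
                                    double seed, int max_tries = 100000) {
  XPtr<Geom> g(geom_ptr);
  RNG rng((uint64_t)seed);
  NumericMatrix out(n, 3);
  const double r0 = region == 1 ? std::max(g->cellR - shell_thickness, 0.0) : 0.0;
  double p[3];
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      if (region == 1) rng.shell(r0, g->cellR, p);
      else rng.ball(g->cellR, p);
      if (g->accessible(p[0], p[1], p[2], probe)) {
        out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
        placed = true;
        break;
      }
    }
    if (!placed) stop("accessible placement sampling saturated");
  }
  return out;
}
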