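// Core DPD engine: soft pairwise forces (conservative + Groot-Warren
// thermostat pair), harmonic bonds, modified velocity-Verlet integration,
// linked-cell neighbour search under cubic periodic boundaries.
//
// All per-pair randomness is counter-based: the random variate for pair
// (i, j) at a given step is a pure hash of (seed, step, i, j), so forces are
// independent of pair enumeration order and bit-reproducible across the
// brute-force and cell-list paths.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // uniform on (0, 1), 53-bit mantissa
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Unit-variance symmetric variate for pair (i < j) at a step.
// uniform on [-sqrt(3), sqrt(3)] by default; Gaussian via Box-Muller.
static inline double pair_theta(uint64_t seed, uint64_t step,
                                int i, int j, bool gaussian) {
  uint64_t a = splitmix64(seed ^ (0x9E3779B97F4A7C15ULL * (step + 1)));
  uint64_t h = splitmix64(a ^ (((uint64_t)(uint32_t)i << 32) |
                               (uint64_t)(uint32_t)j));
  if (!gaussian)
    return 1.7320508075688772935 * (2.0 * u01(h) - 1.0);
  uint64_t h2 = splitmix64(h);
  return std::sqrt(-2.0 * std::log(u01(h))) *
         std::cos(6.283185307179586477 * u01(h2));
}

struct Params {
  double a[2][2];   // species: 0 = polymer, 1 = solvent
  double rc, rc2;
  double k, l0;
  double gamma, sigma, dt, inv_sqrt_dt;
  bool gaussian;
  bool f_cons, f_diss, f_rand;
};

struct System {
  int n;
  std::vector<double> x, y, z;     // true (unwrapped) coordinates
  std::vector<double> wx, wy, wz;  // wrapped copies for the periodic
                                   // non-bonded interactions
  std::vector<double> vx, vy, vz;
  std::vector<int> sp;
  double box;
  void refresh_wrapped() {
    for (int i = 0; i < n; ++i) {
      wx[i] = x[i] - box * std::floor(x[i] / box);
      wy[i] = y[i] - box * std::floor(y[i] / box);
      wz[i] = z[i] - box * std::floor(z[i] / box);
    }
  }
};

static inline void pair_interact(System &s, const Params &p,
                                 std::vector<double> &fx,
                                 std::vector<double> &fy,
                                 std::vector<double> &fz,
                                 int i, int j,
                                 uint64_t seed, uint64_t step) {
  double hb = 0.5 * s.box;
  double dx = s.wx[i] - s.wx[j];
  if (dx > hb) dx -= s.box; else if (dx < -hb) dx += s.box;
  double dy = s.wy[i] - s.wy[j];
  if (dy > hb) dy -= s.box; else if (dy < -hb) dy += s.box;
  double dz = s.wz[i] - s.wz[j];
  if (dz > hb) dz -= s.box; else if (dz < -hb) dz += s.box;
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= p.rc2 || r2 < 1e-24) return;
  double r = std::sqrt(r2);
  double invr = 1.0 / r;
  double w = 1.0 - r / p.rc;
  double ex = dx * invr, ey = dy * invr, ez = dz * invr;
  double f = 0.0;
  if (p.f_cons)
    f += p.a[s.sp[i]][s.sp[j]] * w;
  if (p.f_diss) {
    double vdot = ex * (s.vx[i] - s.vx[j]) + ey * (s.vy[i] - s.vy[j]) +
                  ez * (s.vz[i] - s.vz[j]);
    f -= p.gamma * w * w * vdot;
  }
  if (p.f_rand)
    f += p.sigma * w * pair_theta(seed, step, i, j, p.gaussian) *
         p.inv_sqrt_dt;
  fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
  fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
}

// Linked-cell neighbour search; falls back to the O(N^2) loop when the box
// holds fewer than 3 cells per edge (periodic stencil needs >= 3).
struct CellList {
  int nc = -1;
  double cell;
  std::vector<int> head, nxt, nbr;  // nbr: 13 half-stencil cells per cell
  void build(const System &s, double rc) {
    int newnc = (int)std::floor(s.box / rc);
    if (newnc < 3) { nc = 0; return; }
    if (newnc != nc) { nc = newnc; build_stencil(); }
    cell = s.box / nc;
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(s.n, -1);
    for (int i = 0; i < s.n; ++i) {
      int cx = (int)(s.wx[i] / cell); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
      int cy = (int)(s.wy[i] / cell); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
      int cz = (int)(s.wz[i] / cell); if (cz >= nc) cz = nc - 1; if (cz < 0) cz = 0;
      int c = (cx * nc + cy) * nc + cz;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  void build_stencil();
};

// half stencil: self + 13 neighbours, so each unordered cell pair is
// visited exactly once
static const int STENCIL[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

void CellList::build_stencil() {
  nbr.assign((size_t)nc * nc * nc * 13, 0);
  for (int cx = 0; cx < nc; ++cx)
    for (int cy = 0; cy < nc; ++cy)
      for (int cz = 0; cz < nc; ++cz) {
        int c = (cx * nc + cy) * nc + cz;
        for (int k = 0; k < 13; ++k) {
          int nx = (cx + STENCIL[k][0] + nc) % nc;
          int ny = (cy + STENCIL[k][1] + nc) % nc;
          int nz = (cz + STENCIL[k][2] + nc) % nc;
          nbr[(size_t)c * 13 + k] = (nx * nc + ny) * nc + nz;
        }
      }
}

static void nonbonded_forces(System &s, const Params &p, CellList &cl,
                             std::vector<double> &fx, std::vector<double> &fy,
                             std::vector<double> &fz,
                             uint64_t seed, uint64_t step, bool brute) {
  if (brute || s.box <= 0.0) {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j)
        pair_interact(s, p, fx, fy, fz, i, j, seed, step);
    return;
  }
  cl.build(s, p.rc);
  if (cl.nc == 0) {
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j)
        pair_interact(s, p, fx, fy, fz, i, j, seed, step);
    return;
  }
  int ncell = cl.nc * cl.nc * cl.nc;
  for (int c = 0; c < ncell; ++c) {
    // within-cell pairs
    for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
      for (int j = cl.nxt[i]; j != -1; j = cl.nxt[j]) {
        int a = std::min(i, j), b = std::max(i, j);
        pair_interact(s, p, fx, fy, fz, a, b, seed, step);
      }
    // neighbour cells (precomputed half stencil)
    const int *nb = &cl.nbr[(size_t)c * 13];
    for (int k = 0; k < 13; ++k) {
      for (int i = cl.head[c]; i != -1; i = cl.nxt[i])
        for (int j = cl.head[nb[k]]; j != -1; j = cl.nxt[j]) {
          int a = std::min(i, j), b = std::max(i, j);
          pair_interact(s, p, fx, fy, fz, a, b, seed, step);
        }
    }
  }
}

static void bond_forces(System &s, const Params &p,
                        const std::vector<int> &bi, const std::vector<int> &bj,
                        std::vector<double> &fx, std::vector<double> &fy,
                        std::vector<double> &fz) {
  // bonds act on true-space displacements: a bond can never be satisfied
  // "through" a periodic image
  for (size_t b = 0; b < bi.size(); ++b) {
    int i = bi[b], j = bj[b];
    double dx = s.x[i] - s.x[j];
    double dy = s.y[i] - s.y[j];
    double dz = s.z[i] - s.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double f = -p.k * (r - p.l0) / r;
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
}

static System sys_from_r(const NumericMatrix &pos, const NumericMatrix &vel,
                         double box, const IntegerVector &species) {
  int n = pos.nrow();
  System s;
  s.n = n; s.box = box;
  s.x.resize(n); s.y.resize(n); s.z.resize(n);
  s.wx.resize(n); s.wy.resize(n); s.wz.resize(n);
  s.vx.resize(n); s.vy.resize(n); s.vz.resize(n);
  s.sp.resize(n);
  for (int i = 0; i < n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
        !std::isfinite(s.z[i]))
      stop("non-finite coordinate for bead %d", i + 1);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.sp[i] = species[i];
    if (s.sp[i] < 0 || s.sp[i] > 1) stop("species must be 0 or 1");
  }
  s.refresh_wrapped();
  return s;
}

static Params params_from_r(const List &par, bool cons, bool diss, bool rnd) {
  Params p;
  double app = as<double>(par["aPP"]), aps = as<double>(par["aPS"]),
         ass = as<double>(par["aSS"]);
  p.a[0][0] = app; p.a[0][1] = aps; p.a[1][0] = aps; p.a[1][1] = ass;
  p.rc = as<double>(par["rC"]); p.rc2 = p.rc * p.rc;
  p.k = as<double>(par["bondK"]); p.l0 = as<double>(par["bondL0"]);
  p.gamma = as<double>(par["gamma"]);
  double kT = as<double>(par["kT"]);
  p.sigma = std::sqrt(2.0 * p.gamma * kT);
  p.dt = as<double>(par["dt"]);
  p.inv_sqrt_dt = 1.0 / std::sqrt(p.dt);
  p.gaussian = as<bool>(par["gaussianTheta"]);
  p.f_cons = cons; p.f_diss = diss; p.f_rand = rnd;
  return p;
}

static double median_of(std::vector<double> v) {
  if (v.empty()) return NA_REAL;
  size_t m = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  double hi = v[m];
  if (v.size() % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + m - 1, v.end());
  return 0.5 * (hi + v[m - 1]);
}

static double bond_median(const System &s, const std::vector<int> &bi,
                          const std::vector<int> &bj) {
  std::vector<double> len(bi.size());
  for (size_t b = 0; b < bi.size(); ++b) {
    double dx = s.x[bi[b]] - s.x[bj[b]];
    double dy = s.y[bi[b]] - s.y[bj[b]];
    double dz = s.z[bi[b]] - s.z[bj[b]];
    len[b] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return median_of(len);
}

// mean radius of gyration of polymer chains (true-space coordinates)
static double mean_chain_rg(const System &s, const IntegerVector &chain_starts,
                            const IntegerVector &chain_ends) {
  int nch = chain_starts.size();
  if (nch == 0) return NA_REAL;
  double acc = 0.0;
  for (int c = 0; c < nch; ++c) {
    int a = chain_starts[c], b = chain_ends[c];  // 0-based inclusive
    int len = b - a + 1;
    double mx = 0, my = 0, mz = 0;
    for (int i = a; i <= b; ++i) { mx += s.x[i]; my += s.y[i]; mz += s.z[i]; }
    mx /= len; my /= len; mz /= len;
    double rg2 = 0;
    for (int i = a; i <= b; ++i)
      rg2 += (s.x[i] - mx) * (s.x[i] - mx) + (s.y[i] - my) * (s.y[i] - my) +
             (s.z[i] - mz) * (s.z[i] - mz);
    acc += std::sqrt(rg2 / len);
  }
  return acc / nch;
}

// [[Rcpp::export]]
NumericMatrix cpp_dpd_forces(NumericMatrix pos, NumericMatrix vel, double box,
                             IntegerVector species, IntegerMatrix bonds,
                             List par, int step, double seed,
                             bool conservative, bool dissipative, bool random,
                             bool bonded, bool brute) {
  System s = sys_from_r(pos, vel, box, species);
  Params p = params_from_r(par, conservative, dissipative, random);
  std::vector<double> fx(s.n, 0.0), fy(s.n, 0.0), fz(s.n, 0.0);
  CellList cl;
  if (conservative || dissipative || random)
    nonbonded_forces(s, p, cl, fx, fy, fz, (uint64_t)seed, (uint64_t)step,
                     brute);
  if (bonded && bonds.nrow() > 0) {
    std::vector<int> bi(bonds.nrow()), bj(bonds.nrow());
    for (int b = 0; b < bonds.nrow(); ++b) { bi[b] = bonds(b, 0); bj[b] = bonds(b, 1); }
    bond_forces(s, p, bi, bj, fx, fy, fz);
  }
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dpd_run(NumericMatrix pos, NumericMatrix vel, double box,
                 IntegerVector species, IntegerMatrix bonds,
                 IntegerVector bond_type, List par,
                 int n_steps, double seed,
                 IntegerVector chain_starts, IntegerVector chain_ends,
                 int monitor_every, int converge_mode, double tol,
                 int min_steps) {
  System s = sys_from_r(pos, vel, box, species);
  Params p = params_from_r(par, true, true, true);
  int nb = bonds.nrow();
  std::vector<int> bi(nb), bj(nb);
  std::vector<int> bbi, bbj, rbi, rbj;   // backbone / restraint split
  for (int b = 0; b < nb; ++b) {
    bi[b] = bonds(b, 0); bj[b] = bonds(b, 1);
    if (bond_type[b] == 0) { bbi.push_back(bi[b]); bbj.push_back(bj[b]); }
    else { rbi.push_back(bi[b]); rbj.push_back(bj[b]); }
  }
  uint64_t sd = (uint64_t)seed;
  CellList cl;
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  std::vector<double> nfx(s.n), nfy(s.n), nfz(s.n);

  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  nonbonded_forces(s, p, cl, fx, fy, fz, sd, 0, false);
  bond_forces(s, p, bi, bj, fx, fy, fz);

  double half_box = (box > 0) ? 0.5 * box : R_PosInf;
  double lambda = as<double>(par["lambdaVV"]);
  double dt = p.dt, dt2h = 0.5 * dt * dt;

  std::vector<double> mon_step, mon_temp, mon_rg, mon_bb, mon_re;
  std::vector<double> conv_hist;
  bool converged = (converge_mode == 0);
  int steps_run = 0;

  // which statistic drives convergence: restraint median if requested and
  // present, else backbone median, else chain Rg
  bool use_restraint = (converge_mode == 2 && !rbi.empty());
  bool use_backbone = (converge_mode == 2 && rbi.empty() && !bbi.empty());

  auto record = [&](int step) {
    double ke = 0.0;
    for (int i = 0; i < s.n; ++i)
      ke += s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i];
    double temp = ke / (3.0 * s.n);
    double rg = mean_chain_rg(s, chain_starts, chain_ends);
    double mbb = bond_median(s, bbi, bbj);
    double mre = bond_median(s, rbi, rbj);
    mon_step.push_back(step); mon_temp.push_back(temp);
    mon_rg.push_back(rg); mon_bb.push_back(mbb); mon_re.push_back(mre);
    if (converge_mode == 1) conv_hist.push_back(rg);
    else if (use_restraint) conv_hist.push_back(mre);
    else if (use_backbone) conv_hist.push_back(mbb);
    else if (converge_mode != 0) conv_hist.push_back(rg);
  };

  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < s.n; ++i) {
      double ddx = dt * s.vx[i] + dt2h * fx[i];
      double ddy = dt * s.vy[i] + dt2h * fy[i];
      double ddz = dt * s.vz[i] + dt2h * fz[i];
      if (std::fabs(ddx) > half_box || std::fabs(ddy) > half_box ||
          std::fabs(ddz) > half_box)
        stop("unstable integration: bead %d moved more than box/2 in one step",
             i + 1);
      s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
      // velocity prediction for the dissipative force
      s.vx[i] += lambda * dt * fx[i];
      s.vy[i] += lambda * dt * fy[i];
      s.vz[i] += lambda * dt * fz[i];
    }
    s.refresh_wrapped();
    std::fill(nfx.begin(), nfx.end(), 0.0);
    std::fill(nfy.begin(), nfy.end(), 0.0);
    std::fill(nfz.begin(), nfz.end(), 0.0);
    nonbonded_forces(s, p, cl, nfx, nfy, nfz, sd, (uint64_t)step, false);
    bond_forces(s, p, bi, bj, nfx, nfy, nfz);
    for (int i = 0; i < s.n; ++i) {
      // undo prediction, then trapezoidal velocity update
      s.vx[i] += (0.5 - lambda) * dt * fx[i] + 0.5 * dt * nfx[i];
      s.vy[i] += (0.5 - lambda) * dt * fy[i] + 0.5 * dt * nfy[i];
      s.vz[i] += (0.5 - lambda) * dt * fz[i] + 0.5 * dt * nfz[i];
      fx[i] = nfx[i]; fy[i] = nfy[i]; fz[i] = nfz[i];
    }
    steps_run = step;
    if (monitor_every > 0 && (step % monitor_every == 0 || step == n_steps)) {
      record(step);
      if (converge_mode != 0 && step >= min_steps) {
        int m = conv_hist.size();
        int w = std::max(6, (int)std::ceil(0.2 * m));
        if (m >= w) {
          // drift of the monitored median over the trailing window:
          // median of the first half vs median of the second half
          std::vector<double> win(conv_hist.end() - w, conv_hist.end());
          std::vector<double> h1(win.begin(), win.begin() + w / 2);
          std::vector<double> h2(win.begin() + w / 2, win.end());
          double m1 = median_of(h1), m2 = median_of(h2);
          double mid = median_of(win);
          if (std::fabs(mid) > 1e-12 &&
              std::fabs(m2 - m1) / std::fabs(mid) < tol) {
            converged = true;
            break;
          }
        }
      }
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix opos(s.n, 3), ovel(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    opos(i, 0) = s.x[i]; opos(i, 1) = s.y[i]; opos(i, 2) = s.z[i];
    ovel(i, 0) = s.vx[i]; ovel(i, 1) = s.vy[i]; ovel(i, 2) = s.vz[i];
  }
  int m = mon_step.size();
  NumericMatrix mon(m, 5);
  for (int r = 0; r < m; ++r) {
    mon(r, 0) = mon_step[r]; mon(r, 1) = mon_temp[r]; mon(r, 2) = mon_rg[r];
    mon(r, 3) = mon_bb[r]; mon(r, 4) = mon_re[r];
  }
  colnames(mon) = CharacterVector::create("step", "temperature", "rg",
                                          "medianBackbone", "medianRestraint");
  return List::create(_["positions"] = opos, _["velocities"] = ovel,
                      _["stepsRun"] = steps_run, _["converged"] = converged,
                      _["monitor"] = mon);
}

// all non-bonded pairs (i < j, 0-based) within r_contact; plain Euclidean
// distances, no periodic wrapping (conformations are unwrapped)
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, double r_contact) {
  int n = pos.nrow();
  double r2max = r_contact * r_contact;
  std::vector<int> vi, vj;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= r2max) { vi.push_back(i); vj.push_back(j); }
    }
  IntegerMatrix out(vi.size(), 2);
  for (size_t k = 0; k < vi.size(); ++k) {
    out(k, 0) = vi[k]; out(k, 1) = vj[k];
  }
  return out;
}
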