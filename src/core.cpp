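// Brownian-dynamics core for a self-avoiding bead-spring chromatin chain
// with optional condensin loop-capture bonds.
//
// Reduced units throughout: bead radius a = 1, kT = 1, friction gamma = 1
// unless the caller says otherwise. Positions are N x 3 row-major matrices.
//
// RNG: counter-free xoshiro256++ stream seeded by splitmix64 from a single
// integer, one stream per call, so a run is bit-reproducible from its seed
// and independent of R's global RNG.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG
// ---------------------------------------------------------------------------

namespace {

struct Xoshiro {
  uint64_t s[4];
  bool have_cached_normal = false;
  double cached_normal = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
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

  // uniform in (0, 1)
  double uniform() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal, Marsaglia polar method with caching
  double normal() {
    if (have_cached_normal) {
      have_cached_normal = false;
      return cached_normal;
    }
    double u, v, s2;
    do {
      u = 2.0 * uniform() - 1.0;
      v = 2.0 * uniform() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached_normal = v * f;
    have_cached_normal = true;
    return u * f;
  }

  // integer in [0, n)
  int below(int n) { return (int)(uniform() * n) % n; }
};

// ---------------------------------------------------------------------------
// Dense cell grid over the conformation's bounding box, cell edge = the
// interaction cutoff. Rebuilt O(N) every step; an epoch stamp makes clearing
// lazy so rebuild cost does not scale with the number of cells.
// ---------------------------------------------------------------------------

struct CellGrid {
  double edge = 1.0;
  double x0 = 0, y0 = 0, z0 = 0;
  int nx = 0, ny = 0, nz = 0;
  int epoch = 0;
  std::vector<int> head;   // per cell, valid only when stamp == epoch
  std::vector<int> stamp;
  std::vector<int> nxt;    // linked list over beads
  std::vector<int> occupied;  // linear indices of non-empty cells

  int cell_index(double xi, double yi, double zi) const {
    const int ix = (int)std::floor((xi - x0) / edge);
    const int iy = (int)std::floor((yi - y0) / edge);
    const int iz = (int)std::floor((zi - z0) / edge);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return -1;
    return (ix * ny + iy) * nz + iz;
  }

  // build from a subset of beads (idx); queries may fall outside the box
  // and then simply see no neighbours
  void build_subset(const std::vector<double> &x, const std::vector<double> &y,
                    const std::vector<double> &z, const std::vector<int> &idx,
                    double cell_edge) {
    edge = cell_edge;
    if (idx.empty()) {
      nx = ny = nz = 0;
      return;
    }
    double xmin = x[idx[0]], xmax = xmin, ymin = y[idx[0]], ymax = ymin,
           zmin = z[idx[0]], zmax = zmin;
    for (int i : idx) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = (int)((xmax - xmin) / edge) + 1;
    ny = (int)((ymax - ymin) / edge) + 1;
    nz = (int)((zmax - zmin) / edge) + 1;
    const size_t ncells = (size_t)nx * ny * nz;
    if (head.size() < ncells) {
      head.resize(ncells);
      stamp.resize(ncells, 0);
    }
    if (nxt.size() < x.size()) nxt.resize(x.size());
    ++epoch;
    occupied.clear();
    for (int i : idx) {
      const int c = cell_index(x[i], y[i], z[i]);
      if (stamp[c] != epoch) {
        stamp[c] = epoch;
        head[c] = -1;
        occupied.push_back(c);
      }
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, int n, double cell_edge) {
    static thread_local std::vector<int> all;
    all.resize(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    build_subset(x, y, z, all, cell_edge);
  }

  int cell_head(int ix, int iy, int iz) const {
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      return -1;
    const int c = (ix * ny + iy) * nz + iz;
    return stamp[c] == epoch ? head[c] : -1;
  }
};

// ---------------------------------------------------------------------------
// Forces
// ---------------------------------------------------------------------------

inline void add_spring_forces(const std::vector<double> &x,
                              const std::vector<double> &y,
                              const std::vector<double> &z, int n,
                              double k_spr, double l0, std::vector<double> &fx,
                              std::vector<double> &fy,
                              std::vector<double> &fz) {
  for (int i = 0; i + 1 < n; ++i) {
    const double dx = x[i + 1] - x[i];
    const double dy = y[i + 1] - y[i];
    const double dz = z[i + 1] - z[i];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ux, uy, uz;
    if (d > 0.0) {
      ux = dx / d;
      uy = dy / d;
      uz = dz / d;
    } else {
      ux = 1.0;  // coincident beads: deterministic +x fallback
      uy = 0.0;
      uz = 0.0;
    }
    const double f = k_spr * (d - l0);  // >0 pulls i towards i+1
    fx[i] += f * ux;
    fy[i] += f * uy;
    fz[i] += f * uz;
    fx[i + 1] -= f * ux;
    fy[i + 1] -= f * uy;
    fz[i + 1] -= f * uz;
  }
}

// soft harmonic overlap: |F| = k_rep * (2a - d) for d < 2a.
// Half-neighbourhood pair iteration: each pair visited exactly once.
static const int kHalfOffsets[13][3] = {
    {1, 0, 0},  {-1, 1, 0}, {0, 1, 0},  {1, 1, 0},  {-1, -1, 1},
    {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},  {1, 0, 1},
    {-1, 1, 1}, {0, 1, 1},  {1, 1, 1}};

inline void add_repulsion_forces(const std::vector<double> &x,
                                 const std::vector<double> &y,
                                 const std::vector<double> &z, int n,
                                 double k_rep, double a, CellGrid &grid,
                                 std::vector<double> &fx,
                                 std::vector<double> &fy,
                                 std::vector<double> &fz) {
  const double cutoff = 2.0 * a;
  grid.build(x, y, z, n, cutoff);
  const double cut2 = cutoff * cutoff;
  auto pair_force = [&](int i, int j) {
    const double dx = x[i] - x[j];
    const double dy = y[i] - y[j];
    const double dz = z[i] - z[j];
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= cut2) return;
    const double d = std::sqrt(d2);
    if (d > 0.0) {
      const double f = k_rep * (cutoff - d) / d;
      fx[i] += f * dx;
      fy[i] += f * dy;
      fz[i] += f * dz;
      fx[j] -= f * dx;
      fy[j] -= f * dy;
      fz[j] -= f * dz;
    } else {
      // exactly coincident pair: deterministic +x fallback direction,
      // higher index pushed +x, lower index -x
      const int hi = i > j ? i : j, lo = i > j ? j : i;
      fx[hi] += k_rep * cutoff;
      fx[lo] -= k_rep * cutoff;
    }
  };
  for (int i = 0; i < n; ++i) {
    const int ix = (int)std::floor((x[i] - grid.x0) / cutoff);
    const int iy = (int)std::floor((y[i] - grid.y0) / cutoff);
    const int iz = (int)std::floor((z[i] - grid.z0) / cutoff);
    // own cell, pairs once via index order
    for (int j = grid.cell_head(ix, iy, iz); j != -1; j = grid.nxt[j])
      if (j < i) pair_force(i, j);
    for (int k = 0; k < 13; ++k)
      for (int j = grid.cell_head(ix + kHalfOffsets[k][0],
                                  iy + kHalfOffsets[k][1],
                                  iz + kHalfOffsets[k][2]);
           j != -1; j = grid.nxt[j])
        pair_force(i, j);
  }
}

inline void add_bond_forces(const std::vector<double> &x,
                            const std::vector<double> &y,
                            const std::vector<double> &z,
                            const std::vector<int> &bond_i,
                            const std::vector<int> &bond_j, double k_bond,
                            double rest, std::vector<double> &fx,
                            std::vector<double> &fy, std::vector<double> &fz) {
  for (size_t b = 0; b < bond_i.size(); ++b) {
    const int i = bond_i[b], j = bond_j[b];
    const double dx = x[j] - x[i];
    const double dy = y[j] - y[i];
    const double dz = z[j] - z[i];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ux = 1.0, uy = 0.0, uz = 0.0;
    if (d > 0.0) {
      ux = dx / d;
      uy = dy / d;
      uz = dz / d;
    }
    const double f = k_bond * (d - rest);
    fx[i] += f * ux;
    fy[i] += f * uy;
    fz[i] += f * uz;
    fx[j] -= f * ux;
    fy[j] -= f * uy;
    fz[j] -= f * uz;
  }
}

// ---------------------------------------------------------------------------
// Closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric method),
// descending order.
// ---------------------------------------------------------------------------

inline void sym3_eigenvalues(double a11, double a22, double a33, double a12,
                             double a13, double a23, double out[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    out[0] = a11;
    out[1] = a22;
    out[2] = a33;
  } else {
    const double q = (a11 + a22 + a33) / 3.0;
    const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                      (a33 - q) * (a33 - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    out[0] = q + 2.0 * p * std::cos(phi);
    out[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    out[1] = 3.0 * q - out[0] - out[2];
  }
  // sort descending (trig method is ordered, the p1 == 0 branch may not be)
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (out[j] > out[i]) std::swap(out[i], out[j]);
}

// covariance-eigenvalue shape: L = 2 sqrt(l1), w = 2 sqrt(l2), d = 2 sqrt(l3)
inline void shape_of(const std::vector<double> &x, const std::vector<double> &y,
                     const std::vector<double> &z, int n, double out[3]) {
  double mx = 0, my = 0, mz = 0;
  for (int i = 0; i < n; ++i) {
    mx += x[i];
    my += y[i];
    mz += z[i];
  }
  mx /= n;
  my /= n;
  mz /= n;
  double cxx = 0, cyy = 0, czz = 0, cxy = 0, cxz = 0, cyz = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my, dz = z[i] - mz;
    cxx += dx * dx;
    cyy += dy * dy;
    czz += dz * dz;
    cxy += dx * dy;
    cxz += dx * dz;
    cyz += dy * dz;
  }
  // population normalisation: shape of this point cloud, not an estimator
  cxx /= n;
  cyy /= n;
  czz /= n;
  cxy /= n;
  cxz /= n;
  cyz /= n;
  double ev[3];
  sym3_eigenvalues(cxx, cyy, czz, cxy, cxz, cyz, ev);
  for (int k = 0; k < 3; ++k) out[k] = 2.0 * std::sqrt(std::max(ev[k], 0.0));
}

// ---------------------------------------------------------------------------
// Loop-capture bond update: release each bond w.p. p_release, then bond
// eligible free site pairs (distance < d_cutoff) in uniformly shuffled order,
// each w.p. p_capture, never exceeding one bond per site.
// partner[s] = site-array index of bonded partner, or -1.
// ---------------------------------------------------------------------------

inline void update_bonds_inplace(const std::vector<double> &x,
                                 const std::vector<double> &y,
                                 const std::vector<double> &z,
                                 const std::vector<int> &sites,
                                 std::vector<int> &partner, double d_cutoff,
                                 double p_capture, double p_release,
                                 int min_sep, Xoshiro &rng) {
  const int ns = (int)sites.size();
  // release
  for (int s = 0; s < ns; ++s) {
    if (partner[s] > s) {
      if (rng.uniform() < p_release) {
        partner[partner[s]] = -1;
        partner[s] = -1;
      }
    }
  }
  // eligible free pairs
  const double cut2 = d_cutoff * d_cutoff;
  std::vector<int> pi, pj;
  for (int s = 0; s < ns; ++s) {
    if (partner[s] != -1) continue;
    const int bi = sites[s];
    for (int t = s + 1; t < ns; ++t) {
      if (partner[t] != -1) continue;
      if (t - s < min_sep) continue;  // condensin contacts are long-range
      const int bj = sites[t];
      const double dx = x[bi] - x[bj];
      const double dy = y[bi] - y[bj];
      const double dz = z[bi] - z[bj];
      if (dx * dx + dy * dy + dz * dz < cut2) {
        pi.push_back(s);
        pj.push_back(t);
      }
    }
  }
  // Fisher-Yates shuffle of the eligible pair list
  const int np = (int)pi.size();
  for (int k = np - 1; k > 0; --k) {
    const int m = rng.below(k + 1);
    std::swap(pi[k], pi[m]);
    std::swap(pj[k], pj[m]);
  }
  for (int k = 0; k < np; ++k) {
    const int s = pi[k], t = pj[k];
    if (partner[s] != -1 || partner[t] != -1) continue;
    if (rng.uniform() < p_capture) {
      partner[s] = t;
      partner[t] = s;
    }
  }
}

void unpack_positions(const NumericMatrix &pos, std::vector<double> &x,
                      std::vector<double> &y, std::vector<double> &z) {
  const int n = pos.nrow();
  x.resize(n);
  y.resize(n);
  z.resize(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
  }
}

NumericMatrix pack_positions(const std::vector<double> &x,
                             const std::vector<double> &y,
                             const std::vector<double> &z) {
  const int n = (int)x.size();
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i];
    pos(i, 1) = y[i];
    pos(i, 2) = z[i];
  }
  return pos;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported force kernels (thin wrappers for the R-level operations)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_spring_force(NumericMatrix pos, double k_spr, double l0) {
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  const int n = pos.nrow();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  add_spring_forces(x, y, z, n, k_spr, l0, fx, fy, fz);
  return pack_positions(fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix cpp_repulsion_force(NumericMatrix pos, double k_rep, double a) {
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  const int n = pos.nrow();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  CellGrid grid;
  add_repulsion_forces(x, y, z, n, k_rep, a, grid, fx, fy, fz);
  return pack_positions(fx, fy, fz);
}

// bonds: 2-column matrix of 1-based bead indices
// [[Rcpp::export]]
NumericMatrix cpp_condensin_force(NumericMatrix pos, IntegerMatrix bonds,
                                  double k_bond, double rest) {
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  const int n = pos.nrow();
  std::vector<int> bi, bj;
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    if (i < 0 || j < 0 || i >= n || j >= n)
      stop("bond %d references bead index out of range", b + 1);
    bi.push_back(i);
    bj.push_back(j);
  }
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  add_bond_forces(x, y, z, bi, bj, k_bond, rest, fx, fy, fz);
  return pack_positions(fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix cpp_covariance_dims(NumericMatrix pos) {
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  double dims[3];
  shape_of(x, y, z, pos.nrow(), dims);
  NumericMatrix out(1, 3);
  out(0, 0) = dims[0];
  out(0, 1) = dims[1];
  out(0, 2) = dims[2];
  return out;
}

// ---------------------------------------------------------------------------
// Integrator. extra is a constant per-bead force added at every step
// (0 x 0 matrix for none). k_spr = 0 / k_rep = 0 switch those terms off.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_step_brownian(NumericMatrix pos, double k_spr, double l0,
                       double k_rep, double a, double kT, double gamma,
                       double dt, NumericMatrix extra, int n_steps,
                       double seed) {
  const int n = pos.nrow();
  const bool has_extra = extra.nrow() == n;
  if (extra.nrow() != 0 && !has_extra)
    stop("extra forces must be %d x 3 or empty", n);
  if (has_extra)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        if (!R_finite(extra(i, k)))
          stop("non-finite force input at bead %d", i + 1);
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  std::vector<double> fx(n), fy(n), fz(n);
  CellGrid grid;
  Xoshiro rng((uint64_t)seed);
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * (kT / gamma) * dt);
  for (int s = 0; s < n_steps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    if (k_spr != 0.0) add_spring_forces(x, y, z, n, k_spr, l0, fx, fy, fz);
    if (k_rep != 0.0)
      add_repulsion_forces(x, y, z, n, k_rep, a, grid, fx, fy, fz);
    if (has_extra)
      for (int i = 0; i < n; ++i) {
        fx[i] += extra(i, 0);
        fy[i] += extra(i, 1);
        fz[i] += extra(i, 2);
      }
    for (int i = 0; i < n; ++i) {
      x[i] += mob * fx[i] + sig * rng.normal();
      y[i] += mob * fy[i] + sig * rng.normal();
      z[i] += mob * fz[i] + sig * rng.normal();
    }
  }
  return List::create(_["positions"] = pack_positions(x, y, z),
                      _["time"] = (double)n_steps * dt);
}

// ---------------------------------------------------------------------------
// Standalone bond update (1-based site indices; bonds as 2-col matrix of
// site indices, not bead indices)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_update_bonds(NumericMatrix pos, IntegerVector sites,
                               IntegerMatrix bonds, double d_cutoff,
                               double p_capture, double p_release,
                               int min_sep, double seed) {
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  const int ns = sites.size();
  std::vector<int> site0(ns);
  for (int s = 0; s < ns; ++s) site0[s] = sites[s] - 1;
  std::vector<int> partner(ns, -1);
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int s = bonds(b, 0) - 1, t = bonds(b, 1) - 1;
    if (s < 0 || t < 0 || s >= ns || t >= ns || s == t)
      stop("invalid bond row %d", b + 1);
    if (partner[s] != -1 || partner[t] != -1)
      stop("bond set violates one-bond-per-site matching at row %d", b + 1);
    partner[s] = t;
    partner[t] = s;
  }
  Xoshiro rng((uint64_t)seed);
  update_bonds_inplace(x, y, z, site0, partner, d_cutoff, p_capture,
                       p_release, min_sep, rng);
  int nb = 0;
  for (int s = 0; s < ns; ++s)
    if (partner[s] > s) ++nb;
  IntegerMatrix out(nb, 2);
  int r = 0;
  for (int s = 0; s < ns; ++s)
    if (partner[s] > s) {
      out(r, 0) = s + 1;
      out(r, 1) = partner[s] + 1;
      ++r;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Main simulation loop: dynamics steps interleaved with bond updates every
// bond_every steps (when capture = true). Samples shape (and optionally
// frames) every sample_every steps, including the initial state.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, double t0, double k_spr, double l0,
             double k_rep, double a, double kT, double gamma, double dt,
             bool capture, IntegerVector sites, IntegerMatrix bonds0,
             double d_cutoff, double p_capture, double p_release,
             int min_sep, double k_bond, double bond_rest, int bond_every,
             int n_steps, int sample_every, double seed,
             bool store_frames) {
  const int n = pos0.nrow();
  std::vector<double> x, y, z;
  unpack_positions(pos0, x, y, z);
  const int ns = sites.size();
  std::vector<int> site0(ns);
  for (int s = 0; s < ns; ++s) {
    site0[s] = sites[s] - 1;
    if (site0[s] < 0 || site0[s] >= n) stop("site index out of range");
  }
  std::vector<int> partner(ns, -1);
  for (int b = 0; b < bonds0.nrow(); ++b) {
    const int s = bonds0(b, 0) - 1, t = bonds0(b, 1) - 1;
    partner[s] = t;
    partner[t] = s;
  }
  std::vector<int> bond_i, bond_j;
  auto collect_bonds = [&]() {
    bond_i.clear();
    bond_j.clear();
    for (int s = 0; s < ns; ++s)
      if (partner[s] > s) {
        bond_i.push_back(site0[s]);
        bond_j.push_back(site0[partner[s]]);
      }
  };
  collect_bonds();

  const int n_samples = n_steps / sample_every + 1;
  NumericMatrix shapes(n_samples, 6);  // time, L, w, d, r, n_bonds
  NumericVector frames;
  if (store_frames) {
    frames = NumericVector(Dimension(n, 3, n_samples));
  }
  int sample_idx = 0;
  auto take_sample = [&](int step) {
    double dims[3];
    shape_of(x, y, z, n, dims);
    shapes(sample_idx, 0) = t0 + step * dt;
    shapes(sample_idx, 1) = dims[0];
    shapes(sample_idx, 2) = dims[1];
    shapes(sample_idx, 3) = dims[2];
    shapes(sample_idx, 4) = dims[0] > 0 ? dims[1] / dims[0] : NA_REAL;
    shapes(sample_idx, 5) = (double)bond_i.size();
    if (store_frames) {
      for (int i = 0; i < n; ++i) {
        frames[sample_idx * 3 * n + 0 * n + i] = x[i];
        frames[sample_idx * 3 * n + 1 * n + i] = y[i];
        frames[sample_idx * 3 * n + 2 * n + i] = z[i];
      }
    }
    ++sample_idx;
  };
  take_sample(0);

  std::vector<double> fx(n), fy(n), fz(n);
  CellGrid grid;
  Xoshiro rng((uint64_t)seed);
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * (kT / gamma) * dt);
  const double blow = 10.0 * l0;

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    add_spring_forces(x, y, z, n, k_spr, l0, fx, fy, fz);
    add_repulsion_forces(x, y, z, n, k_rep, a, grid, fx, fy, fz);
    if (capture && !bond_i.empty())
      add_bond_forces(x, y, z, bond_i, bond_j, k_bond, bond_rest, fx, fy, fz);
    for (int i = 0; i < n; ++i) {
      x[i] += mob * fx[i] + sig * rng.normal();
      y[i] += mob * fy[i] + sig * rng.normal();
      z[i] += mob * fz[i] + sig * rng.normal();
    }
    if (capture && step % bond_every == 0) {
      update_bonds_inplace(x, y, z, site0, partner, d_cutoff, p_capture,
                           p_release, min_sep, rng);
      collect_bonds();
    }
    if (step % sample_every == 0) {
      // instability check at sampling cadence
      for (int i = 0; i + 1 < n; ++i) {
        const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                     dz = z[i + 1] - z[i];
        if (dx * dx + dy * dy + dz * dz > blow * blow)
          stop("bond %d exceeded 10x rest length at t = %g: timestep too "
               "large, reduce dt",
               i + 1, t0 + step * dt);
      }
      take_sample(step);
      Rcpp::checkUserInterrupt();
    }
  }

  int nb = 0;
  for (int s = 0; s < ns; ++s)
    if (partner[s] > s) ++nb;
  IntegerMatrix bonds_out(nb, 2);
  int r = 0;
  for (int s = 0; s < ns; ++s)
    if (partner[s] > s) {
      bonds_out(r, 0) = s + 1;
      bonds_out(r, 1) = partner[s] + 1;
      ++r;
    }

  List out = List::create(
      _["shapes"] = shapes, _["positions"] = pack_positions(x, y, z),
      _["bonds"] = bonds_out, _["time"] = t0 + (double)n_steps * dt);
  if (store_frames) out["frames"] = frames;
  return out;
}

// ---------------------------------------------------------------------------
// Metropolis pivot Monte Carlo for the self-avoiding chain: rotates the
// shorter arm about a uniformly chosen interior bead by a uniform random
// rotation and accepts by the change in soft-overlap energy
// U(d) = k_rep (2a - d)^2 / 2 for d < 2a. Bond lengths are preserved
// exactly, so this samples the fixed-bond-length chain; a short Brownian
// relaxation restores bond-length fluctuations afterwards.
// ---------------------------------------------------------------------------

namespace {

inline void random_rotation(Xoshiro &rng, double R[3][3]) {
  const double u1 = rng.uniform(), u2 = rng.uniform(), u3 = rng.uniform();
  const double q0 = std::sqrt(1.0 - u1) * std::sin(2.0 * M_PI * u2);
  const double q1 = std::sqrt(1.0 - u1) * std::cos(2.0 * M_PI * u2);
  const double q2 = std::sqrt(u1) * std::sin(2.0 * M_PI * u3);
  const double q3 = std::sqrt(u1) * std::cos(2.0 * M_PI * u3);
  R[0][0] = 1 - 2 * (q2 * q2 + q3 * q3);
  R[0][1] = 2 * (q1 * q2 - q0 * q3);
  R[0][2] = 2 * (q1 * q3 + q0 * q2);
  R[1][0] = 2 * (q1 * q2 + q0 * q3);
  R[1][1] = 1 - 2 * (q1 * q1 + q3 * q3);
  R[1][2] = 2 * (q2 * q3 - q0 * q1);
  R[2][0] = 2 * (q1 * q3 - q0 * q2);
  R[2][1] = 2 * (q2 * q3 + q0 * q1);
  R[2][2] = 1 - 2 * (q2 * q2 + q1 * q1);
}

// overlap energy between the moved bead set (coordinates xs/ys/zs) and the
// static part of the chain held in a pre-built cell grid
inline double cross_energy(const CellGrid &grid, const std::vector<double> &x,
                           const std::vector<double> &y,
                           const std::vector<double> &z,
                           const std::vector<double> &xs,
                           const std::vector<double> &ys,
                           const std::vector<double> &zs, double k_rep,
                           double a) {
  const double cutoff = 2.0 * a;
  const double cut2 = cutoff * cutoff;
  double e = 0.0;
  const int m = (int)xs.size();
  for (int q = 0; q < m; ++q) {
    const double xi = xs[q], yi = ys[q], zi = zs[q];
    const int cx = (int)std::floor((xi - grid.x0) / cutoff);
    const int cy = (int)std::floor((yi - grid.y0) / cutoff);
    const int cz = (int)std::floor((zi - grid.z0) / cutoff);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz)
          for (int j = grid.cell_head(cx + ox, cy + oy, cz + oz); j != -1;
               j = grid.nxt[j]) {
            const double dx = xi - x[j];
            const double dy = yi - y[j];
            const double dz = zi - z[j];
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < cut2) {
              const double s = cutoff - std::sqrt(d2);
              e += 0.5 * k_rep * s * s;
            }
          }
  }
  return e;
}

}  // namespace

// [[Rcpp::export]]
List cpp_pivot(NumericMatrix pos, double k_rep, double a, double kT,
               int n_attempts, double seed) {
  const int n = pos.nrow();
  std::vector<double> x, y, z;
  unpack_positions(pos, x, y, z);
  Xoshiro rng((uint64_t)seed);
  int accepted = 0;
  std::vector<double> xs, ys, zs;
  std::vector<int> static_idx;
  CellGrid grid;
  for (int att = 0; att < n_attempts; ++att) {
    const int p = 1 + rng.below(n - 2);  // interior pivot bead
    // rotate the shorter arm
    int lo, hi;
    if (p < n - 1 - p) {
      lo = 0;
      hi = p - 1;
    } else {
      lo = p + 1;
      hi = n - 1;
    }
    const int m = hi - lo + 1;
    xs.resize(m);
    ys.resize(m);
    zs.resize(m);
    double R[3][3];
    random_rotation(rng, R);
    const double px = x[p], py = y[p], pz = z[p];
    for (int i = lo; i <= hi; ++i) {
      const double dx = x[i] - px, dy = y[i] - py, dz = z[i] - pz;
      xs[i - lo] = px + R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
      ys[i - lo] = py + R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
      zs[i - lo] = pz + R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
    }
    static_idx.clear();
    for (int j = 0; j < n; ++j)
      if (j < lo || j > hi) static_idx.push_back(j);
    grid.build_subset(x, y, z, static_idx, 2.0 * a);
    std::vector<double> xo(x.begin() + lo, x.begin() + hi + 1);
    std::vector<double> yo(y.begin() + lo, y.begin() + hi + 1);
    std::vector<double> zo(z.begin() + lo, z.begin() + hi + 1);
    const double e_old = cross_energy(grid, x, y, z, xo, yo, zo, k_rep, a);
    const double e_new = cross_energy(grid, x, y, z, xs, ys, zs, k_rep, a);
    const double dU = e_new - e_old;
    if (dU <= 0.0 || rng.uniform() < std::exp(-dU / kT)) {
      for (int i = lo; i <= hi; ++i) {
        x[i] = xs[i - lo];
        y[i] = ys[i - lo];
        z[i] = zs[i - lo];
      }
      ++accepted;
    }
    if (att % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["positions"] = pack_positions(x, y, z),
                      _["accepted"] = accepted);
}
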