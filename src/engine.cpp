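// Monte Carlo kernels: soft-repulsive pair/bond/wall energies, xy-periodic
// cell lists, and the grand-canonical Metropolis sweep engine.
//
// Reduced units throughout: lengths in rc (cutoff = 1), energies in kBT.
// Geometry: box periodic in x and y, bounded in z by the grafting surface
// (z = 0) and the tip wall (z = h).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// Deterministic single-stream RNG (xoshiro256++ seeded via splitmix64).
// Identical seed => identical move sequence, independent of R's RNG state.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0,1)
};

inline double pair_u(double r, double a) {
  if (r >= 1.0) return 0.0;
  const double t = 1.0 - r;
  return 0.5 * a * t * t;
}
// soft wall, same quadratic family; gap may be negative (penetration)
inline double wall_u(double gap, double aw) {
  if (gap >= 1.0) return 0.0;
  const double t = 1.0 - gap;
  return 0.5 * aw * t * t;
}

struct Interactions {
  int S = 1;                    // number of species (solvent + populations)
  std::vector<double> a;        // S x S row-major repulsion amplitudes
  double aws = 25.0, awt = 25.0;
  bool exclude_bonded = false;
  double amp(int s1, int s2) const { return a[s1 * S + s2]; }
};

struct Engine {
  double Lx, Ly, h;
  Interactions inter;

  // particle state; brush beads occupy indices [0, n_brush), solvent after
  std::vector<double> px, py, pz;
  std::vector<int> sp;   // 0 = solvent, 1..P = brush population
  std::vector<int> mob;  // 0 free, 1 graft (xy-mobile), 2 graft (frozen)
  int n_brush = 0;

  std::vector<int> b_i, b_j;          // bond endpoints (0-based)
  std::vector<double> b_k, b_r0;
  std::vector<std::vector<int>> adj;  // bond ids per brush bead

  // cell list
  int ncx = 1, ncy = 1, ncz = 1;
  double icx = 1, icy = 1, icz = 1;  // cells per unit length
  std::vector<std::vector<int>> cells;
  std::vector<int> cellof, slot;

  int n() const { return (int)px.size(); }
  int n_solvent() const { return n() - n_brush; }

  // minimum image by branch: valid because wrapped coordinates keep every
  // difference within (-L, L)
  double mi_x(double dx) const {
    if (dx > 0.5 * Lx) return dx - Lx;
    if (dx < -0.5 * Lx) return dx + Lx;
    return dx;
  }
  double mi_y(double dy) const {
    if (dy > 0.5 * Ly) return dy - Ly;
    if (dy < -0.5 * Ly) return dy + Ly;
    return dy;
  }
  static double wrap(double v, double L) {
    v -= L * std::floor(v / L);
    if (v >= L) v -= L;       // guard against fp edge
    if (v < 0.0) v = 0.0;
    return v;
  }

  // --- cell list ------------------------------------------------------------
  void cell_geometry() {
    ncx = (int)std::floor(Lx); if (ncx < 3) ncx = 1;
    ncy = (int)std::floor(Ly); if (ncy < 3) ncy = 1;
    ncz = (int)std::floor(h);  if (ncz < 1) ncz = 1;
    icx = ncx / Lx; icy = ncy / Ly; icz = ncz / h;
  }
  int cell_index(double x, double y, double z) const {
    int cx = (int)(x * icx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(y * icy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)(z * icz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
    return (cz * ncy + cy) * ncx + cx;
  }
  void rebuild_cells() {
    cell_geometry();
    cells.assign((size_t)ncx * ncy * ncz, {});
    cellof.assign(n(), -1);
    slot.assign(n(), -1);
    for (int i = 0; i < n(); ++i) cell_add(i);
  }
  void cell_add(int i) {
    int c = cell_index(px[i], py[i], pz[i]);
    cellof[i] = c;
    slot[i] = (int)cells[c].size();
    cells[c].push_back(i);
  }
  void cell_remove(int i) {
    int c = cellof[i], s = slot[i];
    int last = cells[c].back();
    cells[c][s] = last;
    slot[last] = s;
    cells[c].pop_back();
    cellof[i] = -1; slot[i] = -1;
  }
  void cell_move(int i) {
    int c = cell_index(px[i], py[i], pz[i]);
    if (c != cellof[i]) { cell_remove(i); cell_add(i); }
  }

  // --- energies -------------------------------------------------------------
  // pair interaction energy of a (possibly ghost) particle at (x,y,z) with
  // species s, excluding particle `self` (-1 for none)
  double pair_at(double x, double y, double z, int s, int self) const {
    double e = 0.0;
    int cx = (int)(x * icx); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
    int cy = (int)(y * icy); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
    int cz = (int)(z * icz); if (cz >= ncz) cz = ncz - 1; if (cz < 0) cz = 0;
    const int zlo = cz > 0 ? cz - 1 : 0;
    const int zhi = cz < ncz - 1 ? cz + 1 : ncz - 1;
    const int dxr = (ncx >= 3) ? 1 : 0;
    const int dyr = (ncy >= 3) ? 1 : 0;
    for (int zz = zlo; zz <= zhi; ++zz) {
      for (int dy = -dyr; dy <= dyr; ++dy) {
        int yy = cy + dy; if (yy < 0) yy += ncy; else if (yy >= ncy) yy -= ncy;
        for (int dx = -dxr; dx <= dxr; ++dx) {
          int xx = cx + dx; if (xx < 0) xx += ncx; else if (xx >= ncx) xx -= ncx;
          const std::vector<int>& cell = cells[(zz * ncy + yy) * ncx + xx];
          for (int j : cell) {
            if (j == self) continue;
            double ddx = mi_x(px[j] - x);
            double ddy = mi_y(py[j] - y);
            double ddz = pz[j] - z;
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 < 1.0)
              e += pair_u(std::sqrt(r2), inter.amp(s, sp[j]));
          }
        }
      }
    }
    if (inter.exclude_bonded && self >= 0 && self < n_brush) {
      for (int bid : adj[self]) {
        int j = (b_i[bid] == self) ? b_j[bid] : b_i[bid];
        double ddx = mi_x(px[j] - x);
        double ddy = mi_y(py[j] - y);
        double ddz = pz[j] - z;
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 < 1.0)
          e -= pair_u(std::sqrt(r2), inter.amp(s, sp[j]));
      }
    }
    return e;
  }

  double bond_at(int i, double x, double y, double z) const {
    if (i < 0 || i >= n_brush) return 0.0;
    double e = 0.0;
    for (int bid : adj[i]) {
      int j = (b_i[bid] == i) ? b_j[bid] : b_i[bid];
      double ddx = mi_x(px[j] - x);
      double ddy = mi_y(py[j] - y);
      double ddz = pz[j] - z;
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double d = r - b_r0[bid];
      e += 0.5 * b_k[bid] * d * d;
    }
    return e;
  }

  // surface wall acts on non-graft particles only (grafts live in the
  // surface plane); tip wall acts on every particle
  double wall_at(int mobflag, double z) const {
    double e = 0.0;
    if (mobflag == 0) e += wall_u(z, inter.aws);
    e += wall_u(h - z, inter.awt);
    return e;
  }

  void breakdown(double out[4]) const {
    double ep = 0.0, eb = 0.0, ews = 0.0, ewt = 0.0;
    for (int i = 0; i < n(); ++i) {
      // pairs counted once via j > i within the neighbor stencil
      int cx = (int)(px[i] * icx); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(py[i] * icy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)(pz[i] * icz); if (cz >= ncz) cz = ncz - 1;
      const int zlo = cz > 0 ? cz - 1 : 0;
      const int zhi = cz < ncz - 1 ? cz + 1 : ncz - 1;
      const int dxr = (ncx >= 3) ? 1 : 0;
      const int dyr = (ncy >= 3) ? 1 : 0;
      for (int zz = zlo; zz <= zhi; ++zz)
        for (int dy = -dyr; dy <= dyr; ++dy) {
          int yy = cy + dy; if (yy < 0) yy += ncy; else if (yy >= ncy) yy -= ncy;
          for (int dx = -dxr; dx <= dxr; ++dx) {
            int xx = cx + dx; if (xx < 0) xx += ncx; else if (xx >= ncx) xx -= ncx;
            const std::vector<int>& cell = cells[(zz * ncy + yy) * ncx + xx];
            for (int j : cell) {
              if (j <= i) continue;
              double ddx = mi_x(px[j] - px[i]);
              double ddy = mi_y(py[j] - py[i]);
              double ddz = pz[j] - pz[i];
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (r2 < 1.0)
                ep += pair_u(std::sqrt(r2), inter.amp(sp[i], sp[j]));
            }
          }
        }
      if (mob[i] == 0) ews += wall_u(pz[i], inter.aws);
      ewt += wall_u(h - pz[i], inter.awt);
    }
    if (inter.exclude_bonded) {
      for (size_t b = 0; b < b_i.size(); ++b) {
        int i = b_i[b], j = b_j[b];
        double ddx = mi_x(px[j] - px[i]);
        double ddy = mi_y(py[j] - py[i]);
        double ddz = pz[j] - pz[i];
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 < 1.0)
          ep -= pair_u(std::sqrt(r2), inter.amp(sp[i], sp[j]));
      }
    }
    for (size_t b = 0; b < b_i.size(); ++b) {
      int i = b_i[b], j = b_j[b];
      double ddx = mi_x(px[j] - px[i]);
      double ddy = mi_y(py[j] - py[i]);
      double ddz = pz[j] - pz[i];
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double d = r - b_r0[b];
      eb += 0.5 * b_k[b] * d * d;
    }
    out[0] = ep; out[1] = eb; out[2] = ews; out[3] = ewt;
  }

  double tip_force() const {
    double f = 0.0;
    for (int i = 0; i < n(); ++i) {
      double gap = h - pz[i];
      if (gap < 1.0) f += inter.awt * (1.0 - gap);
    }
    return f;
  }
};

Engine build_engine(const List& sys, const List& inter) {
  Engine e;
  NumericVector box = sys["box"];
  e.Lx = box[0]; e.Ly = box[1];
  e.h = as<double>(sys["h"]);
  NumericMatrix pos = sys["positions"];
  IntegerVector spc = sys["species"];
  IntegerVector mbv = sys["mobility"];
  int n = pos.nrow();
  e.px.resize(n); e.py.resize(n); e.pz.resize(n);
  e.sp.resize(n); e.mob.resize(n);
  for (int i = 0; i < n; ++i) {
    e.px[i] = Engine::wrap(pos(i, 0), e.Lx);
    e.py[i] = Engine::wrap(pos(i, 1), e.Ly);
    e.pz[i] = pos(i, 2);
    if (e.pz[i] < 0.0 || e.pz[i] > e.h)
      stop("particle %d has z outside [0, h]", i + 1);
    e.sp[i] = spc[i];
    e.mob[i] = mbv[i];
  }
  e.n_brush = as<int>(sys["n_brush"]);
  for (int i = e.n_brush; i < n; ++i)
    if (e.sp[i] != 0) stop("solvent block contains a brush bead");

  NumericMatrix bonds = sys["bonds"];
  int m = bonds.nrow();
  e.b_i.resize(m); e.b_j.resize(m); e.b_k.resize(m); e.b_r0.resize(m);
  e.adj.assign(e.n_brush, {});
  for (int b = 0; b < m; ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    if (i < 0 || j < 0 || i >= e.n_brush || j >= e.n_brush)
      stop("bond %d references a non-brush particle", b + 1);
    e.b_i[b] = i; e.b_j[b] = j;
    e.b_k[b] = bonds(b, 2); e.b_r0[b] = bonds(b, 3);
    e.adj[i].push_back(b);
    e.adj[j].push_back(b);
  }

  NumericMatrix a = inter["a"];
  e.inter.S = a.nrow();
  e.inter.a.resize((size_t)e.inter.S * e.inter.S);
  for (int r = 0; r < e.inter.S; ++r)
    for (int c = 0; c < e.inter.S; ++c)
      e.inter.a[r * e.inter.S + c] = a(r, c);
  for (int i = 0; i < n; ++i)
    if (e.sp[i] < 0 || e.sp[i] >= e.inter.S)
      stop("species index out of range of interaction table");
  e.inter.aws = as<double>(inter["a_wall_surface"]);
  e.inter.awt = as<double>(inter["a_wall_tip"]);
  e.inter.exclude_bonded = as<bool>(inter["exclude_bonded"]);
  e.rebuild_cells();
  return e;
}

List system_from_engine(const Engine& e, const List& sys_template) {
  int n = e.n();
  NumericMatrix pos(n, 3);
  IntegerVector spc(n), mbv(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = e.px[i]; pos(i, 1) = e.py[i]; pos(i, 2) = e.pz[i];
    spc[i] = e.sp[i]; mbv[i] = e.mob[i];
  }
  List out = clone(sys_template);
  out["positions"] = pos;
  out["species"] = spc;
  out["mobility"] = mbv;
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_energy_breakdown(List sys, List inter) {
  Engine e = build_engine(sys, inter);
  double out[4];
  e.breakdown(out);
  return List::create(_["pair"] = out[0], _["bond"] = out[1],
                      _["wall_surface"] = out[2], _["wall_tip"] = out[3],
                      _["total"] = out[0] + out[1] + out[2] + out[3]);
}

// Enumerate interacting pairs (minimum-image distance < 1 rc).
// method: "cell" uses the cell list; "all" brute-force O(N^2).
// [[Rcpp::export]]
IntegerMatrix cpp_pair_list(List sys, List inter, std::string method) {
  Engine e = build_engine(sys, inter);
  std::vector<std::pair<int, int>> pairs;
  int n = e.n();
  if (method == "all") {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = e.mi_x(e.px[j] - e.px[i]);
        double dy = e.mi_y(e.py[j] - e.py[i]);
        double dz = e.pz[j] - e.pz[i];
        if (dx * dx + dy * dy + dz * dz < 1.0) pairs.push_back({i, j});
      }
  } else {
    for (int i = 0; i < n; ++i) {
      int cx = (int)(e.px[i] * e.icx); if (cx >= e.ncx) cx = e.ncx - 1;
      int cy = (int)(e.py[i] * e.icy); if (cy >= e.ncy) cy = e.ncy - 1;
      int cz = (int)(e.pz[i] * e.icz);  if (cz >= e.ncz) cz = e.ncz - 1;
      const int zlo = cz > 0 ? cz - 1 : 0;
      const int zhi = cz < e.ncz - 1 ? cz + 1 : e.ncz - 1;
      const int dxr = (e.ncx >= 3) ? 1 : 0;
      const int dyr = (e.ncy >= 3) ? 1 : 0;
      for (int zz = zlo; zz <= zhi; ++zz)
        for (int dy = -dyr; dy <= dyr; ++dy) {
          int yy = cy + dy; if (yy < 0) yy += e.ncy; else if (yy >= e.ncy) yy -= e.ncy;
          for (int dx = -dxr; dx <= dxr; ++dx) {
            int xx = cx + dx; if (xx < 0) xx += e.ncx; else if (xx >= e.ncx) xx -= e.ncx;
            const std::vector<int>& cell = e.cells[(zz * e.ncy + yy) * e.ncx + xx];
            for (int j : cell) {
              if (j <= i) continue;
              double ddx = e.mi_x(e.px[j] - e.px[i]);
              double ddy = e.mi_y(e.py[j] - e.py[i]);
              double ddz = e.pz[j] - e.pz[i];
              if (ddx * ddx + ddy * ddy + ddz * ddz < 1.0) pairs.push_back({i, j});
            }
          }
        }
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}

// Energy change for displacing particle i (1-based) to new_pos.
// [[Rcpp::export]]
double cpp_delta_displacement(List sys, List inter, int i, NumericVector new_pos) {
  Engine e = build_engine(sys, inter);
  int idx = i - 1;
  if (idx < 0 || idx >= e.n()) stop("particle index out of range");
  if (e.mob[idx] == 2) stop("cannot displace a solid-graft particle");
  double nx = Engine::wrap(new_pos[0], e.Lx);
  double ny = Engine::wrap(new_pos[1], e.Ly);
  double nz = new_pos[2];
  if (nz < 0.0 || nz > e.h) stop("proposed z outside [0, h]");
  double old_e = e.pair_at(e.px[idx], e.py[idx], e.pz[idx], e.sp[idx], idx) +
                 e.bond_at(idx, e.px[idx], e.py[idx], e.pz[idx]) +
                 e.wall_at(e.mob[idx], e.pz[idx]);
  double new_e = e.pair_at(nx, ny, nz, e.sp[idx], idx) +
                 e.bond_at(idx, nx, ny, nz) +
                 e.wall_at(e.mob[idx], nz);
  return new_e - old_e;
}

// Interaction energy of inserting a ghost solvent particle at pos.
// [[Rcpp::export]]
double cpp_insertion_energy(List sys, List inter, NumericVector pos) {
  Engine e = build_engine(sys, inter);
  double x = Engine::wrap(pos[0], e.Lx), y = Engine::wrap(pos[1], e.Ly), z = pos[2];
  if (z < 0.0 || z > e.h) stop("insertion z outside [0, h]");
  return e.pair_at(x, y, z, 0, -1) + e.wall_at(0, z);
}

// Interaction energy of existing particle i (pair + bond + wall terms it owns).
// [[Rcpp::export]]
double cpp_particle_energy(List sys, List inter, int i) {
  Engine e = build_engine(sys, inter);
  int idx = i - 1;
  if (idx < 0 || idx >= e.n()) stop("particle index out of range");
  return e.pair_at(e.px[idx], e.py[idx], e.pz[idx], e.sp[idx], idx) +
         e.bond_at(idx, e.px[idx], e.py[idx], e.pz[idx]) +
         e.wall_at(e.mob[idx], e.pz[idx]);
}

// [[Rcpp::export]]
double cpp_tip_force(List sys, List inter) {
  Engine e = build_engine(sys, inter);
  return e.tip_force();
}

// ---------------------------------------------------------------------------
// GCMC run engine
// ---------------------------------------------------------------------------
// opts: n_equilibration, n_production, sample_interval, seed, max_displacement,
//       tune (bool), activity, gc_fraction, bin_width, record_frames (bool)
// [[Rcpp::export]]
List cpp_run_chain(List sys, List inter, List opts) {
  Engine e = build_engine(sys, inter);

  const int n_eq = as<int>(opts["n_equilibration"]);
  const int n_prod = as<int>(opts["n_production"]);
  const int sample_interval = as<int>(opts["sample_interval"]);
  const double seed = as<double>(opts["seed"]);
  // separate trial amplitudes for unbonded (solvent) and bonded (brush)
  // particles: stiff springs need far smaller steps than the solvent to
  // keep their acceptance usable, and one global amplitude would be tuned
  // by the solvent majority and freeze stiff chains
  double max_disp = as<double>(opts["max_displacement"]);
  double max_disp_brush = as<double>(opts["max_displacement_brush"]);
  const bool tune = as<bool>(opts["tune"]);
  const double activity = as<double>(opts["activity"]);
  const double gc_frac = as<double>(opts["gc_fraction"]);
  const double bin_width = as<double>(opts["bin_width"]);
  const bool record_frames = as<bool>(opts["record_frames"]);
  if (sample_interval < 1) stop("sample_interval must be >= 1");
  if (bin_width <= 0) stop("bin_width must be positive");

  Xoshiro rng((uint64_t)seed);
  const double V = e.Lx * e.Ly * e.h;

  // counts of immobile grafts to size displacement attempts
  int n_solid = 0;
  for (int i = 0; i < e.n(); ++i) if (e.mob[i] == 2) ++n_solid;

  // insertion/deletion attempts per sweep, frozen at the run-start solvent
  // count: a state-dependent application count of an N-changing kernel
  // would break stationarity of the grand-canonical distribution
  const int n_gc = (gc_frac > 0.0)
                       ? std::max(1, (int)std::lround(gc_frac * e.n_solvent()))
                       : 0;

  double eb0[4];
  e.breakdown(eb0);
  double E = eb0[0] + eb0[1] + eb0[2] + eb0[3];

  // statistics: displace_free, displace_graft_liquid, insert, delete
  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};
  long tune_att_s = 0, tune_acc_s = 0, tune_att_b = 0, tune_acc_b = 0;
  const int tune_interval = 50;

  // samples
  std::vector<double> s_sweep, s_nsolv, s_energy, s_force;
  const int nbins = std::max(1, (int)std::ceil(e.h / bin_width - 1e-9));
  std::vector<double> hist_brush(nbins, 0.0), hist_solv(nbins, 0.0);
  std::vector<int> graft_ids;
  for (int i = 0; i < e.n_brush; ++i) if (e.mob[i] >= 1) graft_ids.push_back(i);
  std::vector<double> traces;  // row-major: sample x (2 * ngraft)
  List frames;
  std::vector<NumericMatrix> frame_store;

  const int total_sweeps = n_eq + n_prod;
  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    const bool in_prod = sweep > n_eq;

    // displacement moves: one attempt per mobile particle
    int n_disp = e.n() - n_solid;
    for (int k = 0; k < n_disp; ++k) {
      int i;
      do { i = (int)(rng.unif() * e.n()); } while (e.mob[i] == 2);
      const int cls = (e.mob[i] == 1) ? 1 : 0;
      const bool bonded = i < e.n_brush;
      const double d = bonded ? max_disp_brush : max_disp;
      ++att[cls];
      if (!in_prod) { if (bonded) ++tune_att_b; else ++tune_att_s; }
      double nx = e.px[i] + (2.0 * rng.unif() - 1.0) * d;
      double ny = e.py[i] + (2.0 * rng.unif() - 1.0) * d;
      double nz = e.pz[i];
      if (e.mob[i] == 0) nz += (2.0 * rng.unif() - 1.0) * d;
      if (nz < 0.0 || nz > e.h) continue;  // hard reflection: reject
      nx = Engine::wrap(nx, e.Lx);
      ny = Engine::wrap(ny, e.Ly);
      double old_e = e.pair_at(e.px[i], e.py[i], e.pz[i], e.sp[i], i) +
                     e.bond_at(i, e.px[i], e.py[i], e.pz[i]) +
                     e.wall_at(e.mob[i], e.pz[i]);
      double new_e = e.pair_at(nx, ny, nz, e.sp[i], i) +
                     e.bond_at(i, nx, ny, nz) +
                     e.wall_at(e.mob[i], nz);
      double dU = new_e - old_e;
      bool ok = dU <= 0.0 || rng.unif() < std::exp(-dU);
      if (ok) {
        e.px[i] = nx; e.py[i] = ny; e.pz[i] = nz;
        e.cell_move(i);
        E += dU;
        ++acc[cls];
        if (!in_prod) { if (bonded) ++tune_acc_b; else ++tune_acc_s; }
      }
    }

    // grand-canonical moves on the solvent
    for (int k = 0; k < n_gc; ++k) {
      if (rng.unif() < 0.5) {  // insertion
        ++att[2];
        double x = rng.unif() * e.Lx, y = rng.unif() * e.Ly, z = rng.unif() * e.h;
        double dU = e.pair_at(x, y, z, 0, -1) + e.wall_at(0, z);
        double log_acc = std::log(activity * V / (e.n_solvent() + 1.0)) - dU;
        if (log_acc >= 0.0 || rng.unif() < std::exp(log_acc)) {
          e.px.push_back(x); e.py.push_back(y); e.pz.push_back(z);
          e.sp.push_back(0); e.mob.push_back(0);
          e.cellof.push_back(-1); e.slot.push_back(-1);
          e.cell_add(e.n() - 1);
          E += dU;
          ++acc[2];
        }
      } else {  // deletion
        ++att[3];
        int ns = e.n_solvent();
        if (ns == 0) continue;  // nothing to delete: rejected attempt
        int i = e.n_brush + (int)(rng.unif() * ns);
        double u = e.pair_at(e.px[i], e.py[i], e.pz[i], 0, i) +
                   e.wall_at(0, e.pz[i]);
        double dU = -u;
        double log_acc = std::log(ns / (activity * V)) - dU;
        if (log_acc >= 0.0 || rng.unif() < std::exp(log_acc)) {
          e.cell_remove(i);
          int last = e.n() - 1;
          if (i != last) {
            // move the final solvent particle into slot i
            e.cell_remove(last);
            e.px[i] = e.px[last]; e.py[i] = e.py[last]; e.pz[i] = e.pz[last];
            e.sp[i] = e.sp[last]; e.mob[i] = e.mob[last];
            e.px.pop_back(); e.py.pop_back(); e.pz.pop_back();
            e.sp.pop_back(); e.mob.pop_back();
            e.cellof.pop_back(); e.slot.pop_back();
            e.cell_add(i);
          } else {
            e.px.pop_back(); e.py.pop_back(); e.pz.pop_back();
            e.sp.pop_back(); e.mob.pop_back();
            e.cellof.pop_back(); e.slot.pop_back();
          }
          E += dU;
          ++acc[3];
        }
      }
    }

    // auto-tune trial displacements toward ~40% acceptance (equilibration
    // only; frozen for production to keep detailed balance)
    if (tune && !in_prod && sweep % tune_interval == 0) {
      if (tune_att_s > 0) {
        double frac = (double)tune_acc_s / (double)tune_att_s;
        if (frac > 0.45) max_disp *= 1.10;
        else if (frac < 0.35) max_disp *= 0.90;
        if (max_disp > 1.0) max_disp = 1.0;
        if (max_disp < 0.01) max_disp = 0.01;
      }
      if (tune_att_b > 0) {
        double frac = (double)tune_acc_b / (double)tune_att_b;
        if (frac > 0.45) max_disp_brush *= 1.10;
        else if (frac < 0.35) max_disp_brush *= 0.90;
        if (max_disp_brush > 1.0) max_disp_brush = 1.0;
        if (max_disp_brush < 0.005) max_disp_brush = 0.005;
      }
      tune_att_s = 0; tune_acc_s = 0; tune_att_b = 0; tune_acc_b = 0;
    }

    if (in_prod && (sweep - n_eq) % sample_interval == 0) {
      s_sweep.push_back(sweep - n_eq);
      s_nsolv.push_back(e.n_solvent());
      s_energy.push_back(E);
      s_force.push_back(e.tip_force());
      for (int i = 0; i < e.n(); ++i) {
        int b = (int)(e.pz[i] / bin_width);
        if (b >= nbins) b = nbins - 1;
        if (e.sp[i] > 0) hist_brush[b] += 1.0; else hist_solv[b] += 1.0;
      }
      for (int g : graft_ids) {
        traces.push_back(e.px[g]);
        traces.push_back(e.py[g]);
      }
      if (record_frames) {
        NumericMatrix fr(e.n(), 3);
        for (int i = 0; i < e.n(); ++i) {
          fr(i, 0) = e.px[i]; fr(i, 1) = e.py[i]; fr(i, 2) = e.pz[i];
        }
        frame_store.push_back(fr);
      }
    }
  }

  // energy drift check against a full recompute
  double ebf[4];
  e.breakdown(ebf);
  double E_exact = ebf[0] + ebf[1] + ebf[2] + ebf[3];

  int nsamp = (int)s_sweep.size();
  int ngraft = (int)graft_ids.size();
  NumericMatrix trace_mat(nsamp, 2 * ngraft);
  for (int s = 0; s < nsamp; ++s)
    for (int g = 0; g < 2 * ngraft; ++g)
      trace_mat(s, g) = traces[(size_t)s * 2 * ngraft + g];
  IntegerVector graft_iv(ngraft);
  for (int g = 0; g < ngraft; ++g) graft_iv[g] = graft_ids[g] + 1;

  if (record_frames) {
    frames = List(frame_store.size());
    for (size_t i = 0; i < frame_store.size(); ++i) frames[i] = frame_store[i];
  }

  DataFrame samples = DataFrame::create(
      _["sweep"] = s_sweep, _["n_solvent"] = s_nsolv,
      _["energy"] = s_energy, _["tip_force"] = s_force);
  DataFrame stats = DataFrame::create(
      _["move"] = CharacterVector::create("displace_free", "displace_graft_liquid",
                                          "insert", "delete"),
      _["attempted"] = NumericVector::create(att[0], att[1], att[2], att[3]),
      _["accepted"] = NumericVector::create(acc[0], acc[1], acc[2], acc[3]));

  return List::create(
      _["system"] = system_from_engine(e, sys),
      _["samples"] = samples,
      _["stats"] = stats,
      _["hist_brush"] = NumericVector(hist_brush.begin(), hist_brush.end()),
      _["hist_solvent"] = NumericVector(hist_solv.begin(), hist_solv.end()),
      _["bin_width"] = bin_width,
      _["n_hist_samples"] = nsamp,
      _["graft_ids"] = graft_iv,
      _["graft_trace"] = trace_mat,
      _["max_displacement_final"] = max_disp,
      _["max_displacement_brush_final"] = max_disp_brush,
      _["energy_running"] = E,
      _["energy_final"] = E_exact,
      _["energy_drift"] = std::fabs(E - E_exact),
      _["frames"] = frames);
}
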