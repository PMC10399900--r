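// Coarse-grained force field and Langevin dynamics engine.
//
// Units: length Angstrom, energy kcal/mol, mass amu,
// time tu = sqrt(amu A^2 / (kcal/mol)) ~ 48.89 fs.
//
// Bead classes: 0 disordered protein, 1 folded protein (DBD),
//               2 DNA site, 3 crowder sphere.
//
// Nonbonded rules:
//   crowder involved               -> WCA excluded volume only
//   protein-protein, in HPS scope  -> Ashbaugh-Hatch HPS (shift-truncated)
//   any other pair                 -> WCA excluded volume
//   + Debye-Hueckel if both beads charged and electrostatics enabled
// Exclusions: directly bonded pairs and harmonic (elastic-network) pairs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

// deterministic RNG: mt19937_64 + Box-Muller (cached)
struct RNG {
  std::uint64_t s[4];
  bool has_cache = false;
  double cache = 0.0;
  explicit RNG(std::uint64_t seed) {
    // splitmix64 expansion of the seed into xoshiro256+ state
    std::uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    std::uint64_t result = s[0] + s[3];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    cache = r * std::sin(a);
    has_cache = true;
    return r * std::cos(a);
  }
};

struct System {
  int n;
  std::vector<double> x, y, z;       // unwrapped coordinates
  std::vector<double> wx, wy, wz;    // wrapped shadow coordinates (force/list)
  double hb[3];                      // half box
  std::vector<double> sigma, lam, q, mass;
  std::vector<int> cls;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bk, b0;
  // harmonic pairs (elastic network, DNA restraints)
  std::vector<int> ei, ej; std::vector<double> ek, e0;
  // per-bead exclusion lists (sorted)
  std::vector< std::vector<int> > excl;
  // optional tethers
  std::vector<double> tk, tx, ty, tz;
  bool has_tether = false;
  double box[3];
};

struct FF {
  double eps_hps, hps_cut;
  double eps_ev;
  double kcoul;        // 332.0637 / dielectric
  double ldebye, dh_cut;
  bool elec, nonbonded;
  int scope;           // 0 both-disordered, 1 all residues, 2 either-disordered
};

static bool excluded(const System& S, int i, int j) {
  const std::vector<int>& v = S.excl[i];
  return std::binary_search(v.begin(), v.end(), j);
}

static inline double mi(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// fast min image, valid when |d| < 1.5 L (wrapped coordinates + skin drift)
static inline double fmi(double d, double L, double hL) {
  if (d > hL) d -= L; else if (d < -hL) d += L;
  return d;
}

static void rewrap(System& S) {
  for (int d = 0; d < 3; ++d) S.hb[d] = 0.5 * S.box[d];
  for (int i = 0; i < S.n; ++i) {
    S.wx[i] = S.x[i] - S.box[0] * std::floor(S.x[i] / S.box[0]);
    S.wy[i] = S.y[i] - S.box[1] * std::floor(S.y[i] / S.box[1]);
    S.wz[i] = S.z[i] - S.box[2] * std::floor(S.z[i] / S.box[2]);
  }
}

// ---- pair lists -----------------------------------------------------------
//
// Two Verlet lists sharing one cell traversal: a short-range list (HPS /
// excluded volume) at rshort and an electrostatic list at relec restricted
// to pairs where both beads are charged.

struct PairLists {
  // short-range list with packed pair parameters
  std::vector<int> si, sj;
  std::vector<double> psig, plam;   // pair sigma / lambda (lam < 0: WCA pair)
  // electrostatic list (both charged), packed charge product
  std::vector<int> ei, ej;
  std::vector<double> pqq;
};

static void build_pairs(const System& S, const FF& F, double rshort,
                        double relec, PairLists& P) {
  P.si.clear(); P.sj.clear(); P.psig.clear(); P.plam.clear();
  P.ei.clear(); P.ej.clear(); P.pqq.clear();
  const int n = S.n;
  const double rlist = std::max(rshort, relec);
  const double rs2 = rshort * rshort, re2 = relec * relec;
  auto consider = [&](int i, int j) {
    double dx = fmi(S.wx[i] - S.wx[j], S.box[0], S.hb[0]);
    double dy = fmi(S.wy[i] - S.wy[j], S.box[1], S.hb[1]);
    double dz = fmi(S.wz[i] - S.wz[j], S.box[2], S.hb[2]);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rs2 && !(d2 < re2 && S.q[i] != 0.0 && S.q[j] != 0.0)) return;
    if (excluded(S, i, j)) return;
    int a = std::min(i, j), b = std::max(i, j);
    if (d2 < rs2) {
      int ci = S.cls[i], cj = S.cls[j];
      bool hps = false;
      if (ci != 3 && cj != 3 && ci <= 1 && cj <= 1) {
        if (F.scope == 1) hps = true;
        else if (F.scope == 2) hps = (ci == 0 || cj == 0);
        else hps = (ci == 0 && cj == 0);
      }
      P.si.push_back(a); P.sj.push_back(b);
      P.psig.push_back(0.5 * (S.sigma[i] + S.sigma[j]));
      P.plam.push_back(hps ? 0.5 * (S.lam[i] + S.lam[j]) : -1.0);
    }
    if (d2 < re2 && S.q[i] != 0.0 && S.q[j] != 0.0) {
      P.ei.push_back(a); P.ej.push_back(b);
      P.pqq.push_back(S.q[i] * S.q[j]);
    }
  };
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = std::max(1, (int)std::floor(S.box[d] / rlist));
  bool cells_ok = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 && n > 200;
  if (!cells_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int c[3];
    double w[3] = { S.wx[i], S.wy[i], S.wz[i] };
    for (int d = 0; d < 3; ++d) {
      double ww = w[d] - S.box[d] * std::floor(w[d] / S.box[d]);
      c[d] = std::min(nc[d] - 1, (int)std::floor(ww / S.box[d] * nc[d]));
    }
    int cid = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[i] = head[cid]; head[cid] = i;
  }
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cid = (cz * nc[1] + cy) * nc[0] + cx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ox = (cx + dx + nc[0]) % nc[0];
              int oy = (cy + dy + nc[1]) % nc[1];
              int oz = (cz + dz + nc[2]) % nc[2];
              int oid = (oz * nc[1] + oy) * nc[0] + ox;
              if (oid < cid) continue;
              for (int i = head[cid]; i >= 0; i = nxt[i])
                for (int j = (oid == cid ? nxt[i] : head[oid]); j >= 0; j = nxt[j])
                  consider(i, j);
            }
      }
}

// ---- energy / forces ------------------------------------------------------

struct Energy {
  double bond = 0, elastic = 0, hps = 0, ev = 0, dh = 0, tether = 0;
  double total() const { return bond + elastic + hps + ev + dh + tether; }
};

static Energy compute_forces(const System& S, const FF& ff, const PairLists& P,
                             std::vector<double>& fx, std::vector<double>& fy,
                             std::vector<double>& fz) {
  Energy E;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const double SIXTH = 1.1224620483093730; // 2^(1/6)

  // bonds
  for (size_t m = 0; m < S.bi.size(); ++m) {
    int i = S.bi[m], j = S.bj[m];
    double dx = fmi(S.wx[i] - S.wx[j], S.box[0], S.hb[0]);
    double dy = fmi(S.wy[i] - S.wy[j], S.box[1], S.hb[1]);
    double dz = fmi(S.wz[i] - S.wz[j], S.box[2], S.hb[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.b0[m];
    E.bond += S.bk[m] * dr * dr;
    double fmag = -2.0 * S.bk[m] * dr / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }
  // harmonic pairs
  for (size_t m = 0; m < S.ei.size(); ++m) {
    int i = S.ei[m], j = S.ej[m];
    double dx = fmi(S.wx[i] - S.wx[j], S.box[0], S.hb[0]);
    double dy = fmi(S.wy[i] - S.wy[j], S.box[1], S.hb[1]);
    double dz = fmi(S.wz[i] - S.wz[j], S.box[2], S.hb[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - S.e0[m];
    E.elastic += S.ek[m] * dr * dr;
    double fmag = -2.0 * S.ek[m] * dr / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }
  // tethers
  if (S.has_tether) {
    for (int i = 0; i < S.n; ++i) {
      if (S.tk[i] <= 0) continue;
      double dx = S.x[i] - S.tx[i], dy = S.y[i] - S.ty[i], dz = S.z[i] - S.tz[i];
      E.tether += 0.5 * S.tk[i] * (dx * dx + dy * dy + dz * dz);
      fx[i] -= S.tk[i] * dx; fy[i] -= S.tk[i] * dy; fz[i] -= S.tk[i] * dz;
    }
  }
  if (!ff.nonbonded) return E;

  const double hps_cut2 = ff.hps_cut * ff.hps_cut;
  const double inv_hps_cut2 = 1.0 / hps_cut2;
  const double L0 = S.box[0], L1 = S.box[1], L2 = S.box[2];
  const double H0 = S.hb[0], H1 = S.hb[1], H2 = S.hb[2];
  for (size_t m = 0; m < P.si.size(); ++m) {
    int i = P.si[m], j = P.sj[m];
    double dx = fmi(S.wx[i] - S.wx[j], L0, H0);
    double dy = fmi(S.wy[i] - S.wy[j], L1, H1);
    double dz = fmi(S.wz[i] - S.wz[j], L2, H2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-4) stop("singular distance between beads %d and %d", i + 1, j + 1);

    double sig = P.psig[m];
    double lam = P.plam[m];
    double fmag = 0.0; // -dU/dr / r, so force on i is +fmag*d

    if (lam >= 0.0) {
      if (r2 < hps_cut2) {
        double inv_r2 = 1.0 / r2;
        double s2 = sig * sig * inv_r2;
        double s6 = s2 * s2 * s2;
        double lj = 4.0 * ff.eps_hps * s6 * (s6 - 1.0);
        double dlj = 24.0 * ff.eps_hps * s6 * (2.0 * s6 - 1.0) * inv_r2;
        double sc2 = sig * sig * inv_hps_cut2;
        double sc6 = sc2 * sc2 * sc2;
        double ljc = 4.0 * ff.eps_hps * sc6 * (sc6 - 1.0);
        double rmin2 = SIXTH * SIXTH * sig * sig;
        if (r2 < rmin2) {
          E.hps += lj + (1.0 - lam) * ff.eps_hps - lam * ljc;
          fmag += dlj;
        } else {
          E.hps += lam * (lj - ljc);
          fmag += lam * dlj;
        }
      }
    } else {
      // WCA excluded volume, cutoff 2^(1/6) sigma
      double rcut2 = SIXTH * SIXTH * sig * sig;
      if (r2 < rcut2) {
        double inv_r2 = 1.0 / r2;
        double s2 = sig * sig * inv_r2;
        double s6 = s2 * s2 * s2;
        E.ev += 4.0 * ff.eps_ev * s6 * (s6 - 1.0) + ff.eps_ev;
        fmag += 24.0 * ff.eps_ev * s6 * (2.0 * s6 - 1.0) * inv_r2;
      }
    }
    if (fmag != 0.0) {
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }
  if (ff.elec) {
    const double dh_cut2 = ff.dh_cut * ff.dh_cut;
    for (size_t m = 0; m < P.ei.size(); ++m) {
      int i = P.ei[m], j = P.ej[m];
      double dx = fmi(S.wx[i] - S.wx[j], S.box[0], S.hb[0]);
      double dy = fmi(S.wy[i] - S.wy[j], S.box[1], S.hb[1]);
      double dz = fmi(S.wz[i] - S.wz[j], S.box[2], S.hb[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= dh_cut2) continue;
      if (r2 < 1e-4) stop("singular distance between beads %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2);
      double a = ff.kcoul * P.pqq[m];
      double u = a * std::exp(-r / ff.ldebye) / r;
      double uc = a * std::exp(-ff.dh_cut / ff.ldebye) / ff.dh_cut;
      E.dh += u - uc;
      double fmag = u * (1.0 / r2 + 1.0 / (r * ff.ldebye));
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }
  return E;
}

// ---- packing from R -------------------------------------------------------

static System unpack_system(NumericMatrix coords, List sys) {
  System S;
  S.n = coords.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = coords(i, 0); S.y[i] = coords(i, 1); S.z[i] = coords(i, 2);
  }
  NumericVector sg = sys["sigma"], lm = sys["lam"], qq = sys["charge"], mm = sys["mass"];
  IntegerVector cc = sys["cls"];
  S.sigma.assign(sg.begin(), sg.end());
  S.lam.assign(lm.begin(), lm.end());
  S.q.assign(qq.begin(), qq.end());
  S.mass.assign(mm.begin(), mm.end());
  S.cls.assign(cc.begin(), cc.end());
  NumericVector bx = sys["box"];
  for (int d = 0; d < 3; ++d) S.box[d] = bx[d];
  S.wx.resize(S.n); S.wy.resize(S.n); S.wz.resize(S.n);
  IntegerMatrix B = sys["bonds"];
  NumericVector Bk = sys["bond_k"], B0 = sys["bond_b0"];
  for (int m = 0; m < B.nrow(); ++m) {
    S.bi.push_back(B(m, 0) - 1); S.bj.push_back(B(m, 1) - 1);
    S.bk.push_back(Bk[m]); S.b0.push_back(B0[m]);
  }
  IntegerMatrix EP = sys["epairs"];
  NumericVector Ek = sys["epair_k"], E0 = sys["epair_r0"];
  for (int m = 0; m < EP.nrow(); ++m) {
    S.ei.push_back(EP(m, 0) - 1); S.ej.push_back(EP(m, 1) - 1);
    S.ek.push_back(Ek[m]); S.e0.push_back(E0[m]);
  }
  S.excl.assign(S.n, std::vector<int>());
  for (size_t m = 0; m < S.bi.size(); ++m) {
    S.excl[S.bi[m]].push_back(S.bj[m]); S.excl[S.bj[m]].push_back(S.bi[m]);
  }
  for (size_t m = 0; m < S.ei.size(); ++m) {
    S.excl[S.ei[m]].push_back(S.ej[m]); S.excl[S.ej[m]].push_back(S.ei[m]);
  }
  for (int i = 0; i < S.n; ++i) std::sort(S.excl[i].begin(), S.excl[i].end());
  if (sys.containsElementNamed("tether_k") && !Rf_isNull(sys["tether_k"])) {
    NumericVector tk = sys["tether_k"];
    NumericMatrix tr = sys["tether_ref"];
    S.tk.assign(tk.begin(), tk.end());
    S.tx.resize(S.n); S.ty.resize(S.n); S.tz.resize(S.n);
    for (int i = 0; i < S.n; ++i) {
      S.tx[i] = tr(i, 0); S.ty[i] = tr(i, 1); S.tz[i] = tr(i, 2);
    }
    S.has_tether = true;
  }
  return S;
}

static FF unpack_ff(List ff) {
  FF F;
  F.eps_hps = as<double>(ff["epsilon_hps"]);
  F.hps_cut = as<double>(ff["hps_cutoff"]);
  F.eps_ev = as<double>(ff["epsilon_ev"]);
  F.kcoul = 332.0637 / as<double>(ff["dielectric"]);
  F.ldebye = as<double>(ff["debye_length"]);
  F.dh_cut = as<double>(ff["dh_cutoff"]);
  F.elec = as<bool>(ff["electrostatics"]);
  F.nonbonded = as<bool>(ff["nonbonded"]);
  F.scope = as<int>(ff["scope"]);
  return F;
}

static double short_cutoff(const System& S, const FF& F) {
  double smax = 0;
  for (int i = 0; i < S.n; ++i) smax = std::max(smax, S.sigma[i]);
  double r = 1.122462 * smax;
  if (F.nonbonded) r = std::max(r, F.hps_cut);
  return r;
}

static double elec_cutoff(const System& S, const FF& F) {
  if (!F.nonbonded || !F.elec) return 0.0;
  for (int i = 0; i < S.n; ++i) if (S.q[i] != 0.0) return F.dh_cut;
  return 0.0;
}

// [[Rcpp::export(name = ".cpp_energy_forces")]]
List cpp_energy_forces(NumericMatrix coords, List sys, List ff) {
  System S = unpack_system(coords, sys);
  rewrap(S);
  FF F = unpack_ff(ff);
  PairLists P;
  build_pairs(S, F, short_cutoff(S, F), elec_cutoff(S, F), P);
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  Energy E = compute_forces(S, F, P, fx, fy, fz);
  NumericMatrix forces(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    forces(i, 0) = fx[i]; forces(i, 1) = fy[i]; forces(i, 2) = fz[i];
  }
  return List::create(
    _["energy"] = E.total(),
    _["terms"] = NumericVector::create(
      _["bond"] = E.bond, _["elastic"] = E.elastic, _["hps"] = E.hps,
      _["ev"] = E.ev, _["dh"] = E.dh, _["tether"] = E.tether),
    _["forces"] = forces);
}

// [[Rcpp::export(name = ".cpp_langevin")]]
List cpp_langevin(NumericMatrix coords, List sys, List ff, List run) {
  System S = unpack_system(coords, sys);
  rewrap(S);
  FF F = unpack_ff(ff);
  const double dt = as<double>(run["dt"]);
  const double gamma = as<double>(run["friction"]);
  const double T = as<double>(run["temperature"]);
  const long n_steps = (long)as<double>(run["n_steps"]);
  const long save_int = (long)as<double>(run["save_interval"]);
  const std::uint64_t seed = (std::uint64_t)as<double>(run["seed"]);
  const double skin = 4.0;
  // optional shrink protocol
  double shrink_dz = 0.0, target_lz = S.box[2];
  long shrink_every = 0;
  if (run.containsElementNamed("shrink_dz")) {
    shrink_dz = as<double>(run["shrink_dz"]);
    shrink_every = (long)as<double>(run["shrink_every"]);
    target_lz = as<double>(run["target_lz"]);
  }

  RNG rng(seed);
  std::vector<double> vx(S.n), vy(S.n), vz(S.n);
  bool zero_vel = run.containsElementNamed("zero_velocities") &&
                  as<bool>(run["zero_velocities"]);
  for (int i = 0; i < S.n; ++i) {
    double sd = (T > 0 && !zero_vel) ? std::sqrt(KB * T / S.mass[i]) : 0.0;
    vx[i] = sd * rng.norm(); vy[i] = sd * rng.norm(); vz[i] = sd * rng.norm();
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  PairLists P;
  std::vector<double> x0(S.n), y0(S.n), z0(S.n); // positions at list build
  double rshort = short_cutoff(S, F) + skin;
  double relec = elec_cutoff(S, F);
  if (relec > 0) relec += skin;
  build_pairs(S, F, rshort, relec, P);
  for (int i = 0; i < S.n; ++i) { x0[i] = S.x[i]; y0[i] = S.y[i]; z0[i] = S.z[i]; }
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  compute_forces(S, F, P, fx, fy, fz);

  long n_frames = n_steps / save_int + 1;
  NumericVector frames(Dimension(S.n, 3, n_frames));
  NumericVector kinT(n_frames), steps_out(n_frames);
  NumericMatrix box_out(n_frames, 3);
  long fr = 0;
  auto record = [&](long step) {
    // layout: [bead, axis, frame]
    for (int i = 0; i < S.n; ++i) {
      frames[(long)i + (long)S.n * 0 + (long)S.n * 3 * fr] = S.x[i];
      frames[(long)i + (long)S.n * 1 + (long)S.n * 3 * fr] = S.y[i];
      frames[(long)i + (long)S.n * 2 + (long)S.n * 3 * fr] = S.z[i];
    }
    double ke = 0;
    for (int i = 0; i < S.n; ++i)
      ke += 0.5 * S.mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    kinT[fr] = 2.0 * ke / (3.0 * S.n * KB);
    steps_out[fr] = (double)step;
    box_out(fr, 0) = S.box[0]; box_out(fr, 1) = S.box[1]; box_out(fr, 2) = S.box[2];
    ++fr;
  };
  record(0);

  const double sq_kT = std::sqrt(KB * T);
  for (long step = 1; step <= n_steps; ++step) {
    // shrink event (before integration step)
    if (shrink_every > 0 && (step % shrink_every) == 0 && S.box[2] > target_lz) {
      double newLz = std::max(target_lz, S.box[2] - shrink_dz);
      double s = newLz / S.box[2];
      for (int i = 0; i < S.n; ++i) { S.z[i] *= s; z0[i] *= s; }
      S.box[2] = newLz;
      rewrap(S);
    }
    for (int i = 0; i < S.n; ++i) {
      double im = 0.5 * dt / S.mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
      double hdt = 0.5 * dt;
      S.x[i] += hdt * vx[i]; S.y[i] += hdt * vy[i]; S.z[i] += hdt * vz[i];
      S.wx[i] += hdt * vx[i]; S.wy[i] += hdt * vy[i]; S.wz[i] += hdt * vz[i];
      double sd = c2 * sq_kT / std::sqrt(S.mass[i]);
      vx[i] = c1 * vx[i] + sd * rng.norm();
      vy[i] = c1 * vy[i] + sd * rng.norm();
      vz[i] = c1 * vz[i] + sd * rng.norm();
      S.x[i] += hdt * vx[i]; S.y[i] += hdt * vy[i]; S.z[i] += hdt * vz[i];
      S.wx[i] += hdt * vx[i]; S.wy[i] += hdt * vy[i]; S.wz[i] += hdt * vz[i];
    }
    // neighbor list refresh on displacement
    double maxd2 = 0;
    for (int i = 0; i < S.n; ++i) {
      double dx = S.x[i] - x0[i], dy = S.y[i] - y0[i], dz = S.z[i] - z0[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > 0.25 * skin * skin) {
      rewrap(S);
      build_pairs(S, F, rshort, relec, P);
      for (int i = 0; i < S.n; ++i) { x0[i] = S.x[i]; y0[i] = S.y[i]; z0[i] = S.z[i]; }
    }
    Energy E = compute_forces(S, F, P, fx, fy, fz);
    for (int i = 0; i < S.n; ++i) {
      double im = 0.5 * dt / S.mass[i];
      vx[i] += im * fx[i]; vy[i] += im * fy[i]; vz[i] += im * fz[i];
    }
    if (step % save_int == 0) {
      if (!std::isfinite(E.total()) || !std::isfinite(S.x[0]))
        stop("dynamics diverged at step %ld (non-finite energy or coordinate)", step);
      record(step);
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  frames.attr("dim") = Dimension(S.n, 3, n_frames);
  NumericMatrix final_coords(S.n, 3), final_vel(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    final_coords(i, 0) = S.x[i]; final_coords(i, 1) = S.y[i]; final_coords(i, 2) = S.z[i];
    final_vel(i, 0) = vx[i]; final_vel(i, 1) = vy[i]; final_vel(i, 2) = vz[i];
  }
  return List::create(
    _["frames"] = frames, _["steps"] = steps_out, _["kinetic_temperature"] = kinT,
    _["box"] = box_out, _["final_coords"] = final_coords,
    _["final_velocities"] = final_vel);
}

// ---- analysis kernels -----------------------------------------------------

// all bead pairs within cutoff (1-based indices)
// [[Rcpp::export(name = ".cpp_pairs_within")]]
IntegerMatrix cpp_pairs_within(NumericMatrix coords, NumericVector box, double cutoff) {
  int n = coords.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = mi(coords(i, 0) - coords(j, 0), box[0]);
      double dy = mi(coords(i, 1) - coords(j, 1), box[1]);
      double dz = mi(coords(i, 2) - coords(j, 2), box[2]);
      if (dx * dx + dy * dy + dz * dz <= c2) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  IntegerMatrix out(pi.size(), 2);
  for (size_t m = 0; m < pi.size(); ++m) { out(m, 0) = pi[m]; out(m, 1) = pj[m]; }
  return out;
}

// molecule-molecule adjacency: any bead pair within cutoff
// [[Rcpp::export(name = ".cpp_mol_graph")]]
LogicalMatrix cpp_mol_graph(NumericMatrix coords, IntegerVector molid,
                            NumericVector box, double cutoff) {
  int n = coords.nrow();
  int M = 0;
  for (int i = 0; i < n; ++i) M = std::max(M, molid[i]);
  std::vector< std::vector<int> > members(M);
  for (int i = 0; i < n; ++i) members[molid[i] - 1].push_back(i);
  // molecule bounding radius around centroid (PBC-naive: use raw coords, valid
  // because bead coordinates within one molecule are stored unwrapped)
  std::vector<double> cx(M), cy(M), cz(M), rad(M, 0.0);
  for (int m = 0; m < M; ++m) {
    double sx = 0, sy = 0, sz = 0;
    for (int i : members[m]) { sx += coords(i,0); sy += coords(i,1); sz += coords(i,2); }
    int k = members[m].size();
    if (k == 0) continue;
    cx[m] = sx / k; cy[m] = sy / k; cz[m] = sz / k;
    for (int i : members[m]) {
      double dx = coords(i,0) - cx[m], dy = coords(i,1) - cy[m], dz = coords(i,2) - cz[m];
      rad[m] = std::max(rad[m], std::sqrt(dx * dx + dy * dy + dz * dz));
    }
  }
  double c2 = cutoff * cutoff;
  LogicalMatrix adj(M, M);
  for (int a = 0; a < M; ++a) {
    adj(a, a) = true;
    for (int b = a + 1; b < M; ++b) {
      if (members[a].empty() || members[b].empty()) continue;
      double dx = mi(cx[a] - cx[b], box[0]);
      double dy = mi(cy[a] - cy[b], box[1]);
      double dz = mi(cz[a] - cz[b], box[2]);
      double cd = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (cd > cutoff + rad[a] + rad[b]) continue;
      bool hit = false;
      for (size_t u = 0; u < members[a].size() && !hit; ++u)
        for (size_t v = 0; v < members[b].size(); ++v) {
          int i = members[a][u], j = members[b][v];
          double ex = mi(coords(i, 0) - coords(j, 0), box[0]);
          double ey = mi(coords(i, 1) - coords(j, 1), box[1]);
          double ez = mi(coords(i, 2) - coords(j, 2), box[2]);
          if (ex * ex + ey * ey + ez * ez <= c2) { hit = true; break; }
        }
      adj(a, b) = adj(b, a) = hit;
    }
  }
  return adj;
}

// residue x residue inter-molecular contact counts summed over unordered
// molecule pairs (both orderings accumulated -> symmetric matrix)
// [[Rcpp::export(name = ".cpp_contact_counts")]]
NumericMatrix cpp_contact_counts(NumericMatrix coords, IntegerVector molid,
                                 IntegerVector resid, NumericVector box,
                                 double cutoff, int L) {
  int n = coords.nrow();
  int M = 0;
  for (int i = 0; i < n; ++i) M = std::max(M, molid[i]);
  std::vector< std::vector<int> > members(M);
  for (int i = 0; i < n; ++i) members[molid[i] - 1].push_back(i);
  double c2 = cutoff * cutoff;
  NumericMatrix cm(L, L);
  for (int a = 0; a < M; ++a)
    for (int b = a + 1; b < M; ++b)
      for (int i : members[a])
        for (int j : members[b]) {
          double ex = mi(coords(i, 0) - coords(j, 0), box[0]);
          double ey = mi(coords(i, 1) - coords(j, 1), box[1]);
          double ez = mi(coords(i, 2) - coords(j, 2), box[2]);
          if (ex * ex + ey * ey + ez * ez <= c2) {
            int ri = resid[i] - 1, rj = resid[j] - 1;
            cm(ri, rj) += 1.0;
            cm(rj, ri) += 1.0;
          }
        }
  return cm;
}

// any bead of A within cutoff of any bead of B (placement overlap test)
// [[Rcpp::export(name = ".cpp_any_within")]]
bool cpp_any_within(NumericMatrix A, NumericMatrix B, NumericVector box, double cutoff) {
  double c2 = cutoff * cutoff;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = mi(A(i, 0) - B(j, 0), box[0]);
      double dy = mi(A(i, 1) - B(j, 1), box[1]);
      double dz = mi(A(i, 2) - B(j, 2), box[2]);
      if (dx * dx + dy * dy + dz * dz < c2) return true;
    }
  return false;
}
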