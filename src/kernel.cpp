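// Monte Carlo transport kernel.
//
// Design notes:
//  * One counter-based RNG stream per history (splitmix64 -> xoshiro256++),
//    so results are independent of execution order and two runs with the same
//    seed are correlated history-by-history (used for room-influence studies).
//  * Energies are eV throughout; lengths cm; cross sections built on a shared
//    log-energy grid per material so the R-level macroscopic_xs() and the
//    kernel see the identical interpolated values.
//  * Charged particles are not tracked (kerma approximation): their kinetic
//    energy is deposited at the interaction site and tagged "proton",
//    "neutron" or "electron" so doses can be reported per particle type or
//    grouped by primary lineage.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  bool have_cache = false;
  double cache = 0.0;

  void seed(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xA5A5A5A55A5A5A5AULL + stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    have_cache = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    if (have_cache) { have_cache = false; return cache; }
    double u1 = u01(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cache = r * std::sin(a); have_cache = true;
    return r * std::cos(a);
  }
};

// ----------------------------------------------------------- constants ----

static const double MEC2_EV   = 510998.95;     // electron rest energy, eV
static const double RE_CM     = 2.8179403e-13; // classical electron radius, cm
static const double PAIR_THR  = 1.0219979e6;   // 2 m_e c^2, eV
static const double PE_SIGMA0 = 73.9e-24;      // cm^2, O at 10 keV anchor
static const double PP_C      = 0.00288e-24;   // cm^2, pair-production scale

// Klein-Nishina total cross section per electron (cm^2), E in eV.
static double kn_total(double E) {
  double k = E / MEC2_EV;
  if (k < 1e-3)  // Thomson limit with leading corrections (exact form cancels)
    return 6.6524587e-25 * (1.0 - 2.0 * k + 5.2 * k * k);
  double a = 1.0 + 2.0 * k;
  double t1 = (1.0 + k) / (k * k) * (2.0 * (1.0 + k) / a - std::log(a) / k);
  double t2 = std::log(a) / (2.0 * k);
  double t3 = (1.0 + 3.0 * k) / (a * a);
  return 2.0 * M_PI * RE_CM * RE_CM * (t1 + t2 - t3);
}

static inline double pe_sigma(double Z, double E) { // per atom, cm^2
  double r = 1e4 / E;
  return PE_SIGMA0 * std::pow(Z / 8.0, 4.5) * r * r * r;
}

static inline double pp_sigma(double Z, double E) { // per atom, cm^2
  if (E <= PAIR_THR) return 0.0;
  double f = 1.0 - PAIR_THR / E;
  return PP_C * Z * Z * f * f * f;
}

// ------------------------------------------------------- physics tables ----

struct PhysicsDB {
  int nel = 0, nmat = 0;
  std::vector<double> Ar, A, Z, cap_th, Egam, Qcap;       // per element
  std::vector<std::vector<double>> el_logE, el_logS;      // elastic anchors
  std::vector<std::vector<int>> mat_elem;                 // element indices
  std::vector<std::vector<double>> mat_N;                 // atoms/cm^3
  std::vector<double> mat_ne;                             // electrons/cm^3
  std::vector<double> mat_capC;                           // Sig_cap = capC/sqrt(E)
  std::vector<char> mat_vac;

  // shared log-energy grid
  int ng = 1024;
  double lE0 = std::log(1e-3), lE1 = std::log(2.05e7), dlE = 0.0;
  std::vector<std::vector<double>> g_el_tot;              // per mat
  std::vector<std::vector<std::vector<double>>> g_el_i;   // per mat per elem
  std::vector<std::vector<double>> g_pc, g_pe, g_pp;      // photon channels

  double el_sigma(int e, double E) const {                // barns, log-log interp
    const std::vector<double> &xe = el_logE[e], &ye = el_logS[e];
    double lx = std::log(E);
    if (lx <= xe.front()) return std::exp(ye.front());
    if (lx >= xe.back())  return std::exp(ye.back());
    size_t hi = std::lower_bound(xe.begin(), xe.end(), lx) - xe.begin();
    size_t lo = hi - 1;
    double w = (lx - xe[lo]) / (xe[hi] - xe[lo]);
    return std::exp(ye[lo] + w * (ye[hi] - ye[lo]));
  }

  void build_grids() {
    dlE = (lE1 - lE0) / (ng - 1);
    g_el_tot.assign(nmat, std::vector<double>(ng, 0.0));
    g_el_i.assign(nmat, {});
    g_pc.assign(nmat, std::vector<double>(ng, 0.0));
    g_pe.assign(nmat, std::vector<double>(ng, 0.0));
    g_pp.assign(nmat, std::vector<double>(ng, 0.0));
    for (int m = 0; m < nmat; ++m) {
      size_t ne = mat_elem[m].size();
      g_el_i[m].assign(ne, std::vector<double>(ng, 0.0));
      for (int j = 0; j < ng; ++j) {
        double E = std::exp(lE0 + j * dlE);
        double tot = 0.0, pc = 0.0, pe = 0.0, pp = 0.0;
        for (size_t k = 0; k < ne; ++k) {
          int e = mat_elem[m][k];
          double N = mat_N[m][k];
          double s = N * el_sigma(e, E) * 1e-24;
          g_el_i[m][k][j] = s;
          tot += s;
          pe += N * pe_sigma(Z[e], E);
          pp += N * pp_sigma(Z[e], E);
        }
        pc = mat_ne[m] * kn_total(E);
        g_el_tot[m][j] = tot; g_pc[m][j] = pc; g_pe[m][j] = pe; g_pp[m][j] = pp;
      }
    }
  }

  // linear interpolation on the shared grid
  inline double ginterp(const std::vector<double> &g, double E) const {
    double x = (std::log(E) - lE0) / dlE;
    if (x <= 0.0) return g.front();
    if (x >= ng - 1) return g.back();
    int j = (int)x; double w = x - j;
    return g[j] + w * (g[j + 1] - g[j]);
  }

  inline double sig_tot_n(int m, double E) const {
    if (m < 0 || mat_vac[m]) return 0.0;
    return ginterp(g_el_tot[m], E) + mat_capC[m] / std::sqrt(E);
  }
  inline double sig_tot_g(int m, double E) const {
    if (m < 0 || mat_vac[m]) return 0.0;
    return ginterp(g_pc[m], E) + ginterp(g_pe[m], E) + ginterp(g_pp[m], E);
  }
};

static PhysicsDB build_physics(List physics) {
  PhysicsDB db;
  List elements = physics["elements"];
  List materials = physics["materials"];
  db.nel = elements.size(); db.nmat = materials.size();
  for (int i = 0; i < db.nel; ++i) {
    List e = elements[i];
    db.Ar.push_back(as<double>(e["Ar"]));
    db.A.push_back(std::round(as<double>(e["Ar"])));
    db.Z.push_back(as<double>(e["Z"]));
    db.cap_th.push_back(as<double>(e["cap_th"]));
    db.Egam.push_back(as<double>(e["Egam_eV"]));
    db.Qcap.push_back(as<double>(e["Q_eV"]));
    NumericVector lE = e["logE"], lS = e["logS"];
    db.el_logE.emplace_back(lE.begin(), lE.end());
    db.el_logS.emplace_back(lS.begin(), lS.end());
  }
  for (int m = 0; m < db.nmat; ++m) {
    List mm = materials[m];
    IntegerVector ei = mm["elem"];
    NumericVector N = mm["N"];
    db.mat_elem.emplace_back(ei.begin(), ei.end());
    db.mat_N.emplace_back(N.begin(), N.end());
    db.mat_vac.push_back(as<bool>(mm["vacuum"]) ? 1 : 0);
    double ne = 0.0, capC = 0.0;
    for (int k = 0; k < ei.size(); ++k) {
      ne += N[k] * db.Z[ei[k]];
      capC += N[k] * db.cap_th[ei[k]] * 1e-24 * std::sqrt(0.0253);
    }
    db.mat_ne.push_back(ne);
    db.mat_capC.push_back(capC);
  }
  db.build_grids();
  return db;
}

// ------------------------------------------------------------ geometry ----

static const int REG_NONE = -1;
static const int MAT_ESCAPE = -2, MAT_VOID = -1;

struct SolidGeom {
  double wx0, wx1, wyh, wzh;          // water interior
  double ox0, ox1, oyh, ozh;          // outer Perspex box
  double win_yh, win_zh, al_x1;       // entrance window / Al plates
  bool room = false;
  double rx0, rx1, ryh, rzh;          // room cavity
  double rwx0, rwx1, rwyh, rwzh;      // room outer
  double rwin_yh, rwin_zh;            // beam window in entry wall
  double wb_x0, wb_x1, wb_yh, wb_zh;  // world box
  int mat_water, mat_perspex, mat_al, mat_air, mat_concrete;
  int nch = 0; double ch_first, ch_pitch, ch_r, ch_hh;
  std::vector<double> px, py, pz;     // candidate boundary planes

  void build_planes() {
    px = {wx0, wx1, ox0, ox1, al_x1, wb_x0, wb_x1};
    py = {wyh, -wyh, oyh, -oyh, win_yh, -win_yh, wb_yh, -wb_yh};
    pz = {wzh, -wzh, ozh, -ozh, win_zh, -win_zh, wb_zh, -wb_zh};
    if (room) {
      px.insert(px.end(), {rx0, rx1, rwx0, rwx1});
      py.insert(py.end(), {ryh, -ryh, rwyh, -rwyh, rwin_yh, -rwin_yh});
      pz.insert(pz.end(), {rzh, -rzh, rwzh, -rwzh, rwin_zh, -rwin_zh});
    }
  }

  inline int mat_at(double x, double y, double z) const {
    if (x < wb_x0 || x > wb_x1 || std::fabs(y) > wb_yh || std::fabs(z) > wb_zh)
      return MAT_ESCAPE;
    if (x >= ox0 && x <= ox1 && std::fabs(y) <= oyh && std::fabs(z) <= ozh) {
      if (x >= wx0 && x <= wx1 && std::fabs(y) <= wyh && std::fabs(z) <= wzh)
        return mat_water;
      if (x < wx0 && std::fabs(y) <= win_yh && std::fabs(z) <= win_zh)
        return (x <= al_x1) ? mat_al : mat_water;
      return mat_perspex;
    }
    if (room) {
      if (x >= rx0 && x <= rx1 && std::fabs(y) <= ryh && std::fabs(z) <= rzh)
        return mat_air;
      if (x < rx0 && std::fabs(y) <= rwin_yh && std::fabs(z) <= rwin_zh)
        return mat_air;  // window channel through the entry wall
      return mat_concrete;
    }
    return MAT_VOID;
  }

  inline double dist_boundary(const double p[3], const double d[3]) const {
    double tmin = std::numeric_limits<double>::infinity();
    if (d[0] != 0.0) for (double pl : px) { double t = (pl - p[0]) / d[0]; if (t > 1e-9 && t < tmin) tmin = t; }
    if (d[1] != 0.0) for (double pl : py) { double t = (pl - p[1]) / d[1]; if (t > 1e-9 && t < tmin) tmin = t; }
    if (d[2] != 0.0) for (double pl : pz) { double t = (pl - p[2]) / d[2]; if (t > 1e-9 && t < tmin) tmin = t; }
    return tmin;
  }

  inline int chamber_at(double x, double y, double z) const {
    if (nch == 0 || std::fabs(z) > ch_hh) return REG_NONE;
    int i = (int)std::lround((x - ch_first) / ch_pitch);
    if (i < 0 || i >= nch) return REG_NONE;
    double dx = x - (ch_first + i * ch_pitch);
    return (dx * dx + y * y <= ch_r * ch_r) ? i : REG_NONE;
  }
};

struct VoxGeom {
  int nx, ny, nz;
  double dx, dy, dz, ox, oy, oz;
  const int *mat;  // 0-based material index per voxel, x fastest
  inline int idx(int ix, int iy, int iz) const { return ix + nx * (iy + ny * iz); }
};

// ------------------------------------------------------------- kinematics --

static inline void iso_dir(Rng &rng, double d[3]) {
  double mu = 2.0 * rng.u01() - 1.0;
  double ph = 6.283185307179586 * rng.u01();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  d[0] = s * std::cos(ph); d[1] = s * std::sin(ph); d[2] = mu;
}

// Elastic scattering on a free nucleus of mass number A; target at rest above
// `thermal`, free-gas Maxwellian motion (temperature kT, eV) below.
// Velocity bookkeeping uses w = v * sqrt(m_n/2) so that E = |w|^2 for the
// neutron and E_t = A |w_t|^2 for the target.
static void elastic_scatter_core(double E, double A, bool freegas, double kT,
                                 Rng &rng, double dir[3],
                                 double &E2, double &mu_lab) {
  double wn[3] = { dir[0], dir[1], dir[2] };
  double v = std::sqrt(E);
  for (int i = 0; i < 3; ++i) wn[i] *= v;
  double wt[3] = {0.0, 0.0, 0.0};
  if (freegas) {
    double sd = std::sqrt(kT / (2.0 * A));
    for (int it = 0; it < 1000; ++it) {
      for (int i = 0; i < 3; ++i) wt[i] = sd * rng.normal();
      double vr = std::sqrt((wn[0]-wt[0])*(wn[0]-wt[0]) + (wn[1]-wt[1])*(wn[1]-wt[1]) + (wn[2]-wt[2])*(wn[2]-wt[2]));
      double vt = std::sqrt(wt[0]*wt[0] + wt[1]*wt[1] + wt[2]*wt[2]);
      if (rng.u01() * (v + vt) <= vr) break;
      if (it == 999) { wt[0] = wt[1] = wt[2] = 0.0; }
    }
  }
  double vcm[3], g[3];
  for (int i = 0; i < 3; ++i) vcm[i] = (wn[i] + A * wt[i]) / (1.0 + A);
  for (int i = 0; i < 3; ++i) g[i] = wn[i] - vcm[i];
  double gmag = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
  double om[3]; iso_dir(rng, om);
  double wn2[3];
  for (int i = 0; i < 3; ++i) wn2[i] = vcm[i] + gmag * om[i];
  E2 = wn2[0]*wn2[0] + wn2[1]*wn2[1] + wn2[2]*wn2[2];
  double n2 = std::sqrt(E2);
  if (n2 > 0.0 && v > 0.0)
    mu_lab = (wn[0]*wn2[0] + wn[1]*wn2[1] + wn[2]*wn2[2]) / (v * n2);
  else mu_lab = 1.0;
  if (n2 > 0.0) for (int i = 0; i < 3; ++i) dir[i] = wn2[i] / n2;
}

// Klein-Nishina sampling of E'/E; returns x and sets cos(theta).
static double compton_sample_core(double E, Rng &rng, double &costh) {
  double k = E / MEC2_EV;
  double xmin = 1.0 / (1.0 + 2.0 * k);
  double env = xmin + 1.0 / xmin;
  double x = 1.0, f, ct = 1.0;
  for (int it = 0; it < 10000; ++it) {
    x = xmin + rng.u01() * (1.0 - xmin);
    double omc = (1.0 - x) / (k * x);  // 1 - cos(theta)
    ct = 1.0 - omc;
    double s2 = std::max(0.0, 1.0 - ct * ct);
    f = x + 1.0 / x - s2;
    if (rng.u01() * env <= f) break;
  }
  costh = ct;
  return x;
}

static inline void rotate_dir(double d[3], double mu, double phi) {
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double dz = d[2];
  if (std::fabs(dz) > 0.99999999) {
    d[0] = s * cp; d[1] = s * sp; d[2] = mu * (dz > 0 ? 1.0 : -1.0);
    return;
  }
  double den = std::sqrt(1.0 - dz * dz);
  double nd0 = mu * d[0] + s * (d[0] * dz * cp - d[1] * sp) / den;
  double nd1 = mu * d[1] + s * (d[1] * dz * cp + d[0] * sp) / den;
  double nd2 = mu * dz  - s * den * cp;
  double nn = std::sqrt(nd0*nd0 + nd1*nd1 + nd2*nd2);
  d[0] = nd0 / nn; d[1] = nd1 / nn; d[2] = nd2 / nn;
}

// ------------------------------------------------------------ tallying ----

struct HistAcc {  // per-history deposit buffer
  std::unordered_map<int, std::array<double, 4>> dep;
  std::unordered_map<int, double> flu;
  inline void add(int reg, int ch, double e) {
    if (reg < 0) return;
    auto &a = dep[reg];
    a[ch] += e;
  }
};

enum { CH_PROTON = 0, CH_NEUTRON = 1, CH_ELEC_N = 2, CH_ELEC_P = 3 };

struct Particle { int kind; double E; double p[3], d[3]; };

// --------------------------------------------------------------- kernel ----

struct RunCfg {
  long n_hist; uint64_t seed;
  double cut_n, cut_g, thermal_E, kT;
  bool score_channels, fluence, first_x, log_in_bin, woodcock;
  int flu_nb; double flu_le0, flu_dle;
};

struct Tallies {
  int nreg;
  double *sum_tot, *ssq_tot, *sum_ch, *ssq_ch, *flu_sum, *flu_ssq;
  // audit
  double max_imb = 0.0, E_src = 0.0, E_dep = 0.0, E_esc = 0.0, E_rel = 0.0;
  long n_overflow = 0;
};

// track-length fluence tally across a flight segment (solid geometry chambers)
static void tally_track_solid(const SolidGeom &G, const RunCfg &C, HistAcc &h,
                              const double p[3], const double d[3], double L,
                              double E) {
  if (G.nch == 0 || L <= 0.0) return;
  // parameter interval where |z| <= ch_hh and |y| <= ch_r
  double t0 = 0.0, t1 = L;
  for (int ax = 1; ax <= 2; ++ax) {
    double lim = (ax == 1) ? G.ch_r : G.ch_hh;
    double pp = p[ax], dd = d[ax];
    if (dd == 0.0) { if (std::fabs(pp) > lim) return; }
    else {
      double ta = (-lim - pp) / dd, tb = (lim - pp) / dd;
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      if (t0 >= t1) return;
    }
  }
  double xa = p[0] + t0 * d[0], xb = p[0] + t1 * d[0];
  if (xa > xb) std::swap(xa, xb);
  int i0 = (int)std::floor((xa - G.ch_first - G.ch_r) / G.ch_pitch);
  int i1 = (int)std::ceil((xb - G.ch_first + G.ch_r) / G.ch_pitch);
  i0 = std::max(i0, 0); i1 = std::min(i1, G.nch - 1);
  if (i0 > i1) return;
  int bin = (int)((std::log(E) - C.flu_le0) / C.flu_dle);
  if (bin < 0) bin = 0;
  if (bin >= C.flu_nb) bin = C.flu_nb - 1;
  for (int i = i0; i <= i1; ++i) {
    double xc = G.ch_first + i * G.ch_pitch;
    // (px + t dx - xc)^2 + (py + t dy)^2 = r^2
    double fx = p[0] - xc, fy = p[1];
    double a = d[0]*d[0] + d[1]*d[1];
    double b = 2.0 * (fx*d[0] + fy*d[1]);
    double c = fx*fx + fy*fy - G.ch_r*G.ch_r;
    double ta, tb;
    if (a < 1e-14) { if (c > 0.0) continue; ta = -1e30; tb = 1e30; }
    else {
      double disc = b*b - 4.0*a*c;
      if (disc <= 0.0) continue;
      double sq = std::sqrt(disc);
      ta = (-b - sq) / (2.0*a); tb = (-b + sq) / (2.0*a);
    }
    double lo = std::max(ta, t0), hi = std::min(tb, t1);
    if (hi > lo) h.flu[i * C.flu_nb + bin] += (hi - lo);
  }
}

// Fly a particle until collision or escape.  Returns 1 if collided (pos and
// mat set), 0 if escaped.  tau is the sampled optical depth.
static int fly_solid(const SolidGeom &G, const PhysicsDB &db, const RunCfg &C,
                     HistAcc &h, Particle &P, double tau, int &mat_out,
                     bool tally_flu) {
  for (int step = 0; step < 100000; ++step) {
    double probe[3] = { P.p[0] + P.d[0] * 1e-7, P.p[1] + P.d[1] * 1e-7, P.p[2] + P.d[2] * 1e-7 };
    int m = G.mat_at(probe[0], probe[1], probe[2]);
    if (m == MAT_ESCAPE) return 0;
    double tb = G.dist_boundary(P.p, P.d);
    if (!std::isfinite(tb)) return 0;
    double Sig = (P.kind == 0) ? db.sig_tot_n(m, P.E) : db.sig_tot_g(m, P.E);
    if (Sig > 0.0 && tau < Sig * tb) {
      double t = tau / Sig;
      if (tally_flu) tally_track_solid(G, C, h, P.p, P.d, t, P.E);
      for (int i = 0; i < 3; ++i) P.p[i] += P.d[i] * t;
      mat_out = m;
      return 1;
    }
    if (tally_flu && Sig >= 0.0) tally_track_solid(G, C, h, P.p, P.d, tb, P.E);
    tau -= Sig * tb;
    for (int i = 0; i < 3; ++i) P.p[i] += P.d[i] * (tb + 1e-7);
  }
  return 0;
}

// Woodcock (delta) tracking through a voxel grid: flights are sampled with a
// grid-wide majorant cross section and collisions accepted with probability
// Sigma(local)/Sigma_majorant, so no voxel-boundary bookkeeping is needed.
static int fly_voxel_woodcock(const VoxGeom &G, const PhysicsDB &db,
                              const std::vector<int> &mats_present,
                              Particle &P, Rng &rng, int &mat_out,
                              int &reg_out) {
  double sig_maj = 0.0;
  for (int m : mats_present) {
    double s = (P.kind == 0) ? db.sig_tot_n(m, P.E) : db.sig_tot_g(m, P.E);
    if (s > sig_maj) sig_maj = s;
  }
  double x0 = G.ox, x1 = G.ox + G.nx * G.dx;
  double y0 = G.oy, y1 = G.oy + G.ny * G.dy;
  double z0 = G.oz, z1 = G.oz + G.nz * G.dz;
  // advance to the grid if outside
  double tin = 0.0, tout = std::numeric_limits<double>::infinity();
  const double lo[3] = {x0, y0, z0}, hi[3] = {x1, y1, z1};
  for (int ax = 0; ax < 3; ++ax) {
    if (P.d[ax] == 0.0) {
      if (P.p[ax] < lo[ax] || P.p[ax] > hi[ax]) return 0;
    } else {
      double ta = (lo[ax] - P.p[ax]) / P.d[ax], tb = (hi[ax] - P.p[ax]) / P.d[ax];
      if (ta > tb) std::swap(ta, tb);
      tin = std::max(tin, ta); tout = std::min(tout, tb);
    }
  }
  if (tout <= tin || sig_maj <= 0.0) return 0;
  double t = std::max(tin, 0.0) + 1e-9;
  for (int it = 0; it < 10000000; ++it) {
    t += -std::log(rng.u01()) / sig_maj;
    if (t >= tout) return 0;
    double px = P.p[0] + t * P.d[0], py = P.p[1] + t * P.d[1], pz = P.p[2] + t * P.d[2];
    int ix = (int)((px - x0) / G.dx), iy = (int)((py - y0) / G.dy), iz = (int)((pz - z0) / G.dz);
    if (ix < 0 || ix >= G.nx || iy < 0 || iy >= G.ny || iz < 0 || iz >= G.nz)
      return 0;
    int vi = G.idx(ix, iy, iz);
    int m = G.mat[vi];
    double s = (P.kind == 0) ? db.sig_tot_n(m, P.E) : db.sig_tot_g(m, P.E);
    if (rng.u01() * sig_maj <= s) {
      for (int i = 0; i < 3; ++i) P.p[i] += P.d[i] * t;
      mat_out = m; reg_out = vi;
      return 1;
    }
  }
  return 0;
}

static int fly_voxel(const VoxGeom &G, const PhysicsDB &db, Particle &P,
                     double tau, int &mat_out, int &reg_out) {
  // enter the grid if outside
  double x0 = G.ox, x1 = G.ox + G.nx * G.dx;
  double y0 = G.oy, y1 = G.oy + G.ny * G.dy;
  double z0 = G.oz, z1 = G.oz + G.nz * G.dz;
  double tin = 0.0, tout = std::numeric_limits<double>::infinity();
  const double lo[3] = {x0, y0, z0}, hi[3] = {x1, y1, z1};
  for (int ax = 0; ax < 3; ++ax) {
    if (P.d[ax] == 0.0) {
      if (P.p[ax] < lo[ax] || P.p[ax] > hi[ax]) return 0;
    } else {
      double ta = (lo[ax] - P.p[ax]) / P.d[ax], tb = (hi[ax] - P.p[ax]) / P.d[ax];
      if (ta > tb) std::swap(ta, tb);
      tin = std::max(tin, ta); tout = std::min(tout, tb);
    }
  }
  if (tout <= tin) return 0;
  double tcur = std::max(tin, 0.0) + 1e-9;
  double px = P.p[0] + tcur * P.d[0], py = P.p[1] + tcur * P.d[1], pz = P.p[2] + tcur * P.d[2];
  int ix = (int)((px - x0) / G.dx), iy = (int)((py - y0) / G.dy), iz = (int)((pz - z0) / G.dz);
  ix = std::min(std::max(ix, 0), G.nx - 1);
  iy = std::min(std::max(iy, 0), G.ny - 1);
  iz = std::min(std::max(iz, 0), G.nz - 1);
  int sx = (P.d[0] > 0) - (P.d[0] < 0), sy = (P.d[1] > 0) - (P.d[1] < 0), sz = (P.d[2] > 0) - (P.d[2] < 0);
  double inf = std::numeric_limits<double>::infinity();
  double tdx = sx ? G.dx / std::fabs(P.d[0]) : inf;
  double tdy = sy ? G.dy / std::fabs(P.d[1]) : inf;
  double tdz = sz ? G.dz / std::fabs(P.d[2]) : inf;
  double tmx = sx ? ((x0 + (ix + (sx > 0)) * G.dx) - P.p[0]) / P.d[0] : inf;
  double tmy = sy ? ((y0 + (iy + (sy > 0)) * G.dy) - P.p[1]) / P.d[1] : inf;
  double tmz = sz ? ((z0 + (iz + (sz > 0)) * G.dz) - P.p[2]) / P.d[2] : inf;

  while (true) {
    int vi = G.idx(ix, iy, iz);
    int m = G.mat[vi];
    double tnext = std::min(tmx, std::min(tmy, tmz));
    double seg = tnext - tcur;
    if (seg < 0.0) seg = 0.0;
    double Sig = (P.kind == 0) ? db.sig_tot_n(m, P.E) : db.sig_tot_g(m, P.E);
    if (Sig > 0.0 && tau < Sig * seg) {
      double t = tcur + tau / Sig;
      for (int i = 0; i < 3; ++i) P.p[i] += P.d[i] * t;
      mat_out = m; reg_out = vi;
      return 1;
    }
    tau -= Sig * seg;
    tcur = tnext;
    if (tmx <= tmy && tmx <= tmz) { ix += sx; tmx += tdx; if (ix < 0 || ix >= G.nx) break; }
    else if (tmy <= tmz)          { iy += sy; tmy += tdy; if (iy < 0 || iy >= G.ny) break; }
    else                          { iz += sz; tmz += tdz; if (iz < 0 || iz >= G.nz) break; }
  }
  // escaped the grid
  for (int i = 0; i < 3; ++i) P.p[i] += P.d[i] * (tcur + 1e-7);
  return 0;
}

// ---------------------------------------------------------- main driver ----

// [[Rcpp::export]]
List cpp_run_transport(List physics, List geometry, List beam, List config) {
  PhysicsDB db = build_physics(physics);

  std::string gtype = as<std::string>(geometry["type"]);
  SolidGeom SG; VoxGeom VG;
  IntegerVector vox_mats;
  int nreg;
  if (gtype == "solid") {
    List g = geometry;
    SG.wx0 = g["wx0"]; SG.wx1 = g["wx1"]; SG.wyh = g["wyh"]; SG.wzh = g["wzh"];
    SG.ox0 = g["ox0"]; SG.ox1 = g["ox1"]; SG.oyh = g["oyh"]; SG.ozh = g["ozh"];
    SG.win_yh = g["win_yh"]; SG.win_zh = g["win_zh"]; SG.al_x1 = g["al_x1"];
    SG.room = as<bool>(g["room"]);
    if (SG.room) {
      SG.rx0 = g["rx0"]; SG.rx1 = g["rx1"]; SG.ryh = g["ryh"]; SG.rzh = g["rzh"];
      SG.rwx0 = g["rwx0"]; SG.rwx1 = g["rwx1"]; SG.rwyh = g["rwyh"]; SG.rwzh = g["rwzh"];
      SG.rwin_yh = g["rwin_yh"]; SG.rwin_zh = g["rwin_zh"];
    }
    SG.wb_x0 = g["wb_x0"]; SG.wb_x1 = g["wb_x1"]; SG.wb_yh = g["wb_yh"]; SG.wb_zh = g["wb_zh"];
    SG.mat_water = as<int>(g["mat_water"]); SG.mat_perspex = as<int>(g["mat_perspex"]);
    SG.mat_al = as<int>(g["mat_al"]); SG.mat_air = as<int>(g["mat_air"]);
    SG.mat_concrete = as<int>(g["mat_concrete"]);
    SG.nch = as<int>(g["nch"]); SG.ch_first = g["ch_first"]; SG.ch_pitch = g["ch_pitch"];
    SG.ch_r = g["ch_r"]; SG.ch_hh = as<double>(g["ch_height"]) / 2.0;
    SG.build_planes();
    nreg = SG.nch;
  } else {
    IntegerVector dim = geometry["dim"];
    NumericVector vs = geometry["voxsize"], orc = geometry["origin"];
    vox_mats = geometry["mats"];
    VG.nx = dim[0]; VG.ny = dim[1]; VG.nz = dim[2];
    VG.dx = vs[0]; VG.dy = vs[1]; VG.dz = vs[2];
    VG.ox = orc[0]; VG.oy = orc[1]; VG.oz = orc[2];
    VG.mat = vox_mats.begin();
    nreg = VG.nx * VG.ny * VG.nz;
  }

  RunCfg C;
  C.n_hist = (long)as<double>(config["n_histories"]);
  C.seed = (uint64_t)as<double>(config["seed"]);
  C.cut_n = config["cut_n"]; C.cut_g = config["cut_g"];
  C.thermal_E = config["thermal_E"]; C.kT = config["kT"];
  C.score_channels = as<bool>(config["score_channels"]);
  C.fluence = as<bool>(config["fluence"]) && gtype == "solid";
  C.first_x = as<bool>(config["first_x"]);
  C.log_in_bin = as<bool>(config["log_in_bin"]);
  C.woodcock = as<bool>(config["woodcock"]) && gtype == "voxel";
  std::vector<int> mats_present;
  if (C.woodcock) {
    std::vector<char> seen(db.nmat, 0);
    for (int i = 0; i < vox_mats.size(); ++i) seen[vox_mats[i]] = 1;
    for (int m = 0; m < db.nmat; ++m) if (seen[m]) mats_present.push_back(m);
  }
  if (C.fluence) {
    C.flu_nb = as<int>(config["flu_nbins"]);
    double e0 = config["flu_emin"], e1 = config["flu_emax"];
    C.flu_le0 = std::log(e0);
    C.flu_dle = (std::log(e1) - C.flu_le0) / C.flu_nb;
  } else { C.flu_nb = 0; C.flu_le0 = 0; C.flu_dle = 1; }

  int kind = as<int>(beam["kind"]);
  double bx0 = beam["x0"], bcy = beam["cy"], bcz = beam["cz"];
  double bw = beam["width"], bh = beam["height"];
  NumericVector edges = beam["edges"], cum = beam["cum"];
  int nb = cum.size();

  NumericVector sum_tot(nreg), ssq_tot(nreg);
  NumericVector sum_ch, ssq_ch;
  if (C.score_channels) { sum_ch = NumericVector(nreg * 4); ssq_ch = NumericVector(nreg * 4); }
  NumericVector flu_sum, flu_ssq;
  if (C.fluence) { flu_sum = NumericVector(nreg * C.flu_nb); flu_ssq = NumericVector(nreg * C.flu_nb); }
  NumericVector first_x;
  if (C.first_x) { first_x = NumericVector(C.n_hist, NA_REAL); }

  Tallies T; T.nreg = nreg;
  Rng rng;
  HistAcc h;
  std::vector<Particle> stack;
  stack.reserve(64);

  for (long hist = 0; hist < C.n_hist; ++hist) {
    if ((hist & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    rng.seed(C.seed, (uint64_t)hist);
    h.dep.clear(); h.flu.clear();

    // --- sample primary
    Particle prim;
    prim.kind = kind;
    double u = rng.u01();
    int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (b >= nb) b = nb - 1;
    double lo = edges[b], hi = edges[b + 1], uu = rng.u01();
    prim.E = C.log_in_bin ? lo * std::pow(hi / lo, uu) : lo + uu * (hi - lo);
    prim.p[0] = bx0;
    prim.p[1] = bcy + (rng.u01() - 0.5) * bw;
    prim.p[2] = bcz + (rng.u01() - 0.5) * bh;
    prim.d[0] = 1.0; prim.d[1] = 0.0; prim.d[2] = 0.0;

    double E_src = prim.E, E_rel = 0.0, E_dep = 0.0, E_esc = 0.0;
    bool prim_first_done = false;

    stack.clear();
    stack.push_back(prim);

    while (!stack.empty()) {
      Particle P = stack.back(); stack.pop_back();
      bool is_primary_particle = stack.empty() && !prim_first_done && P.kind == kind;
      // NOTE: the primary is transported first (LIFO, pushed first & alone)

      for (int coll = 0; coll < 100000; ++coll) {
        double cut = (P.kind == 0) ? C.cut_n : C.cut_g;
        if (P.E < cut) {
          int reg;
          if (gtype == "solid") { reg = SG.chamber_at(P.p[0], P.p[1], P.p[2]); }
          else {
            int ix = (int)((P.p[0] - VG.ox) / VG.dx), iy = (int)((P.p[1] - VG.oy) / VG.dy), iz = (int)((P.p[2] - VG.oz) / VG.dz);
            reg = (ix >= 0 && ix < VG.nx && iy >= 0 && iy < VG.ny && iz >= 0 && iz < VG.nz) ? VG.idx(ix, iy, iz) : REG_NONE;
          }
          int ch = (P.kind == 0) ? CH_NEUTRON : (kind == 0 ? CH_ELEC_N : CH_ELEC_P);
          h.add(reg, ch, P.E);
          E_dep += P.E;
          break;
        }
        int mat = -1, reg = REG_NONE;
        int hitres;
        if (gtype == "solid") {
          double tau = -std::log(rng.u01());
          hitres = fly_solid(SG, db, C, h, P, tau, mat, C.fluence && P.kind == 0);
          if (hitres) reg = SG.chamber_at(P.p[0], P.p[1], P.p[2]);
        } else if (C.woodcock) {
          hitres = fly_voxel_woodcock(VG, db, mats_present, P, rng, mat, reg);
        } else {
          double tau = -std::log(rng.u01());
          hitres = fly_voxel(VG, db, P, tau, mat, reg);
        }
        if (!hitres) { E_esc += P.E; break; }

        if (is_primary_particle && !prim_first_done) {
          prim_first_done = true;
          if (C.first_x) first_x[hist] = P.p[0];
        }

        if (P.kind == 0) {
          // ---- neutron collision: pick element & channel
          size_t ne = db.mat_elem[mat].size();
          double tot = 0.0;
          double rates[32];
          for (size_t kx = 0; kx < ne; ++kx) {
            int e = db.mat_elem[mat][kx];
            double sel = db.ginterp(db.g_el_i[mat][kx], P.E);
            double sca = db.mat_N[mat][kx] * db.cap_th[e] * 1e-24 * std::sqrt(0.0253 / P.E);
            rates[2 * kx] = sel; rates[2 * kx + 1] = sca;
            tot += sel + sca;
          }
          double r = rng.u01() * tot;
          size_t pick = 0;
          for (; pick < 2 * ne - 1; ++pick) { r -= rates[pick]; if (r <= 0.0) break; }
          size_t kx = pick / 2; int e = db.mat_elem[mat][kx];
          if (pick % 2 == 0) {  // elastic
            double E2, mu;
            bool fg = P.E < C.thermal_E;
            elastic_scatter_core(P.E, db.A[e], fg, C.kT, rng, P.d, E2, mu);
            double d = P.E - E2;
            if (d > 0.0) {
              int ch = (db.A[e] < 1.5) ? CH_PROTON : CH_NEUTRON;
              h.add(reg, ch, d); E_dep += d;
            } else { E_rel += -d; }  // thermal up-scatter: energy from the bath
            P.E = E2;
            if (P.E <= 0.0) { break; }
          } else {              // radiative capture
            if (db.Egam[e] > 0.0) {
              Particle ph2; ph2.kind = 1; ph2.E = db.Egam[e];
              for (int i = 0; i < 3; ++i) ph2.p[i] = P.p[i];
              iso_dir(rng, ph2.d);
              if (stack.size() < 4096) stack.push_back(ph2);
              E_rel += db.Egam[e];
              h.add(reg, CH_NEUTRON, P.E); E_dep += P.E;
            } else {
              h.add(reg, CH_NEUTRON, P.E + db.Qcap[e]);
              E_dep += P.E + db.Qcap[e];
              E_rel += db.Qcap[e];
            }
            break;  // neutron absorbed
          }
        } else {
          // ---- photon collision
          double sc = db.ginterp(db.g_pc[mat], P.E);
          double spe = db.ginterp(db.g_pe[mat], P.E);
          double spp = db.ginterp(db.g_pp[mat], P.E);
          double r = rng.u01() * (sc + spe + spp);
          int ech = (kind == 0) ? CH_ELEC_N : CH_ELEC_P;
          if (r <= sc) {  // Compton
            double ct;
            double x = compton_sample_core(P.E, rng, ct);
            double T = P.E * (1.0 - x);
            h.add(reg, ech, T); E_dep += T;
            P.E *= x;
            rotate_dir(P.d, ct, 6.283185307179586 * rng.u01());
          } else if (r <= sc + spe) {  // photoelectric
            h.add(reg, ech, P.E); E_dep += P.E;
            break;
          } else {  // pair production
            double T = P.E - PAIR_THR;
            h.add(reg, ech, T); E_dep += T;
            double ad[3]; iso_dir(rng, ad);
            Particle g1, g2;
            g1.kind = g2.kind = 1;
            g1.E = g2.E = PAIR_THR / 2.0;
            for (int i = 0; i < 3; ++i) { g1.p[i] = g2.p[i] = P.p[i]; g1.d[i] = ad[i]; g2.d[i] = -ad[i]; }
            if (stack.size() < 4094) { stack.push_back(g1); stack.push_back(g2); }
            break;
          }
        }
        if (coll == 99999) T.n_overflow++;
      }
    }

    // --- flush per-history accumulators
    for (auto &kv : h.dep) {
      int reg = kv.first;
      double tot = kv.second[0] + kv.second[1] + kv.second[2] + kv.second[3];
      sum_tot[reg] += tot; ssq_tot[reg] += tot * tot;
      if (C.score_channels) {
        for (int c = 0; c < 4; ++c) {
          double v = kv.second[c];
          if (v != 0.0) { sum_ch[reg * 4 + c] += v; ssq_ch[reg * 4 + c] += v * v; }
        }
      }
    }
    if (C.fluence) {
      for (auto &kv : h.flu) { flu_sum[kv.first] += kv.second; flu_ssq[kv.first] += kv.second * kv.second; }
    }
    double in = E_src + E_rel, out = E_dep + E_esc;
    double imb = std::fabs(in - out) / std::max(in, 1e-300);
    if (imb > T.max_imb) T.max_imb = imb;
    T.E_src += E_src; T.E_rel += E_rel; T.E_dep += E_dep; T.E_esc += E_esc;
  }

  List audit = List::create(
    _["max_rel_imbalance"] = T.max_imb,
    _["E_source_eV"] = T.E_src, _["E_released_eV"] = T.E_rel,
    _["E_deposited_eV"] = T.E_dep, _["E_escaped_eV"] = T.E_esc,
    _["n_overflow"] = (double)T.n_overflow);

  List out = List::create(
    _["sum_tot"] = sum_tot, _["ssq_tot"] = ssq_tot,
    _["sum_ch"] = C.score_channels ? (SEXP)sum_ch : R_NilValue,
    _["ssq_ch"] = C.score_channels ? (SEXP)ssq_ch : R_NilValue,
    _["flu_sum"] = C.fluence ? (SEXP)flu_sum : R_NilValue,
    _["flu_ssq"] = C.fluence ? (SEXP)flu_ssq : R_NilValue,
    _["first_x"] = C.first_x ? (SEXP)first_x : R_NilValue,
    _["n_histories"] = (double)C.n_hist,
    _["nreg"] = nreg,
    _["audit"] = audit);
  return out;
}

// ------------------------------------------------ exported test surface ----

// [[Rcpp::export]]
NumericVector cpp_kn_total(NumericVector E_eV) {
  NumericVector out(E_eV.size());
  for (int i = 0; i < E_eV.size(); ++i) out[i] = kn_total(E_eV[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_elastic(double E_eV, double A, int n, double seed,
                                 bool freegas, double kT_eV) {
  NumericMatrix out(n, 2);
  Rng rng;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double d[3] = {1.0, 0.0, 0.0};
    double E2, mu;
    elastic_scatter_core(E_eV, A, freegas, kT_eV, rng, d, E2, mu);
    out(i, 0) = E2; out(i, 1) = mu;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E_eV, int n, double seed) {
  NumericMatrix out(n, 3);  // E', T, cos(theta)
  Rng rng;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double ct;
    double x = compton_sample_core(E_eV, rng, ct);
    out(i, 0) = E_eV * x; out(i, 1) = E_eV * (1.0 - x); out(i, 2) = ct;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_iso_dirs(int n, double seed) {
  NumericMatrix out(n, 3);
  Rng rng;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double d[3]; iso_dir(rng, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_traverse(NumericVector origin, NumericVector dir, IntegerVector dim,
                  NumericVector voxsize, NumericVector gorigin) {
  // Amanatides-Woo grid walk; returns 0-based voxel indices and chord lengths.
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (nrm <= 0) stop("zero direction");
  for (int i = 0; i < 3; ++i) d[i] /= nrm;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = voxsize[0], dy = voxsize[1], dz = voxsize[2];
  double x0 = gorigin[0], y0 = gorigin[1], z0 = gorigin[2];
  const double lo[3] = {x0, y0, z0};
  const double hi[3] = {x0 + nx * dx, y0 + ny * dy, z0 + nz * dz};
  double tin = 0.0, tout = std::numeric_limits<double>::infinity();
  for (int ax = 0; ax < 3; ++ax) {
    if (d[ax] == 0.0) {
      if (p[ax] <= lo[ax] || p[ax] >= hi[ax]) tout = -1.0;
    } else {
      double ta = (lo[ax] - p[ax]) / d[ax], tb = (hi[ax] - p[ax]) / d[ax];
      if (ta > tb) std::swap(ta, tb);
      tin = std::max(tin, ta); tout = std::min(tout, tb);
    }
  }
  std::vector<int> vix, viy, viz; std::vector<double> len;
  if (tout > tin) {
    double tcur = std::max(tin, 0.0);
    double eps = 1e-12 * std::max(1.0, tout);
    double sx0 = p[0] + (tcur + eps) * d[0], sy0 = p[1] + (tcur + eps) * d[1], sz0 = p[2] + (tcur + eps) * d[2];
    int ix = std::min(std::max((int)((sx0 - x0) / dx), 0), nx - 1);
    int iy = std::min(std::max((int)((sy0 - y0) / dy), 0), ny - 1);
    int iz = std::min(std::max((int)((sz0 - z0) / dz), 0), nz - 1);
    int sx = (d[0] > 0) - (d[0] < 0), sy = (d[1] > 0) - (d[1] < 0), sz = (d[2] > 0) - (d[2] < 0);
    double inf = std::numeric_limits<double>::infinity();
    double tdx = sx ? dx / std::fabs(d[0]) : inf;
    double tdy = sy ? dy / std::fabs(d[1]) : inf;
    double tdz = sz ? dz / std::fabs(d[2]) : inf;
    double tmx = sx ? ((x0 + (ix + (sx > 0)) * dx) - p[0]) / d[0] : inf;
    double tmy = sy ? ((y0 + (iy + (sy > 0)) * dy) - p[1]) / d[1] : inf;
    double tmz = sz ? ((z0 + (iz + (sz > 0)) * dz) - p[2]) / d[2] : inf;
    while (tcur < tout - 1e-12) {
      double tnext = std::min(std::min(tmx, tmy), std::min(tmz, tout));
      vix.push_back(ix); viy.push_back(iy); viz.push_back(iz);
      len.push_back(tnext - tcur);
      tcur = tnext;
      if (tcur >= tout - 1e-12) break;
      if (tmx <= tmy && tmx <= tmz) { ix += sx; tmx += tdx; if (ix < 0 || ix >= nx) break; }
      else if (tmy <= tmz)          { iy += sy; tmy += tdy; if (iy < 0 || iy >= ny) break; }
      else                          { iz += sz; tmz += tdz; if (iz < 0 || iz >= nz) break; }
    }
  }
  return List::create(_["ix"] = wrap(vix), _["iy"] = wrap(viy), _["iz"] = wrap(viz),
                      _["length"] = wrap(len));
}

// [[Rcpp::export]]
List cpp_macro_xs(List physics, int mat_idx0, double E_eV, int kind) {
  PhysicsDB db = build_physics(physics);
  int m = mat_idx0;
  if (kind == 0) {
    double el = db.ginterp(db.g_el_tot[m], E_eV);
    double cap = db.mat_vac[m] ? 0.0 : db.mat_capC[m] / std::sqrt(E_eV);
    if (db.mat_vac[m]) el = 0.0;
    return List::create(_["elastic"] = el, _["capture"] = cap, _["total"] = el + cap);
  }
  double sc = db.mat_vac[m] ? 0.0 : db.ginterp(db.g_pc[m], E_eV);
  double spe = db.mat_vac[m] ? 0.0 : db.ginterp(db.g_pe[m], E_eV);
  double spp = db.mat_vac[m] ? 0.0 : db.ginterp(db.g_pp[m], E_eV);
  return List::create(_["compton"] = sc, _["photoelectric"] = spe,
                      _["pair"] = spp, _["total"] = sc + spe + spp);
}
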