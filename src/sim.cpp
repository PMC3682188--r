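// Coarse-grained membrane simulator core.
//
// Particles: single-site anisotropic (Gay-Berne) lipids carrying a
// head->tail director, plus isotropic protein CG sites connected by
// harmonic springs within each domain.  Units: nm, ps, kcal/mol, K.
//
// Lipid-lipid: Gay-Berne with an added head-tail asymmetry term odd under
// director flip.  Protein-lipid / protein-protein: tabulated 12-6 LJ
// (attractive channels) or WCA excluded volume.  Dynamics: velocity Verlet
// with torque integration for directors (linear-rotor model) and a
// Nose-Hoover thermostat (single chain).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>

using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/(mol K)

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct GBParamsC {
  double sigma0, eps0, chi, chip, mu, nu, eps_hb;
  double rho_sw, rho_cut; // switch bounds in reduced separation rho
  double max_range;       // largest real-space interaction distance
};

// x^p for the common integer exponents, falling back to std::pow
static inline double dpow(double x, double p) {
  if (p == 2.0) return x * x;
  if (p == 1.0) return x;
  return std::pow(x, p);
}

// quintic switching function: 1 below rsw, 0 above rcut, C2-smooth
static inline void switch_fn(double r, double rsw, double rcut, double& S, double& dS) {
  if (r <= rsw) { S = 1.0; dS = 0.0; return; }
  if (r >= rcut) { S = 0.0; dS = 0.0; return; }
  double t = (r - rsw) / (rcut - rsw);
  double t2 = t * t, t3 = t2 * t;
  S = 1.0 - t3 * (10.0 - 15.0 * t + 6.0 * t2);
  dS = -30.0 * t2 * (1.0 - 2.0 * t + t2) / (rcut - rsw);
}

// Gay-Berne pair interaction + head-tail asymmetry, smoothly truncated in
// the reduced separation rho = (r - sigma(orientations) + sigma0)/sigma0
// (orientation-dependent real-space cutoff).
// s = x_i - x_j (minimum image already applied).  Outputs: energy,
// force on i (fi), and orientation gradients gi = dU/du_i, gj = dU/du_j.
static double gb_pair(const Vec3& s, const Vec3& ui, const Vec3& uj,
                      const GBParamsC& p, Vec3& fi, Vec3& gi, Vec3& gj) {
  double r = norm(s);
  fi = Vec3(); gi = Vec3(); gj = Vec3();
  if (r >= p.max_range) return 0.0;
  if (r < 1e-10) Rcpp::stop("Zero separation between lipids (overlap).");
  Vec3 rh = (1.0 / r) * s;
  double a = dot(ui, rh), b = dot(uj, rh), c = dot(ui, uj);
  double apb = a + b, amb = a - b;

  double hp = 1.0 + p.chi * c, hm = 1.0 - p.chi * c;
  double Q = 0.5 * p.chi * (apb * apb / hp + amb * amb / hm);
  double sig = p.sigma0 / std::sqrt(1.0 - Q);

  double rho = (r - sig + p.sigma0) / p.sigma0;
  if (rho >= p.rho_cut) return 0.0; // outside the orientation-dependent cutoff
  if (rho < 0.05) rho = 0.05; // clamped hard-core; divergence guard handles pathologies

  double dQda = p.chi * (apb / hp + amb / hm);
  double dQdb = p.chi * (apb / hp - amb / hm);
  double dQdc = -0.5 * p.chi * p.chi * (apb * apb / (hp * hp) - amb * amb / (hm * hm));
  double dsig_fac = 0.5 * sig * sig * sig / (p.sigma0 * p.sigma0);

  double hp2 = 1.0 + p.chip * c, hm2 = 1.0 - p.chip * c;
  double Q2 = 0.5 * p.chip * (apb * apb / hp2 + amb * amb / hm2);
  double eps2 = 1.0 - Q2;
  double dQ2da = p.chip * (apb / hp2 + amb / hm2);
  double dQ2db = p.chip * (apb / hp2 - amb / hm2);
  double dQ2dc = -0.5 * p.chip * p.chip * (apb * apb / (hp2 * hp2) - amb * amb / (hm2 * hm2));
  double eps1s = 1.0 / (1.0 - p.chi * p.chi * c * c); // eps1^2
  double eps = p.eps0 * dpow(std::sqrt(eps1s), p.nu) * dpow(eps2, p.mu);

  double ir = 1.0 / rho;
  double r6 = ir * ir * ir; r6 = r6 * r6;
  double r12 = r6 * r6;

  // energy as U(rho, a, b, c) = S(rho) [4 eps (rho^-12 - rho^-6)
  //                                     + eps_hb (a - b) rho^-6]
  double core = 4.0 * eps * (r12 - r6) + p.eps_hb * amb * r6;
  double S, dS;
  switch_fn(rho, p.rho_sw, p.rho_cut, S, dS);
  double Utot = core * S;

  double dcore_drho = (4.0 * eps * (6.0 * r6 - 12.0 * r12) - 6.0 * p.eps_hb * amb * r6) * ir;
  double dU_drho = dcore_drho * S + core * dS;

  double lj = 4.0 * (r12 - r6);
  double deps_da = -eps * p.mu * dQ2da / eps2;
  double deps_db = -eps * p.mu * dQ2db / eps2;
  double deps_dc = eps * (p.nu * p.chi * p.chi * c * eps1s - p.mu * dQ2dc / eps2);

  // partials at fixed rho, then the chain through rho(a,b,c) via sigma
  double drho_fac = -dsig_fac / p.sigma0; // drho/dx = drho_fac * dQdx
  double dU_da = S * (deps_da * lj + p.eps_hb * r6) + dU_drho * drho_fac * dQda;
  double dU_db = S * (deps_db * lj - p.eps_hb * r6) + dU_drho * drho_fac * dQdb;
  double dU_dc = S * (deps_dc * lj) + dU_drho * drho_fac * dQdc;
  double dU_dr = dU_drho / p.sigma0;

  // fi = -grad_{x_i} U ; grad_s a = (ui - a rh)/r, etc.
  Vec3 grad = dU_dr * rh + (dU_da / r) * (ui - a * rh) + (dU_db / r) * (uj - b * rh);
  fi = -1.0 * grad;
  gi = dU_da * rh + dU_dc * uj;
  gj = dU_db * rh + dU_dc * ui;
  return Utot;
}

// 12-6 LJ, switched, or WCA if attractive=false.  Returns energy; adds
// -dU/dx_i to fi (force factor applied outside via direction).
static double lj_pair(double r, double eps, double sigma, bool attractive,
                      double rsw, double rcut, double& fmag /* = -dU/dr */) {
  fmag = 0.0;
  if (r < 1e-10) Rcpp::stop("Zero separation in LJ pair (overlap).");
  if (attractive) {
    if (r >= rcut) return 0.0;
    double sr = sigma / r;
    double sr6 = sr * sr * sr; sr6 = sr6 * sr6;
    double sr12 = sr6 * sr6;
    double U = 4.0 * eps * (sr12 - sr6);
    double dU_dr = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
    double S, dS;
    switch_fn(r, rsw, rcut, S, dS);
    fmag = -(dU_dr * S + U * dS);
    return U * S;
  } else {
    double rmin = sigma * 1.1224620483089301; // 2^(1/6) sigma
    if (r >= rmin) return 0.0;
    double sr = sigma / r;
    double sr6 = sr * sr * sr; sr6 = sr6 * sr6;
    double sr12 = sr6 * sr6;
    double U = 4.0 * eps * (sr12 - sr6) + eps;
    fmag = -4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
    return U;
  }
}

struct System {
  int n_lip, n_pro, n;
  std::vector<Vec3> pos, dir, vel, ang; // ang: director angular velocity
  std::vector<int> pip2;   // n_lip
  std::vector<int> ptype;  // n_pro (0 generic, 1 H0, 2 patch, 3 R114, 4 pocket)
  std::vector<int> domain; // n_pro
  std::vector<double> spr_k, spr_r0;
  std::vector<int> spr_i, spr_j;
  double box[3];
  int periodic[3];
  GBParamsC gb;
  double mass_l, mass_p, inertia;
  double lj_rcut, lj_rsw, eps_rep;
  double pl_eps[7], pl_sigma[7];
  double pp_eps[7][7], pp_sigma[7][7];
  // neighbor list
  std::vector<int> nl_i, nl_j;
  std::vector<Vec3> pos_at_build;
  double rlist;
  // forces
  std::vector<Vec3> frc, gu; // gu = dU/du per lipid
  double e_gb, e_pl, e_pp, e_spring;

  inline Vec3 minimg(const Vec3& d) const {
    Vec3 r = d;
    if (periodic[0]) r.x -= box[0] * std::round(r.x / box[0]);
    if (periodic[1]) r.y -= box[1] * std::round(r.y / box[1]);
    if (periodic[2]) r.z -= box[2] * std::round(r.z / box[2]);
    return r;
  }
  double mass(int i) const { return i < n_lip ? mass_l : mass_p; }
};

static void build_neighbor_list(System& sys) {
  const int n = sys.n;
  sys.nl_i.clear(); sys.nl_j.clear();
  double rl = sys.rlist, rl2 = rl * rl;
  // cell grid
  double lo[3], hi[3], cl[3];
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    if (sys.periodic[d]) {
      lo[d] = 0.0; hi[d] = sys.box[d];
    } else {
      lo[d] = 1e30; hi[d] = -1e30;
      for (int i = 0; i < n; ++i) {
        double v = d == 0 ? sys.pos[i].x : (d == 1 ? sys.pos[i].y : sys.pos[i].z);
        lo[d] = std::min(lo[d], v); hi[d] = std::max(hi[d], v);
      }
      lo[d] -= 0.5 * rl; hi[d] += 0.5 * rl;
    }
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / rl));
    cl[d] = (hi[d] - lo[d]) / nc[d];
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1), cellof(n);
  for (int i = 0; i < n; ++i) {
    double v[3] = { sys.pos[i].x, sys.pos[i].y, sys.pos[i].z };
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double u = v[d] - lo[d];
      if (sys.periodic[d]) u -= sys.box[d] * std::floor(u / sys.box[d]);
      int k = (int)std::floor(u / cl[d]);
      if (k < 0) k = 0; if (k >= nc[d]) k = nc[d] - 1;
      c[d] = k;
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cellof[i] = ci; nxt[i] = head[ci]; head[ci] = i;
  }
  std::vector<int> nbr;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        nbr.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (sys.periodic[0]) ex = (ex + nc[0]) % nc[0]; else if (ex < 0 || ex >= nc[0]) continue;
              if (sys.periodic[1]) ey = (ey + nc[1]) % nc[1]; else if (ey < 0 || ey >= nc[1]) continue;
              if (sys.periodic[2]) ez = (ez + nc[2]) % nc[2]; else if (ez < 0 || ez >= nc[2]) continue;
              nbr.push_back((ez * nc[1] + ey) * nc[0] + ex);
            }
        std::sort(nbr.begin(), nbr.end());
        nbr.erase(std::unique(nbr.begin(), nbr.end()), nbr.end());
        for (int cj : nbr) {
          if (cj < ci) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i]) {
            for (int j = (cj == ci ? nxt[i] : head[cj]); j >= 0; j = nxt[j]) {
              // exclude intra-domain protein pairs (springs handle those)
              if (i >= sys.n_lip && j >= sys.n_lip &&
                  sys.domain[i - sys.n_lip] == sys.domain[j - sys.n_lip]) continue;
              Vec3 d = sys.minimg(sys.pos[i] - sys.pos[j]);
              if (dot(d, d) < rl2) { sys.nl_i.push_back(i); sys.nl_j.push_back(j); }
            }
          }
        }
      }
  sys.pos_at_build = sys.pos;
}

static bool need_rebuild(const System& sys, double skin) {
  double half2 = 0.25 * skin * skin;
  for (int i = 0; i < sys.n; ++i) {
    Vec3 d = sys.minimg(sys.pos[i] - sys.pos_at_build[i]);
    if (dot(d, d) > half2) return true;
  }
  return false;
}

static void compute_forces(System& sys) {
  sys.frc.assign(sys.n, Vec3());
  sys.gu.assign(sys.n_lip, Vec3());
  sys.e_gb = sys.e_pl = sys.e_pp = sys.e_spring = 0.0;
  const int nl = sys.n_lip;
  size_t np = sys.nl_i.size();
  const double gb_range2 = sys.gb.max_range * sys.gb.max_range;
  const double lj_rcut2 = sys.lj_rcut * sys.lj_rcut;
  for (size_t k = 0; k < np; ++k) {
    int i = sys.nl_i[k], j = sys.nl_j[k];
    Vec3 s = sys.minimg(sys.pos[i] - sys.pos[j]);
    double r2 = dot(s, s);
    if (i < nl && j < nl) {
      if (r2 >= gb_range2) continue;
      Vec3 fi, gi, gj;
      double e = gb_pair(s, sys.dir[i], sys.dir[j], sys.gb, fi, gi, gj);
      sys.e_gb += e;
      sys.frc[i] = sys.frc[i] + fi;
      sys.frc[j] = sys.frc[j] - fi;
      sys.gu[i] = sys.gu[i] + gi;
      sys.gu[j] = sys.gu[j] + gj;
    } else if (i >= nl && j >= nl) {
      if (r2 >= lj_rcut2) continue;
      int ti = sys.ptype[i - nl], tj = sys.ptype[j - nl];
      double eps = sys.pp_eps[ti][tj], sig = sys.pp_sigma[ti][tj];
      bool att = eps > 0.0;
      if (!att) { // WCA reach is short; reject on r2 first
        double rmin = sig * 1.1224620483089301;
        if (r2 >= rmin * rmin) continue;
      }
      double r = std::sqrt(r2), fmag;
      double e = lj_pair(r, att ? eps : sys.eps_rep, sig, att, sys.lj_rsw, sys.lj_rcut, fmag);
      sys.e_pp += e;
      Vec3 f = (fmag / r) * s;
      sys.frc[i] = sys.frc[i] + f;
      sys.frc[j] = sys.frc[j] - f;
    } else {
      if (r2 >= lj_rcut2) continue;
      int ip = (i >= nl) ? i : j; // protein index
      int il = (i >= nl) ? j : i; // lipid index
      int t = sys.ptype[ip - nl];
      double eps = sys.pl_eps[t], sig = sys.pl_sigma[t];
      bool att = eps > 0.0;
      if (t == 5 && !sys.pip2[il]) att = false; // pocket binds only PIP2 lipids
      if (!att) {
        double rmin = sig * 1.1224620483089301;
        if (r2 >= rmin * rmin) continue;
      }
      double r = std::sqrt(r2), fmag;
      double e = lj_pair(r, att ? eps : sys.eps_rep, sig, att, sys.lj_rsw, sys.lj_rcut, fmag);
      sys.e_pl += e;
      Vec3 f = (fmag / r) * s; // s = pos_i - pos_j
      sys.frc[i] = sys.frc[i] + f;
      sys.frc[j] = sys.frc[j] - f;
    }
  }
  // springs (global indices)
  for (size_t k = 0; k < sys.spr_i.size(); ++k) {
    int i = sys.spr_i[k], j = sys.spr_j[k];
    Vec3 s = sys.minimg(sys.pos[i] - sys.pos[j]);
    double r = norm(s);
    double dr = r - sys.spr_r0[k];
    sys.e_spring += 0.5 * sys.spr_k[k] * dr * dr;
    double fmag = -sys.spr_k[k] * dr; // -dU/dr
    Vec3 f = (fmag / r) * s;
    sys.frc[i] = sys.frc[i] + f;
    sys.frc[j] = sys.frc[j] - f;
  }
}

static double kinetic_total(const System& sys) {
  double K = 0.0;
  for (int i = 0; i < sys.n; ++i) K += 0.5 * sys.mass(i) * dot(sys.vel[i], sys.vel[i]);
  for (int i = 0; i < sys.n_lip; ++i) K += 0.5 * sys.inertia * dot(sys.ang[i], sys.ang[i]);
  return K;
}

static System unpack_system(const List& state) {
  System sys;
  NumericMatrix pos = state["pos"];
  sys.n = pos.nrow();
  sys.n_lip = as<int>(state["n_lip"]);
  sys.n_pro = sys.n - sys.n_lip;
  sys.pos.resize(sys.n);
  for (int i = 0; i < sys.n; ++i) sys.pos[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  if (sys.n_lip > 0) {
    NumericMatrix dir = state["dir"];
    sys.dir.resize(sys.n_lip);
    for (int i = 0; i < sys.n_lip; ++i) {
      Vec3 u(dir(i, 0), dir(i, 1), dir(i, 2));
      double nn = norm(u);
      if (std::abs(nn - 1.0) > 1e-6) u = (1.0 / nn) * u;
      sys.dir[i] = u;
    }
    IntegerVector pp = state["pip2"];
    sys.pip2.assign(pp.begin(), pp.end());
  }
  if (sys.n_pro > 0) {
    IntegerVector pt = state["ptype"];
    IntegerVector dm = state["domain"];
    sys.ptype.assign(pt.begin(), pt.end());
    sys.domain.assign(dm.begin(), dm.end());
  }
  NumericMatrix spr = state["springs"]; // i j k r0 (1-based global indices)
  for (int r = 0; r < spr.nrow(); ++r) {
    sys.spr_i.push_back((int)spr(r, 0) - 1);
    sys.spr_j.push_back((int)spr(r, 1) - 1);
    sys.spr_k.push_back(spr(r, 2));
    sys.spr_r0.push_back(spr(r, 3));
  }
  NumericVector box = state["box"];
  LogicalVector per = state["periodic"];
  for (int d = 0; d < 3; ++d) { sys.box[d] = box[d]; sys.periodic[d] = per[d] ? 1 : 0; }
  List par = state["params"];
  double kappa = as<double>(par["aspect_ratio"]);
  double kappap = as<double>(par["well_anisotropy"]);
  sys.gb.mu = as<double>(par["mu"]);
  sys.gb.nu = as<double>(par["nu"]);
  sys.gb.chi = (kappa * kappa - 1.0) / (kappa * kappa + 1.0);
  double cp = std::pow(kappap, 1.0 / sys.gb.mu);
  sys.gb.chip = (cp - 1.0) / (cp + 1.0);
  sys.gb.sigma0 = as<double>(par["sigma0"]);
  sys.gb.eps0 = as<double>(par["epsilon0"]);
  sys.gb.eps_hb = as<double>(par["head_tail_asymmetry"]);
  sys.gb.rho_cut = as<double>(par["cutoff"]);   // reduced separation units
  sys.gb.rho_sw = as<double>(par["switch_on"]);
  sys.gb.max_range = sys.gb.sigma0 * (kappa - 1.0 + sys.gb.rho_cut);
  sys.mass_l = as<double>(par["mass_lipid"]);
  sys.mass_p = as<double>(par["mass_site"]);
  sys.inertia = as<double>(par["inertia"]);
  sys.lj_rcut = as<double>(par["lj_cutoff"]);
  sys.lj_rsw = as<double>(par["lj_switch_on"]);
  sys.eps_rep = as<double>(par["eps_repulsive"]);
  NumericVector ple = par["pl_eps"], pls = par["pl_sigma"];
  for (int t = 0; t < 7; ++t) { sys.pl_eps[t] = ple[t]; sys.pl_sigma[t] = pls[t]; }
  NumericMatrix ppe = par["pp_eps"], pps = par["pp_sigma"];
  for (int a = 0; a < 7; ++a) for (int b = 0; b < 7; ++b) {
    sys.pp_eps[a][b] = ppe(a, b); sys.pp_sigma[a][b] = pps(a, b);
  }
  double skin = as<double>(par["skin"]);
  sys.rlist = std::max(sys.gb.max_range, sys.lj_rcut) + skin;
  return sys;
}

// [[Rcpp::export]]
List total_energy_cpp(List state) {
  System sys = unpack_system(state);
  build_neighbor_list(sys);
  compute_forces(sys);
  NumericMatrix frc(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    frc(i, 0) = sys.frc[i].x; frc(i, 1) = sys.frc[i].y; frc(i, 2) = sys.frc[i].z;
  }
  NumericMatrix gu(std::max(sys.n_lip, 1), 3);
  for (int i = 0; i < sys.n_lip; ++i) {
    gu(i, 0) = sys.gu[i].x; gu(i, 1) = sys.gu[i].y; gu(i, 2) = sys.gu[i].z;
  }
  return List::create(
    _["gb"] = sys.e_gb, _["protein_lipid"] = sys.e_pl,
    _["protein_protein"] = sys.e_pp, _["spring"] = sys.e_spring,
    _["total"] = sys.e_gb + sys.e_pl + sys.e_pp + sys.e_spring,
    _["forces"] = frc, _["dir_grad"] = gu);
}

// [[Rcpp::export]]
List gb_pair_cpp(NumericVector xi, NumericVector xj, NumericVector ui,
                 NumericVector uj, List par) {
  GBParamsC p;
  double kappa = as<double>(par["aspect_ratio"]);
  double kappap = as<double>(par["well_anisotropy"]);
  p.mu = as<double>(par["mu"]); p.nu = as<double>(par["nu"]);
  p.chi = (kappa * kappa - 1.0) / (kappa * kappa + 1.0);
  double cp = std::pow(kappap, 1.0 / p.mu);
  p.chip = (cp - 1.0) / (cp + 1.0);
  p.sigma0 = as<double>(par["sigma0"]);
  p.eps0 = as<double>(par["epsilon0"]);
  p.eps_hb = as<double>(par["head_tail_asymmetry"]);
  p.rho_cut = as<double>(par["cutoff"]);
  p.rho_sw = as<double>(par["switch_on"]);
  p.max_range = p.sigma0 * (kappa - 1.0 + p.rho_cut);
  Vec3 s(xi[0] - xj[0], xi[1] - xj[1], xi[2] - xj[2]);
  Vec3 u1(ui[0], ui[1], ui[2]), u2(uj[0], uj[1], uj[2]);
  Vec3 fi, gi, gj;
  double e = gb_pair(s, u1, u2, p, fi, gi, gj);
  return List::create(
    _["energy"] = e,
    _["force_i"] = NumericVector::create(fi.x, fi.y, fi.z),
    _["du_i"] = NumericVector::create(gi.x, gi.y, gi.z),
    _["du_j"] = NumericVector::create(gj.x, gj.y, gj.z));
}

// [[Rcpp::export]]
List run_nvt_cpp(List state, int n_steps, double dt, double temperature,
                 double tau, int seed, bool thermostat, int log_stride,
                 int snap_stride, bool init_velocities, bool freeze_proteins) {
  System sys = unpack_system(state);
  double skin = sys.rlist - std::max(sys.gb.max_range, sys.lj_rcut);
  double kT = KB * temperature;
  int n_mobile = freeze_proteins ? sys.n_lip : sys.n;
  int g_dof = 3 * n_mobile + 2 * sys.n_lip - 3;
  double Q = g_dof * kT * tau * tau;
  double xi = 0.0;

  sys.vel.assign(sys.n, Vec3());
  sys.ang.assign(std::max(sys.n_lip, 0), Vec3());
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  if (init_velocities) {
    for (int i = 0; i < n_mobile; ++i) {
      double s = std::sqrt(kT / sys.mass(i));
      sys.vel[i] = Vec3(s * gauss(rng), s * gauss(rng), s * gauss(rng));
    }
    Vec3 pmom;
    double mtot = 0.0;
    for (int i = 0; i < n_mobile; ++i) { pmom = pmom + sys.mass(i) * sys.vel[i]; mtot += sys.mass(i); }
    Vec3 vcm = (1.0 / mtot) * pmom;
    for (int i = 0; i < n_mobile; ++i) sys.vel[i] = sys.vel[i] - vcm;
    double sw = std::sqrt(kT / sys.inertia);
    for (int i = 0; i < sys.n_lip; ++i) {
      Vec3 w(sw * gauss(rng), sw * gauss(rng), sw * gauss(rng));
      // project perpendicular to the director (linear rotor: 2 dof)
      w = w - dot(w, sys.dir[i]) * sys.dir[i];
      sys.ang[i] = w;
    }
  } else if (state.containsElementNamed("vel")) {
    NumericMatrix v = state["vel"];
    for (int i = 0; i < sys.n; ++i) sys.vel[i] = Vec3(v(i, 0), v(i, 1), v(i, 2));
    if (sys.n_lip > 0 && state.containsElementNamed("ang")) {
      NumericMatrix w = state["ang"];
      for (int i = 0; i < sys.n_lip; ++i) sys.ang[i] = Vec3(w(i, 0), w(i, 1), w(i, 2));
    }
  }

  if (freeze_proteins) {
    for (int i = sys.n_lip; i < sys.n; ++i) sys.vel[i] = Vec3();
  }
  build_neighbor_list(sys);
  compute_forces(sys);
  double pot_prev = sys.e_gb + sys.e_pl + sys.e_pp + sys.e_spring;

  int n_logs = n_steps / std::max(log_stride, 1) + 2;
  NumericMatrix log(n_logs, 8);
  CharacterVector lognames = CharacterVector::create(
    "step", "temperature", "e_gb", "e_protein_lipid", "e_protein_protein",
    "e_spring", "e_kinetic", "e_total");
  int logrow = 0;
  List snaps_pos, snaps_dir;
  std::vector<int> snap_steps;
  bool diverged = false;
  std::string divmsg;

  auto log_now = [&](int step) {
    if (logrow >= n_logs) return;
    double K = kinetic_total(sys);
    double pot = sys.e_gb + sys.e_pl + sys.e_pp + sys.e_spring;
    log(logrow, 0) = step;
    log(logrow, 1) = 2.0 * K / (g_dof * KB);
    log(logrow, 2) = sys.e_gb; log(logrow, 3) = sys.e_pl;
    log(logrow, 4) = sys.e_pp; log(logrow, 5) = sys.e_spring;
    log(logrow, 6) = K; log(logrow, 7) = K + pot;
    ++logrow;
  };
  auto snap_now = [&](int step) {
    NumericMatrix p(sys.n, 3);
    for (int i = 0; i < sys.n; ++i) { p(i, 0) = sys.pos[i].x; p(i, 1) = sys.pos[i].y; p(i, 2) = sys.pos[i].z; }
    snaps_pos.push_back(p);
    if (sys.n_lip > 0) {
      NumericMatrix d(sys.n_lip, 3);
      for (int i = 0; i < sys.n_lip; ++i) { d(i, 0) = sys.dir[i].x; d(i, 1) = sys.dir[i].y; d(i, 2) = sys.dir[i].z; }
      snaps_dir.push_back(d);
    }
    snap_steps.push_back(step);
  };

  log_now(0);
  if (snap_stride > 0) snap_now(0);

  double dt2 = 0.5 * dt, dt4 = 0.25 * dt;
  auto nh_update = [&]() {
    double K = kinetic_total(sys);
    xi += dt4 * (2.0 * K - g_dof * kT) / Q;
    double s = std::exp(-xi * dt2);
    for (int i = 0; i < sys.n; ++i) sys.vel[i] = s * sys.vel[i];
    for (int i = 0; i < sys.n_lip; ++i) sys.ang[i] = s * sys.ang[i];
    K *= s * s;
    xi += dt4 * (2.0 * K - g_dof * kT) / Q;
  };

  for (int step = 1; step <= n_steps; ++step) {
    if (thermostat) nh_update();
    // half kick
    for (int i = 0; i < n_mobile; ++i) sys.vel[i] = sys.vel[i] + (dt2 / sys.mass(i)) * sys.frc[i];
    for (int i = 0; i < sys.n_lip; ++i) {
      Vec3 tq = -1.0 * cross(sys.dir[i], sys.gu[i]); // torque
      Vec3 wdot = (1.0 / sys.inertia) * tq;
      sys.ang[i] = sys.ang[i] + dt2 * wdot;
      sys.ang[i] = sys.ang[i] - dot(sys.ang[i], sys.dir[i]) * sys.dir[i];
    }
    // drift
    for (int i = 0; i < n_mobile; ++i) sys.pos[i] = sys.pos[i] + dt * sys.vel[i];
    for (int i = 0; i < sys.n_lip; ++i) {
      Vec3 du = cross(sys.ang[i], sys.dir[i]);
      Vec3 u = sys.dir[i] + dt * du;
      double nn = norm(u);
      sys.dir[i] = (1.0 / nn) * u;
      sys.ang[i] = sys.ang[i] - dot(sys.ang[i], sys.dir[i]) * sys.dir[i];
    }
    if (need_rebuild(sys, skin)) build_neighbor_list(sys);
    compute_forces(sys);
    // half kick
    for (int i = 0; i < n_mobile; ++i) sys.vel[i] = sys.vel[i] + (dt2 / sys.mass(i)) * sys.frc[i];
    for (int i = 0; i < sys.n_lip; ++i) {
      Vec3 tq = -1.0 * cross(sys.dir[i], sys.gu[i]);
      sys.ang[i] = sys.ang[i] + (dt2 / sys.inertia) * tq;
      sys.ang[i] = sys.ang[i] - dot(sys.ang[i], sys.dir[i]) * sys.dir[i];
    }
    if (thermostat) nh_update();

    double pot = sys.e_gb + sys.e_pl + sys.e_pp + sys.e_spring;
    if (!std::isfinite(pot) || std::abs(pot - pot_prev) > 1e3) {
      diverged = true;
      divmsg = "Energy divergence at step " + std::to_string(step) +
        " (|dE| = " + std::to_string(std::abs(pot - pot_prev)) + " kcal/mol)";
      log_now(step);
      snap_now(step);
      break;
    }
    pot_prev = pot;
    if (log_stride > 0 && step % log_stride == 0) log_now(step);
    if (snap_stride > 0 && step % snap_stride == 0) snap_now(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(sys.n, 3), vel_out(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) {
    pos_out(i, 0) = sys.pos[i].x; pos_out(i, 1) = sys.pos[i].y; pos_out(i, 2) = sys.pos[i].z;
    vel_out(i, 0) = sys.vel[i].x; vel_out(i, 1) = sys.vel[i].y; vel_out(i, 2) = sys.vel[i].z;
  }
  NumericMatrix dir_out(std::max(sys.n_lip, 1), 3), ang_out(std::max(sys.n_lip, 1), 3);
  for (int i = 0; i < sys.n_lip; ++i) {
    dir_out(i, 0) = sys.dir[i].x; dir_out(i, 1) = sys.dir[i].y; dir_out(i, 2) = sys.dir[i].z;
    ang_out(i, 0) = sys.ang[i].x; ang_out(i, 1) = sys.ang[i].y; ang_out(i, 2) = sys.ang[i].z;
  }
  colnames(log) = lognames;
  return List::create(
    _["pos"] = pos_out, _["dir"] = dir_out, _["vel"] = vel_out, _["ang"] = ang_out,
    _["log"] = log(Range(0, std::max(logrow - 1, 0)), _),
    _["snap_pos"] = snaps_pos, _["snap_dir"] = snaps_dir,
    _["snap_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
    _["diverged"] = diverged, _["divergence_message"] = divmsg);
}
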