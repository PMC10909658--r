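// Axisymmetric incompressible projection solver on a terrain-following
// (z, sigma) grid, with regularized Casson rheology.
//
// Staggering: axial velocity w on z-faces ((Nz+1) x Ns), radial velocity u
// on sigma-faces (Nz x (Ns+1)), pressure p at cell centers (Nz x Ns).
// All quantities SI. Physical derivatives follow from the mapping
// r(z, s) = eps(z) + s h(z):
//   d/dr = (1/h) d/ds,   d/dz|_r = d/dz|_s - (r_z / h) d/ds.
//
// Time scheme: explicit advection (hybrid central / second-order upwind),
// approximately factored implicit diffusion: the full momentum RHS is
// evaluated explicitly and the velocity increment is passed through
// (I - dt Lx)(I - dt Ls) sweeps (tridiagonal in each direction), so both
// principal diffusion directions are unconditionally stable -- essential
// because the regularized plug viscosity exceeds the plastic viscosity by
// orders of magnitude -- while the steady state satisfies the unsplit
// discrete equations exactly. Cross-metric (mixed-derivative) viscous
// terms stay explicit; the transformed operator is uniformly elliptic
// (mixed coefficient strictly dominated by the principal ones) and the
// sigma-implicit coefficient is augmented by the cross-metric weight,
// which keeps the explicit remainder stable at advective CFL steps.
//
// Pressure: incremental projection. The orthogonal+augmented part of the
// variable-geometry pressure operator is factored once per grid with
// LAPACK banded LU; non-orthogonal cross-metric terms are handled by
// deferred-correction outer iterations until the discrete divergence
// meets tolerance, so the converged field is divergence-free in the full
// curvilinear sense.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>
#include <algorithm>

#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// ---------------------------------------------------------------- fields

struct Field {
  int nr = 0, nc = 0;
  std::vector<double> v;
  void resize(int r, int c) { nr = r; nc = c; v.assign((size_t)r * c, 0.0); }
  double& operator()(int i, int j) { return v[(size_t)i + (size_t)j * nr]; }
  double operator()(int i, int j) const { return v[(size_t)i + (size_t)j * nr]; }
};

static void from_R(const NumericMatrix& m, Field& f) {
  f.resize(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), f.v.begin());
}
static NumericMatrix to_R(const Field& f) {
  NumericMatrix m(f.nr, f.nc);
  std::copy(f.v.begin(), f.v.end(), m.begin());
  return m;
}

// derivative at the middle point of three non-uniform samples
static inline double d3mid(double x1, double f1, double x2, double f2,
                           double x3, double f3) {
  double h1 = x2 - x1, h2 = x3 - x2;
  return (-h2 / (h1 * (h1 + h2))) * f1 + ((h2 - h1) / (h1 * h2)) * f2 +
         (h1 / (h2 * (h1 + h2))) * f3;
}
// derivative at the right end (backward-biased quadratic)
static inline double d3right(double x1, double f1, double x2, double f2,
                             double x3, double f3) {
  double h1 = x2 - x1, h2 = x3 - x2;
  return (h2 / (h1 * (h1 + h2))) * f1 - ((h1 + h2) / (h1 * h2)) * f2 +
         ((h1 + 2 * h2) / (h2 * (h1 + h2))) * f3;
}
// derivative at the left end (forward-biased quadratic)
static inline double d3left(double x1, double f1, double x2, double f2,
                            double x3, double f3) {
  double h1 = x2 - x1, h2 = x3 - x2;
  return (-(2 * h1 + h2) / (h1 * (h1 + h2))) * f1 +
         ((h1 + h2) / (h1 * h2)) * f2 - (h1 / (h2 * (h1 + h2))) * f3;
}

struct Grid {
  int Nz, Ns;
  bool axis; // inner boundary is the symmetry axis (open tube), not a wall
  std::vector<double> xf, xc, dx, sf, sc, ds, h_f, h_c;
  Field rw, rzw, ru, rzu, rc, rzc, rk, rzk, volr; // rk = corner radii
  std::vector<double> dxc;   // xc[i]-xc[i-1] (1..Nz-1); dxc[Nz] = xf[Nz]-xc[Nz-1]
  std::vector<double> dscc;  // sc[j]-sc[j-1] (1..Ns-1); dscc[0]=sc[0], dscc[Ns]=1-sc[Ns-1]
};

static std::vector<double> vec(const List& g, const char* nm) {
  NumericVector x = g[nm];
  return std::vector<double>(x.begin(), x.end());
}

static Grid read_grid(const List& g) {
  Grid G;
  G.Nz = as<int>(g["Nz"]);
  G.Ns = as<int>(g["Ns"]);
  G.axis = g.containsElementNamed("axis") ? as<bool>(g["axis"]) : false;
  G.xf = vec(g, "xf"); G.xc = vec(g, "xc"); G.dx = vec(g, "dx");
  G.sf = vec(g, "sf"); G.sc = vec(g, "sc"); G.ds = vec(g, "ds");
  G.h_f = vec(g, "h_f"); G.h_c = vec(g, "h_c");
  from_R(g["rw"], G.rw);   from_R(g["rzw"], G.rzw);
  from_R(g["ru"], G.ru);   from_R(g["rzu"], G.rzu);
  from_R(g["rc"], G.rc);   from_R(g["rzc"], G.rzc);
  from_R(g["rcorn"], G.rk); from_R(g["rzcorn"], G.rzk);
  NumericMatrix vol = g["vol"];
  G.volr.resize(G.Nz, G.Ns);
  for (int k = 0; k < G.Nz * G.Ns; ++k) G.volr.v[k] = vol[k] / (2.0 * M_PI);
  G.dxc.assign(G.Nz + 1, 0.0);
  for (int i = 1; i < G.Nz; ++i) G.dxc[i] = G.xc[i] - G.xc[i - 1];
  G.dxc[G.Nz] = G.xf[G.Nz] - G.xc[G.Nz - 1];
  G.dscc.assign(G.Ns + 1, 0.0);
  G.dscc[0] = G.sc[0];
  for (int j = 1; j < G.Ns; ++j) G.dscc[j] = G.sc[j] - G.sc[j - 1];
  G.dscc[G.Ns] = 1.0 - G.sc[G.Ns - 1];
  return G;
}

struct Rheo {
  double mu_p, tau_y, rho, gfloor;
  bool literal;
  double mu_lit;
};
static Rheo read_rheo(const List& r) {
  Rheo R;
  R.mu_p = as<double>(r["mu_p"]);
  R.tau_y = as<double>(r["tau_y"]);
  R.rho = as<double>(r["rho"]);
  R.gfloor = as<double>(r["gammadot_floor"]);
  std::string mode = as<std::string>(r["mode"]);
  R.literal = (mode == "literal_constant");
  double zeta = as<double>(r["zeta"]), m = as<double>(r["m"]);
  R.mu_lit = std::pow(std::sqrt(zeta) - std::sqrt(m), 2);
  return R;
}
static inline double visc_of(const Rheo& R, double gam) {
  if (R.literal) return R.mu_lit;
  double g = std::max(gam, R.gfloor);
  double s = std::sqrt(R.mu_p) + std::sqrt(R.tau_y / g);
  return s * s;
}

// ------------------------------------------------------------- workspace

struct Work {
  Field u, w, p;                       // state
  Field mu_c, gam_c, Szz, Srr, Stt;    // cell-center fields
  Field Srz_k, mu_k;                   // corner fields
  Field dwds_f;                        // dw/ds at w-points
  Field phi;                           // pressure increment
  void init(const Grid& G) {
    u.resize(G.Nz, G.Ns + 1);
    w.resize(G.Nz + 1, G.Ns);
    p.resize(G.Nz, G.Ns);
    mu_c.resize(G.Nz, G.Ns); gam_c.resize(G.Nz, G.Ns);
    Szz.resize(G.Nz, G.Ns); Srr.resize(G.Nz, G.Ns); Stt.resize(G.Nz, G.Ns);
    Srz_k.resize(G.Nz + 1, G.Ns + 1); mu_k.resize(G.Nz + 1, G.Ns + 1);
    dwds_f.resize(G.Nz + 1, G.Ns);
    phi.resize(G.Nz, G.Ns);
  }
};

static void state_from_R(const List& st, Work& W, const Grid& G) {
  W.init(G);
  from_R(st["u"], W.u);
  from_R(st["w"], W.w);
  from_R(st["p"], W.p);
}
static List state_to_R(const Work& W, double t) {
  return List::create(_["u"] = to_R(W.u), _["w"] = to_R(W.w),
                      _["p"] = to_R(W.p), _["t"] = t);
}

// dw/ds at w-point (i,j) using the wall values w = 0 at s = 0, 1
static void fill_dwds_f(const Grid& G, Work& W) {
  for (int i = 0; i <= G.Nz; ++i)
    for (int j = 0; j < G.Ns; ++j) {
      double d;
      if (j == 0)
        d = G.axis
          // symmetry: mirror w across the axis
          ? d3mid(-G.sc[0], W.w(i, 0), G.sc[0], W.w(i, 0), G.sc[1], W.w(i, 1))
          : d3mid(0.0, 0.0, G.sc[0], W.w(i, 0), G.sc[1], W.w(i, 1));
      else if (j == G.Ns - 1)
        d = d3mid(G.sc[j - 1], W.w(i, j - 1), G.sc[j], W.w(i, j), 1.0, 0.0);
      else
        d = d3mid(G.sc[j - 1], W.w(i, j - 1), G.sc[j], W.w(i, j),
                  G.sc[j + 1], W.w(i, j + 1));
      W.dwds_f(i, j) = d;
    }
}

// x-derivative of u at (xc[i], sf[j]) (central, one-sided at ends)
static inline double dudx_at(const Grid& G, const Work& W, int i, int j) {
  if (i == 0) return (W.u(1, j) - W.u(0, j)) / (G.xc[1] - G.xc[0]);
  if (i == G.Nz - 1)
    return (W.u(i, j) - W.u(i - 1, j)) / (G.xc[i] - G.xc[i - 1]);
  return d3mid(G.xc[i - 1], W.u(i - 1, j), G.xc[i], W.u(i, j),
               G.xc[i + 1], W.u(i + 1, j));
}

// cell-center s-derivative of a center field (one-sided at walls)
static inline double dcent_ds(const Grid& G, const Field& F, int i, int j) {
  if (j == 0) return (F(i, 1) - F(i, 0)) / (G.sc[1] - G.sc[0]);
  if (j == G.Ns - 1) return (F(i, j) - F(i, j - 1)) / (G.sc[j] - G.sc[j - 1]);
  return d3mid(G.sc[j - 1], F(i, j - 1), G.sc[j], F(i, j),
               G.sc[j + 1], F(i, j + 1));
}

static void compute_rheo_fields(const Grid& G, const Rheo& R, Work& W) {
  fill_dwds_f(G, W);
  for (int i = 0; i < G.Nz; ++i) {
    for (int j = 0; j < G.Ns; ++j) {
      double duds = (W.u(i, j + 1) - W.u(i, j)) / G.ds[j];
      double Drr = duds / G.h_c[i];
      double ucc = 0.5 * (W.u(i, j) + W.u(i, j + 1));
      double Dtt = ucc / G.rc(i, j);
      double dwdx = (W.w(i + 1, j) - W.w(i, j)) / G.dx[i];
      double dwds = 0.5 * (W.dwds_f(i, j) + W.dwds_f(i + 1, j));
      double Dzz = dwdx - (G.rzc(i, j) / G.h_c[i]) * dwds;
      double dudx = 0.5 * (dudx_at(G, W, i, j) + dudx_at(G, W, i, j + 1));
      double Drz = 0.5 * (dudx - (G.rzc(i, j) / G.h_c[i]) * duds +
                          dwds / G.h_c[i]);
      double gam = std::sqrt(2.0 * (Drr * Drr + Dtt * Dtt + Dzz * Dzz +
                                    2.0 * Drz * Drz));
      double mu = visc_of(R, gam);
      W.gam_c(i, j) = gam;
      W.mu_c(i, j) = mu;
      W.Szz(i, j) = 2.0 * mu * Dzz;
      W.Srr(i, j) = 2.0 * mu * Drr;
      W.Stt(i, j) = 2.0 * mu * Dtt;
    }
  }
  // corner viscosity and S_rz
  for (int i = 0; i <= G.Nz; ++i) {
    int il = std::max(i - 1, 0), ir = std::min(i, G.Nz - 1);
    for (int j = 0; j <= G.Ns; ++j) {
      int jl = std::max(j - 1, 0), jr = std::min(j, G.Ns - 1);
      double mu = 0.25 * (W.mu_c(il, jl) + W.mu_c(il, jr) +
                          W.mu_c(ir, jl) + W.mu_c(ir, jr));
      W.mu_k(i, j) = mu;
      double dwds_k;
      if (j == 0)
        // wall value w = 0 plus two interior samples: one-sided quadratic
        dwds_k = G.axis ? 0.0
               : d3left(0.0, 0.0, G.sc[0], W.w(i, 0), G.sc[1], W.w(i, 1));
      else if (j == G.Ns)
        dwds_k = d3right(G.sc[G.Ns - 2], W.w(i, G.Ns - 2),
                         G.sc[G.Ns - 1], W.w(i, G.Ns - 1), 1.0, 0.0);
      else dwds_k = (W.w(i, j) - W.w(i, j - 1)) / G.dscc[j];
      double dwdr_k = dwds_k / G.h_f[i];
      double dudx_k;
      if (i == 0) dudx_k = (W.u(1, j) - W.u(0, j)) / (G.xc[1] - G.xc[0]);
      else if (i == G.Nz) dudx_k = (W.u(G.Nz - 1, j) - W.u(G.Nz - 2, j)) /
                                   (G.xc[G.Nz - 1] - G.xc[G.Nz - 2]);
      else dudx_k = (W.u(i, j) - W.u(i - 1, j)) / G.dxc[i];
      double duds_k;
      if (j == 0)
        duds_k = (0.5 * (W.u(il, 1) + W.u(ir, 1)) -
                  0.5 * (W.u(il, 0) + W.u(ir, 0))) / (G.sf[1] - G.sf[0]);
      else if (j == G.Ns)
        duds_k = (0.5 * (W.u(il, G.Ns) + W.u(ir, G.Ns)) -
                  0.5 * (W.u(il, G.Ns - 1) + W.u(ir, G.Ns - 1))) /
                 (G.sf[G.Ns] - G.sf[G.Ns - 1]);
      else
        duds_k = (0.5 * (W.u(il, j + 1) + W.u(ir, j + 1)) -
                  0.5 * (W.u(il, j - 1) + W.u(ir, j - 1))) /
                 (G.sf[j + 1] - G.sf[j - 1]);
      double dudz_k = dudx_k - (G.rzk(i, j) / G.h_f[i]) * duds_k;
      W.Srz_k(i, j) = mu * (dudz_k + dwdr_k);
    }
  }
}

// ---------------------------------------------------- momentum operators

// full discrete viscous term of the w-equation at interior w-point (i,j), /rho
static inline double visc_w_full(const Grid& G, const Rheo& R, Work& W,
                                 int i, int j) {
  double t1 = (G.rk(i, j + 1) * W.Srz_k(i, j + 1) -
               G.rk(i, j) * W.Srz_k(i, j)) /
              (G.rw(i, j) * G.h_f[i] * G.ds[j]);
  double t2 = (W.Szz(i, j) - W.Szz(i - 1, j)) / G.dxc[i];
  double dS = 0.5 * (dcent_ds(G, W.Szz, i - 1, j) + dcent_ds(G, W.Szz, i, j));
  double t3 = -(G.rzw(i, j) / G.h_f[i]) * dS;
  return (t1 + t2 + t3) / R.rho;
}

static inline double visc_u_full(const Grid& G, const Rheo& R, Work& W,
                                 int i, int j) {
  double t1 = (G.rc(i, j) * W.Srr(i, j) - G.rc(i, j - 1) * W.Srr(i, j - 1)) /
              (G.ru(i, j) * G.h_c[i] * G.dscc[j]);
  double t2 = (W.Srz_k(i + 1, j) - W.Srz_k(i, j)) / G.dx[i];
  double dSl = (W.Srz_k(i, j + 1) - W.Srz_k(i, j - 1)) /
               (G.sf[j + 1] - G.sf[j - 1]);
  double dSr = (W.Srz_k(i + 1, j + 1) - W.Srz_k(i + 1, j - 1)) /
               (G.sf[j + 1] - G.sf[j - 1]);
  double t3 = -(G.rzu(i, j) / G.h_c[i]) * 0.5 * (dSl + dSr);
  return (t1 + t2 + t3) / R.rho;
}

// sigma-implicit diffusion coefficients for w at (i,j): flux-form
// tridiagonal with wall Dirichlet w = 0; coefficient augmented by the
// cross-metric weight (1 + 2 r_z^2)
static inline void lw_coeffs(const Grid& G, const Rheo& R, Work& W,
                             int i, int j, double& cD, double& cU,
                             double& denom) {
  double cimpU = W.mu_k(i, j + 1) *
                 (1.0 + 2.0 * G.rzk(i, j + 1) * G.rzk(i, j + 1));
  double cimpD = W.mu_k(i, j) * (1.0 + 2.0 * G.rzk(i, j) * G.rzk(i, j));
  cU = G.rk(i, j + 1) * cimpU / G.dscc[j + 1];
  cD = G.rk(i, j) * cimpD / G.dscc[j];
  denom = R.rho * G.rw(i, j) * G.h_f[i] * G.h_f[i] * G.ds[j];
}

static inline void lu_coeffs(const Grid& G, const Rheo& R, Work& W,
                             int i, int j, double& cD, double& cU,
                             double& denom) {
  double cimpU = W.mu_c(i, j) * (2.0 + G.rzc(i, j) * G.rzc(i, j));
  double cimpD = W.mu_c(i, j - 1) *
                 (2.0 + G.rzc(i, j - 1) * G.rzc(i, j - 1));
  cU = G.rc(i, j) * cimpU / G.ds[j];
  cD = G.rc(i, j - 1) * cimpD / G.ds[j - 1];
  denom = R.rho * G.ru(i, j) * G.h_c[i] * G.h_c[i] * G.dscc[j];
}

// hybrid advective x-derivative for w at w-point (i,j)
static inline double dwdx_adv(const Grid& G, const Rheo& R, Work& W,
                              int i, int j) {
  double vel = W.w(i, j);
  double mu = 0.5 * (W.mu_c(i - 1, j) + W.mu_c(i, j));
  double pe = R.rho * std::fabs(vel) * G.dxc[i] / std::max(mu, 1e-300);
  if (pe <= 2.0)
    return d3mid(G.xf[i - 1], W.w(i - 1, j), G.xf[i], W.w(i, j),
                 G.xf[i + 1], W.w(i + 1, j));
  if (vel > 0.0) {
    if (i >= 2)
      return d3right(G.xf[i - 2], W.w(i - 2, j), G.xf[i - 1], W.w(i - 1, j),
                     G.xf[i], W.w(i, j));
    return (W.w(i, j) - W.w(i - 1, j)) / (G.xf[i] - G.xf[i - 1]);
  }
  if (i <= G.Nz - 2)
    return d3left(G.xf[i], W.w(i, j), G.xf[i + 1], W.w(i + 1, j),
                  G.xf[i + 2], W.w(i + 2, j));
  return (W.w(i + 1, j) - W.w(i, j)) / (G.xf[i + 1] - G.xf[i]);
}

// hybrid advective x-derivative for u at u-point (i,j)
static inline double dudx_adv(const Grid& G, const Rheo& R, Work& W,
                              int i, int j, double wvel) {
  if (i == 0) return (W.u(1, j) - W.u(0, j)) / (G.xc[1] - G.xc[0]);
  if (i == G.Nz - 1)
    return (W.u(i, j) - W.u(i - 1, j)) / (G.xc[i] - G.xc[i - 1]);
  double mu = 0.5 * (W.mu_c(i, j - 1) + W.mu_c(i, j));
  double pe = R.rho * std::fabs(wvel) * (G.xc[i] - G.xc[i - 1]) /
              std::max(mu, 1e-300);
  if (pe <= 2.0)
    return d3mid(G.xc[i - 1], W.u(i - 1, j), G.xc[i], W.u(i, j),
                 G.xc[i + 1], W.u(i + 1, j));
  if (wvel > 0.0) {
    if (i >= 2)
      return d3right(G.xc[i - 2], W.u(i - 2, j), G.xc[i - 1], W.u(i - 1, j),
                     G.xc[i], W.u(i, j));
    return (W.u(i, j) - W.u(i - 1, j)) / (G.xc[i] - G.xc[i - 1]);
  }
  if (i <= G.Nz - 3)
    return d3left(G.xc[i], W.u(i, j), G.xc[i + 1], W.u(i + 1, j),
                  G.xc[i + 2], W.u(i + 2, j));
  return (W.u(i + 1, j) - W.u(i, j)) / (G.xc[i + 1] - G.xc[i]);
}

// full momentum RHS (advection + viscous + pressure), /rho,
// for w at interior (i,j)
static inline double rhs_w_point(const Grid& G, const Rheo& R, Work& W,
                                 int i, int j, bool adv, bool visc,
                                 bool pres) {
  double out = 0.0;
  if (adv) {
    double uw = 0.25 * (W.u(i - 1, j) + W.u(i - 1, j + 1) +
                        W.u(i, j) + W.u(i, j + 1));
    double sdot = (uw - W.w(i, j) * G.rzw(i, j)) / G.h_f[i];
    out -= W.w(i, j) * dwdx_adv(G, R, W, i, j) + sdot * W.dwds_f(i, j);
  }
  if (visc) out += visc_w_full(G, R, W, i, j);
  if (pres) {
    double gz = (W.p(i, j) - W.p(i - 1, j)) / G.dxc[i];
    double dp = 0.5 * (dcent_ds(G, W.p, i - 1, j) + dcent_ds(G, W.p, i, j));
    out -= (gz - (G.rzw(i, j) / G.h_f[i]) * dp) / R.rho;
  }
  return out;
}

static inline double rhs_u_point(const Grid& G, const Rheo& R, Work& W,
                                 int i, int j, bool adv, bool visc,
                                 bool pres) {
  double out = 0.0;
  double wu = 0.25 * (W.w(i, j - 1) + W.w(i, j) +
                      W.w(i + 1, j - 1) + W.w(i + 1, j));
  if (adv) {
    double sdot = (W.u(i, j) - wu * G.rzu(i, j)) / G.h_c[i];
    double duds = d3mid(G.sf[j - 1], W.u(i, j - 1), G.sf[j], W.u(i, j),
                        G.sf[j + 1], W.u(i, j + 1));
    out -= wu * dudx_adv(G, R, W, i, j, wu) + sdot * duds;
  }
  if (visc) {
    double stt = 0.5 * (W.Stt(i, j - 1) + W.Stt(i, j));
    out += visc_u_full(G, R, W, i, j) - stt / (G.ru(i, j) * R.rho);
  }
  if (pres)
    out -= (W.p(i, j) - W.p(i, j - 1)) /
           (G.h_c[i] * G.dscc[j] * R.rho);
  return out;
}

// Thomas tridiagonal solve (solution left in d)
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d, int n) {
  for (int k = 1; k < n; ++k) {
    double m = a[k] / b[k - 1];
    b[k] -= m * c[k - 1];
    d[k] -= m * d[k - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int k = n - 2; k >= 0; --k) d[k] = (d[k] - c[k] * d[k + 1]) / b[k];
}

// momentum predictor: factored-increment form
//   (I - dt Lx)(I - dt Ls) (q* - q) = dt * F(q)
// updates W.u, W.w in place (assumes compute_rheo_fields has been called)
static void predictor(const Grid& G, const Rheo& R, Work& W, double dt) {
  int Ns = G.Ns, Nz = G.Nz;
  int nmax = std::max(Ns, Nz) + 2;
  std::vector<double> a(nmax), b(nmax), c(nmax), d(nmax);

  // ---- w component ----
  Field Fw; Fw.resize(Nz + 1, Ns);
  for (int i = 1; i < Nz; ++i)
    for (int j = 0; j < Ns; ++j)
      Fw(i, j) = dt * rhs_w_point(G, R, W, i, j, true, true, true);

  // x-sweep per row j: (I - dt Lx) y = Fw, y = 0 at inlet/outlet faces,
  // Lx y = (1/rho) d/dx(2 mu dy/dx)
  Field Yw; Yw.resize(Nz + 1, Ns);
  for (int j = 0; j < Ns; ++j) {
    for (int i = 1; i < Nz; ++i) {
      double cW = 2.0 * W.mu_c(i - 1, j) / G.dx[i - 1];
      double cE = 2.0 * W.mu_c(i, j) / G.dx[i];
      double den = R.rho * G.dxc[i];
      a[i - 1] = -dt * cW / den;
      c[i - 1] = -dt * cE / den;
      b[i - 1] = 1.0 + dt * (cW + cE) / den;
      d[i - 1] = Fw(i, j);
    }
    thomas(a, b, c, d, Nz - 1);
    for (int i = 1; i < Nz; ++i) Yw(i, j) = d[i - 1];
  }
  // s-sweep per column i: (I - dt Ls + dt A_s) delta = y, walls Dirichlet
  // 0; A_s is first-order upwind sigma-advection (contravariant velocity),
  // included implicitly so steep-wall cells do not throttle the time step
  for (int i = 1; i < Nz; ++i) {
    for (int j = 0; j < Ns; ++j) {
      double cD, cU, den;
      lw_coeffs(G, R, W, i, j, cD, cU, den);
      a[j] = -dt * cD / den;
      c[j] = -dt * cU / den;
      b[j] = 1.0 + dt * (cD + cU) / den;
      double uw = 0.25 * (W.u(i - 1, j) + W.u(i - 1, j + 1) +
                          W.u(i, j) + W.u(i, j + 1));
      double sdot = (uw - W.w(i, j) * G.rzw(i, j)) / G.h_f[i];
      if (sdot > 0.0) {
        double adv = dt * sdot / G.dscc[j];
        b[j] += adv; a[j] -= adv;
      } else if (sdot < 0.0) {
        double adv = -dt * sdot / G.dscc[j + 1];
        b[j] += adv; c[j] -= adv;
      }
      d[j] = Yw(i, j);
    }
    thomas(a, b, c, d, Ns);
    for (int j = 0; j < Ns; ++j) W.w(i, j) += d[j];
  }

  // ---- u component ----
  Field Fu; Fu.resize(Nz, Ns + 1);
  for (int i = 0; i < Nz; ++i)
    for (int j = 1; j < Ns; ++j)
      Fu(i, j) = dt * rhs_u_point(G, R, W, i, j, true, true, true);

  // x-sweep per row j (zero-flux ends): Lx y = (1/rho) d/dx(mu dy/dx)
  Field Yu; Yu.resize(Nz, Ns + 1);
  for (int j = 1; j < Ns; ++j) {
    for (int i = 0; i < Nz; ++i) {
      double cW = (i > 0) ? W.mu_k(i, j) / G.dxc[i] : 0.0;
      double cE = (i < Nz - 1) ? W.mu_k(i + 1, j) / G.dxc[i + 1] : 0.0;
      double den = R.rho * G.dx[i];
      a[i] = -dt * cW / den;
      c[i] = -dt * cE / den;
      b[i] = 1.0 + dt * (cW + cE) / den;
      d[i] = Fu(i, j);
    }
    thomas(a, b, c, d, Nz);
    for (int i = 0; i < Nz; ++i) Yu(i, j) = d[i];
  }
  // s-sweep per column i (walls Dirichlet 0), hoop term on the diagonal,
  // implicit upwind sigma-advection as for w
  for (int i = 0; i < Nz; ++i) {
    for (int j = 1; j < Ns; ++j) {
      double cD, cU, den;
      lu_coeffs(G, R, W, i, j, cD, cU, den);
      double mu_u = 0.5 * (W.mu_c(i, j - 1) + W.mu_c(i, j));
      double dtt = 2.0 * mu_u / (R.rho * G.ru(i, j) * G.ru(i, j));
      a[j - 1] = -dt * cD / den;
      c[j - 1] = -dt * cU / den;
      b[j - 1] = 1.0 + dt * (cD + cU) / den + dt * dtt;
      double wu = 0.25 * (W.w(i, j - 1) + W.w(i, j) +
                          W.w(i + 1, j - 1) + W.w(i + 1, j));
      double sdot = (W.u(i, j) - wu * G.rzu(i, j)) / G.h_c[i];
      if (sdot > 0.0) {
        double adv = dt * sdot / G.ds[j - 1];
        b[j - 1] += adv; a[j - 1] -= adv;
      } else if (sdot < 0.0) {
        double adv = -dt * sdot / G.ds[j];
        b[j - 1] += adv; c[j - 1] -= adv;
      }
      d[j - 1] = Yu(i, j);
    }
    thomas(a, b, c, d, Ns - 1);
    for (int j = 1; j < Ns; ++j) W.u(i, j) += d[j - 1];
  }

  // outlet zero-gradient on the provisional field
  for (int j = 0; j < Ns; ++j) W.w(Nz, j) = W.w(Nz - 1, j);
}

// -------------------------------------------------------------- pressure

// cell flux-sum (per radian, m^3/s) over cell rows [ilo, ihi];
// returns max |div| (1/s) over that range
static double flux_divergence_uw(const Grid& G, const Field& u,
                                 const Field& w, Field& fsum,
                                 int ilo, int ihi) {
  int Ns = G.Ns;
  double dmax = 0.0;
  for (int i = ilo; i <= ihi; ++i) {
    for (int j = 0; j < Ns; ++j) {
      double FzW = w(i, j) * G.rw(i, j) * G.h_f[i] * G.ds[j];
      double FzE = w(i + 1, j) * G.rw(i + 1, j) * G.h_f[i + 1] * G.ds[j];
      double FsS = 0.0, FsN = 0.0;
      if (j > 0) {
        double wb = 0.25 * (w(i, j - 1) + w(i, j) +
                            w(i + 1, j - 1) + w(i + 1, j));
        FsS = (u(i, j) - wb * G.rzu(i, j)) * G.ru(i, j) * G.dx[i];
      }
      if (j < Ns - 1) {
        double wb = 0.25 * (w(i, j) + w(i, j + 1) +
                            w(i + 1, j) + w(i + 1, j + 1));
        FsN = (u(i, j + 1) - wb * G.rzu(i, j + 1)) * G.ru(i, j + 1) *
              G.dx[i];
      }
      double f = FzE - FzW + FsN - FsS;
      fsum(i, j) = f;
      double dloc = std::fabs(f) / G.volr(i, j);
      if (dloc > dmax) dmax = dloc;
    }
  }
  return dmax;
}
static double flux_divergence(const Grid& G, Work& W, Field& fsum) {
  return flux_divergence_uw(G, W.u, W.w, fsum, 0, G.Nz - 1);
}

// apply the pressure-gradient velocity correction
//   w -= coef * (d phi/dz|_r),  u -= coef * (1/h) d phi/ds
// over w-faces [iwlo, iwhi] and u-cells [iulo, iuhi]; this single code
// path defines the discrete gradient used both when correcting
// velocities and when assembling the projection operator
static void apply_phi_correction(const Grid& G, const Field& phi,
                                 double coef, Field& u, Field& w,
                                 int iwlo, int iwhi, int iulo, int iuhi) {
  int Nz = G.Nz, Ns = G.Ns;
  for (int i = std::max(iwlo, 1); i <= std::min(iwhi, Nz); ++i) {
    for (int j = 0; j < Ns; ++j) {
      double gz, dps;
      if (i < Nz) {
        gz = (phi(i, j) - phi(i - 1, j)) / G.dxc[i];
        dps = 0.5 * (dcent_ds(G, phi, i - 1, j) + dcent_ds(G, phi, i, j));
      } else {
        gz = (0.0 - phi(Nz - 1, j)) / G.dxc[Nz];
        dps = dcent_ds(G, phi, Nz - 1, j);
      }
      w(i, j) -= coef * (gz - (G.rzw(i, j) / G.h_f[i]) * dps);
    }
  }
  for (int i = std::max(iulo, 0); i <= std::min(iuhi, Nz - 1); ++i)
    for (int j = 1; j < Ns; ++j)
      u(i, j) -= coef * (phi(i, j) - phi(i, j - 1)) /
                 (G.h_c[i] * G.dscc[j]);
}

struct BandFac {
  int n, kl, ku, ldab;
  std::vector<double> ab;
  std::vector<int> ipiv;
};

static void band_solve(BandFac* F, std::vector<double>& b) {
  int info = 0, nrhs = 1;
  F77_CALL(dgbtrs)("N", &F->n, &F->kl, &F->ku, &nrhs, F->ab.data(),
                   &F->ldab, F->ipiv.data(), b.data(), &F->n, &info FCONE);
  if (info != 0) stop("pressure solve failed (dgbtrs info = %d)", info);
}

// incremental projection with the exact factored operator; corrects W in
// place. The operator is the exact composition of the discrete divergence
// with the discrete pressure gradient, so one solve reaches tolerance;
// the loop only mops up floating-point residue.
static List project(const Grid& G, Work& W, BandFac* F, double rho,
                    double dt, double tol_abs, int max_iters) {
  int Nz = G.Nz, Ns = G.Ns, N = Nz * Ns;
  Field fsum; fsum.resize(Nz, Ns);
  std::vector<double> b(N);
  std::vector<double> hist;
  double dmax = flux_divergence(G, W, fsum);
  hist.push_back(dmax);
  int it = 0;
  while (dmax > tol_abs && it < max_iters) {
    for (int i = 0; i < Nz; ++i)
      for (int j = 0; j < Ns; ++j)
        b[(size_t)i * Ns + j] = -(rho / dt) * fsum(i, j);
    band_solve(F, b);
    for (int i = 0; i < Nz; ++i)
      for (int j = 0; j < Ns; ++j)
        W.phi(i, j) = b[(size_t)i * Ns + j];
    apply_phi_correction(G, W.phi, dt / rho, W.u, W.w, 1, Nz, 0, Nz - 1);
    for (int i = 0; i < Nz; ++i)
      for (int j = 0; j < Ns; ++j)
        W.p(i, j) += W.phi(i, j);
    dmax = flux_divergence(G, W, fsum);
    ++it;
    hist.push_back(dmax);
  }
  return List::create(_["div_linf"] = dmax, _["iters"] = it,
                      _["history"] = NumericVector(hist.begin(), hist.end()));
}

// --------------------------------------------------------- time stepping

struct Inflow {
  double Q_si;      // target volumetric rate, m^3/s
  double ramp_s;    // 0 => no ramp
  std::vector<double> shape; // Ns values at inlet-face sigma centers
};
static Inflow read_inflow(const List& l) {
  Inflow I;
  I.Q_si = as<double>(l["Q_si"]);
  I.ramp_s = as<double>(l["ramp_s"]);
  NumericVector s = l["shape"];
  I.shape.assign(s.begin(), s.end());
  return I;
}
static inline double ramp_factor(double t, double ramp_s) {
  if (ramp_s <= 0.0) return 1.0;
  double x = t / ramp_s;
  if (x <= 0.0) return 0.0;
  if (x >= 1.0) return 1.0;
  return x * x * (3.0 - 2.0 * x);
}

static void apply_bcs(const Grid& G, Work& W, const Inflow& I, double t) {
  int Nz = G.Nz, Ns = G.Ns;
  for (int i = 0; i < Nz; ++i) { W.u(i, 0) = 0.0; W.u(i, Ns) = 0.0; }
  // inlet: scale the shape so the discrete flux matches the ramped target
  double denom = 0.0;
  for (int j = 0; j < Ns; ++j)
    denom += I.shape[j] * G.rw(0, j) * G.h_f[0] * G.ds[j];
  double qr = I.Q_si / (2.0 * M_PI) * ramp_factor(t, I.ramp_s);
  double scale = (denom > 0.0) ? qr / denom : 0.0;
  for (int j = 0; j < Ns; ++j) W.w(0, j) = scale * I.shape[j];
  // outlet: zero-gradient velocity
  for (int j = 0; j < Ns; ++j) W.w(Nz, j) = W.w(Nz - 1, j);
}

// spec-form CFL velocity scale: max over cells of |w|/dz + |u|/dr
static double courant_max_field(const Grid& G, Work& W) {
  double m = 0.0;
  for (int i = 0; i < G.Nz; ++i)
    for (int j = 0; j < G.Ns; ++j) {
      double wc = 0.5 * std::fabs(W.w(i, j) + W.w(i + 1, j));
      double uc = 0.5 * std::fabs(W.u(i, j) + W.u(i, j + 1));
      double v = wc / G.dx[i] + uc / (G.h_c[i] * G.ds[j]);
      if (v > m) m = v;
    }
  return m;
}

static void check_finite(const Grid& G, Work& W, int nstep, double t) {
  for (size_t k = 0; k < W.w.v.size(); ++k)
    if (!std::isfinite(W.w.v[k]))
      stop("numerical blowup: non-finite axial velocity at step %d (t = %g s)",
           nstep, t);
  for (size_t k = 0; k < W.u.v.size(); ++k)
    if (!std::isfinite(W.u.v[k]))
      stop("numerical blowup: non-finite radial velocity at step %d (t = %g s)",
           nstep, t);
}

// ------------------------------------------------------------- exports

// [[Rcpp::export]]
SEXP cpp_poisson_factor(List grid) {
  Grid G = read_grid(grid);
  int Nz = G.Nz, Ns = G.Ns, N = Nz * Ns;
  // stencil reach: +-1 cell axially, +-2 in sigma (cross-metric terms)
  int kl = Ns + 2, ku = Ns + 2, ldab = 2 * kl + ku + 1;
  XPtr<BandFac> F(new BandFac());
  F->n = N; F->kl = kl; F->ku = ku; F->ldab = ldab;
  F->ab.assign((size_t)ldab * N, 0.0);
  F->ipiv.assign(N, 0);
  // assemble the exact divergence-of-gradient operator column by column
  // by probing the shared correction/divergence code with unit vectors
  Field phi1; phi1.resize(Nz, Ns);
  Field du; du.resize(Nz, Ns + 1);
  Field dw; dw.resize(Nz + 1, Ns);
  Field fs; fs.resize(Nz, Ns);
  for (int i0 = 0; i0 < Nz; ++i0) {
    for (int j0 = 0; j0 < Ns; ++j0) {
      int col = i0 * Ns + j0;
      phi1(i0, j0) = 1.0;
      int iwlo = i0, iwhi = std::min(i0 + 1, Nz);
      apply_phi_correction(G, phi1, 1.0, du, dw, iwlo, iwhi, i0, i0);
      int clo = std::max(i0 - 1, 0), chi = std::min(i0 + 1, Nz - 1);
      flux_divergence_uw(G, du, dw, fs, clo, chi);
      for (int ic = clo; ic <= chi; ++ic) {
        for (int jc = 0; jc < Ns; ++jc) {
          double v = fs(ic, jc);
          if (v != 0.0) {
            int row = ic * Ns + jc;
            if (std::abs(row - col) > ku)
              stop("projection operator exceeded the assumed bandwidth");
            F->ab[(size_t)(kl + ku + row - col) + (size_t)col * ldab] = v;
          }
        }
      }
      // reset the probed window
      phi1(i0, j0) = 0.0;
      for (int i = iwlo; i <= iwhi; ++i)
        for (int j = 0; j < Ns; ++j) dw(i, j) = 0.0;
      for (int j = 0; j <= Ns; ++j) du(i0, j) = 0.0;
      for (int ic = clo; ic <= chi; ++ic)
        for (int jc = 0; jc < Ns; ++jc) fs(ic, jc) = 0.0;
    }
  }
  int info = 0;
  F77_CALL(dgbtrf)(&N, &N, &kl, &ku, F->ab.data(), &ldab, F->ipiv.data(),
                   &info);
  if (info != 0)
    stop("pressure operator factorization failed (info = %d)", info);
  return F;
}

// [[Rcpp::export]]
List cpp_apply_bcs(List state, List grid, List inflow, double t) {
  Grid G = read_grid(grid);
  Work W; state_from_R(state, W, G);
  Inflow I = read_inflow(inflow);
  apply_bcs(G, W, I, t);
  return state_to_R(W, t);
}

// [[Rcpp::export]]
double cpp_cfl_dt(List state, List grid, double courant_max, double dt_init) {
  Grid G = read_grid(grid);
  Work W; state_from_R(state, W, G);
  double m = courant_max_field(G, W);
  if (m <= 0.0) return dt_init;
  return std::min(dt_init, courant_max / m);
}

// [[Rcpp::export]]
double cpp_courant_of(List state, List grid, double dt) {
  Grid G = read_grid(grid);
  Work W; state_from_R(state, W, G);
  return dt * courant_max_field(G, W);
}

// [[Rcpp::export]]
List cpp_momentum_rhs(List state, List grid, List rheo,
                      bool advection = true, bool viscous = true,
                      bool pressure = true) {
  Grid G = read_grid(grid);
  Rheo R = read_rheo(rheo);
  Work W; state_from_R(state, W, G);
  compute_rheo_fields(G, R, W);
  Field rw_, ru_;
  rw_.resize(G.Nz + 1, G.Ns);
  ru_.resize(G.Nz, G.Ns + 1);
  for (int i = 1; i < G.Nz; ++i)
    for (int j = 0; j < G.Ns; ++j)
      rw_(i, j) = rhs_w_point(G, R, W, i, j, advection, viscous, pressure);
  for (int i = 0; i < G.Nz; ++i)
    for (int j = 1; j < G.Ns; ++j)
      ru_(i, j) = rhs_u_point(G, R, W, i, j, advection, viscous, pressure);
  return List::create(_["rhs_w"] = to_R(rw_), _["rhs_u"] = to_R(ru_));
}

// [[Rcpp::export]]
List cpp_predict(List state, List grid, List rheo, double dt) {
  Grid G = read_grid(grid);
  Rheo R = read_rheo(rheo);
  Work W; state_from_R(state, W, G);
  compute_rheo_fields(G, R, W);
  predictor(G, R, W, dt);
  return state_to_R(W, as<double>(state["t"]));
}

// [[Rcpp::export]]
List cpp_project(List state, List grid, SEXP fac, double rho, double dt,
                 double tol_abs, int max_iters) {
  Grid G = read_grid(grid);
  Work W; state_from_R(state, W, G);
  BandFac* F = XPtr<BandFac>(fac).get();
  List info = project(G, W, F, rho, dt, tol_abs, max_iters);
  return List::create(_["state"] = state_to_R(W, as<double>(state["t"])),
                      _["div_linf"] = info["div_linf"],
                      _["iters"] = info["iters"],
                      _["history"] = info["history"]);
}

// [[Rcpp::export]]
List cpp_div_field(List state, List grid) {
  Grid G = read_grid(grid);
  Work W; state_from_R(state, W, G);
  Field fsum; fsum.resize(G.Nz, G.Ns);
  double dmax = flux_divergence(G, W, fsum);
  Field div; div.resize(G.Nz, G.Ns);
  for (int k = 0; k < G.Nz * G.Ns; ++k) div.v[k] = fsum.v[k] / G.volr.v[k];
  return List::create(_["div"] = to_R(div), _["div_linf"] = dmax);
}

struct StepDiag { double dt, courant, div_linf; int outer; };

static StepDiag do_step(const Grid& G, const Rheo& R, Work& W, BandFac* F,
                        const Inflow& I, double courant_max, double dt_init,
                        double dt_prev, double tol_abs, int max_outer,
                        double& t) {
  double cmax = courant_max_field(G, W);
  double dt = dt_init;
  if (cmax > 0.0) dt = std::min(dt, courant_max / cmax);
  if (dt_prev > 0.0) dt = std::min(dt, 1.1 * dt_prev);
  double courant = dt * cmax;
  t += dt;
  apply_bcs(G, W, I, t);
  compute_rheo_fields(G, R, W);
  predictor(G, R, W, dt);
  apply_bcs(G, W, I, t); // re-pin inlet/walls before enforcing continuity
  List info = project(G, W, F, R.rho, dt, tol_abs, max_outer);
  StepDiag d;
  d.dt = dt; d.courant = courant;
  d.div_linf = as<double>(info["div_linf"]);
  d.outer = as<int>(info["iters"]);
  return d;
}

// [[Rcpp::export]]
List cpp_step(List state, List grid, SEXP fac, List rheo, List inflow,
              List cfg) {
  Grid G = read_grid(grid);
  Rheo R = read_rheo(rheo);
  Inflow I = read_inflow(inflow);
  Work W; state_from_R(state, W, G);
  double t = as<double>(state["t"]);
  StepDiag d = do_step(G, R, W, XPtr<BandFac>(fac).get(), I,
                       as<double>(cfg["courant_max"]),
                       as<double>(cfg["dt_init"]),
                       as<double>(cfg["dt_prev"]),
                       as<double>(cfg["div_tol_abs"]),
                       as<int>(cfg["max_outer_iters"]), t);
  check_finite(G, W, 1, t);
  return List::create(_["state"] = state_to_R(W, t), _["dt"] = d.dt,
                      _["courant"] = d.courant, _["div_linf"] = d.div_linf,
                      _["outer_iters"] = d.outer);
}

// [[Rcpp::export]]
List cpp_run(List grid, SEXP fac, List rheo, List inflow, List cfg,
             Nullable<List> state0 = R_NilValue) {
  Grid G = read_grid(grid);
  Rheo R = read_rheo(rheo);
  Inflow I = read_inflow(inflow);
  BandFac* F = XPtr<BandFac>(fac).get();

  double courant_max = as<double>(cfg["courant_max"]);
  double dt_init = as<double>(cfg["dt_init"]);
  double t_end = as<double>(cfg["t_end"]);
  double tol_abs = as<double>(cfg["div_tol_abs"]);
  int max_outer = as<int>(cfg["max_outer_iters"]);
  double out_int = as<double>(cfg["output_interval"]);
  double steady_tol = as<double>(cfg["steady_tol"]);
  bool stop_steady = as<bool>(cfg["stop_at_steady"]);
  double t_transit = as<double>(cfg["t_transit"]);
  double t_min_steady = as<double>(cfg["t_min_steady"]);
  int n_check = as<int>(cfg["steady_check_every"]);
  long max_steps = (long)as<double>(cfg["max_steps"]);

  Work W;
  double t = 0.0;
  if (state0.isNotNull()) {
    List s0(state0);
    state_from_R(s0, W, G);
    t = as<double>(s0["t"]);
  } else {
    W.init(G);
  }

  List snapshots;
  std::vector<double> snap_times;
  double next_out = out_int > 0 ? out_int : t_end + 1.0;
  double max_courant = 0.0, dt_prev = -1.0, div_last = 0.0;
  long nstep = 0;
  bool steady = false;
  Field w_prev = W.w;
  double t_prev_check = t;
  std::vector<double> dt_hist;
  std::vector<int> outer_hist;
  dt_hist.reserve(4096); outer_hist.reserve(4096);

  auto take_snapshot = [&](double tt) {
    compute_rheo_fields(G, R, W);
    snapshots.push_back(List::create(
      _["u"] = to_R(W.u), _["w"] = to_R(W.w), _["p"] = to_R(W.p),
      _["mu"] = to_R(W.mu_c), _["gammadot"] = to_R(W.gam_c), _["t"] = tt));
    snap_times.push_back(tt);
  };

  while (t < t_end - 1e-12 && nstep < max_steps) {
    StepDiag d = do_step(G, R, W, F, I, courant_max, dt_init, dt_prev,
                         tol_abs, max_outer, t);
    dt_prev = d.dt;
    div_last = d.div_linf;
    if (d.courant > max_courant) max_courant = d.courant;
    dt_hist.push_back(d.dt);
    outer_hist.push_back(d.outer);
    ++nstep;
    if (nstep % 50 == 0) check_finite(G, W, (int)nstep, t);
    if (t >= next_out - 1e-12) {
      take_snapshot(t);
      next_out += out_int;
    }
    // steady when the field changes by less than steady_tol (relative,
    // L-infinity) over one full transit time
    if (t - t_prev_check >= t_transit) {
      double num = 0.0, den = 1e-300;
      for (size_t k = 0; k < W.w.v.size(); ++k) {
        num = std::max(num, std::fabs(W.w.v[k] - w_prev.v[k]));
        den = std::max(den, std::fabs(W.w.v[k]));
      }
      w_prev = W.w;
      t_prev_check = t;
      if (t >= t_min_steady && num / den < steady_tol) {
        steady = true;
        if (stop_steady) break;
      }
    }
    if (nstep % n_check == 0) Rcpp::checkUserInterrupt();
  }
  check_finite(G, W, (int)nstep, t);
  if (snap_times.empty() || std::fabs(snap_times.back() - t) > 1e-12)
    take_snapshot(t);

  List summary = List::create(
    _["n_steps"] = (double)nstep, _["t_final"] = t,
    _["max_courant"] = max_courant, _["final_divergence_linf"] = div_last,
    _["steady"] = steady,
    _["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()),
    _["dt_history"] = NumericVector(dt_hist.begin(), dt_hist.end()),
    _["outer_iters"] = IntegerVector(outer_hist.begin(), outer_hist.end()));
  return List::create(_["snapshots"] = snapshots, _["summary"] = summary);
}
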