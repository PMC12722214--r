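// Multi-pool Bloch-McConnell core: piecewise-constant generator matrices
// propagated with matrix exponentials. Free pools (water + mobile solutes)
// carry full transverse + longitudinal dynamics; the semisolid pool is
// longitudinal-only with an RF saturation rate pi * w1^2 * g(delta) where g
// is a Lorentzian or super-Lorentzian absorption lineshape.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GAMMA_HZ = 42.5764e6;   // 1H gyromagnetic ratio, Hz/T
static const double TWO_PI = 6.283185307179586;

struct FreePool {
  double shift;  // ppm
  double r1, r2; // 1/s
  double k;      // solute -> water exchange rate, 1/s
  double f;      // proton volume fraction (water = 1)
};

struct Tissue {
  std::vector<FreePool> free_pools; // [0] is water (shift 0, k 0, f 1)
  bool has_ss;
  double ss_shift, ss_r1, ss_t2, ss_k, ss_f;
  int ss_lineshape; // 0 lorentzian, 1 super-lorentzian
  double b0_shift;  // ppm
};

static Tissue parse_tissue(const List& tl) {
  Tissue t;
  NumericVector water = tl["water"]; // c(t1, t2)
  FreePool w;
  w.shift = 0.0; w.r1 = 1.0 / water[0]; w.r2 = 1.0 / water[1];
  w.k = 0.0; w.f = 1.0;
  t.free_pools.push_back(w);
  NumericMatrix pools = tl["pools"]; // 5 x np: shift, t1, t2, k, f
  for (int j = 0; j < pools.ncol(); j++) {
    FreePool p;
    p.shift = pools(0, j);
    p.r1 = 1.0 / pools(1, j);
    p.r2 = 1.0 / pools(2, j);
    p.k = pools(3, j);
    p.f = pools(4, j);
    t.free_pools.push_back(p);
  }
  t.has_ss = false;
  if (tl.containsElementNamed("semisolid") && !Rf_isNull(tl["semisolid"])) {
    NumericVector ss = tl["semisolid"]; // shift, t1, t2, k, f, lineshape
    t.has_ss = true;
    t.ss_shift = ss[0];
    t.ss_r1 = 1.0 / ss[1];
    t.ss_t2 = ss[2];
    t.ss_k = ss[3];
    t.ss_f = ss[4];
    t.ss_lineshape = (int)ss[5];
  }
  t.b0_shift = as<double>(tl["b0_shift"]);
  return t;
}

// Super-Lorentzian absorption lineshape (seconds), numerically integrated
// over fiber orientations. Singular on resonance; callers interpolate below
// |delta| = cutoff.
static double super_lorentzian_g(double delta, double t2) {
  const int N = 256;
  double s = 0.0;
  for (int i = 0; i < N; i++) {
    double u = (i + 0.5) / N;
    double den = 3.0 * u * u - 1.0;
    if (std::fabs(den) < 1e-9) continue;
    double arg = delta * t2 / den;
    s += t2 / std::fabs(den) * std::exp(-2.0 * arg * arg);
  }
  return std::sqrt(2.0 / M_PI) * s / N;
}

// RF saturation rate of the semisolid pool: pi * w1^2 * g(delta).
// The super-Lorentzian on-resonance singularity is bridged by quadratic
// interpolation through anchors at 1, 1.5, and 2 ppm from the pool center.
static double ss_sat_rate(double omega1, double delta, double t2,
                          int lineshape, double omega_per_ppm) {
  double g;
  if (lineshape == 0) {
    g = (t2 / M_PI) / (1.0 + delta * delta * t2 * t2);
  } else {
    double cutoff = std::fabs(omega_per_ppm); // 1 ppm
    double ad = std::fabs(delta);
    if (ad >= cutoff) {
      g = super_lorentzian_g(ad, t2);
    } else {
      double x1 = cutoff, x2 = 1.5 * cutoff, x3 = 2.0 * cutoff;
      double g1 = super_lorentzian_g(x1, t2);
      double g2 = super_lorentzian_g(x2, t2);
      double g3 = super_lorentzian_g(x3, t2);
      double l1 = (ad - x2) * (ad - x3) / ((x1 - x2) * (x1 - x3));
      double l2 = (ad - x1) * (ad - x3) / ((x2 - x1) * (x2 - x3));
      double l3 = (ad - x1) * (ad - x2) / ((x3 - x1) * (x3 - x2));
      g = g1 * l1 + g2 * l2 + g3 * l3;
      if (g < 0.0) g = 0.0;
    }
  }
  return M_PI * omega1 * omega1 * g;
}

// Assemble generator dM/dt = A M + c for a continuous-wave block.
// State ordering: x_0..x_{nf-1}, y_0..y_{nf-1}, z_0..z_{nf-1}, [z_ss].
static void build_system(const Tissue& t, double b1_uT, double offset_ppm,
                         double b0_field, arma::mat& A, arma::vec& c) {
  int nf = (int)t.free_pools.size();
  int d = 3 * nf + (t.has_ss ? 1 : 0);
  double omega_per_ppm = TWO_PI * GAMMA_HZ * b0_field * 1e-6;
  double omega1 = TWO_PI * GAMMA_HZ * b1_uT * 1e-6; // rad/s
  A.zeros(d, d);
  c.zeros(d);
  for (int i = 0; i < nf; i++) {
    const FreePool& p = t.free_pools[i];
    int ix = i, iy = nf + i, iz = 2 * nf + i;
    double delta = omega_per_ppm * (p.shift + t.b0_shift - offset_ppm);
    A(ix, ix) -= p.r2;  A(ix, iy) -= delta;
    A(iy, ix) += delta; A(iy, iy) -= p.r2; A(iy, iz) += omega1;
    A(iz, iy) -= omega1; A(iz, iz) -= p.r1;
    c(iz) += p.r1 * p.f;
    if (i > 0 && p.k > 0.0) { // star topology: each solute <-> water
      double kf = p.k, kb = p.f * p.k;
      int comp_i[3] = {ix, iy, iz};
      int comp_w[3] = {0, nf, 2 * nf};
      for (int cI = 0; cI < 3; cI++) {
        A(comp_i[cI], comp_i[cI]) -= kf;
        A(comp_i[cI], comp_w[cI]) += kb;
        A(comp_w[cI], comp_w[cI]) -= kb;
        A(comp_w[cI], comp_i[cI]) += kf;
      }
    }
  }
  if (t.has_ss) {
    int izss = 3 * nf, izw = 2 * nf;
    double delta = omega_per_ppm * (t.ss_shift + t.b0_shift - offset_ppm);
    double w = ss_sat_rate(omega1, delta, t.ss_t2, t.ss_lineshape,
                           omega_per_ppm);
    double kf = t.ss_k, kb = t.ss_f * t.ss_k;
    A(izss, izss) -= (t.ss_r1 + w + kf);
    A(izss, izw) += kb;
    A(izw, izw) -= kb;
    A(izw, izss) += kf;
    c(izss) += t.ss_r1 * t.ss_f;
  }
}

static arma::vec equilibrium(const Tissue& t) {
  int nf = (int)t.free_pools.size();
  int d = 3 * nf + (t.has_ss ? 1 : 0);
  arma::vec m(d, arma::fill::zeros);
  for (int i = 0; i < nf; i++) m(2 * nf + i) = t.free_pools[i].f;
  if (t.has_ss) m(3 * nf) = t.ss_f;
  return m;
}

// M(t) = m_inf + expm(A t) (M0 - m_inf), m_inf = -A^{-1} c.
static arma::vec propagate(const arma::mat& A, const arma::vec& c,
                           const arma::vec& m0, double dur) {
  arma::vec minf = arma::solve(A, -c);
  arma::mat E = arma::expmat(A * dur);
  return minf + E * (m0 - minf);
}

// [[Rcpp::export(name = ".bm_equilibrium")]]
NumericVector bm_equilibrium(List tissue) {
  Tissue t = parse_tissue(tissue);
  return wrap(equilibrium(t));
}

// [[Rcpp::export(name = ".bm_evolve")]]
NumericVector bm_evolve(List tissue, NumericVector state, double b1_uT,
                        double offset_ppm, double duration, double b0_field) {
  Tissue t = parse_tissue(tissue);
  arma::mat A; arma::vec c;
  build_system(t, b1_uT, offset_ppm, b0_field, A, c);
  arma::vec m0 = as<arma::vec>(state);
  if ((int)m0.n_elem != (int)A.n_rows)
    stop("state length does not match the tissue model");
  return wrap(propagate(A, c, m0, duration));
}

// Fixed-step classical Runge-Kutta integration of the same generator;
// serves as an independent propagation route for cross-checking.
// [[Rcpp::export(name = ".bm_evolve_rk4")]]
NumericVector bm_evolve_rk4(List tissue, NumericVector state, double b1_uT,
                            double offset_ppm, double duration,
                            double b0_field, double step) {
  Tissue t = parse_tissue(tissue);
  arma::mat A; arma::vec c;
  build_system(t, b1_uT, offset_ppm, b0_field, A, c);
  arma::vec m = as<arma::vec>(state);
  if ((int)m.n_elem != (int)A.n_rows)
    stop("state length does not match the tissue model");
  int nstep = (int)std::ceil(duration / step);
  double h = duration / nstep;
  for (int i = 0; i < nstep; i++) {
    arma::vec k1 = A * m + c;
    arma::vec k2 = A * (m + 0.5 * h * k1) + c;
    arma::vec k3 = A * (m + 0.5 * h * k2) + c;
    arma::vec k4 = A * (m + h * k3) + c;
    m += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return wrap(m);
}

// One trajectory across a schedule. Schedule matrix columns:
// has_sat, b1_uT, offset_ppm, dur_s, tr_s, te_s.
// Per entry: evolve under saturation, read out water z * exp(-te/T2w),
// spoil transverse everywhere, null water z (ideal 90 degree excitation),
// then relax for the remaining TR.
static arma::vec trajectory(const Tissue& t, const NumericMatrix& sched,
                            double b0_field,
                            std::map<double, std::pair<arma::mat, arma::vec>>* rec_cache) {
  int nf = (int)t.free_pools.size();
  int izw = 2 * nf;
  double t2w = 1.0 / t.free_pools[0].r2;
  arma::vec m = equilibrium(t);
  int ne = sched.nrow();
  arma::vec sig(ne);
  arma::mat A; arma::vec c;
  for (int e = 0; e < ne; e++) {
    bool has_sat = sched(e, 0) != 0.0;
    double dur = has_sat ? sched(e, 3) : 0.0;
    if (has_sat) {
      build_system(t, sched(e, 1), sched(e, 2), b0_field, A, c);
      m = propagate(A, c, m, dur);
    }
    double te = sched(e, 5);
    sig(e) = m(izw) * std::exp(-te / t2w);
    for (int i = 0; i < 2 * nf; i++) m(i) = 0.0; // spoil transverse
    m(izw) = 0.0;                                // ideal 90, water z consumed
    double rec = sched(e, 4) - dur - te;
    if (rec > 0) {
      auto it = rec_cache->find(rec);
      if (it == rec_cache->end()) {
        build_system(t, 0.0, 0.0, b0_field, A, c);
        arma::vec minf = arma::solve(A, -c);
        arma::mat E = arma::expmat(A * rec);
        it = rec_cache->emplace(rec, std::make_pair(E, minf)).first;
      }
      m = it->second.second + it->second.first * (m - it->second.second);
    }
  }
  return sig;
}

// [[Rcpp::export(name = ".bm_trajectory")]]
NumericVector bm_trajectory(List tissue, NumericMatrix sched, double b0_field) {
  Tissue t = parse_tissue(tissue);
  std::map<double, std::pair<arma::mat, arma::vec>> cache;
  return wrap(trajectory(t, sched, b0_field, &cache));
}

// Batch simulation over a parameter matrix. Each row overrides fields of the
// base tissue: role_target 0 = water, -1 = semisolid, j >= 1 = solute pool j;
// role_field 1 = t1, 2 = t2, 3 = exchange rate, 4 = volume fraction,
// 5 = chemical shift.
// [[Rcpp::export(name = ".bm_dictionary")]]
NumericMatrix bm_dictionary(List tissue, NumericMatrix params,
                            IntegerVector role_target,
                            IntegerVector role_field,
                            NumericMatrix sched, double b0_field) {
  Tissue base = parse_tissue(tissue);
  int n = params.nrow(), np = params.ncol(), ne = sched.nrow();
  if (np != role_target.size() || np != role_field.size())
    stop("parameter roles do not match the parameter matrix");
  NumericMatrix out(n, ne);
  for (int r = 0; r < n; r++) {
    Tissue t = base;
    for (int j = 0; j < np; j++) {
      double v = params(r, j);
      int tgt = role_target[j], fld = role_field[j];
      if (tgt == 0) {
        if (fld == 1) t.free_pools[0].r1 = 1.0 / v;
        else if (fld == 2) t.free_pools[0].r2 = 1.0 / v;
        else stop("invalid water field");
      } else if (tgt == -1) {
        if (!t.has_ss) stop("base tissue has no semisolid pool");
        if (fld == 1) t.ss_r1 = 1.0 / v;
        else if (fld == 2) t.ss_t2 = v;
        else if (fld == 3) t.ss_k = v;
        else if (fld == 4) t.ss_f = v;
        else if (fld == 5) t.ss_shift = v;
        else stop("invalid semisolid field");
      } else {
        if (tgt >= (int)t.free_pools.size())
          stop("solute pool index out of range");
        FreePool& p = t.free_pools[tgt];
        if (fld == 1) p.r1 = 1.0 / v;
        else if (fld == 2) p.r2 = 1.0 / v;
        else if (fld == 3) p.k = v;
        else if (fld == 4) p.f = v;
        else if (fld == 5) p.shift = v;
        else stop("invalid pool field");
      }
    }
    std::map<double, std::pair<arma::mat, arma::vec>> cache;
    arma::vec sig = trajectory(t, sched, b0_field, &cache);
    for (int e = 0; e < ne; e++) out(r, e) = sig(e);
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".bm_lineshape_g")]]
double bm_lineshape_g(double delta_rad, double t2, int lineshape,
                      double omega_per_ppm) {
  double w = ss_sat_rate(1.0, delta_rad, t2, lineshape, omega_per_ppm);
  return w / M_PI; // g itself (w1 = 1 rad/s)
}
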