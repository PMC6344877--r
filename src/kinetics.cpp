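#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// Equilibrium complex concentration: smaller root of
//   y^2 - (yA + yB + q) y + yA yB = 0.
// Computed as 2 yA yB / (S + sqrt(S^2 - 4 yA yB)), S = yA + yB + q,
// which avoids the catastrophic cancellation of the textbook
// (S - sqrt(...)) / 2 form when q >> yA, yB.
static inline double complex_conc1(double yA, double yB, double q) {
  if (yA <= 0.0 || yB <= 0.0) return 0.0;
  double S = yA + yB + q;
  double disc = S * S - 4.0 * yA * yB;
  if (disc < 0.0) disc = 0.0; // roundoff guard; analytically >= 0
  return 2.0 * yA * yB / (S + std::sqrt(disc));
}

// [[Rcpp::export]]
NumericVector cpp_complex_concentration(NumericVector yA, NumericVector yB,
                                        NumericVector q) {
  R_xlen_t n = std::max(yA.size(), std::max(yB.size(), q.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = complex_conc1(yA[i % yA.size()], yB[i % yB.size()],
                           q[i % q.size()]);
  }
  return out;
}

// overflow-safe logistic
static inline double sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// linear interpolation on a sorted grid; clamped at the ends
static double interp(const double* xs, const double* ys, int n, double x) {
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (xs[mid] <= x) lo = mid; else hi = mid;
  }
  double t = (x - xs[lo]) / (xs[lo + 1] - xs[lo]);
  return ys[lo] + t * (ys[lo + 1] - ys[lo]);
}

struct OdeSpec {
  int kind;              // 0 constant, 1 direct, 2 cooperative
  double k1, k2, w, b, q;
  const double* tf;      // fine regulator grid
  const double* rA;
  const double* rB;
  int nf;
};

static inline double rhs(const OdeSpec& s, double t, double x) {
  double syn;
  if (s.kind == 0) {
    syn = s.k1;
  } else {
    double y;
    if (s.kind == 1) {
      y = interp(s.tf, s.rA, s.nf, t);
    } else {
      double yA = interp(s.tf, s.rA, s.nf, t);
      double yB = interp(s.tf, s.rB, s.nf, t);
      y = complex_conc1(yA, yB, s.q);
    }
    syn = s.k1 * sigmoid(s.w * y + s.b);
  }
  return syn - s.k2 * x;
}

// Cash-Karp embedded Runge-Kutta 4(5), adaptive step, scalar state.
// Integrates from t0 to t1 and returns x(t1).
static double rkck_segment(const OdeSpec& s, double t0, double t1, double x,
                           double reltol, double abstol) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
                      d6 = c6 - 0.25;
  static const double a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875;

  double t = t0;
  double span = t1 - t0;
  if (span <= 0.0) return x;
  double h = span / 8.0;
  const double hmin = span * 1e-10;
  int iter = 0;
  while (t < t1 && iter++ < 100000) {
    if (t + h > t1) h = t1 - t;
    double k1v = rhs(s, t, x);
    double k2v = rhs(s, t + a2 * h, x + h * b21 * k1v);
    double k3v = rhs(s, t + a3 * h, x + h * (b31 * k1v + b32 * k2v));
    double k4v = rhs(s, t + a4 * h, x + h * (b41 * k1v + b42 * k2v + b43 * k3v));
    double k5v = rhs(s, t + a5 * h,
                     x + h * (b51 * k1v + b52 * k2v + b53 * k3v + b54 * k4v));
    double k6v = rhs(s, t + a6 * h,
                     x + h * (b61 * k1v + b62 * k2v + b63 * k3v + b64 * k4v +
                              b65 * k5v));
    double x5 = x + h * (c1 * k1v + c3 * k3v + c4 * k4v + c6 * k6v);
    double err = std::fabs(h * (d1 * k1v + d3 * k3v + d4 * k4v + d5 * k5v +
                                d6 * k6v));
    double tol = abstol + reltol * std::max(std::fabs(x), std::fabs(x5));
    if (err <= tol || h <= hmin) {
      t += h;
      x = x5;
      double fac = (err > 0.0) ? 0.9 * std::pow(tol / err, 0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(tol / err, 0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < hmin) h = hmin;
    }
  }
  return x;
}

static void simulate_core(const OdeSpec& s, double x0,
                          const double* times, int nt, double* out,
                          double reltol, double abstol) {
  out[0] = x0;
  double x = x0;
  for (int i = 1; i < nt; ++i) {
    x = rkck_segment(s, times[i - 1], times[i], x, reltol, abstol);
    out[i] = x;
  }
}

static OdeSpec make_spec(int kind, const NumericVector& par,
                         const NumericVector& tf, const NumericVector& rA,
                         const NumericVector& rB) {
  OdeSpec s;
  s.kind = kind;
  s.k1 = par[0];
  s.k2 = par[1];
  s.w = (kind >= 1) ? par[2] : 0.0;
  s.b = (kind >= 1) ? par[3] : 0.0;
  s.q = (kind == 2) ? par[4] : 0.0;
  s.tf = tf.size() ? &tf[0] : nullptr;
  s.rA = rA.size() ? &rA[0] : nullptr;
  s.rB = rB.size() ? &rB[0] : nullptr;
  s.nf = tf.size();
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_simulate(int kind, NumericVector par, double x0,
                           NumericVector times, NumericVector tf,
                           NumericVector rA, NumericVector rB,
                           double reltol, double abstol) {
  OdeSpec s = make_spec(kind, par, tf, rA, rB);
  int nt = times.size();
  NumericVector out(nt);
  simulate_core(s, x0, &times[0], nt, &out[0], reltol, abstol);
  return out;
}

static double cost_rmse(const OdeSpec& s, double x0, const double* times,
                        const double* target, int nt, double reltol,
                        double abstol, std::vector<double>& buf) {
  simulate_core(s, x0, times, nt, buf.data(), reltol, abstol);
  double ss = 0.0;
  for (int i = 0; i < nt; ++i) {
    double d = buf[i] - target[i];
    ss += d * d;
  }
  return std::sqrt(ss / nt);
}

// rmse of the forward simulation against a target series (used by the
// R-side local polish of annealing results)
// [[Rcpp::export]]
double cpp_fit_cost(int kind, NumericVector par, NumericVector times,
                    NumericVector target, double x0, NumericVector tf,
                    NumericVector rA, NumericVector rB, double reltol,
                    double abstol, bool q_log = false) {
  NumericVector p = clone(par);
  if (kind == 2 && q_log) p[4] = std::pow(10.0, p[4]);
  OdeSpec s = make_spec(kind, p, tf, rA, rB);
  int nt = times.size();
  std::vector<double> buf(nt);
  return cost_rmse(s, x0, &times[0], &target[0], nt, reltol, abstol, buf);
}

// Simulated annealing over the box [lower, upper]; geometric cooling.
// One restart per seed in `seeds`; best parameter vector kept overall.
// [[Rcpp::export]]
List cpp_fit_anneal(int kind, NumericVector times, NumericVector target,
                    double x0, NumericVector tf, NumericVector rA,
                    NumericVector rB, NumericVector lower, NumericVector upper,
                    int n_steps, double t_init, double t_final,
                    IntegerVector seeds, double reltol, double abstol,
                    bool q_log = false,
                    Nullable<NumericMatrix> inits = R_NilValue) {
  NumericMatrix init_mat = inits.isNotNull() ? NumericMatrix(inits)
                                             : NumericMatrix(0, 0);
  int np = lower.size();
  int nt = times.size();
  std::vector<double> buf(nt);
  double scale = 0.0;
  for (int i = 0; i < nt; ++i) scale += std::fabs(target[i]);
  scale = scale / nt;
  if (scale <= 0.0) scale = 1.0;
  double cool = std::pow(t_final / t_init, 1.0 / std::max(1, n_steps - 1));

  NumericVector best_par(np);
  double best_cost = R_PosInf;

  for (int r = 0; r < seeds.size(); ++r) {
    std::mt19937 rng(static_cast<uint32_t>(seeds[r]));
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::normal_distribution<double> norm(0.0, 1.0);

    NumericVector par(np);
    if (r < init_mat.ncol()) {
      for (int j = 0; j < np; ++j) {
        double v = init_mat(j, r);
        par[j] = std::min(std::max(v, lower[j]), upper[j]);
      }
    } else {
      for (int j = 0; j < np; ++j)
        par[j] = lower[j] + unif(rng) * (upper[j] - lower[j]);
    }
    double cost = cpp_fit_cost(kind, par, times, target, x0, tf, rA, rB,
                               reltol, abstol, q_log) / scale;
    NumericVector cur = clone(par);
    double cur_cost = cost;
    if (cur_cost < best_cost) { best_cost = cur_cost; best_par = clone(cur); }

    double temp = t_init;
    NumericVector cand(np);
    for (int step = 0; step < n_steps; ++step) {
      for (int j = 0; j < np; ++j) {
        double width = upper[j] - lower[j];
        // proposal narrows with temperature but keeps a floor for mixing
        double sd = width * std::max(0.01, 0.10 * temp / t_init);
        double v = cur[j] + sd * norm(rng);
        // reflect once at the box edges, then clamp
        if (v < lower[j]) v = 2.0 * lower[j] - v;
        if (v > upper[j]) v = 2.0 * upper[j] - v;
        if (v < lower[j]) v = lower[j];
        if (v > upper[j]) v = upper[j];
        cand[j] = v;
      }
      double c = cpp_fit_cost(kind, cand, times, target, x0, tf, rA, rB,
                              reltol, abstol, q_log) / scale;
      if (c < cur_cost || unif(rng) < std::exp((cur_cost - c) / temp)) {
        cur = clone(cand);
        cur_cost = c;
        if (c < best_cost) { best_cost = c; best_par = clone(cur); }
      }
      temp *= cool;
    }
  }
  return List::create(_["par"] = best_par, _["rmse"] = best_cost * scale,
                      _["scaled_cost"] = best_cost);
}
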