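#include <Rcpp.h>
using namespace Rcpp;

// Exact-in-bout trajectory engine shared by the ensemble estimators.
// Uses R's RNG (so set.seed() on the R side makes runs bit-reproducible)
// and the same closed-form within-bout updates as the R reference
// implementation in simulate_positions().

// acceleration families: 0 gaussian, 1 uniform, 2 two_point
static inline double draw_accel(int family, double nu_a) {
  switch (family) {
  case 0:  return R::rnorm(0.0, nu_a);
  case 1:  return R::runif(-1.7320508075688772 * nu_a,
                            1.7320508075688772 * nu_a);
  default: return unif_rand() < 0.5 ? nu_a : -nu_a;
  }
}

// g + exp(-g) - 1, stable at small g
static inline double f2(double g) {
  if (g < 1e-4)
    return g * g * (0.5 - g * (1.0 / 6.0 - g * (1.0 / 24.0 - g / 120.0)));
  return g + expm1(-g);
}

// advance (y, v) by dt within a bout of constant acceleration a
static inline void advance(double &y, double &v, double a, double gamma,
                           double dt, bool dragfree) {
  if (dt <= 0.0) return;
  if (dragfree) {
    y += v * dt + 0.5 * a * dt * dt;
    v += a * dt;
    return;
  }
  double g = gamma * dt;
  double em1 = -expm1(-g); // 1 - e^{-gamma dt}
  y += (v / gamma) * em1 + (a / (gamma * gamma)) * f2(g);
  v = v * (1.0 - em1) + (a / gamma) * em1;
}

// Accumulate sum(x^2) and sum(x^4) at each sample time over n independent
// trajectories started at rest. sample_times must be sorted ascending.
// [[Rcpp::export(.sim_msd_sums)]]
List sim_msd_sums(int n, NumericVector sample_times, double gamma,
                  double omega, double nu_a, int family) {
  const int m = sample_times.size();
  NumericVector s2(m), s4(m);
  const bool dragfree = gamma < 1e-12;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double t = 0.0, y = 0.0, v = 0.0;
    double a = draw_accel(family, nu_a);
    double bout_end = R::rexp(1.0 / omega);
    for (int j = 0; j < m; ++j) {
      const double s = sample_times[j];
      while (bout_end < s) {
        advance(y, v, a, gamma, bout_end - t, dragfree);
        t = bout_end;
        a = draw_accel(family, nu_a);
        bout_end += R::rexp(1.0 / omega);
      }
      advance(y, v, a, gamma, s - t, dragfree); // bout keeps its residual
      t = s;
      const double x2 = y * y;
      s2[j] += x2;
      s4[j] += x2 * x2;
    }
    if ((i & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum_x2"] = s2, _["sum_x4"] = s4);
}

// Positions of n independent trajectories at each sample time
// (n x m matrix). Used by the dispersal-kernel estimator and tests.
// [[Rcpp::export(.sim_positions_matrix)]]
NumericMatrix sim_positions_matrix(int n, NumericVector sample_times,
                                   double gamma, double omega, double nu_a,
                                   int family) {
  const int m = sample_times.size();
  NumericMatrix out(n, m);
  const bool dragfree = gamma < 1e-12;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double t = 0.0, y = 0.0, v = 0.0;
    double a = draw_accel(family, nu_a);
    double bout_end = R::rexp(1.0 / omega);
    for (int j = 0; j < m; ++j) {
      const double s = sample_times[j];
      while (bout_end < s) {
        advance(y, v, a, gamma, bout_end - t, dragfree);
        t = bout_end;
        a = draw_accel(family, nu_a);
        bout_end += R::rexp(1.0 / omega);
      }
      advance(y, v, a, gamma, s - t, dragfree);
      t = s;
      out(i, j) = y;
    }
    if ((i & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
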