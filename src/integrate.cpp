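// Time-domain integrators for the simulator: zero-order-hold stepping of
// the linear neural states and RK4 integration of the balloon-Windkessel
// hemodynamics (log-state form).  These are the only hot loops in the
// package; everything else stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// x_{t} = Ed x_{t-1} + Bd v_t, returned as an n x N matrix.
// [[Rcpp::export(name = ".neural_zoh")]]
NumericMatrix neural_zoh(NumericMatrix Ed, NumericMatrix Bd,
                         NumericMatrix v) {
  const int n = Ed.nrow(), N = v.nrow();
  NumericMatrix x(n, N);
  std::vector<double> state(n, 0.0), nxt(n);
  for (int t = 0; t < N; ++t) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j)
        acc += Ed(i, j) * state[j] + Bd(i, j) * v(t, j);
      nxt[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(nxt[i]) || std::fabs(nxt[i]) > 1e6)
        stop("neural integration blew up at step %d", t + 1);
      state[i] = nxt[i];
      x(i, t) = nxt[i];
    }
  }
  return x;
}

struct BalloonPars {
  double kappa, gamma, grubb, E0, k1, k2, k3, V0, transit;
};

static inline void balloon_deriv(const double st[4], double u,
                                 const BalloonPars &p, double d[4]) {
  // st = (s, log f, log v, log q); floors keep the equations defined at
  // the model's flow -> 0 boundary
  const double f = std::max(std::exp(st[1]), 0.05);
  const double v = std::max(std::exp(st[2]), 0.05);
  const double q = std::max(std::exp(st[3]), 0.05);
  const double fv = std::pow(v, 1.0 / p.grubb);
  const double Ef = (1.0 - std::pow(1.0 - p.E0, 1.0 / f)) / p.E0;
  d[0] = u - p.kappa * st[0] - p.gamma * (f - 1.0);
  d[1] = st[0] / f;
  d[2] = (f - fv) / (p.transit * v);
  d[3] = (f * Ef - fv * q / v) / (p.transit * q);
}

// [[Rcpp::export(name = ".balloon_rk4")]]
NumericMatrix balloon_rk4(NumericMatrix x, double dt,
                          NumericVector transit, NumericVector epsilon,
                          List constants, int substeps) {
  const int n = x.nrow(), N = x.ncol();
  const double kappa = constants["kappa"], gamma = constants["gamma"],
               grubb = constants["grubb"], E0 = constants["E0"],
               TE = constants["TE"], V0 = constants["V0"],
               nu0 = constants["nu0"], r0 = constants["r0"];
  NumericMatrix y(n, N);
  const double h = dt / substeps;
  for (int i = 0; i < n; ++i) {
    BalloonPars p;
    p.kappa = kappa; p.gamma = gamma; p.grubb = grubb; p.E0 = E0;
    p.V0 = V0; p.transit = transit[i];
    p.k1 = 4.3 * nu0 * E0 * TE;
    p.k2 = epsilon[i] * r0 * E0 * TE;
    p.k3 = 1.0 - epsilon[i];
    double st[4] = {0.0, 0.0, 0.0, 0.0};
    double d1[4], d2[4], d3[4], d4[4], tmp[4];
    for (int t = 0; t < N; ++t) {
      const double u = x(i, t);
      for (int ss = 0; ss < substeps; ++ss) {
        balloon_deriv(st, u, p, d1);
        for (int j = 0; j < 4; ++j) tmp[j] = st[j] + 0.5 * h * d1[j];
        balloon_deriv(tmp, u, p, d2);
        for (int j = 0; j < 4; ++j) tmp[j] = st[j] + 0.5 * h * d2[j];
        balloon_deriv(tmp, u, p, d3);
        for (int j = 0; j < 4; ++j) tmp[j] = st[j] + h * d3[j];
        balloon_deriv(tmp, u, p, d4);
        for (int j = 0; j < 4; ++j)
          st[j] += h / 6.0 * (d1[j] + 2.0 * d2[j] + 2.0 * d3[j] + d4[j]);
      }
      for (int j = 0; j < 4; ++j)
        if (!std::isfinite(st[j]))
          stop("hemodynamic integration blew up at step %d", t + 1);
      const double vv = std::exp(st[2]), qq = std::exp(st[3]);
      y(i, t) = V0 * (p.k1 * (1.0 - qq) + p.k2 * (1.0 - qq / vv) +
                      p.k3 * (1.0 - vv));
    }
  }
  return y;
}
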