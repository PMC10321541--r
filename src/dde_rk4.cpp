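#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the two-variable HES7 delay system by the
// method of steps:
//   dM/dt = a_m / (1 + (P(t - tau_M)/p0)^h) - b_m * M
//   dP/dt = a_p * M(t - tau_P) - b_p * P
// Constant history (M0, P0) for t <= 0. Delayed values at RK4 stage times
// are linearly interpolated from the stored solution grid; a delay of zero
// means the term uses the current stage value. Positive delays smaller than
// dt are rejected because stage lookups would then need future values.

static inline double interp_hist(const std::vector<double> &y, double s,
                                 double dt, double y0) {
  if (s <= 0.0) return y0;
  double idx = s / dt;
  int i0 = (int)std::floor(idx);
  double frac = idx - i0;
  if (frac < 1e-12) return y[i0];
  return y[i0] * (1.0 - frac) + y[i0 + 1] * frac;
}

// [[Rcpp::export(name = ".dde_hes7_rk4")]]
NumericMatrix dde_hes7_rk4(double a_m, double b_m, double a_p, double b_p,
                           double p0, double h, double tau_M, double tau_P,
                           double dt, double t_end, double M0, double P0) {
  if (dt <= 0.0 || t_end <= 0.0) stop("dt and t_end must be positive");
  if ((tau_M > 0.0 && tau_M < dt) || (tau_P > 0.0 && tau_P < dt))
    stop("integration step dt exceeds a positive delay");

  const int n = (int)std::floor(t_end / dt + 1e-9) + 1;
  std::vector<double> M(n), P(n);
  M[0] = M0;
  P[0] = P0;

  auto fM = [&](double Pd, double m) {
    return a_m / (1.0 + std::pow(Pd / p0, h)) - b_m * m;
  };
  auto fP = [&](double Md, double p) { return a_p * Md - b_p * p; };

  for (int i = 0; i < n - 1; ++i) {
    double t = i * dt;
    double m = M[i], p = P[i];

    // delayed arguments at the four stage times
    double Pd1 = interp_hist(P, t - tau_M, dt, P0);
    double Pd2 = interp_hist(P, t + 0.5 * dt - tau_M, dt, P0);
    double Pd4 = interp_hist(P, t + dt - tau_M, dt, P0);

    double k1m = fM(Pd1, m);
    double Md1 = (tau_P > 0.0) ? interp_hist(M, t - tau_P, dt, M0) : m;
    double k1p = fP(Md1, p);

    double m2 = m + 0.5 * dt * k1m, p2 = p + 0.5 * dt * k1p;
    double k2m = fM(Pd2, m2);
    double Md2 = (tau_P > 0.0) ? interp_hist(M, t + 0.5 * dt - tau_P, dt, M0) : m2;
    double k2p = fP(Md2, p2);

    double m3 = m + 0.5 * dt * k2m, p3 = p + 0.5 * dt * k2p;
    double k3m = fM(Pd2, m3);
    double Md3 = (tau_P > 0.0) ? Md2 : m3;
    double k3p = fP(Md3, p3);

    double m4 = m + dt * k3m, p4 = p + dt * k3p;
    double k4m = fM(Pd4, m4);
    double Md4 = (tau_P > 0.0) ? interp_hist(M, t + dt - tau_P, dt, M0) : m4;
    double k4p = fP(Md4, p4);

    M[i + 1] = m + dt / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
    P[i + 1] = p + dt / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);

    if (M[i + 1] < 0.0 || P[i + 1] < 0.0 || !std::isfinite(M[i + 1]) ||
        !std::isfinite(P[i + 1]))
      stop("numerical instability: negative or non-finite state at t = %f",
           t + dt);
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = i * dt;
    out(i, 1) = M[i];
    out(i, 2) = P[i];
  }
  colnames(out) = CharacterVector::create("time", "M", "P");
  return out;
}
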