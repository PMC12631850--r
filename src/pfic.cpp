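// Euler-Maruyama integrator for the two-population (E/I) neural-mass model
// and explicit-Euler Balloon-Windkessel hemodynamics. Kept in C++ because the
// neural states advance at sub-millisecond steps over minutes of simulated
// time; all randomness comes from R's RNG so seeds behave like any other R
// code.
#include <Rcpp.h>
using namespace Rcpp;

static inline double phi(double I, double a, double b, double d) {
  double x = a * I - b;
  double dx = d * x;
  if (std::fabs(dx) < 1e-8)
    return 1.0 / d + x / 2.0 + d * x * x / 12.0;  // removable singularity
  return x / (1.0 - std::exp(-dx));
}

// [[Rcpp::export]]
List pfic_integrate_cpp(NumericMatrix C, double G,
                        NumericVector W_EE, NumericVector W_EI,
                        NumericVector W_IE, double W_II,
                        NumericVector sigma,
                        double w_E, double w_I, double I_0, double J,
                        double a_E, double b_E, double d_E,
                        double a_I, double b_I, double d_I,
                        double tau_E, double tau_I, double gamma,
                        NumericVector S_E0, NumericVector S_I0,
                        double duration, double dt, double burn_in,
                        int store_every) {
  const int n = C.nrow();
  const long n_burn = (long)std::llround(burn_in / dt);
  const long n_keep = (long)std::llround(duration / dt);
  const long n_store = n_keep / store_every;
  const double sdt = std::sqrt(dt);

  std::vector<double> SE(S_E0.begin(), S_E0.end());
  std::vector<double> SI(S_I0.begin(), S_I0.end());
  NumericMatrix oSE(n, n_store), oSI(n, n_store), orE(n, n_store),
      orI(n, n_store), oIE(n, n_store), oII(n, n_store);

  bool noise = false;
  for (int j = 0; j < n; ++j) if (sigma[j] > 0) noise = true;

  std::vector<double> IE(n), II(n), rE(n), rI(n), net(n);
  long stored = 0;
  for (long step = 0; step < n_burn + n_keep; ++step) {
    // network input: G * J * C %*% S_E
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) acc += C(j, k) * SE[k];
      net[j] = G * J * acc;
    }
    for (int j = 0; j < n; ++j) {
      IE[j] = w_E * I_0 + W_EE[j] * J * SE[j] + net[j] - W_IE[j] * SI[j];
      II[j] = w_I * I_0 + W_EI[j] * J * SE[j] - W_II * SI[j];
      if (!std::isfinite(IE[j]) || !std::isfinite(II[j]))
        stop("neural integration diverged at t = %f s (region %d)",
             step * dt, j);
      rE[j] = phi(IE[j], a_E, b_E, d_E);
      rI[j] = phi(II[j], a_I, b_I, d_I);
    }
    if (step >= n_burn && (step - n_burn) % store_every == 0 &&
        stored < n_store) {
      for (int j = 0; j < n; ++j) {
        oSE(j, stored) = SE[j]; oSI(j, stored) = SI[j];
        orE(j, stored) = rE[j]; orI(j, stored) = rI[j];
        oIE(j, stored) = IE[j]; oII(j, stored) = II[j];
      }
      ++stored;
    }
    for (int j = 0; j < n; ++j) {
      double dSE = (-SE[j] / tau_E + (1.0 - SE[j]) * gamma * rE[j]) * dt;
      double dSI = (-SI[j] / tau_I + rI[j]) * dt;
      if (noise && sigma[j] > 0) {
        dSE += sigma[j] * sdt * norm_rand();
        dSI += sigma[j] * sdt * norm_rand();
      }
      SE[j] += dSE;
      SI[j] += dSI;
      if (SE[j] < 0.0) SE[j] = 0.0; else if (SE[j] > 1.0) SE[j] = 1.0;
      if (SI[j] < 0.0) SI[j] = 0.0; else if (SI[j] > 1.0) SI[j] = 1.0;
    }
  }
  return List::create(_["S_E"] = oSE, _["S_I"] = oSI,
                      _["r_E"] = orE, _["r_I"] = orI,
                      _["I_E"] = oIE, _["I_I"] = oII);
}

// [[Rcpp::export]]
NumericMatrix bw_integrate_cpp(NumericMatrix drive, double dt,
                               double kappa, double gamma_h, double tau_h,
                               double alpha, double rho,
                               double V0, double k1, double k2, double k3) {
  const int n = drive.nrow();
  const long nt = drive.ncol();
  const double ialpha = 1.0 / alpha;
  NumericMatrix bold(n, nt);
  std::vector<double> s(n, 0.0), f(n, 1.0), v(n, 1.0), q(n, 1.0);
  for (long t = 0; t < nt; ++t) {
    for (int j = 0; j < n; ++j) {
      double z = drive(j, t);
      double E_f = 1.0 - std::pow(1.0 - rho, 1.0 / f[j]);
      double vout = std::pow(v[j], ialpha);
      double ds = z - kappa * s[j] - gamma_h * (f[j] - 1.0);
      double df = s[j];
      double dv = (f[j] - vout) / tau_h;
      double dq = (f[j] * E_f / rho - vout * q[j] / v[j]) / tau_h;
      s[j] += dt * ds;
      f[j] += dt * df;
      v[j] += dt * dv;
      q[j] += dt * dq;
      if (f[j] < 1e-6) f[j] = 1e-6;
      if (v[j] < 1e-6) v[j] = 1e-6;
      if (q[j] < 1e-6) q[j] = 1e-6;
      if (!std::isfinite(s[j]) || !std::isfinite(v[j]) || !std::isfinite(q[j]))
        stop("hemodynamic integration diverged at t = %f s (region %d)",
             t * dt, j);
      bold(j, t) = V0 * (k1 * (1.0 - q[j]) + k2 * (1.0 - q[j] / v[j]) +
                         k3 * (1.0 - v[j]));
    }
  }
  return bold;
}
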