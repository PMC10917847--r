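// Compiled hot loop of the network simulation: the same seven-equation
// AdEx mean-field dynamics as the R implementation in R/meanfield.R /
// R/simulate.R (which serves as its independent reference in the tests),
// integrated with the stochastic Heun scheme over a delayed network.
//
// Units here match the package-internal convention: rates kHz, time ms,
// potentials mV, conductances nS, capacitance pF, currents pA.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double T, b_e, a, E_L_e, E_L_i, tau_w, N_e, N_i, C_m, g_L;
  double E_exc, E_inh, Q_e, Q_i, tau_e, tau_i, T_refrac, K_e, K_i;
};

const double RATE_FLOOR = 1e-6;  // kHz, keeps fluctuation formulas defined
const double TF_DF = 1e-7;       // kHz, finite-difference step
// difference quotients are formed over the step expressed in Hz, following
// the reference implementation's numerical convention (see R/meanfield.R)
const double TF_DF_HZ = TF_DF * 1e3;

inline void moments(double fe, double fi, double W, const Params &p,
                    double E_L, double &mu_V, double &sigma_V,
                    double &tau_V) {
  double fe_a = (fe + RATE_FLOOR) * p.K_e;
  if (fe_a < 0) fe_a = 0;
  double fi_a = (fi + RATE_FLOOR) * p.K_i;
  if (fi_a < 0) fi_a = 0;
  const double mu_Ge = p.Q_e * p.tau_e * fe_a;
  const double mu_Gi = p.Q_i * p.tau_i * fi_a;
  const double mu_G = p.g_L + mu_Ge + mu_Gi;
  const double tau_m = p.C_m / mu_G;
  mu_V = (mu_Ge * p.E_exc + mu_Gi * p.E_inh + p.g_L * E_L - W) / mu_G;
  const double U_e = p.Q_e / mu_G * (p.E_exc - mu_V);
  const double U_i = p.Q_i / mu_G * (p.E_inh - mu_V);
  const double s_e = fe_a * (U_e * p.tau_e) * (U_e * p.tau_e);
  const double s_i = fi_a * (U_i * p.tau_i) * (U_i * p.tau_i);
  sigma_V = std::sqrt(s_e / (2 * (p.tau_e + tau_m)) +
                      s_i / (2 * (p.tau_i + tau_m)));
  const double den = s_e / (p.tau_e + tau_m) + s_i / (p.tau_i + tau_m);
  tau_V = den > 0 ? (s_e + s_i) / den : tau_m;
}

inline double tf(double fe, double fi, double W, const Params &p,
                 const double *P, double E_L) {
  double mu_V, sigma_V, tau_V;
  moments(fe, fi, W, p, E_L, mu_V, sigma_V, tau_V);
  const double TvN = tau_V * p.g_L / p.C_m;
  const double V = (mu_V + 60) / 10;
  const double S = (sigma_V - 4) / 6;
  const double Tn = TvN - 0.5;
  const double vthr =
      1000 * (P[0] + P[1] * V + P[2] * S + P[3] * Tn + P[4] * V * V +
              P[5] * S * S + P[6] * Tn * Tn + P[7] * V * S + P[8] * V * Tn +
              P[9] * S * Tn);
  double rate =
      std::erfc((vthr - mu_V) / (std::sqrt(2.0) * sigma_V)) / (2 * tau_V);
  if (!(rate > 0)) rate = 0;  // also catches NaN from sigma_V == 0
  const double rmax = 1.0 / p.T_refrac;
  return rate > rmax ? rmax : rate;
}

// transfer function and its first/second input-derivatives (central
// differences), one population, one node
inline void tf_derivs(double fe, double fi, double W, const Params &p,
                      const double *P, double E_L, double &F, double &d_e,
                      double &d_i, double &d2_ee, double &d2_ii,
                      double &d2_ei) {
  const double h = TF_DF;
  const double f00 = tf(fe, fi, W, p, P, E_L);
  const double fp0 = tf(fe + h, fi, W, p, P, E_L);
  const double fm0 = tf(fe - h, fi, W, p, P, E_L);
  const double f0p = tf(fe, fi + h, W, p, P, E_L);
  const double f0m = tf(fe, fi - h, W, p, P, E_L);
  const double fpp = tf(fe + h, fi + h, W, p, P, E_L);
  const double fpm = tf(fe + h, fi - h, W, p, P, E_L);
  const double fmp = tf(fe - h, fi + h, W, p, P, E_L);
  const double fmm = tf(fe - h, fi - h, W, p, P, E_L);
  const double hz = TF_DF_HZ;
  F = f00;
  d_e = (fp0 - fm0) / (2 * hz);
  d_i = (f0p - f0m) / (2 * hz);
  d2_ee = (fp0 - 2 * f00 + fm0) / (hz * hz);
  d2_ii = (f0p - 2 * f00 + f0m) / (hz * hz);
  d2_ei = (fpp - fpm - fmp + fmm) / (4 * hz * hz);
}

// seven-equation right-hand side for one node; s and ds are length-7
// arrays in the package state layout
inline void node_derivs(const double *s, double ext, const Params &p,
                        const double *P_e, const double *P_i, double *ds) {
  const double nu_e = s[0], nu_i = s[1];
  const double c_ee = s[2], c_ei = s[3], c_ii = s[4];
  const double W_e = s[5], W_i = s[6];
  const double fe_tot = nu_e + ext;

  double Fe, de_e, de_i, d2e_ee, d2e_ii, d2e_ei;
  double Fi, di_e, di_i, d2i_ee, d2i_ii, d2i_ei;
  tf_derivs(fe_tot, nu_i, W_e, p, P_e, p.E_L_e, Fe, de_e, de_i, d2e_ee,
            d2e_ii, d2e_ei);
  tf_derivs(fe_tot, nu_i, W_i, p, P_i, p.E_L_i, Fi, di_e, di_i, d2i_ee,
            d2i_ii, d2i_ei);

  ds[0] = ((Fe - nu_e) +
           0.5 * (c_ee * d2e_ee + 2 * c_ei * d2e_ei + c_ii * d2e_ii)) / p.T;
  ds[1] = ((Fi - nu_i) +
           0.5 * (c_ee * d2i_ee + 2 * c_ei * d2i_ei + c_ii * d2i_ii)) / p.T;

  const double invT = 1.0 / p.T;
  const double ge = Fe - nu_e, gi = Fi - nu_i;
  ds[2] = (Fe * (invT - Fe) / p.N_e + ge * ge +
           2 * (de_e * c_ee + de_i * c_ei) - 2 * c_ee) / p.T;
  // cross-covariance pairing as realised in the reference implementation
  ds[3] = (ge * gi + de_e * c_ee + (di_e + de_i) * c_ei + di_i * c_ii -
           2 * c_ei) / p.T;
  ds[4] = (Fi * (invT - Fi) / p.N_i + gi * gi +
           2 * (di_e * c_ei + di_i * c_ii) - 2 * c_ii) / p.T;

  if (p.a != 0) {
    double mu_V, sg, tv;
    moments(fe_tot, nu_i, W_e, p, p.E_L_e, mu_V, sg, tv);
    ds[5] = -W_e / p.tau_w + p.b_e * nu_e + p.a * (mu_V - p.E_L_e) / p.tau_w;
  } else {
    ds[5] = -W_e / p.tau_w + p.b_e * nu_e;
  }
  ds[6] = -W_i / p.tau_w;
}

// Domain guards applied after each integrator stage. Rates live in
// [0, 1/T_refrac] (a population of refractory neurons cannot exceed the
// refractory-limited rate; only finite-difference overshoot of the
// second-order correction can violate it). Covariances are capped at the
// maximal variance of a rate bounded by 1/T_refrac, i.e. (1/(2 T_refrac))^2:
// the truncated moment expansion is linearly unstable where the transfer
// function is steep, and without the cap covariances can run away during
// regime transitions. The caps never bind at the model's fixed points.
inline void clamp_states(double *s, int n, const Params &p) {
  const double rmax = 1.0 / p.T_refrac;
  const double cmax = (0.5 / p.T_refrac) * (0.5 / p.T_refrac);
  for (int k = 0; k < n; ++k) {
    double *x = s + 7 * k;
    for (int v = 0; v < 2; ++v) {
      if (x[v] < 0) x[v] = 0;
      if (x[v] > rmax) x[v] = rmax;
    }
    if (x[2] < 0) x[2] = 0;
    if (x[2] > cmax) x[2] = cmax;
    if (x[3] < -cmax) x[3] = -cmax;
    if (x[3] > cmax) x[3] = cmax;
    if (x[4] < 0) x[4] = 0;
    if (x[4] > cmax) x[4] = cmax;
  }
}

Params unpack(const List &par) {
  Params p;
  p.T = par["T"]; p.b_e = par["b_e"]; p.a = par["a"];
  p.E_L_e = par["E_L_e"]; p.E_L_i = par["E_L_i"]; p.tau_w = par["tau_w"];
  p.N_e = par["N_e"]; p.N_i = par["N_i"];
  p.C_m = par["C_m"]; p.g_L = par["g_L"];
  p.E_exc = par["E_exc"]; p.E_inh = par["E_inh"];
  p.Q_e = par["Q_e"]; p.Q_i = par["Q_i"];
  p.tau_e = par["tau_syn_e"]; p.tau_i = par["tau_syn_i"];
  p.T_refrac = par["T_refrac"]; p.K_e = par["K_e"]; p.K_i = par["K_i"];
  return p;
}

}  // namespace

// Full network integration. init: n x 7 state (kHz units); weights: n x n
// connectome (C[j,k] = weight j -> k); delay_steps: n x n integer delays
// in units of dt; noise: n_steps x n standard-normal increments (may have
// zero rows when sigma == 0). Records every step with t > transient_steps.
// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericMatrix init, NumericMatrix weights,
                  IntegerMatrix delay_steps, NumericMatrix noise, List par,
                  double dt, int n_steps, int transient_steps, double S,
                  double nu_aff, double nu_drive, double sigma,
                  double tau_OU) {
  const int n = init.nrow();
  const Params p = unpack(par);
  double P_e[10], P_i[10];
  {
    NumericVector pe = par["P_e"], pi = par["P_i"];
    for (int i = 0; i < 10; ++i) { P_e[i] = pe[i]; P_i[i] = pi[i]; }
  }
  const bool have_noise = noise.nrow() > 0;
  if (have_noise && (noise.nrow() < n_steps || noise.ncol() != n))
    stop("noise matrix must be n_steps x n_regions");

  int max_d = 0;
  for (int i = 0; i < n * n; ++i)
    if (delay_steps[i] > max_d) max_d = delay_steps[i];
  const int L = max_d + 1;

  // ring buffer of past excitatory rates; column (t % L) holds time t.
  // Initialised by replicating the initial rates over the delay horizon.
  NumericMatrix hist(n, L);
  std::vector<double> state(7 * n), ds1(7 * n), ds2(7 * n), pred(7 * n);
  for (int k = 0; k < n; ++k)
    for (int v = 0; v < 7; ++v) state[7 * k + v] = init(k, v);
  for (int c = 0; c < L; ++c)
    for (int k = 0; k < n; ++k) hist(k, c) = state[7 * k];

  std::vector<double> xi(n, 0.0), ext(n);
  const double sqdt = std::sqrt(dt);

  const int n_keep = n_steps - transient_steps;
  List out(7);
  std::vector<NumericMatrix> rec;
  for (int v = 0; v < 7; ++v) {
    NumericMatrix m(n_keep > 0 ? n_keep : 0, n);
    rec.push_back(m);
    out[v] = m;
  }

  for (int t = 0; t < n_steps; ++t) {
    // OU drive (one independent process per node)
    for (int k = 0; k < n; ++k) {
      if (have_noise) xi[k] += -xi[k] * dt / tau_OU + sqdt * noise(t, k);
      double drive = nu_drive + sigma * xi[k];
      if (drive < 0) drive = 0;
      ext[k] = nu_aff + drive;
    }
    // delayed coupling: S * sum_j C[j,k] * nu_e^j(t - d_jk)
    if (S > 0) {
      for (int k = 0; k < n; ++k) {
        double acc = 0;
        for (int j = 0; j < n; ++j) {
          const double w = weights(j, k);
          if (w == 0) continue;
          int col = (t - delay_steps(j, k)) % L;
          if (col < 0) col += L;
          acc += w * hist(j, col);
        }
        ext[k] += S * acc;
      }
    }
    // stochastic Heun: Euler predictor, trapezoidal corrector, drive and
    // delayed inputs held over the step
    for (int k = 0; k < n; ++k)
      node_derivs(&state[7 * k], ext[k], p, P_e, P_i, &ds1[7 * k]);
    for (int i = 0; i < 7 * n; ++i) pred[i] = state[i] + dt * ds1[i];
    clamp_states(&pred[0], n, p);
    for (int k = 0; k < n; ++k)
      node_derivs(&pred[7 * k], ext[k], p, P_e, P_i, &ds2[7 * k]);
    for (int i = 0; i < 7 * n; ++i)
      state[i] += 0.5 * dt * (ds1[i] + ds2[i]);
    clamp_states(&state[0], n, p);
    for (int i = 0; i < 7 * n; ++i)
      if (!std::isfinite(state[i]))
        stop("integration blow-up at t = %.2f ms (node %d)", (t + 1) * dt,
             i / 7 + 1);
    // push rates at time t+1 into the ring buffer
    const int col = (t + 1) % L;
    for (int k = 0; k < n; ++k) hist(k, col) = state[7 * k];
    if (t + 1 > transient_steps) {
      const int r = t - transient_steps;
      for (int k = 0; k < n; ++k)
        for (int v = 0; v < 7; ++v) rec[v](r, k) = state[7 * k + v];
    }
  }
  out.attr("names") = CharacterVector::create("nu_e", "nu_i", "c_ee", "c_ei",
                                              "c_ii", "W_e", "W_i");
  return out;
}
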