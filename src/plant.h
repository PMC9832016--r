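// Conductance-based three-neuron corticothalamic motif (TC relay, CT cortical,
// RT reticular) with kinetic AMPA/GABA_A/GABA_B synapses and two transmission
// delays, plus the Gaussian-membership fuzzy basis used by the adaptive
// controllers.  All voltages mV, time ms, currents uA/cm^2, conductances
// mS/cm^2, capacitance uF/cm^2.
#ifndef CAEDBS_PLANT_H
#define CAEDBS_PLANT_H

#include <cmath>
#include <vector>
#include <algorithm>

namespace caedbs {

constexpr int N_STATE = 27;
constexpr int N_ION = 28;  // 14 channels x (gbar, E_rev), drift applies here

// ---- state vector layout ----
enum StateIdx {
  S_V_TC = 0, S_V_CT, S_V_RT,
  // TC gating
  S_TC_NA_M, S_TC_NA_H, S_TC_K_N, S_TC_T_M, S_TC_T_H, S_TC_H_R,
  S_TC_K2_M, S_TC_K2_H,
  // CT gating
  S_CT_NA_M, S_CT_NA_H, S_CT_K_N, S_CT_M_P,
  // RT gating
  S_RT_NA_M, S_RT_NA_H, S_RT_K_N, S_RT_TS_M, S_RT_TS_H,
  // synaptic gates
  S_A_CT_TC, S_GA_RT_TC, S_GB_S, S_GB_R, S_A_TC_CT, S_GA_RT_RT, S_A_TC_RT
};

// ---- parameter vector layout (length N_PARAM) ----
// ionic block: (gbar, E) pairs, order:
//   TC: L, Na, K, T, h, K2 | CT: L, Na, K, M | RT: L, Na, K, TS
enum ParamIdx {
  P_C_TC = 0, P_C_CT, P_C_RT,
  P_IEXT_TC, P_IEXT_CT, P_IEXT_RT,
  P_ION0 = 6,
  P_TC_L_G = 6, P_TC_L_E, P_TC_NA_G, P_TC_NA_E, P_TC_K_G, P_TC_K_E,
  P_TC_T_G, P_TC_T_E, P_TC_H_G, P_TC_H_E, P_TC_K2_G, P_TC_K2_E,
  P_CT_L_G, P_CT_L_E, P_CT_NA_G, P_CT_NA_E, P_CT_K_G, P_CT_K_E,
  P_CT_M_G, P_CT_M_E,
  P_RT_L_G, P_RT_L_E, P_RT_NA_G, P_RT_NA_E, P_RT_K_G, P_RT_K_E,
  P_RT_TS_G, P_RT_TS_E,
  P_A_CT_TC_G = 34, P_A_CT_TC_E, P_A_CT_TC_A, P_A_CT_TC_B,
  P_GA_RT_TC_G, P_GA_RT_TC_E, P_GA_RT_TC_A, P_GA_RT_TC_B,
  P_GB_G, P_GB_E, P_GB_KD,
  P_A_TC_CT_G, P_A_TC_CT_E, P_A_TC_CT_A, P_A_TC_CT_B,
  P_GA_RT_RT_G, P_GA_RT_RT_E, P_GA_RT_RT_A, P_GA_RT_RT_B,
  P_A_TC_RT_G, P_A_TC_RT_E, P_A_TC_RT_A, P_A_TC_RT_B,
  N_PARAM
};

// spike-generation threshold offsets (Traub-Miles kinetics)
constexpr double VT_TC = -52.0, VT_CT = -55.0, VT_RT = -67.0;

// GABA_B receptor/G-protein cascade rate constants (1/ms)
constexpr double GB_K1 = 0.18, GB_K2 = 0.034, GB_K3 = 0.5, GB_K4 = 0.0012;

// x/(exp(x/y)-1), guarded at the removable singularity
inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - r / 2.0);
  return x / (std::exp(r) - 1.0);
}

// presynaptic transmitter concentration (Table-style sigmoid)
inline double transmitter(double v_pre) {
  return 2.84 / (1.0 + std::exp((2.0 - v_pre) / 5.0));
}

struct GateRates { double inf, tau; };

// ---- Traub-Miles spike currents (rate form) ----
inline void na_rates(double v, double vt, double& am, double& bm,
                     double& ah, double& bh) {
  double v2 = v - vt;
  am = 0.32 * vtrap(13.0 - v2, 4.0);
  bm = 0.28 * vtrap(v2 - 40.0, 5.0);
  ah = 0.128 * std::exp((17.0 - v2) / 18.0);
  bh = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
}
inline void k_rates(double v, double vt, double& an, double& bn) {
  double v2 = v - vt;
  an = 0.032 * vtrap(15.0 - v2, 5.0);
  bn = 0.5 * std::exp((10.0 - v2) / 40.0);
}

// ---- TC low-threshold Ca (IT), 36 C ----
inline GateRates it_m(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
  g.tau = (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) +
                          std::exp((v + 16.8) / 18.2))) / 4.57;
  return g;
}
inline GateRates it_h(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
  double t;
  if (v < -80.0) t = std::exp((v + 467.0) / 66.6);
  else t = 28.0 + std::exp(-(v + 22.0) / 10.5);
  g.tau = t / 3.73;
  return g;
}

// ---- TC hyperpolarization-activated mixed cation (Ih), voltage-only ----
inline GateRates ih_r(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
  g.tau = 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) +
                           std::exp(-(v + 89.0) / 11.6));
  return g;
}

// ---- TC slow K (IK2) ----
inline GateRates ik2_m(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 43.0) / 17.0));
  g.tau = 1.0 / (std::exp((v - 81.0) / 25.6) +
                 std::exp(-(v + 132.0) / 18.0)) + 9.9;
  return g;
}
inline GateRates ik2_h(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp((v + 58.0) / 10.6));
  g.tau = 1.0 / (std::exp((v - 1329.0) / 200.0) +
                 std::exp(-(v + 130.0) / 7.1)) + 120.0;
  return g;
}

// ---- CT muscarinic K (IM) ----
inline GateRates im_p(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  g.tau = 1000.0 / (3.3 * std::exp((v + 35.0) / 20.0) +
                    std::exp(-(v + 35.0) / 20.0));
  return g;
}

// ---- RT low-threshold Ca (ITS), 36 C ----
inline GateRates its_m(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4));
  g.tau = (1.0 + 0.33 / (std::exp((v + 27.0) / 10.0) +
                         std::exp(-(v + 102.0) / 15.0))) / 3.0;
  return g;
}
inline GateRates its_h(double v) {
  GateRates g;
  g.inf = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
  g.tau = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) +
                         std::exp(-(v + 407.0) / 50.0))) / 3.0;
  return g;
}

// Full state derivative.  v_ct_del = V_CT(t - tau1), v_tc_del = V_TC(t - tau2).
// If f / ftau are non-null they receive the canonical voltage-equation split
// (f: all non-delayed terms incl. I_ext; ftau: delayed-pathway synaptic terms);
// control u and disturbance d enter as G.(u) + d with G = diag(1/C).
inline void plant_deriv(const double* x, double v_ct_del, double v_tc_del,
                        const double* p, const double* u, const double* d,
                        double* dx, double* f = nullptr, double* ftau = nullptr) {
  const double v_tc = x[S_V_TC], v_ct = x[S_V_CT], v_rt = x[S_V_RT];

  // --- synaptic gate kinetics ---
  const double T_rt = transmitter(v_rt);
  dx[S_A_CT_TC] = p[P_A_CT_TC_A] * transmitter(v_ct_del) * (1.0 - x[S_A_CT_TC])
                  - p[P_A_CT_TC_B] * x[S_A_CT_TC];
  dx[S_GA_RT_TC] = p[P_GA_RT_TC_A] * T_rt * (1.0 - x[S_GA_RT_TC])
                   - p[P_GA_RT_TC_B] * x[S_GA_RT_TC];
  dx[S_GB_S] = GB_K1 * x[S_GB_R] - GB_K2 * x[S_GB_S];
  dx[S_GB_R] = GB_K3 * T_rt * (1.0 - x[S_GB_R]) - GB_K4 * x[S_GB_R];
  dx[S_A_TC_CT] = p[P_A_TC_CT_A] * transmitter(v_tc_del) * (1.0 - x[S_A_TC_CT])
                  - p[P_A_TC_CT_B] * x[S_A_TC_CT];
  dx[S_GA_RT_RT] = p[P_GA_RT_RT_A] * T_rt * (1.0 - x[S_GA_RT_RT])
                   - p[P_GA_RT_RT_B] * x[S_GA_RT_RT];
  dx[S_A_TC_RT] = p[P_A_TC_RT_A] * transmitter(v_tc) * (1.0 - x[S_A_TC_RT])
                  - p[P_A_TC_RT_B] * x[S_A_TC_RT];

  // --- synaptic currents ---
  const double i_ampa_ct_tc = p[P_A_CT_TC_G] * x[S_A_CT_TC] * (v_tc - p[P_A_CT_TC_E]);
  const double i_gaa_rt_tc  = p[P_GA_RT_TC_G] * x[S_GA_RT_TC] * (v_tc - p[P_GA_RT_TC_E]);
  const double s4 = std::pow(x[S_GB_S], 4);
  const double i_gab_rt_tc  = p[P_GB_G] * s4 / (s4 + p[P_GB_KD]) * (v_tc - p[P_GB_E]);
  const double i_ampa_tc_ct = p[P_A_TC_CT_G] * x[S_A_TC_CT] * (v_ct - p[P_A_TC_CT_E]);
  const double i_gaa_rt_rt  = p[P_GA_RT_RT_G] * x[S_GA_RT_RT] * (v_rt - p[P_GA_RT_RT_E]);
  const double i_ampa_tc_rt = p[P_A_TC_RT_G] * x[S_A_TC_RT] * (v_rt - p[P_A_TC_RT_E]);

  // --- TC gating ---
  {
    double am, bm, ah, bh, an, bn;
    na_rates(v_tc, VT_TC, am, bm, ah, bh);
    k_rates(v_tc, VT_TC, an, bn);
    dx[S_TC_NA_M] = am * (1.0 - x[S_TC_NA_M]) - bm * x[S_TC_NA_M];
    dx[S_TC_NA_H] = ah * (1.0 - x[S_TC_NA_H]) - bh * x[S_TC_NA_H];
    dx[S_TC_K_N]  = an * (1.0 - x[S_TC_K_N]) - bn * x[S_TC_K_N];
    GateRates g;
    g = it_m(v_tc);  dx[S_TC_T_M]  = (g.inf - x[S_TC_T_M]) / g.tau;
    g = it_h(v_tc);  dx[S_TC_T_H]  = (g.inf - x[S_TC_T_H]) / g.tau;
    g = ih_r(v_tc);  dx[S_TC_H_R]  = (g.inf - x[S_TC_H_R]) / g.tau;
    g = ik2_m(v_tc); dx[S_TC_K2_M] = (g.inf - x[S_TC_K2_M]) / g.tau;
    g = ik2_h(v_tc); dx[S_TC_K2_H] = (g.inf - x[S_TC_K2_H]) / g.tau;
  }
  // --- CT gating ---
  {
    double am, bm, ah, bh, an, bn;
    na_rates(v_ct, VT_CT, am, bm, ah, bh);
    k_rates(v_ct, VT_CT, an, bn);
    dx[S_CT_NA_M] = am * (1.0 - x[S_CT_NA_M]) - bm * x[S_CT_NA_M];
    dx[S_CT_NA_H] = ah * (1.0 - x[S_CT_NA_H]) - bh * x[S_CT_NA_H];
    dx[S_CT_K_N]  = an * (1.0 - x[S_CT_K_N]) - bn * x[S_CT_K_N];
    GateRates g = im_p(v_ct);
    dx[S_CT_M_P] = (g.inf - x[S_CT_M_P]) / g.tau;
  }
  // --- RT gating ---
  {
    double am, bm, ah, bh, an, bn;
    na_rates(v_rt, VT_RT, am, bm, ah, bh);
    k_rates(v_rt, VT_RT, an, bn);
    dx[S_RT_NA_M] = am * (1.0 - x[S_RT_NA_M]) - bm * x[S_RT_NA_M];
    dx[S_RT_NA_H] = ah * (1.0 - x[S_RT_NA_H]) - bh * x[S_RT_NA_H];
    dx[S_RT_K_N]  = an * (1.0 - x[S_RT_K_N]) - bn * x[S_RT_K_N];
    GateRates g;
    g = its_m(v_rt); dx[S_RT_TS_M] = (g.inf - x[S_RT_TS_M]) / g.tau;
    g = its_h(v_rt); dx[S_RT_TS_H] = (g.inf - x[S_RT_TS_H]) / g.tau;
  }

  // --- ionic currents ---
  double m, h, n;
  m = x[S_TC_NA_M]; h = x[S_TC_NA_H]; n = x[S_TC_K_N];
  const double i_ion_tc =
      p[P_TC_L_G] * (v_tc - p[P_TC_L_E]) +
      p[P_TC_NA_G] * m * m * m * h * (v_tc - p[P_TC_NA_E]) +
      p[P_TC_K_G] * n * n * n * n * (v_tc - p[P_TC_K_E]) +
      p[P_TC_T_G] * x[S_TC_T_M] * x[S_TC_T_M] * x[S_TC_T_H] * (v_tc - p[P_TC_T_E]) +
      p[P_TC_H_G] * x[S_TC_H_R] * (v_tc - p[P_TC_H_E]) +
      p[P_TC_K2_G] * x[S_TC_K2_M] * x[S_TC_K2_H] * (v_tc - p[P_TC_K2_E]);
  m = x[S_CT_NA_M]; h = x[S_CT_NA_H]; n = x[S_CT_K_N];
  const double i_ion_ct =
      p[P_CT_L_G] * (v_ct - p[P_CT_L_E]) +
      p[P_CT_NA_G] * m * m * m * h * (v_ct - p[P_CT_NA_E]) +
      p[P_CT_K_G] * n * n * n * n * (v_ct - p[P_CT_K_E]) +
      p[P_CT_M_G] * x[S_CT_M_P] * (v_ct - p[P_CT_M_E]);
  m = x[S_RT_NA_M]; h = x[S_RT_NA_H]; n = x[S_RT_K_N];
  const double i_ion_rt =
      p[P_RT_L_G] * (v_rt - p[P_RT_L_E]) +
      p[P_RT_NA_G] * m * m * m * h * (v_rt - p[P_RT_NA_E]) +
      p[P_RT_K_G] * n * n * n * n * (v_rt - p[P_RT_K_E]) +
      p[P_RT_TS_G] * x[S_RT_TS_M] * x[S_RT_TS_M] * x[S_RT_TS_H] * (v_rt - p[P_RT_TS_E]);

  // --- voltage equations: C dV/dt = -I_ion - I_syn + I_ext + u + d ---
  const double f_tc = (-i_ion_tc - i_gaa_rt_tc - i_gab_rt_tc + p[P_IEXT_TC]) / p[P_C_TC];
  const double f_ct = (-i_ion_ct + p[P_IEXT_CT]) / p[P_C_CT];
  const double f_rt = (-i_ion_rt - i_gaa_rt_rt - i_ampa_tc_rt + p[P_IEXT_RT]) / p[P_C_RT];
  const double ft_tc = -i_ampa_ct_tc / p[P_C_TC];
  const double ft_ct = -i_ampa_tc_ct / p[P_C_CT];

  const double u_tc = u ? u[0] : 0.0, u_ct = u ? u[1] : 0.0, u_rt = u ? u[2] : 0.0;
  const double d_tc = d ? d[0] : 0.0, d_ct = d ? d[1] : 0.0, d_rt = d ? d[2] : 0.0;
  dx[S_V_TC] = f_tc + ft_tc + u_tc / p[P_C_TC] + d_tc;
  dx[S_V_CT] = f_ct + ft_ct + u_ct / p[P_C_CT] + d_ct;
  dx[S_V_RT] = f_rt + 0.0   + u_rt / p[P_C_RT] + d_rt;

  if (f)    { f[0] = f_tc;  f[1] = f_ct;  f[2] = f_rt; }
  if (ftau) { ftau[0] = ft_tc; ftau[1] = ft_ct; ftau[2] = 0.0; }
}

// Per-stage delayed voltages for one RK4 step over [t, t + dt]:
// values at t - tau, t + dt/2 - tau, t + dt - tau.  A zero delay is signalled
// with inst = true, in which case the integrator substitutes the stage's own
// instantaneous voltage.
struct StageDelay {
  double v[3];
  bool inst;
};

// classical RK4 step; delayed voltages supplied per stage (method of steps)
inline void rk4_step(double* x, const StageDelay& ct, const StageDelay& tc,
                     const double* p, const double* u, const double* d,
                     double dt) {
  double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE], xt[N_STATE];
  auto dct = [&](const double* xs, int stage) {
    return ct.inst ? xs[S_V_CT] : ct.v[stage];
  };
  auto dtc = [&](const double* xs, int stage) {
    return tc.inst ? xs[S_V_TC] : tc.v[stage];
  };
  plant_deriv(x, dct(x, 0), dtc(x, 0), p, u, d, k1);
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  plant_deriv(xt, dct(xt, 1), dtc(xt, 1), p, u, d, k2);
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  plant_deriv(xt, dct(xt, 1), dtc(xt, 1), p, u, d, k3);
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + dt * k3[i];
  plant_deriv(xt, dct(xt, 2), dtc(xt, 2), p, u, d, k4);
  for (int i = 0; i < N_STATE; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// gating and synaptic gates at their steady state for given voltages
inline void steady_state(double v_tc, double v_ct, double v_rt,
                         const double* p, double* x) {
  for (int i = 0; i < N_STATE; ++i) x[i] = 0.0;
  x[S_V_TC] = v_tc; x[S_V_CT] = v_ct; x[S_V_RT] = v_rt;
  double am, bm, ah, bh, an, bn;
  na_rates(v_tc, VT_TC, am, bm, ah, bh);
  k_rates(v_tc, VT_TC, an, bn);
  x[S_TC_NA_M] = am / (am + bm); x[S_TC_NA_H] = ah / (ah + bh);
  x[S_TC_K_N] = an / (an + bn);
  x[S_TC_T_M] = it_m(v_tc).inf;  x[S_TC_T_H] = it_h(v_tc).inf;
  x[S_TC_H_R] = ih_r(v_tc).inf;
  x[S_TC_K2_M] = ik2_m(v_tc).inf; x[S_TC_K2_H] = ik2_h(v_tc).inf;
  na_rates(v_ct, VT_CT, am, bm, ah, bh);
  k_rates(v_ct, VT_CT, an, bn);
  x[S_CT_NA_M] = am / (am + bm); x[S_CT_NA_H] = ah / (ah + bh);
  x[S_CT_K_N] = an / (an + bn);
  x[S_CT_M_P] = im_p(v_ct).inf;
  na_rates(v_rt, VT_RT, am, bm, ah, bh);
  k_rates(v_rt, VT_RT, an, bn);
  x[S_RT_NA_M] = am / (am + bm); x[S_RT_NA_H] = ah / (ah + bh);
  x[S_RT_K_N] = an / (an + bn);
  x[S_RT_TS_M] = its_m(v_rt).inf; x[S_RT_TS_H] = its_h(v_rt).inf;
  // synaptic gates: first-order equilibria at the instantaneous presynaptic V
  auto s_eq = [](double a, double T, double b) { return a * T / (a * T + b); };
  const double T_ct = transmitter(v_ct), T_tc = transmitter(v_tc),
               T_rt = transmitter(v_rt);
  x[S_A_CT_TC] = s_eq(p[P_A_CT_TC_A], T_ct, p[P_A_CT_TC_B]);
  x[S_GA_RT_TC] = s_eq(p[P_GA_RT_TC_A], T_rt, p[P_GA_RT_TC_B]);
  x[S_GB_R] = GB_K3 * T_rt / (GB_K3 * T_rt + GB_K4);
  x[S_GB_S] = GB_K1 / GB_K2 * x[S_GB_R];
  x[S_A_TC_CT] = s_eq(p[P_A_TC_CT_A], T_tc, p[P_A_TC_CT_B]);
  x[S_GA_RT_RT] = s_eq(p[P_GA_RT_RT_A], T_rt, p[P_GA_RT_RT_B]);
  x[S_A_TC_RT] = s_eq(p[P_A_TC_RT_A], T_tc, p[P_A_TC_RT_B]);
}

// ---- fuzzy basis ----
// normalized product-inference basis over a 5x5x5 rule grid; evaluated in the
// log domain (raw Gaussian products underflow for narrow widths) so the
// normalized vector is always well defined and sums to 1.
constexpr int N_RULE = 125;

inline void fuzzy_basis(const double x[3], const double* c /*5*/, double delta,
                        double* zeta /*125*/) {
  double lm[3][5];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 5; ++i) {
      double z = (x[j] - c[i]) / delta;
      lm[j][i] = -0.5 * z * z;
    }
  double lw[N_RULE];
  double mx = -1e300;
  int k = 0;
  for (int i1 = 0; i1 < 5; ++i1)
    for (int i2 = 0; i2 < 5; ++i2)
      for (int i3 = 0; i3 < 5; ++i3, ++k) {
        lw[k] = lm[0][i1] + lm[1][i2] + lm[2][i3];
        if (lw[k] > mx) mx = lw[k];
      }
  double sum = 0.0;
  for (k = 0; k < N_RULE; ++k) {
    double e = lw[k] - mx;
    zeta[k] = (e < -745.0) ? 0.0 : std::exp(e);
    sum += zeta[k];
  }
  const double inv = 1.0 / std::max(sum, 1e-20);
  for (k = 0; k < N_RULE; ++k) zeta[k] *= inv;
}

// sparse basis evaluation for the inner loop: with narrow memberships only
// a handful of rules carry non-negligible weight (components below
// exp(-40) of the peak are exact zeros after normalization at double
// precision, since the peak component is >= 1/125 of the sum)
inline int fuzzy_basis_sparse(const double x[3], const double* c, double delta,
                              double* vals, int* idx) {
  double lm[3][5];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 5; ++i) {
      double z = (x[j] - c[i]) / delta;
      lm[j][i] = -0.5 * z * z;
    }
  double mx = -1e300;
  int k = 0;
  double lw[N_RULE];
  for (int i1 = 0; i1 < 5; ++i1)
    for (int i2 = 0; i2 < 5; ++i2)
      for (int i3 = 0; i3 < 5; ++i3, ++k) {
        lw[k] = lm[0][i1] + lm[1][i2] + lm[2][i3];
        if (lw[k] > mx) mx = lw[k];
      }
  int n = 0;
  double sum = 0.0;
  for (k = 0; k < N_RULE; ++k) {
    double e = lw[k] - mx;
    if (e > -40.0) {
      vals[n] = std::exp(e);
      sum += vals[n];
      idx[n++] = k;
    }
  }
  const double inv = 1.0 / std::max(sum, 1e-20);
  for (k = 0; k < n; ++k) vals[k] *= inv;
  return n;
}

inline double sgn(double v) { return (v > 0.0) - (v < 0.0); }

}  // namespace caedbs

#endif
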