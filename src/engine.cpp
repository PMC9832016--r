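// Rcpp entry points: elementary plant operations (derivative, canonical
// split, one RK4 step, steady-state initialisation), the open-loop simulator
// and the closed-loop trial engine used by run_trial().
#include <Rcpp.h>
#include "plant.h"

using namespace Rcpp;
using namespace caedbs;

namespace {

// fixed-capacity ring buffer of past voltages at grid resolution
struct DelayLine {
  std::vector<double> buf;
  int head = 0;
  explicit DelayLine(int capacity, double fill)
      : buf(std::max(capacity, 1), fill) {}
  void push(double v) {
    head = (head + 1) % static_cast<int>(buf.size());
    buf[head] = v;
  }
  // value k steps in the past (k = 0 -> most recent push / initial fill)
  double lookback(int k) const {
    int n = static_cast<int>(buf.size());
    return buf[((head - k) % n + n) % n];
  }
  // stage values V(t - k dt), V(t + dt/2 - k dt), V(t + dt - k dt) for one
  // RK4 step; half-grid value by 4-point interpolation (order matches RK4)
  StageDelay stages(int k) const {
    StageDelay sd;
    sd.inst = (k == 0);
    if (sd.inst) { sd.v[0] = sd.v[1] = sd.v[2] = 0.0; return sd; }
    const double v0 = lookback(k), v1 = lookback(k - 1);
    sd.v[0] = v0;
    sd.v[2] = v1;
    if (k >= 2) {
      const double vm1 = lookback(k + 1), v2 = lookback(k - 2);
      sd.v[1] = (-vm1 + 9.0 * v0 + 9.0 * v1 - v2) / 16.0;
    } else {
      sd.v[1] = 0.5 * (v0 + v1);
    }
    return sd;
  }
};

void check_param_len(const NumericVector& p) {
  if (p.size() != N_PARAM) stop("parameter vector must have length %d", N_PARAM);
}
void check_state_len(const NumericVector& x) {
  if (x.size() != N_STATE) stop("state vector must have length %d", N_STATE);
}

bool state_bad(const double* x) {
  for (int i = 0; i < 3; ++i)
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > 150.0) return true;
  for (int i = 3; i < N_STATE; ++i)
    if (!std::isfinite(x[i])) return true;
  return false;
}

// solve the symmetric positive definite 3x3 system M y = b (Cholesky)
void solve3(const double M[3][3], const double b[3], double y[3]) {
  double L[3][3] = {{0}};
  L[0][0] = std::sqrt(M[0][0]);
  L[1][0] = M[1][0] / L[0][0];
  L[2][0] = M[2][0] / L[0][0];
  L[1][1] = std::sqrt(M[1][1] - L[1][0] * L[1][0]);
  L[2][1] = (M[2][1] - L[2][0] * L[1][0]) / L[1][1];
  L[2][2] = std::sqrt(M[2][2] - L[2][0] * L[2][0] - L[2][1] * L[2][1]);
  double z[3];
  z[0] = b[0] / L[0][0];
  z[1] = (b[1] - L[1][0] * z[0]) / L[1][1];
  z[2] = (b[2] - L[2][0] * z[0] - L[2][1] * z[1]) / L[2][2];
  y[2] = z[2] / L[2][2];
  y[1] = (z[1] - L[2][1] * y[2]) / L[1][1];
  y[0] = (z[0] - L[1][0] * y[1] - L[2][0] * y[2]) / L[0][0];
}

// RK4 with stage-1 derivative supplied by the caller
void rk4_from_k1(double* x, const double* k1, const StageDelay& ct,
                 const StageDelay& tc, const double* p, const double* u,
                 const double* d, double dt) {
  double k2[N_STATE], k3[N_STATE], k4[N_STATE], xt[N_STATE];
  auto dct = [&](const double* xs, int st) {
    return ct.inst ? xs[S_V_CT] : ct.v[st];
  };
  auto dtc = [&](const double* xs, int st) {
    return tc.inst ? xs[S_V_TC] : tc.v[st];
  };
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  plant_deriv(xt, dct(xt, 1), dtc(xt, 1), p, u, d, k2);
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  plant_deriv(xt, dct(xt, 1), dtc(xt, 1), p, u, d, k3);
  for (int i = 0; i < N_STATE; ++i) xt[i] = x[i] + dt * k3[i];
  plant_deriv(xt, dct(xt, 2), dtc(xt, 2), p, u, d, k4);
  for (int i = 0; i < N_STATE; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

}  // namespace

// [[Rcpp::export]]
List cpp_plant_deriv(NumericVector x, double v_ct_del, double v_tc_del,
                     NumericVector p, NumericVector u, NumericVector d) {
  check_state_len(x);
  check_param_len(p);
  double dx[N_STATE], f[3], ftau[3];
  plant_deriv(REAL(x), v_ct_del, v_tc_del, REAL(p), REAL(u), REAL(d), dx, f, ftau);
  NumericMatrix G(3, 3);
  G(0, 0) = 1.0 / p[P_C_TC];
  G(1, 1) = 1.0 / p[P_C_CT];
  G(2, 2) = 1.0 / p[P_C_RT];
  return List::create(_["dx"] = NumericVector(dx, dx + N_STATE),
                      _["f"] = NumericVector(f, f + 3),
                      _["f_tau"] = NumericVector(ftau, ftau + 3),
                      _["G"] = G);
}

// v_ct_del / v_tc_del: length-3 stage values of the delayed voltage
// (t - tau, t + dt/2 - tau, t + dt - tau); NULL means zero delay
// (instantaneous voltage used at every stage).
// [[Rcpp::export]]
NumericVector cpp_rk4_step(NumericVector x, Nullable<NumericVector> v_ct_del,
                           Nullable<NumericVector> v_tc_del,
                           NumericVector p, NumericVector u, NumericVector d,
                           double dt) {
  check_state_len(x);
  check_param_len(p);
  StageDelay ct, tc;
  auto fill = [](Nullable<NumericVector> v, StageDelay& sd) {
    if (v.isNull()) { sd.inst = true; sd.v[0] = sd.v[1] = sd.v[2] = 0.0; return; }
    NumericVector vv(v);
    sd.inst = false;
    if (vv.size() == 1) { sd.v[0] = sd.v[1] = sd.v[2] = vv[0]; }
    else if (vv.size() == 3) { sd.v[0] = vv[0]; sd.v[1] = vv[1]; sd.v[2] = vv[2]; }
    else stop("delayed voltage must be NULL, length 1 or length 3");
  };
  fill(v_ct_del, ct);
  fill(v_tc_del, tc);
  NumericVector out = clone(x);
  rk4_step(REAL(out), ct, tc, REAL(p), REAL(u), REAL(d), dt);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_steady_state(double v_tc, double v_ct, double v_rt,
                               NumericVector p) {
  check_param_len(p);
  NumericVector x(N_STATE);
  steady_state(v_tc, v_ct, v_rt, REAL(p), REAL(x));
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_fuzzy_basis(NumericVector x, NumericVector centers,
                              double delta) {
  if (x.size() != 3) stop("input must be a 3-vector");
  if (centers.size() != 5) stop("five centers per input are required");
  if (delta <= 0) stop("membership width must be positive");
  NumericVector zeta(N_RULE);
  fuzzy_basis(REAL(x), REAL(centers), delta, REAL(zeta));
  return zeta;
}

// [[Rcpp::export]]
List cpp_simulate_plant(NumericVector p, NumericVector x0, double dt,
                        int n_steps, int tau1_steps, int tau2_steps,
                        int record_every, Nullable<NumericMatrix> u_sched,
                        Nullable<NumericMatrix> d_sched) {
  check_param_len(p);
  check_state_len(x0);
  if (dt <= 0) stop("dt must be positive");
  if (n_steps < 1) stop("at least one step is required");

  double x[N_STATE];
  std::copy(x0.begin(), x0.end(), x);
  DelayLine hist_ct(tau1_steps + 2, x[S_V_CT]);
  DelayLine hist_tc(tau2_steps + 2, x[S_V_TC]);

  NumericMatrix usch, dsch;
  bool has_u = u_sched.isNotNull(), has_d = d_sched.isNotNull();
  if (has_u) {
    usch = NumericMatrix(u_sched);
    if (usch.nrow() != n_steps || usch.ncol() != 3)
      stop("input schedule must be n_steps x 3");
  }
  if (has_d) {
    dsch = NumericMatrix(d_sched);
    if (dsch.nrow() != n_steps || dsch.ncol() != 3)
      stop("disturbance schedule must be n_steps x 3");
  }

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix traj(n_rec, N_STATE);
  NumericMatrix u_rec(n_rec, 3);
  NumericVector t_rec(n_rec);
  int rec = 0;
  bool diverged = false;
  double t_div = NA_REAL;

  double u[3] = {0, 0, 0}, d[3] = {0, 0, 0};
  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (i % record_every == 0 && rec < n_rec) {
      t_rec[rec] = t;
      for (int j = 0; j < N_STATE; ++j) traj(rec, j) = x[j];
      u_rec(rec, 0) = u[0]; u_rec(rec, 1) = u[1]; u_rec(rec, 2) = u[2];
      ++rec;
    }
    if (i == n_steps) break;
    if (has_u) { u[0] = usch(i, 0); u[1] = usch(i, 1); u[2] = usch(i, 2); }
    if (has_d) { d[0] = dsch(i, 0); d[1] = dsch(i, 1); d[2] = dsch(i, 2); }
    rk4_step(x, hist_ct.stages(tau1_steps), hist_tc.stages(tau2_steps),
             REAL(p), u, d, dt);
    hist_ct.push(x[S_V_CT]);
    hist_tc.push(x[S_V_TC]);
    if (state_bad(x)) { diverged = true; t_div = (i + 1) * dt; break; }
  }
  if (rec < n_rec) {
    t_rec = head(t_rec, rec);
    traj = traj(Range(0, std::max(rec - 1, 0)), _);
    u_rec = u_rec(Range(0, std::max(rec - 1, 0)), _);
  }
  return List::create(_["t"] = t_rec, _["state"] = traj, _["u"] = u_rec,
                      _["diverged"] = diverged, _["t_div"] = t_div);
}

// Closed-loop trial: co-simulates the desired (normal) plant and the actual
// (CAE) plant under the selected controller.
// controller: 0 none, 1 AFTSMC, 2 AFSMC, 3 STSMC
// [[Rcpp::export]]
List cpp_run_closed_loop(NumericVector p_des, NumericVector p_act,
                         NumericVector x0_des, NumericVector x0_act,
                         double dt, int n_steps, int tau1_steps, int tau2_steps,
                         int controller, List ctrl, NumericMatrix psi0,
                         NumericVector centers, double delta,
                         NumericVector dist_onsets, double dist_amp,
                         double dist_width, int dist_target,
                         Nullable<NumericMatrix> drift_, double drift_dt,
                         int record_every) {
  check_param_len(p_des);
  check_param_len(p_act);
  check_state_len(x0_des);
  check_state_len(x0_act);
  if (centers.size() != 5) stop("five membership centers are required");
  if (delta <= 0) stop("membership width must be positive");
  if (controller < 0 || controller > 3) stop("unknown controller code");
  if ((controller == 1 || controller == 2) &&
      (psi0.nrow() != 15 || psi0.ncol() != N_RULE))
    stop("initial weights must be a 15 x 125 matrix");

  // controller parameters
  const double sigma = as<double>(ctrl["sigma"]);
  const double eta = as<double>(ctrl["eta"]);
  const double rho = as<double>(ctrl["rho"]);
  NumericVector K1 = ctrl["K1"], K2 = ctrl["K2"];
  const double eps0 = as<double>(ctrl["eps0"]);
  const double sigma0 = as<double>(ctrl["sigma0"]);
  const double kap_f = as<double>(ctrl["kappa_f"]);
  const double kap_ft = as<double>(ctrl["kappa_ftau"]);
  const double kap_g = as<double>(ctrl["kappa_g"]);
  const double kap0 = as<double>(ctrl["kappa0"]);
  const double gam0 = as<double>(ctrl["gamma0"]);
  const double gam1 = as<double>(ctrl["gamma1"]);
  const double gam2 = as<double>(ctrl["gamma2"]);
  const double gam3 = as<double>(ctrl["gamma3"]);
  const double ups0 = as<double>(ctrl["upsilon0"]);
  const double ups_min = as<double>(ctrl["upsilon_min"]);
  const double psi_clip = as<double>(ctrl["psi_clip"]);
  const double eps_g_max = as<double>(ctrl["eps_g_max"]);
  const double u_max = as<double>(ctrl["u_max"]);  // <= 0 disables saturation
  const double lambda = as<double>(ctrl["lambda"]);
  const double k1_lin = as<double>(ctrl["k1_lin"]);
  const double k_sw = as<double>(ctrl["k_sw"]);
  const double st_a = as<double>(ctrl["st_a"]);
  const double st_b = as<double>(ctrl["st_b"]);

  if (sigma <= 0 || eta <= 1 || eta >= 2 || rho <= 0 || rho >= 1)
    stop("surface parameters out of range (sigma > 0, 1 < eta < 2, 0 < rho < 1)");

  // weights: rows 0-2 f, 3-5 f_tau, 6-14 G (row-major)
  std::vector<double> psi(15 * N_RULE, 0.0);
  if (psi0.nrow() == 15)
    for (int r = 0; r < 15; ++r)
      for (int k = 0; k < N_RULE; ++k) psi[r * N_RULE + k] = psi0(r, k);

  NumericMatrix drift;
  bool has_drift = drift_.isNotNull();
  if (has_drift) {
    drift = NumericMatrix(drift_);
    if (drift.ncol() != N_ION)
      stop("drift matrix must have %d columns", N_ION);
  }

  double xd[N_STATE], xa[N_STATE];
  std::copy(x0_des.begin(), x0_des.end(), xd);
  std::copy(x0_act.begin(), x0_act.end(), xa);
  DelayLine d_ct(tau1_steps + 2, xd[S_V_CT]), d_tc(tau2_steps + 2, xd[S_V_TC]);
  DelayLine a_ct(tau1_steps + 2, xa[S_V_CT]), a_tc(tau2_steps + 2, xa[S_V_TC]);

  std::vector<double> p_act_t(REAL(p_act), REAL(p_act) + N_PARAM);

  // controller state
  double ie[3] = {0, 0, 0};
  double eps_f[3] = {0, 0, 0}, eps_ft[3] = {0, 0, 0}, d_hat[3] = {0, 0, 0};
  double eps_g = 0.0, ups = ups0;
  double w_st[3] = {0, 0, 0};  // super-twisting integral state
  double u_prev[3] = {0, 0, 0};
  bool have_u_prev = false;

  // metrics accumulators
  double sse[3] = {0, 0, 0};
  double du_sum[3] = {0, 0, 0};
  double u_min[3] = {1e300, 1e300, 1e300}, u_max_obs[3] = {-1e300, -1e300, -1e300};
  long clip_events = 0;

  const int n_rec = n_steps / record_every + 1;
  NumericVector t_rec(n_rec);
  NumericMatrix vd_rec(n_rec, 3), va_rec(n_rec, 3), u_rec(n_rec, 3),
      s_rec(n_rec, 3), e_rec(n_rec, 3), epsf_rec(n_rec, 3), epsft_rec(n_rec, 3),
      dhat_rec(n_rec, 3);
  NumericVector epsg_rec(n_rec), ups_rec(n_rec), dist_rec(n_rec);
  int rec = 0;

  bool diverged = false;
  double t_div = NA_REAL;
  int dist_ptr = 0;
  const int n_onsets = dist_onsets.size();

  double zxv[N_RULE], zxtv[N_RULE];
  int zxi[N_RULE], zxti[N_RULE];
  int nzx = 0, nzxt = 0;

  for (int i = 0; i <= n_steps; ++i) {
    const double t = i * dt;

    // tracking error at the current sample
    double e[3], s[3];
    for (int j = 0; j < 3; ++j) e[j] = xd[j] - xa[j];

    // terminal or linear sliding variable
    if (controller == 2 || controller == 3) {
      for (int j = 0; j < 3; ++j) s[j] = e[j] + lambda * ie[j];
    } else {
      for (int j = 0; j < 3; ++j)
        s[j] = ie[j] + sigma * std::pow(std::fabs(e[j]), eta) * sgn(e[j]);
    }

    if (i < n_steps) for (int j = 0; j < 3; ++j) sse[j] += e[j] * e[j];

    // disturbance pulse train (merged rectangular pulses)
    double dist_val = 0.0;
    if (n_onsets > 0) {
      while (dist_ptr < n_onsets && dist_onsets[dist_ptr] + dist_width <= t)
        ++dist_ptr;
      if (dist_ptr < n_onsets && dist_onsets[dist_ptr] <= t) dist_val = dist_amp;
    }

    // parameter drift (multipliers on ionic gbar / E_rev of the actual plant)
    if (has_drift) {
      int row = static_cast<int>(t / drift_dt);
      if (row >= drift.nrow()) row = drift.nrow() - 1;
      for (int k = 0; k < N_ION; ++k)
        p_act_t[P_ION0 + k] = p_act[P_ION0 + k] * drift(row, k);
    }

    // desired-plant derivative at t (also RK4 stage 1) -> exact xdot_d
    double k1d[N_STATE];
    const StageDelay sd_dct = d_ct.stages(tau1_steps);
    const StageDelay sd_dtc = d_tc.stages(tau2_steps);
    const double vd_ct_del = sd_dct.inst ? xd[S_V_CT] : sd_dct.v[0];
    const double vd_tc_del = sd_dtc.inst ? xd[S_V_TC] : sd_dtc.v[0];
    plant_deriv(xd, vd_ct_del, vd_tc_del, REAL(p_des), nullptr, nullptr, k1d);
    double xdot_d[3] = {k1d[0], k1d[1], k1d[2]};

    // ---- control law ----
    double u[3] = {0, 0, 0};
    double u_c[3] = {0, 0, 0}, u_0[3] = {0, 0, 0};
    const StageDelay sd_act = a_ct.stages(tau1_steps);
    const StageDelay sd_atc = a_tc.stages(tau2_steps);
    const double va_ct_del = sd_act.inst ? xa[S_V_CT] : sd_act.v[0];
    const double va_tc_del = sd_atc.inst ? xa[S_V_TC] : sd_atc.v[0];

    if (controller == 1 || controller == 2) {
      // fuzzy estimates on x and x_tau
      const double xin[3] = {xa[0], xa[1], xa[2]};
      const double xtin[3] = {va_tc_del, va_ct_del, xa[2]};
      nzx = fuzzy_basis_sparse(xin, REAL(centers), delta, zxv, zxi);
      nzxt = fuzzy_basis_sparse(xtin, REAL(centers), delta, zxtv, zxti);
      double fh[3], fth[3], Gh[3][3];
      for (int j = 0; j < 3; ++j) {
        double af = 0, at = 0;
        const double* wf = &psi[j * N_RULE];
        const double* wt = &psi[(3 + j) * N_RULE];
        for (int k = 0; k < nzx; ++k) af += wf[zxi[k]] * zxv[k];
        for (int k = 0; k < nzxt; ++k) at += wt[zxti[k]] * zxtv[k];
        fh[j] = af; fth[j] = at;
      }
      for (int r = 0; r < 3; ++r)
        for (int cjj = 0; cjj < 3; ++cjj) {
          double a = 0;
          const double* wg = &psi[(6 + r * 3 + cjj) * N_RULE];
          for (int k = 0; k < nzx; ++k) a += wg[zxi[k]] * zxv[k];
          Gh[r][cjj] = a;
        }

      double br[3];  // bracket term
      if (controller == 1) {
        for (int j = 0; j < 3; ++j)
          br[j] = -fh[j] - fth[j] + xdot_d[j] +
                  (1.0 / (eta * sigma)) * std::pow(std::fabs(e[j]), 2.0 - eta) * sgn(e[j]) +
                  K1[j] * s[j] + K2[j] * std::pow(std::fabs(s[j]), rho) * sgn(s[j]);
        // u_c = Ghat^T (eps0 I + Ghat Ghat^T)^-1 br ; u_0 = eps0 (.)^-1 br
        double M[3][3];
        for (int r = 0; r < 3; ++r)
          for (int cjj = 0; cjj < 3; ++cjj) {
            double a = 0;
            for (int k = 0; k < 3; ++k) a += Gh[r][k] * Gh[cjj][k];
            M[r][cjj] = a + (r == cjj ? eps0 : 0.0);
          }
        double y[3];
        solve3(M, br, y);
        for (int j = 0; j < 3; ++j) {
          double a = 0;
          for (int r = 0; r < 3; ++r) a += Gh[r][j] * y[r];  // Ghat^T y
          u_c[j] = a;
          u_0[j] = eps0 * y[j];
        }
      } else {  // AFSMC: linear surface, exponential reaching law with a
                // discontinuous switching term (the chattering source);
                // classical form with the input gain taken as known (G = I)
        for (int j = 0; j < 3; ++j) {
          u_c[j] = -fh[j] - fth[j] + xdot_d[j] + lambda * e[j] +
                   k1_lin * s[j] + k_sw * sgn(s[j]);
          u_0[j] = 0.0;
        }
      }

      double ns2 = s[0] * s[0] + s[1] * s[1] + s[2] * s[2];
      double bsum = 0.0;
      double bvec[3];
      for (int j = 0; j < 3; ++j) {
        bvec[j] = eps_f[j] + eps_ft[j] + eps_g * std::fabs(u_c[j]) + d_hat[j] +
                  std::fabs(u_0[j]);
        bsum += std::fabs(s[j]) * bvec[j];
      }

      if (controller == 1) {
        const double denom = sigma0 * ns2 + ups;
        for (int j = 0; j < 3; ++j) u[j] = u_c[j] + s[j] * bsum / denom;

        // terminal-gradient adaptation of weights and bounds
        double w[3];
        for (int j = 0; j < 3; ++j)
          w[j] = sigma * eta * std::pow(std::fabs(e[j]), eta - 1.0);
        for (int j = 0; j < 3; ++j) {
          const double cf = -kap_f * w[j] * s[j] * dt;
          const double ct = -kap_ft * w[j] * s[j] * dt;
          double* wf = &psi[j * N_RULE];
          double* wt = &psi[(3 + j) * N_RULE];
          for (int k = 0; k < nzx; ++k) wf[zxi[k]] += cf * zxv[k];
          for (int k = 0; k < nzxt; ++k) wt[zxti[k]] += ct * zxtv[k];
          for (int cjj = 0; cjj < 3; ++cjj) {
            const double cg = -kap_g * w[j] * s[j] * u_c[cjj] * dt;
            double* wg = &psi[(6 + j * 3 + cjj) * N_RULE];
            for (int k = 0; k < nzx; ++k) wg[zxi[k]] += cg * zxv[k];
          }
          eps_f[j] += gam0 * w[j] * std::fabs(s[j]) * dt;
          eps_ft[j] += gam1 * w[j] * std::fabs(s[j]) * dt;
          d_hat[j] += gam3 * w[j] * std::fabs(s[j]) * dt;
          eps_g += gam2 * w[j] * std::fabs(s[j]) * std::fabs(u_c[j]) * dt;
          if (eps_g > eps_g_max) eps_g = eps_g_max;  // projection bound
        }
        double ups_num = 0.0;
        for (int j = 0; j < 3; ++j) ups_num += std::fabs(s[j]) * w[j] * bvec[j];
        ups -= kap0 * ups_num / (sigma0 * ns2 + ups) * dt;
        if (ups < ups_min) ups = ups_min;
      } else {
        for (int j = 0; j < 3; ++j) u[j] = u_c[j];
        // classical gradient adaptation
        for (int j = 0; j < 3; ++j) {
          const double cf = -kap_f * s[j] * dt;
          const double ct = -kap_ft * s[j] * dt;
          double* wf = &psi[j * N_RULE];
          double* wt = &psi[(3 + j) * N_RULE];
          for (int k = 0; k < nzx; ++k) wf[zxi[k]] += cf * zxv[k];
          for (int k = 0; k < nzxt; ++k) wt[zxti[k]] += ct * zxtv[k];
        }
      }
      // weight projection (numerical safeguard): only touched weights move
      for (int k = 0; k < nzx; ++k)
        for (int r : {0, 1, 2, 6, 7, 8, 9, 10, 11, 12, 13, 14}) {
          double& wv = psi[r * N_RULE + zxi[k]];
          if (wv > psi_clip) { wv = psi_clip; ++clip_events; }
          else if (wv < -psi_clip) { wv = -psi_clip; ++clip_events; }
        }
      for (int k = 0; k < nzxt; ++k)
        for (int r : {3, 4, 5}) {
          double& wv = psi[r * N_RULE + zxti[k]];
          if (wv > psi_clip) { wv = psi_clip; ++clip_events; }
          else if (wv < -psi_clip) { wv = -psi_clip; ++clip_events; }
        }
      if (!std::isfinite(fh[0] + fth[0] + u[0])) { diverged = true; t_div = t; }
    } else if (controller == 3) {
      for (int j = 0; j < 3; ++j) {
        u[j] = st_a * std::sqrt(std::fabs(s[j])) * sgn(s[j]) + w_st[j];
        w_st[j] += st_b * sgn(s[j]) * dt;
      }
    }

    if (u_max > 0)
      for (int j = 0; j < 3; ++j)
        u[j] = std::max(-u_max, std::min(u_max, u[j]));

    // chattering metric accumulators (full resolution)
    if (i < n_steps) {
      if (have_u_prev)
        for (int j = 0; j < 3; ++j) du_sum[j] += std::fabs(u[j] - u_prev[j]);
      for (int j = 0; j < 3; ++j) {
        u_prev[j] = u[j];
        if (u[j] < u_min[j]) u_min[j] = u[j];
        if (u[j] > u_max_obs[j]) u_max_obs[j] = u[j];
      }
      have_u_prev = true;
    }

    // ---- record ----
    if (i % record_every == 0 && rec < n_rec) {
      t_rec[rec] = t;
      for (int j = 0; j < 3; ++j) {
        vd_rec(rec, j) = xd[j];
        va_rec(rec, j) = xa[j];
        u_rec(rec, j) = u[j];
        s_rec(rec, j) = s[j];
        e_rec(rec, j) = e[j];
        epsf_rec(rec, j) = eps_f[j];
        epsft_rec(rec, j) = eps_ft[j];
        dhat_rec(rec, j) = d_hat[j];
      }
      epsg_rec[rec] = eps_g;
      ups_rec[rec] = ups;
      dist_rec[rec] = dist_val;
      ++rec;
    }
    if (i == n_steps || diverged) break;

    // ---- advance both plants ----
    double dvec[3] = {0, 0, 0};
    dvec[dist_target] = dist_val;
    rk4_from_k1(xd, k1d, sd_dct, sd_dtc, REAL(p_des), nullptr, nullptr, dt);
    rk4_step(xa, sd_act, sd_atc, p_act_t.data(), u, dvec, dt);
    d_ct.push(xd[S_V_CT]); d_tc.push(xd[S_V_TC]);
    a_ct.push(xa[S_V_CT]); a_tc.push(xa[S_V_TC]);
    for (int j = 0; j < 3; ++j) ie[j] += e[j] * dt;

    if (state_bad(xd) || state_bad(xa)) {
      diverged = true;
      t_div = (i + 1) * dt;
    }
  }

  if (rec < n_rec) {
    Range r(0, std::max(rec - 1, 0));
    t_rec = head(t_rec, rec);
    vd_rec = vd_rec(r, _); va_rec = va_rec(r, _); u_rec = u_rec(r, _);
    s_rec = s_rec(r, _); e_rec = e_rec(r, _);
    epsf_rec = epsf_rec(r, _); epsft_rec = epsft_rec(r, _);
    dhat_rec = dhat_rec(r, _);
    epsg_rec = head(epsg_rec, rec); ups_rec = head(ups_rec, rec);
    dist_rec = head(dist_rec, rec);
  }

  NumericVector rmse(3), chat(3);
  for (int j = 0; j < 3; ++j) {
    rmse[j] = std::sqrt(sse[j] / n_steps);
    double range = u_max_obs[j] - u_min[j];
    chat[j] = (range > 0) ? du_sum[j] / (n_steps - 1) / (dt * range) : 0.0;
  }

  return List::create(
      _["t"] = t_rec, _["v_desired"] = vd_rec, _["v_actual"] = va_rec,
      _["u"] = u_rec, _["s"] = s_rec, _["e"] = e_rec, _["d"] = dist_rec,
      _["eps_f"] = epsf_rec, _["eps_ftau"] = epsft_rec, _["d_hat"] = dhat_rec,
      _["eps_g"] = epsg_rec, _["upsilon"] = ups_rec,
      _["rmse"] = rmse, _["chattering"] = chat,
      _["diverged"] = diverged, _["t_div"] = t_div,
      _["clip_events"] = static_cast<double>(clip_events));
}
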