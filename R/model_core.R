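# Elementary model operations (R reference forms) and the open-loop simulator.

#' Presynaptic neurotransmitter concentration
#'
#' Sigmoidal release function `T(V) = 2.84 / (1 + exp((2 - V)/5))` mapping the
#' presynaptic membrane voltage to the transmitter concentration driving the
#' synaptic gate kinetics.
#'
#' @param v_pre presynaptic membrane voltage, mV (vectorised).
#' @return transmitter concentration in `(0, 2.84)`.
#' @examples
#' neurotransmitter_release(2)     # midpoint: 1.42
#' neurotransmitter_release(-60)   # essentially closed
#' @export
neurotransmitter_release <- function(v_pre) {
  if (!all(is.finite(v_pre))) abort("presynaptic voltage must be finite")
  2.84 / (1 + exp((2 - v_pre) / 5))
}

#' First-order synaptic gate kinetics
#'
#' Time-derivative of a first-order transmitter-gated channel fraction,
#' `ds/dt = alpha * T * (1 - s) - beta * s` (AMPA and GABA_A pathways).
#'
#' @param s open fraction in `[0, 1]`.
#' @param T transmitter concentration (see [neurotransmitter_release()]).
#' @param alpha,beta forward / backward rate constants (> 0).
#' @return ds/dt, 1/ms.
#' @export
synapse_kinetics <- function(s, T, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    abort("synaptic rate constants must be positive")
  alpha * T * (1 - s) - beta * s
}

#' GABA_B receptor/G-protein cascade kinetics
#'
#' The slow inhibitory pathway uses a two-stage cascade: receptor activation
#' `dr/dt = 0.5 T (1 - r) - 0.0012 r` and G-protein concentration
#' `ds/dt = 0.18 r - 0.034 s`.  Note `s` is a concentration, not a fraction;
#' its equilibrium is `(0.18/0.034) r` and may exceed 1.  The channel opens
#' with fourth-power cooperativity `s^4 / (s^4 + Kd)`.
#'
#' @param s G-protein concentration (>= 0).
#' @param r activated receptor fraction in `[0, 1]`.
#' @param T transmitter concentration.
#' @return list with elements `ds` and `dr`, 1/ms.
#' @export
gabab_kinetics <- function(s, r, T) {
  list(ds = 0.18 * r - 0.034 * s,
       dr = 0.5 * T * (1 - r) - 0.0012 * r)
}

#' Synaptic currents onto the three neurons
#'
#' Sums the pathway currents: the TC neuron receives AMPA from CT plus
#' GABA_A and GABA_B from RT; the CT neuron receives AMPA from TC; the RT
#' neuron receives its own GABA_A self-inhibition plus AMPA from TC.
#' All currents are conductance * gate * (V - E); the GABA_B conductance is
#' gated by `s^4 / (s^4 + Kd)`.
#'
#' @param state named state vector (see [state_names()]).
#' @param params a [plant_params()] object.
#' @return named numeric 3-vector `c(TC=, CT=, RT=)`, uA/cm^2.
#' @export
synaptic_currents <- function(state, params) {
  v <- state[c("V_TC", "V_CT", "V_RT")]
  sy <- params$syn
  i_ampa_ct_tc <- sy$ampa_ct_tc[["g"]] * state[["s_ampa_ct_tc"]] *
    (v[["V_TC"]] - sy$ampa_ct_tc[["E"]])
  i_gaa_rt_tc <- sy$gabaa_rt_tc[["g"]] * state[["s_gabaa_rt_tc"]] *
    (v[["V_TC"]] - sy$gabaa_rt_tc[["E"]])
  s4 <- state[["s_gabab"]]^4
  i_gab <- sy$gabab_rt_tc[["g"]] * s4 / (s4 + sy$gabab_rt_tc[["Kd"]]) *
    (v[["V_TC"]] - sy$gabab_rt_tc[["E"]])
  i_ampa_tc_ct <- sy$ampa_tc_ct[["g"]] * state[["s_ampa_tc_ct"]] *
    (v[["V_CT"]] - sy$ampa_tc_ct[["E"]])
  i_gaa_rt_rt <- sy$gabaa_rt_rt[["g"]] * state[["s_gabaa_rt_rt"]] *
    (v[["V_RT"]] - sy$gabaa_rt_rt[["E"]])
  i_ampa_tc_rt <- sy$ampa_tc_rt[["g"]] * state[["s_ampa_tc_rt"]] *
    (v[["V_RT"]] - sy$ampa_tc_rt[["E"]])
  c(TC = i_ampa_ct_tc + i_gaa_rt_tc + i_gab,
    CT = i_ampa_tc_ct,
    RT = i_gaa_rt_rt + i_ampa_tc_rt)
}

#' Ionic membrane currents of one neuron
#'
#' Per-channel currents `gbar * (gating product) * (V - E_rev)` for the
#' requested neuron, using the gating variables carried in the state vector.
#'
#' @param state named state vector.
#' @param params a [plant_params()] object.
#' @param neuron `"TC"`, `"CT"` or `"RT"`.
#' @return tibble with columns `channel`, `current` (uA/cm^2); the total is
#'   `sum(current)`.
#' @export
ionic_currents <- function(state, params, neuron = c("TC", "CT", "RT")) {
  neuron <- rlang::arg_match(neuron)
  v <- state[[paste0("V_", neuron)]]
  gate_product <- list(
    TC = list(L = 1,
              Na = state[["TC_Na_m"]]^3 * state[["TC_Na_h"]],
              K = state[["TC_K_n"]]^4,
              T = state[["TC_T_m"]]^2 * state[["TC_T_h"]],
              h = state[["TC_h_r"]],
              K2 = state[["TC_K2_m"]] * state[["TC_K2_h"]]),
    CT = list(L = 1,
              Na = state[["CT_Na_m"]]^3 * state[["CT_Na_h"]],
              K = state[["CT_K_n"]]^4,
              M = state[["CT_M_p"]]),
    RT = list(L = 1,
              Na = state[["RT_Na_m"]]^3 * state[["RT_Na_h"]],
              K = state[["RT_K_n"]]^4,
              TS = state[["RT_TS_m"]]^2 * state[["RT_TS_h"]])
  )[[neuron]]
  chans <- ION_CHANNELS[[neuron]]
  cur <- vapply(chans, function(ch) {
    rec <- params$ionic[[neuron]][[ch]]
    rec[["g"]] * gate_product[[ch]] * (v - rec[["E"]])
  }, numeric(1))
  tibble(channel = chans, current = unname(cur))
}

#' Full plant derivative
#'
#' Right-hand side of the delay-differential plant at one instant:
#' `C dV/dt = -I_ionic - I_syn + I_ext + u + d` for the three voltages plus
#' the kinetics of all gating variables and synaptic gates.  The delayed
#' voltages `V_CT(t - tau1)` and `V_TC(t - tau2)` drive the transmitter of
#' the corticothalamic and thalamocortical AMPA pathways.
#'
#' @param state named state vector.
#' @param params a [plant_params()] object.
#' @param v_ct_delayed,v_tc_delayed delayed presynaptic voltages, mV
#'   (default: the instantaneous values, i.e. zero delay).
#' @param u control current 3-vector, uA/cm^2.
#' @param d disturbance current 3-vector, uA/cm^2.
#' @return named numeric 3-vector `dV/dt` (mV/ms) with the full 27-element
#'   state derivative in attribute `"dstate"`.
#' @export
membrane_derivative <- function(state, params,
                                v_ct_delayed = state[["V_CT"]],
                                v_tc_delayed = state[["V_TC"]],
                                u = c(0, 0, 0), d = c(0, 0, 0)) {
  if (!all(is.finite(state))) abort("non-finite state (divergence)")
  r <- cpp_plant_deriv(unname(state), v_ct_delayed, v_tc_delayed,
                       as_param_vector(params), u, d)
  out <- stats::setNames(r$dx[1:3], NEURONS)
  attr(out, "dstate") <- stats::setNames(r$dx, state_names())
  out
}

#' Canonical decomposition of the voltage dynamics
#'
#' Splits the membrane-voltage derivative into the canonical MIMO state-delay
#' form `dV/dt = f(x) + f_tau(x_tau) + G u + d`: `f` collects every
#' non-delayed term (ionic, non-delayed synaptic, external currents), `f_tau`
#' the synaptic terms of the two delayed pathways, and
#' `G = diag(1/C_TC, 1/C_CT, 1/C_RT)` is the constant positive definite input
#' gain.  Used as the ground-truth oracle for the controller.
#'
#' @inheritParams membrane_derivative
#' @return list with `f` (3-vector), `f_tau` (3-vector), `G` (3x3 diagonal
#'   matrix) and `chi0`, the guaranteed lower bound `1/max(C)` on the gain.
#' @export
true_dynamics_split <- function(state, params,
                                v_ct_delayed = state[["V_CT"]],
                                v_tc_delayed = state[["V_TC"]]) {
  r <- cpp_plant_deriv(unname(state), v_ct_delayed, v_tc_delayed,
                       as_param_vector(params), c(0, 0, 0), c(0, 0, 0))
  list(f = stats::setNames(r$f, NEURONS),
       f_tau = stats::setNames(r$f_tau, NEURONS),
       G = r$G,
       chi0 = 1 / max(params$C))
}

#' Advance the plant by one RK4 step
#'
#' One classical Runge-Kutta step of length `dt` with the delayed voltages
#' supplied externally (method of steps).  `v_ct_delayed` / `v_tc_delayed`
#' may be a single value (held over the step), a length-3 vector of stage
#' values at `t - tau`, `t + dt/2 - tau`, `t + dt - tau`, or `NULL` for a
#' zero delay (instantaneous voltage used at every stage).
#'
#' @inheritParams membrane_derivative
#' @param dt step size, ms.
#' @return the next state (named numeric vector of length 27).
#' @export
step_plant <- function(state, params, dt,
                       v_ct_delayed = NULL, v_tc_delayed = NULL,
                       u = c(0, 0, 0), d = c(0, 0, 0)) {
  if (dt <= 0) abort("dt must be positive")
  x <- cpp_rk4_step(unname(state), v_ct_delayed, v_tc_delayed,
                    as_param_vector(params), u, d, dt)
  if (!all(is.finite(x)) || any(abs(x[1:3]) > 150))
    abort("plant diverged during the step")
  stats::setNames(x, state_names())
}

#' Open-loop simulation of the plant
#'
#' Fixed-step RK4 integration of the delay-differential model, with constant
#' pre-history (the initial voltages) for times before zero.  Delays must be
#' integer multiples of `dt`.
#'
#' @param params a [plant_params()] object.
#' @param duration total simulated time, ms.
#' @param dt integration step, ms (default 0.001, the reference sampling
#'   period; `0.01` is a validated faster profile).
#' @param init either a length-3 vector of initial voltages (gating set to
#'   steady state via [plant_state()]) or a full 27-element state vector.
#' @param record_every record every this-many steps (default: 0.1 ms grid).
#' @param u_schedule optional `n_steps x 3` matrix of control currents.
#' @param d_schedule optional `n_steps x 3` matrix of disturbance currents.
#' @return tibble with columns `t_ms`, the 27 state variables and `u_1..u_3`;
#'   attribute `"diverged"` flags a numerical blow-up (|V| > 150 mV).
#' @examples
#' p <- plant_params("normal")
#' tr <- simulate_plant(p, duration = 50, dt = 0.01, init = c(-65, -65, -65))
#' head(tr)
#' @export
simulate_plant <- function(params, duration, dt = 1e-3,
                           init = c(-65, -65, -65),
                           record_every = NULL, u_schedule = NULL,
                           d_schedule = NULL) {
  if (duration <= 0) abort("duration must be positive")
  n_steps <- as.integer(round(duration / dt))
  k1 <- delay_steps(params$tau1, dt, "tau1")
  k2 <- delay_steps(params$tau2, dt, "tau2")
  record_every <- record_every %||% max(1L, as.integer(round(0.1 / dt)))
  x0 <- if (length(init) == 3) {
    plant_state(init[1], init[2], init[3], params)
  } else if (length(init) == 27) init else {
    abort("init must be 3 voltages or a full 27-element state")
  }
  r <- cpp_simulate_plant(as_param_vector(params), unname(x0), dt, n_steps,
                          k1, k2, record_every, u_schedule, d_schedule)
  st <- r$state
  colnames(st) <- state_names()
  colnames(r$u) <- paste0("u_", 1:3)
  out <- dplyr::bind_cols(tibble(t_ms = r$t), as_tibble(st), as_tibble(r$u))
  attr(out, "diverged") <- r$diverged
  attr(out, "t_div") <- r$t_div
  if (r$diverged)
    warn(paste0("plant diverged at t = ", signif(r$t_div, 6), " ms"))
  out
}

#' Spike and inter-spike-interval statistics of a voltage trace
#'
#' Detects spikes as upward threshold crossings and summarises the rhythm;
#' used to contrast the `normal` (slower single-spiking) and `cae` (faster
#' tonic spiking) regimes.
#'
#' @param v voltage trace, mV.
#' @param t_ms matching time stamps, ms.
#' @param threshold detection threshold, mV.
#' @return one-row tibble: `n_spikes`, `rate_hz`, `isi_mean_ms`, `isi_cv`.
#' @export
spike_statistics <- function(v, t_ms, threshold = 0) {
  stopifnot(length(v) == length(t_ms))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  tt <- t_ms[up + 1]
  isi <- diff(tt)
  tibble(
    n_spikes = length(tt),
    rate_hz = length(tt) / (diff(range(t_ms)) / 1000),
    isi_mean_ms = if (length(isi)) mean(isi) else NA_real_,
    isi_cv = if (length(isi) > 1) stats::sd(isi) / mean(isi) else NA_real_
  )
}
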