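# Parameterisation of the three-neuron corticothalamic plant.
#
# Units everywhere: voltage mV, time ms, current density uA/cm^2, conductance
# density mS/cm^2, capacitance uF/cm^2.

NEURONS <- c("TC", "CT", "RT")

# ionic channels per neuron type (order fixed; mirrored by the C++ engine)
ION_CHANNELS <- list(
  TC = c("L", "Na", "K", "T", "h", "K2"),
  CT = c("L", "Na", "K", "M"),
  RT = c("L", "Na", "K", "TS")
)

SYNAPSES <- c("ampa_ct_tc", "gabaa_rt_tc", "gabab_rt_tc",
              "ampa_tc_ct", "gabaa_rt_rt", "ampa_tc_rt")

#' Plant parameters for the three-neuron absence-epilepsy model
#'
#' Builds the full parameter set of the conductance-based thalamic relay (TC),
#' cortical (CT) and reticular (RT) neuron motif with its kinetic synapses and
#' the two transmission delays.  The two named presets differ *only* in the
#' external drive of the TC neuron and the maximal GABA_A conductance of the
#' RT to TC pathway: `"normal"` uses `I_ext^TC = 5` uA/cm^2 and
#' `g_GABAA(RT->TC) = 0.65` mS/cm^2 (slow single-spiking rhythm), `"cae"` uses
#' `6` and `0.32` (the faster tonic spiking of the epileptic state).
#'
#' Synaptic parameters follow the published table of the motif (AMPA
#' `alpha = 0.94`, `beta = 0.18`; GABA_A `alpha = 5`, `beta = 0.18`;
#' GABA_B cascade `0.18/0.034/0.5/0.0012` with `Kd = 100`).  Ionic channel
#' kinetics are Destexhe-type Hodgkin-Huxley formulations (Traub-Miles spike
#' currents, low-threshold Ca currents IT/ITS, anomalous rectifier Ih, slow K
#' currents IK2/IM); their maximal conductances and reversal potentials are
#' listed in the returned object and can be overridden entry by entry.
#'
#' @param preset `"cae"` (default) or `"normal"`.
#' @param tau1 corticothalamic conduction delay, ms (range 2-10).
#' @param tau2 thalamocortical conduction delay, ms.
#' @param I_ext_TC,g_gabaa_rt_tc optional overrides of the two
#'   preset-defining values.
#' @param ionic,syn optional full replacements of the ionic / synaptic blocks
#'   (same structure as the defaults; see the returned object).
#' @param C membrane capacitances, uF/cm^2, named `TC`, `CT`, `RT`.
#'
#' @return An object of class `plant_params`: a named list with elements
#'   `preset`, `C`, `I_ext`, `tau1`, `tau2`, `ionic`, `syn`.
#' @examples
#' p <- plant_params("normal")
#' p$syn$gabaa_rt_tc[["g"]]
#' @export
plant_params <- function(preset = c("cae", "normal"),
                         tau1 = 10, tau2 = 2.8,
                         I_ext_TC = NULL, g_gabaa_rt_tc = NULL,
                         ionic = NULL, syn = NULL,
                         C = c(TC = 1, CT = 1, RT = 1)) {
  preset <- rlang::arg_match(preset)
  defs <- if (preset == "normal") c(5, 0.65) else c(6, 0.32)
  I_ext <- c(TC = I_ext_TC %||% defs[1], CT = 0, RT = 0)
  g_ga <- g_gabaa_rt_tc %||% defs[2]

  ionic <- ionic %||% list(
    TC = list(L = c(g = 0.01, E = -70), Na = c(g = 90, E = 50),
              K = c(g = 10, E = -90), T = c(g = 2.2, E = 120),
              h = c(g = 0.017, E = -40), K2 = c(g = 0.3, E = -90)),
    CT = list(L = c(g = 0.05, E = -70), Na = c(g = 50, E = 50),
              K = c(g = 5, E = -90), M = c(g = 0.07, E = -90)),
    RT = list(L = c(g = 0.05, E = -77), Na = c(g = 100, E = 50),
              K = c(g = 10, E = -90), TS = c(g = 1.5, E = 120))
  )
  syn <- syn %||% list(
    ampa_ct_tc  = c(g = 0.1,     E = 0,   alpha = 0.94, beta = 0.18),
    gabaa_rt_tc = c(g = g_ga,    E = -85, alpha = 5,    beta = 0.18),
    gabab_rt_tc = c(g = 0.13793, E = -95, Kd = 100),
    ampa_tc_ct  = c(g = 4.138,   E = 0,   alpha = 0.94, beta = 0.18),
    gabaa_rt_rt = c(g = 6,       E = -85, alpha = 5,    beta = 0.18),
    ampa_tc_rt  = c(g = 1.428,   E = 0,   alpha = 0.94, beta = 0.18)
  )

  out <- structure(
    list(preset = preset, C = C, I_ext = I_ext, tau1 = tau1, tau2 = tau2,
         ionic = ionic, syn = syn),
    class = "plant_params"
  )
  validate_plant_params(out)
  out
}

validate_plant_params <- function(p) {
  stopifnot(inherits(p, "plant_params"))
  if (any(p$C <= 0)) abort("membrane capacitances must be positive")
  if (p$tau1 < 0 || p$tau2 < 0) abort("delays must be non-negative")
  for (nn in NEURONS) {
    chs <- p$ionic[[nn]]
    if (!setequal(names(chs), ION_CHANNELS[[nn]]))
      abort(paste0("unknown or missing ionic channel for ", nn, " neuron: ",
                   paste(setdiff(names(chs), ION_CHANNELS[[nn]]), collapse = ", ")))
    for (ch in chs)
      if (ch[["g"]] < 0) abort("maximal conductances must be non-negative")
  }
  for (sn in SYNAPSES) {
    sy <- p$syn[[sn]]
    if (is.null(sy)) abort(paste0("missing synapse record: ", sn))
    if (sy[["g"]] < 0) abort("maximal conductances must be non-negative")
    if (!is.na(sy["alpha"]) && (sy[["alpha"]] <= 0 || sy[["beta"]] <= 0))
      abort("synaptic rate constants must be positive")
  }
  invisible(p)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params> preset:", x$preset, "\n")
  cat("  I_ext (uA/cm^2):", paste(names(x$I_ext), x$I_ext, sep = "=", collapse = " "), "\n")
  cat("  g_GABAA(RT->TC):", x$syn$gabaa_rt_tc[["g"]], "mS/cm^2\n")
  cat("  delays: tau1 =", x$tau1, "ms, tau2 =", x$tau2, "ms\n")
  invisible(x)
}

# flatten to the fixed-layout numeric vector consumed by the C++ engine
as_param_vector <- function(p) {
  validate_plant_params(p)
  ion <- unlist(lapply(NEURONS, function(nn)
    lapply(ION_CHANNELS[[nn]], function(ch) p$ionic[[nn]][[ch]][c("g", "E")])))
  syn <- c(p$syn$ampa_ct_tc[c("g", "E", "alpha", "beta")],
           p$syn$gabaa_rt_tc[c("g", "E", "alpha", "beta")],
           p$syn$gabab_rt_tc[c("g", "E", "Kd")],
           p$syn$ampa_tc_ct[c("g", "E", "alpha", "beta")],
           p$syn$gabaa_rt_rt[c("g", "E", "alpha", "beta")],
           p$syn$ampa_tc_rt[c("g", "E", "alpha", "beta")])
  unname(c(p$C[NEURONS], p$I_ext[NEURONS], ion, syn))
}

# names of the 28 ionic (gbar, E_rev) entries, in engine order; these are the
# parameters subject to time-varying uncertainty
drift_param_names <- function() {
  unlist(lapply(NEURONS, function(nn)
    as.vector(t(outer(ION_CHANNELS[[nn]], c("g", "E"),
                      function(a, b) paste(nn, a, b, sep = "_"))))))
}

#' State-vector element names
#'
#' Names of the 27 dynamic states: three membrane voltages, seventeen ionic
#' gating variables and seven synaptic gates.
#' @return character vector of length 27.
#' @export
state_names <- function() {
  c("V_TC", "V_CT", "V_RT",
    "TC_Na_m", "TC_Na_h", "TC_K_n", "TC_T_m", "TC_T_h", "TC_h_r",
    "TC_K2_m", "TC_K2_h",
    "CT_Na_m", "CT_Na_h", "CT_K_n", "CT_M_p",
    "RT_Na_m", "RT_Na_h", "RT_K_n", "RT_TS_m", "RT_TS_h",
    "s_ampa_ct_tc", "s_gabaa_rt_tc", "s_gabab", "r_gabab",
    "s_ampa_tc_ct", "s_gabaa_rt_rt", "s_ampa_tc_rt")
}

#' Plant state at gating steady state
#'
#' Builds a full 27-element state vector with the given membrane voltages and
#' every gating variable and synaptic gate at its steady state for those
#' voltages (the initialisation used for all simulations).
#'
#' @param v_tc,v_ct,v_rt membrane voltages, mV.
#' @param params a [plant_params()] object.
#' @return named numeric vector of length 27.
#' @export
plant_state <- function(v_tc, v_ct, v_rt, params) {
  x <- cpp_steady_state(v_tc, v_ct, v_rt, as_param_vector(params))
  stats::setNames(x, state_names())
}

# delays must sit on the integration grid
delay_steps <- function(tau, dt, what = "delay") {
  k <- tau / dt
  if (abs(k - round(k)) > 1e-6)
    abort(paste0(what, " (", tau, " ms) must be an integer multiple of dt (",
                 dt, " ms)"))
  as.integer(round(k))
}
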