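# Closed-loop trial orchestration: configuration, single trials and batches.

#' Controller gains
#'
#' All tunable gains of the closed-loop controllers in one validated list.
#' The published study selected its gains by trial and error without printing
#' them; these defaults are this package's documented tuning (see the methods
#' vignette) and every entry can be overridden.
#'
#' @param surface a [surface_params()] object (terminal surface and reaching
#'   law).
#' @param eps0 regularization parameter of the gain inversion (> 0).
#' @param sigma0 robustifying-denominator weight (> 0).
#' @param kappa_f,kappa_ftau,kappa_g fuzzy weight adaptation gains (> 0).
#' @param kappa0,gamma0,gamma1,gamma2,gamma3 bound adaptation rates (> 0).
#' @param upsilon0,upsilon_min initial value and floor of the adaptive
#'   denominator parameter.
#' @param psi_clip numerical projection bound on the fuzzy weights.
#' @param eps_g_max projection bound on the gain-error estimate `eps_g`
#'   (its term in the robustifying numerator scales with the control
#'   magnitude, so an unbounded estimate would eventually destabilise the
#'   discrete-time loop).
#' @param u_max control saturation, uA/cm^2 (0 disables; disabled by
#'   default).
#' @param lambda linear-surface slope of the AFSMC / STSMC baselines.
#' @param k1_lin AFSMC proportional reaching gain.
#' @param k_sw AFSMC switching gain.
#' @param st_a,st_b super-twisting gains.
#' @return object of class `controller_gains`.
#' @export
controller_gains <- function(surface = surface_params(),
                             eps0 = 0.01, sigma0 = 10,
                             kappa_f = 10, kappa_ftau = 10, kappa_g = 0.1,
                             kappa0 = 0.1, gamma0 = 0.1, gamma1 = 0.1,
                             gamma2 = 0.1, gamma3 = 0.1,
                             upsilon0 = 1, upsilon_min = 1e-6,
                             psi_clip = 1e6, eps_g_max = 50, u_max = 0,
                             lambda = 1, k1_lin = 10, k_sw = 20,
                             st_a = 20, st_b = 50) {
  stopifnot(inherits(surface, "surface_params"))
  if (eps0 <= 0 || sigma0 <= 0) abort("eps0 and sigma0 must be positive")
  if (any(c(kappa_f, kappa_ftau, kappa_g, kappa0,
            gamma0, gamma1, gamma2, gamma3) <= 0))
    abort("adaptation gains must be positive")
  structure(list(surface = surface, eps0 = eps0, sigma0 = sigma0,
                 kappa_f = kappa_f, kappa_ftau = kappa_ftau,
                 kappa_g = kappa_g, kappa0 = kappa0, gamma0 = gamma0,
                 gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 upsilon0 = upsilon0, upsilon_min = upsilon_min,
                 psi_clip = psi_clip, eps_g_max = eps_g_max,
                 u_max = u_max, lambda = lambda,
                 k1_lin = k1_lin, k_sw = k_sw, st_a = st_a, st_b = st_b),
            class = "controller_gains")
}

#' Disturbance specification
#'
#' Gamma-process pulse train injected as a disturbance current into one
#' neuron's voltage equation.  The published protocol uses rate 14 Hz, width
#' 1 ms and amplitudes 1.25-2 uA/cm^2 on the CT neuron.
#'
#' @param rate_hz,amplitude,width_ms pulse-train parameters.
#' @param target `"TC"`, `"CT"` (default) or `"RT"`.
#' @param shape gamma shape parameter.
#' @export
disturbance_spec <- function(rate_hz = 14, amplitude = 1.75, width_ms = 1,
                             target = c("CT", "TC", "RT"), shape = 2) {
  target <- rlang::arg_match(target)
  if (rate_hz < 0) abort("rate must be non-negative")
  structure(list(rate_hz = rate_hz, amplitude = amplitude,
                 width_ms = width_ms, target = target, shape = shape),
            class = "disturbance_spec")
}

#' Uncertainty specification
#'
#' Time-varying multiplicative drift of the ionic maximal conductances and
#' reversal potentials of the actual plant (see [parameter_drift()]).
#'
#' @param level drift level in `[0, 0.5]`.
#' @param fn_hz,resample_s,dt_ms drift-generator parameters.
#' @export
uncertainty_spec <- function(level, fn_hz = 0.05, resample_s = 2, dt_ms = 1) {
  if (level < 0 || level > 0.5)
    abort("uncertainty level must lie in [0, 0.5]")
  structure(list(level = level, fn_hz = fn_hz, resample_s = resample_s,
                 dt_ms = dt_ms),
            class = "uncertainty_spec")
}

CONTROLLER_CODES <- c(none = 0L, aftsmc = 1L, afsmc = 2L, stsmc = 3L)

#' Closed-loop trial configuration
#'
#' Everything a single reproducible trial needs: the actual (epileptic) and
#' desired (normal) plants, the controller and its gains, the scenario
#' (disturbance and/or parameter uncertainty), initial-condition ranges and
#' the integration grid.  The seed determines every random draw of the
#' trial.
#'
#' @param duration trial length, ms (default 2000).
#' @param dt integration and control step, ms (default 0.001).
#' @param seed integer seed.
#' @param controller `"aftsmc"`, `"afsmc"`, `"stsmc"` or `"none"`.
#' @param plant actual plant, a [plant_params()] (default: `"cae"` preset).
#' @param desired desired plant (default: `"normal"` preset).
#' @param gains a [controller_gains()].
#' @param membership a [membership_spec()].
#' @param disturbance optional [disturbance_spec()].
#' @param uncertainty optional [uncertainty_spec()].
#' @param init_range initial-voltage range, mV.
#' @param record_every recording decimation in steps (default: a 0.1 ms
#'   output grid).
#' @return object of class `trial_config`.
#' @export
trial_config <- function(duration = 2000, dt = 1e-3, seed = 1L,
                         controller = c("aftsmc", "afsmc", "stsmc", "none"),
                         plant = plant_params("cae"),
                         desired = plant_params("normal"),
                         gains = controller_gains(),
                         membership = membership_spec(),
                         disturbance = NULL, uncertainty = NULL,
                         init_range = c(-60, -20), record_every = NULL) {
  controller <- rlang::arg_match(controller)
  if (duration <= 0 || dt <= 0) abort("duration and dt must be positive")
  stopifnot(inherits(plant, "plant_params"),
            inherits(desired, "plant_params"),
            inherits(gains, "controller_gains"),
            inherits(membership, "membership_spec"))
  if (!is.null(disturbance)) stopifnot(inherits(disturbance, "disturbance_spec"))
  if (!is.null(uncertainty)) stopifnot(inherits(uncertainty, "uncertainty_spec"))
  if (plant$tau1 != desired$tau1 || plant$tau2 != desired$tau2)
    abort("actual and desired plants must share the transmission delays")
  delay_steps(plant$tau1, dt, "tau1")  # grid-multiple validation
  delay_steps(plant$tau2, dt, "tau2")
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 controller = controller, plant = plant, desired = desired,
                 gains = gains, membership = membership,
                 disturbance = disturbance, uncertainty = uncertainty,
                 init_range = init_range,
                 record_every = record_every %||%
                   max(1L, as.integer(round(0.1 / dt)))),
            class = "trial_config")
}

# flatten the gains list for the engine
engine_ctrl <- function(g) {
  sp <- g$surface
  list(sigma = sp$sigma, eta = sp$eta, rho = sp$rho, K1 = sp$K1, K2 = sp$K2,
       eps0 = g$eps0, sigma0 = g$sigma0, kappa_f = g$kappa_f,
       kappa_ftau = g$kappa_ftau, kappa_g = g$kappa_g, kappa0 = g$kappa0,
       gamma0 = g$gamma0, gamma1 = g$gamma1, gamma2 = g$gamma2,
       gamma3 = g$gamma3, upsilon0 = g$upsilon0,
       upsilon_min = g$upsilon_min, psi_clip = g$psi_clip,
       eps_g_max = g$eps_g_max, u_max = g$u_max,
       lambda = g$lambda, k1_lin = g$k1_lin, k_sw = g$k_sw,
       st_a = g$st_a, st_b = g$st_b)
}

#' Run one closed-loop trial
#'
#' Simulates the desired (normal-state) plant and the actual (epileptic)
#' plant side by side; at every step the selected controller turns the
#' tracking error into a stimulation current applied to the actual plant,
#' with the configured disturbance train and/or parameter drift acting on
#' it.  All randomness (initial voltages of both plants, estimator weights,
#' disturbance onsets, drift traces) derives from `config$seed`, so a trial
#' is exactly reproducible from its configuration.
#'
#' @param config a [trial_config()].
#' @return object of class `cae_trial`: list with `trajectory` (tibble of
#'   the decimated desired/actual voltages, control and disturbance),
#'   `adaptation` (tibble of the adaptive bound estimates), `metrics`
#'   (per-neuron RMSE in mV and chattering index), `diverged`, `seeds` and
#'   the resolved `config`.
#' @examples
#' \donttest{
#' cfg <- trial_config(duration = 200, dt = 0.01, seed = 7)
#' tr <- run_trial(cfg)
#' tidy(tr)
#' }
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  k1 <- delay_steps(config$plant$tau1, dt, "tau1")
  k2 <- delay_steps(config$plant$tau2, dt, "tau2")

  drawn <- withr::with_seed(config$seed, {
    ic <- random_initial_conditions(range = config$init_range)
    train <- if (!is.null(config$disturbance)) {
      ds <- config$disturbance
      gamma_pulse_train(ds$rate_hz, ds$amplitude, ds$width_ms,
                        config$duration, shape = ds$shape)
    }
    drift <- if (!is.null(config$uncertainty)) {
      us <- config$uncertainty
      parameter_drift(us$level, config$duration, fn_hz = us$fn_hz,
                      resample_s = us$resample_s, dt_ms = us$dt_ms)
    }
    list(ic = ic, train = train, drift = drift)
  })
  ic <- drawn$ic

  x0_act <- plant_state(ic$v_actual[1], ic$v_actual[2], ic$v_actual[3],
                        config$plant)
  x0_des <- plant_state(ic$v_desired[1], ic$v_desired[2], ic$v_desired[3],
                        config$desired)

  ds <- config$disturbance
  res <- cpp_run_closed_loop(
    as_param_vector(config$desired), as_param_vector(config$plant),
    unname(x0_des), unname(x0_act), dt, n_steps, k1, k2,
    CONTROLLER_CODES[[config$controller]], engine_ctrl(config$gains),
    ic$psi0, config$membership$centers, config$membership$delta,
    if (is.null(drawn$train)) numeric(0) else drawn$train$onsets_ms,
    if (is.null(ds)) 0 else ds$amplitude,
    if (is.null(ds)) 1 else ds$width_ms,
    if (is.null(ds)) 0L else match(ds$target, NEURONS) - 1L,
    if (is.null(drawn$drift)) NULL else drawn$drift$multipliers,
    if (is.null(drawn$drift)) 1 else drawn$drift$dt_ms,
    config$record_every)

  vn <- c("TC", "CT", "RT")
  traj <- tibble(t_ms = res$t)
  for (j in 1:3) traj[[paste0("V_", vn[j])]] <- res$v_actual[, j]
  for (j in 1:3) traj[[paste0("V_", vn[j], "_desired")]] <- res$v_desired[, j]
  for (j in 1:3) traj[[paste0("u_", j)]] <- res$u[, j]
  traj$d <- res$d
  for (j in 1:3) traj[[paste0("e_", vn[j])]] <- res$e[, j]
  for (j in 1:3) traj[[paste0("s_", vn[j])]] <- res$s[, j]

  adaptation <- tibble(t_ms = res$t)
  for (j in 1:3) adaptation[[paste0("eps_f_", vn[j])]] <- res$eps_f[, j]
  for (j in 1:3) adaptation[[paste0("eps_ftau_", vn[j])]] <- res$eps_ftau[, j]
  for (j in 1:3) adaptation[[paste0("d_hat_", vn[j])]] <- res$d_hat[, j]
  adaptation$eps_g <- res$eps_g
  adaptation$upsilon <- res$upsilon

  structure(list(
    trajectory = traj,
    adaptation = adaptation,
    metrics = list(rmse = stats::setNames(res$rmse, vn),
                   chattering = stats::setNames(res$chattering, vn),
                   clip_events = res$clip_events),
    diverged = res$diverged, t_div = res$t_div,
    seeds = config$seed, config = config), class = "cae_trial")
}

#' @export
print.cae_trial <- function(x, ...) {
  cat("<cae_trial>", x$config$controller, "controller,",
      x$config$duration, "ms at dt =", x$config$dt, "ms\n")
  cat("  RMSE (mV): ",
      paste(names(x$metrics$rmse), signif(x$metrics$rmse, 4),
            sep = " = ", collapse = ", "), "\n")
  if (x$diverged) cat("  ** diverged at t =", x$t_div, "ms **\n")
  invisible(x)
}

#' @rdname run_trial
#' @param x a `cae_trial`.
#' @param ... unused.
#' @method tidy cae_trial
#' @export
tidy.cae_trial <- function(x, ...) {
  tibble(neuron = names(x$metrics$rmse),
         rmse_mv = unname(x$metrics$rmse),
         chattering_index = unname(x$metrics$chattering))
}

#' @rdname run_trial
#' @method glance cae_trial
#' @export
glance.cae_trial <- function(x, ...) {
  tibble(controller = x$config$controller,
         duration_ms = x$config$duration, dt_ms = x$config$dt,
         seed = x$seeds, diverged = x$diverged,
         rmse_tc_mv = x$metrics$rmse[["TC"]],
         rmse_ct_mv = x$metrics$rmse[["CT"]],
         rmse_rt_mv = x$metrics$rmse[["RT"]])
}

#' Batched closed-loop experiments
#'
#' Repeats closed-loop trials over independent seeds for each row of a
#' condition grid, re-randomizing every stochastic ingredient (initial
#' voltages, estimator weights, disturbance onsets, drift traces) per trial,
#' and summarises the per-neuron tracking RMSE as mean and standard
#' deviation over trials (population form, matching a mean +/- 1 sd report).
#'
#' @param config base [trial_config()].
#' @param n_trials trials per condition (>= 1).
#' @param seeds optional vector of `n_trials` seeds (default
#'   `config$seed + 0:(n_trials-1)`).
#' @param conditions optional data frame of condition overrides; recognised
#'   columns: `controller`, `amplitude` (disturbance pulse amplitude,
#'   uA/cm^2) and `level` (uncertainty level).  One row per condition;
#'   `NULL` runs the base configuration only.
#' @return object of class `cae_batch`: a tibble with the condition columns
#'   plus `neuron`, `mean_rmse_mv`, `sd_rmse_mv`, `n`, `n_diverged`.
#'   Diverged trials are excluded from the statistics and counted.
#' @export
batch_experiment <- function(config, n_trials = 15, seeds = NULL,
                             conditions = NULL) {
  stopifnot(inherits(config, "trial_config"), n_trials >= 1)
  seeds <- seeds %||% (config$seed + seq_len(n_trials) - 1L)
  if (length(seeds) != n_trials) abort("one seed per trial is required")
  conditions <- conditions %||% tibble(.base = TRUE)

  rows <- purrr::map_dfr(seq_len(nrow(conditions)), function(ci) {
    cond <- conditions[ci, , drop = FALSE]
    cfg <- config
    if (!is.null(cond[["controller"]])) cfg$controller <- cond[["controller"]]
    if (!is.null(cond[["amplitude"]])) {
      base_ds <- cfg$disturbance %||% disturbance_spec()
      base_ds$amplitude <- cond[["amplitude"]]
      cfg$disturbance <- base_ds
    }
    if (!is.null(cond[["level"]]))
      cfg$uncertainty <- uncertainty_spec(cond[["level"]])
    res <- purrr::map(seeds, function(sd) {
      cfg$seed <- as.integer(sd)
      run_trial(cfg)
    })
    ok <- !purrr::map_lgl(res, "diverged")
    rm <- do.call(rbind, purrr::map(res[ok], ~ .x$metrics$rmse))
    pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
    purrr::map_dfr(1:3, function(j) {
      dplyr::bind_cols(
        cond[setdiff(names(cond), c(".base", "controller"))],
        tibble(controller = cfg$controller,
               neuron = NEURONS[j],
               mean_rmse_mv = if (any(ok)) mean(rm[, j]) else NA_real_,
               sd_rmse_mv = if (any(ok)) pop_sd(rm[, j]) else NA_real_,
               n = sum(ok), n_diverged = sum(!ok)))
    })
  })
  structure(rows, class = c("cae_batch", class(rows)))
}
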