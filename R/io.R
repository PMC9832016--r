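# Configuration loading/validation and result export.

CONFIG_KEYS <- list(
  top = c("plant", "controller", "scenario", "output", "seed"),
  plant = c("preset", "desired_preset", "tau1", "tau2", "I_ext_TC",
            "g_gabaa_rt_tc"),
  controller = c("type", "sigma", "eta", "rho", "K1", "K2", "eps0", "sigma0",
                 "kappa_f", "kappa_ftau", "kappa_g", "kappa0", "gamma0",
                 "gamma1", "gamma2", "gamma3", "upsilon0", "upsilon_min",
                 "psi_clip", "u_max", "lambda", "k_sw", "st_a", "st_b",
                 "delta"),
  scenario = c("duration", "dt", "init_range", "record_every", "disturbance",
               "uncertainty"),
  disturbance = c("rate_hz", "amplitude", "width_ms", "target", "shape"),
  uncertainty = c("level", "fn_hz", "resample_s", "dt_ms"),
  output = c("dir", "write_trajectory", "write_metrics")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    abort(paste0("unknown configuration key", if (length(extra) > 1) "s",
                 " in '", where, "': ", paste(extra, collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, applies defaults
#' for everything unspecified and returns a fully resolved
#' [trial_config()].  A minimal file needs nothing beyond
#' `plant: {preset: cae}` and `controller: {type: aftsmc}`.
#'
#' @param path path to a YAML file.
#' @return list with `config` (the resolved [trial_config()]) and `output`
#'   (the output block with defaults applied).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("configuration file not found: ", path))
  raw <- yaml::read_yaml(path)
  check_keys(raw, CONFIG_KEYS$top, "top level")
  pb <- raw$plant %||% list()
  cb <- raw$controller %||% list()
  sb <- raw$scenario %||% list()
  ob <- raw$output %||% list()
  check_keys(pb, CONFIG_KEYS$plant, "plant")
  check_keys(cb, CONFIG_KEYS$controller, "controller")
  check_keys(sb, CONFIG_KEYS$scenario, "scenario")
  check_keys(ob, CONFIG_KEYS$output, "output")
  if (!is.null(sb$disturbance))
    check_keys(sb$disturbance, CONFIG_KEYS$disturbance, "scenario.disturbance")
  if (!is.null(sb$uncertainty))
    check_keys(sb$uncertainty, CONFIG_KEYS$uncertainty, "scenario.uncertainty")

  tau1 <- pb$tau1 %||% 10
  tau2 <- pb$tau2 %||% 2.8
  plant <- plant_params(pb$preset %||% "cae", tau1 = tau1, tau2 = tau2,
                        I_ext_TC = pb$I_ext_TC,
                        g_gabaa_rt_tc = pb$g_gabaa_rt_tc)
  desired <- plant_params(pb$desired_preset %||% "normal",
                          tau1 = tau1, tau2 = tau2)

  sp_args <- cb[intersect(names(cb), c("sigma", "eta", "rho", "K1", "K2"))]
  surface <- do.call(surface_params, sp_args)
  g_args <- cb[intersect(names(cb),
                         setdiff(CONFIG_KEYS$controller,
                                 c("type", "sigma", "eta", "rho", "K1", "K2",
                                   "delta")))]
  gains <- do.call(controller_gains, c(list(surface = surface), g_args))

  dist <- if (!is.null(sb$disturbance))
    do.call(disturbance_spec, sb$disturbance)
  unc <- if (!is.null(sb$uncertainty))
    do.call(uncertainty_spec, sb$uncertainty)

  cfg <- trial_config(
    duration = sb$duration %||% 2000, dt = sb$dt %||% 1e-3,
    seed = raw$seed %||% 1L,
    controller = cb$type %||% "aftsmc",
    plant = plant, desired = desired, gains = gains,
    membership = membership_spec(delta = cb$delta %||% 1),
    disturbance = dist, uncertainty = unc,
    init_range = sb$init_range %||% c(-60, -20),
    record_every = sb$record_every)
  list(config = cfg,
       output = list(dir = ob$dir %||% ".",
                     write_trajectory = ob$write_trajectory %||% TRUE,
                     write_metrics = ob$write_metrics %||% TRUE))
}

# serialisable echo of a resolved configuration (provenance)
config_as_list <- function(cfg) {
  sp <- cfg$gains$surface
  list(
    plant = list(preset = cfg$plant$preset,
                 desired_preset = cfg$desired$preset,
                 tau1 = cfg$plant$tau1, tau2 = cfg$plant$tau2,
                 I_ext_TC = unname(cfg$plant$I_ext[["TC"]]),
                 g_gabaa_rt_tc = unname(cfg$plant$syn$gabaa_rt_tc[["g"]])),
    controller = c(list(type = cfg$controller, sigma = sp$sigma,
                        eta = sp$eta, rho = sp$rho, K1 = sp$K1, K2 = sp$K2,
                        delta = cfg$membership$delta),
                   cfg$gains[setdiff(names(cfg$gains), "surface")]),
    scenario = list(
      duration = cfg$duration, dt = cfg$dt,
      init_range = cfg$init_range, record_every = cfg$record_every,
      disturbance = if (!is.null(cfg$disturbance)) unclass(cfg$disturbance),
      uncertainty = if (!is.null(cfg$uncertainty)) unclass(cfg$uncertainty)),
    seed = cfg$seed)
}

#' Export trial or batch results
#'
#' Writes the standard output set to a directory: the trajectory table
#' (`trajectory.csv` with columns `t_ms`, `V_TC`, `V_CT`, `V_RT`,
#' `u_1..u_3`, `d_1..d_3`), the metrics (`metrics.json`: per-neuron RMSE,
#' chattering indices, seeds, divergence flag) and the fully resolved
#' configuration (`config.yaml`) so any run can be replayed exactly.  For a
#' batch, the summary table is written as `summary.csv`.
#'
#' @param x a `cae_trial` or `cae_batch` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(x, "cae_trial")) {
    tr <- x$trajectory
    ds <- x$config$disturbance
    target_idx <- if (is.null(ds)) 2L else match(ds$target, NEURONS)
    out <- tibble(t_ms = tr$t_ms,
                  V_TC = tr$V_TC, V_CT = tr$V_CT, V_RT = tr$V_RT,
                  u_1 = tr$u_1, u_2 = tr$u_2, u_3 = tr$u_3,
                  d_1 = if (target_idx == 1) tr$d else 0,
                  d_2 = if (target_idx == 2) tr$d else 0,
                  d_3 = if (target_idx == 3) tr$d else 0)
    p_tr <- file.path(dir, "trajectory.csv")
    utils::write.csv(out, p_tr, row.names = FALSE)
    p_m <- file.path(dir, "metrics.json")
    jsonlite::write_json(
      list(rmse_mv = as.list(x$metrics$rmse),
           chattering_index = as.list(x$metrics$chattering),
           diverged = x$diverged, seeds = x$seeds),
      p_m, auto_unbox = TRUE, digits = NA)
    p_c <- file.path(dir, "config.yaml")
    yaml::write_yaml(config_as_list(x$config), p_c)
    paths <- c(p_tr, p_m, p_c)
  } else if (inherits(x, "cae_batch")) {
    p_s <- file.path(dir, "summary.csv")
    utils::write.csv(as.data.frame(x), p_s, row.names = FALSE)
    paths <- p_s
  } else {
    abort("x must be a cae_trial or cae_batch")
  }
  invisible(paths)
}
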