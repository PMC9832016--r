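# shared helpers: cheap configurations for closed-loop tests

# short closed-loop configuration at the reference step
short_cfg <- function(duration = 100, seed = 1, controller = "aftsmc", ...) {
  trial_config(duration = duration, dt = 1e-3, seed = seed,
               controller = controller, ...)
}

# a settled mid-trajectory state of a preset plant (for derivative checks)
settled_state <- function(preset = "cae", t_settle = 300) {
  p <- plant_params(preset)
  tr <- simulate_plant(p, duration = t_settle, dt = 0.01,
                       record_every = round(t_settle / 0.01))
  as.numeric(tr[nrow(tr), state_names()])
}

random_valid_state <- function() {
  v <- runif(3, -90, 40)
  gates <- runif(17, 0, 1)
  syn <- c(runif(2), runif(1, 0, 5), runif(4))  # GABA_B s may exceed 1
  stats::setNames(c(v, gates, syn), state_names())
}
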