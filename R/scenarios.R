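# Generators for the experimental conditions: gamma-process disturbance
# trains, low-pass-filtered parameter drift, and random initial conditions.

#' Gamma-process disturbance pulse train
#'
#' Rectangular current pulses whose onset intervals are i.i.d. gamma
#' distributed with mean `1/rate_hz`.  The gamma shape defaults to 2 (the
#' published protocol states only the mean rate); overlapping pulses merge
#' into a single active window of the same amplitude.
#'
#' @param rate_hz mean pulse rate, Hz (0 gives an identically zero signal).
#' @param amplitude pulse amplitude, uA/cm^2.
#' @param width_ms pulse width, ms.
#' @param duration_ms length of the signal, ms.
#' @param shape gamma shape parameter (> 0).
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @return object of class `pulse_train` with the onset times and the pulse
#'   geometry.
#' @examples
#' tr <- gamma_pulse_train(14, 1.25, 1, 2000, seed = 1)
#' length(tr$onsets_ms) / 2  # about 14 per second
#' @export
gamma_pulse_train <- function(rate_hz, amplitude, width_ms, duration_ms,
                              shape = 2, seed = NULL) {
  if (rate_hz < 0) abort("rate must be non-negative")
  if (width_ms <= 0 || duration_ms <= 0)
    abort("width and duration must be positive")
  if (rate_hz > 0 && width_ms / 1000 * rate_hz >= 1)
    abort("width x rate >= 1: the pulse train would be permanently active")
  draw <- function() {
    if (rate_hz == 0) return(numeric(0))
    mean_iv_ms <- 1000 / rate_hz
    # draw enough intervals to cover the duration with margin
    n_guess <- ceiling(duration_ms / mean_iv_ms * 2 + 20)
    iv <- rgamma(n_guess, shape = shape, scale = mean_iv_ms / shape)
    on <- cumsum(iv)
    while (sum(on <= duration_ms) == length(on)) {
      iv <- rgamma(n_guess, shape = shape, scale = mean_iv_ms / shape)
      on <- c(on, on[length(on)] + cumsum(iv))
    }
    on[on <= duration_ms]
  }
  onsets <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(onsets_ms = onsets, amplitude = amplitude,
                 width_ms = width_ms, duration_ms = duration_ms,
                 rate_hz = rate_hz, shape = shape),
            class = "pulse_train")
}

#' Sample a pulse train
#'
#' @param train a [gamma_pulse_train()].
#' @param t_ms times at which to evaluate the signal.
#' @return disturbance current at each time, uA/cm^2.
#' @export
pulse_signal <- function(train, t_ms) {
  out <- numeric(length(t_ms))
  for (on in train$onsets_ms)
    out[t_ms >= on & t_ms < on + train$width_ms] <- train$amplitude
  out
}

#' Low-pass-filtered parameter drift
#'
#' Time-varying multiplicative uncertainty for the ionic maximal conductances
#' and reversal potentials: an independent uniform sequence on
#' `[-level, +level]` per parameter, resampled every `resample_s` seconds
#' (2 s default, slow enough that the filtered spectrum concentrates below
#' twice the filter frequency),
#' is passed through a critically damped second-order low-pass filter with
#' natural frequency `fn_hz` and added to 1.  The filter is a convex
#' smoother, so every multiplier stays within `[1 - level, 1 + level]` by
#' construction and the drift spectrum concentrates below `fn_hz`.
#'
#' @param level uncertainty level in `[0, 0.5]` (fraction of nominal).
#' @param duration_ms drift schedule length, ms.
#' @param seed optional integer seed.
#' @param fn_hz filter natural frequency, Hz.
#' @param resample_s raw-sequence resampling interval, s.
#' @param dt_ms schedule resolution, ms (the plant holds the multiplier
#'   constant within each slot; the drift band is far slower than this).
#' @return object of class `param_drift`: a `ceiling(duration/dt) x 28`
#'   matrix of multipliers (columns in `drift_param_names()` order) plus the
#'   generation metadata.
#' @export
parameter_drift <- function(level, duration_ms, seed = NULL, fn_hz = 0.05,
                            resample_s = 2, dt_ms = 1) {
  if (level < 0 || level > 0.5)
    abort("uncertainty level must lie in [0, 0.5]")
  n <- ceiling(duration_ms / dt_ms)
  n_par <- length(drift_param_names())
  if (level == 0) {
    mult <- matrix(1, n, n_par)
  } else {
    gen <- function() {
      dt_s <- dt_ms / 1000
      hold <- max(1L, round(resample_s / dt_s))
      n_raw <- ceiling(n / hold)
      a <- 1 - exp(-2 * pi * fn_hz * dt_s)  # per-stage smoothing factor
      m <- matrix(NA_real_, n, n_par)
      for (j in seq_len(n_par)) {
        raw <- rep(runif(n_raw, -level, level), each = hold)[seq_len(n)]
        # stationary start: the filter state begins at the first raw draw,
        # so a short run still sees offsets spanning the full band
        y1 <- raw[1]; y2 <- raw[1]
        col <- numeric(n)
        for (i in seq_len(n)) {  # two cascaded first-order stages
          y1 <- y1 + a * (raw[i] - y1)
          y2 <- y2 + a * (y1 - y2)
          col[i] <- y2
        }
        m[, j] <- col
      }
      1 + pmin(pmax(m, -level), level)
    }
    mult <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  }
  colnames(mult) <- drift_param_names()
  structure(list(multipliers = mult, level = level, fn_hz = fn_hz,
                 resample_s = resample_s, dt_ms = dt_ms),
            class = "param_drift")
}

#' Random initial conditions for a closed-loop trial
#'
#' Draws the initial membrane voltages of the actual and desired plants
#' uniformly from `range` (all gating variables are then set to their steady
#' states for those voltages) and the initial fuzzy estimator weights
#' uniformly from `[0, 1]`.
#'
#' @param seed optional integer seed.
#' @param range voltage range, mV.
#' @return list with `v_actual`, `v_desired` (3-vectors, mV) and `psi0`
#'   (15 x 125 weight matrix).
#' @export
random_initial_conditions <- function(seed = NULL, range = c(-60, -20)) {
  draw <- function() {
    list(v_actual = runif(3, range[1], range[2]),
         v_desired = runif(3, range[1], range[2]),
         psi0 = matrix(runif(15 * 125), nrow = 15))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Tracking root-mean-square error
#'
#' `sqrt(mean((actual - desired)^2))` per channel.
#'
#' @param actual,desired equal-length numeric vectors (or matrices with
#'   matching dimensions, reduced column-wise).
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(actual, desired) {
  if (length(actual) != length(desired))
    abort("actual and desired series must have equal length")
  if (is.matrix(actual))
    return(sqrt(colMeans((actual - desired)^2)))
  sqrt(mean((actual - desired)^2))
}

#' Chattering index of a control signal
#'
#' Mean absolute step-to-step difference normalized by the step size and the
#' signal range: `mean(|diff(u)|) / (dt * (max(u) - min(u)))`.  Zero for a
#' constant signal; large for a switching signal flipping every step.
#'
#' @param u control series (vector, or matrix reduced column-wise).
#' @param dt sampling step, ms.
#' @return per-channel index, 1/ms.
#' @export
chattering_index <- function(u, dt) {
  if (is.matrix(u)) return(apply(u, 2, chattering_index, dt = dt))
  if (length(u) < 2) abort("at least two samples are required")
  rng <- max(u) - min(u)
  if (rng == 0) return(0)
  mean(abs(diff(u))) / (dt * rng)
}
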