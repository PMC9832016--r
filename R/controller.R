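# Terminal sliding-mode control laws: the ideal-knowledge controller (used as
# a finite-time-convergence oracle), the adaptive fuzzy controller deployed in
# closed loop, and the analytic reaching/settling-time bounds.

sgn <- function(x) sign(x)  # sign(0) = 0 throughout

#' Terminal sliding surface and reaching-law parameters
#'
#' The nonsingular terminal surface is
#' `s_i = int_0^t e_i dt + sigma |e_i|^eta sign(e_i)` with `sigma > 0` and
#' `1 < eta < 2`; the fast reaching law is
#' `ds/dt = -K1 s - K2 |s|^rho sign(s)` with `0 < rho < 1` and positive
#' diagonal gain matrices.  Fractional powers keep the control input
#' continuous (chattering-free) while granting finite-time convergence.
#'
#' @param sigma surface weight on the terminal term (> 0).
#' @param eta terminal exponent in `(1, 2)`.
#' @param rho reaching-law exponent in `(0, 1)`.
#' @param K1,K2 positive diagonal gains (length-3 vectors of diagonals).
#' @return object of class `surface_params`; `k1_min` / `k2_min` expose the
#'   smallest diagonal entries used by the analytic time bounds.
#' @export
surface_params <- function(sigma = 0.03, eta = 1.5, rho = 0.6,
                           K1 = rep(400, 3), K2 = rep(200, 3)) {
  if (sigma <= 0) abort("sigma must be positive")
  if (eta <= 1 || eta >= 2) abort("eta must lie in (1, 2)")
  if (rho <= 0 || rho >= 1) abort("rho must lie in (0, 1)")
  K1 <- rep_len(as.numeric(K1), 3)
  K2 <- rep_len(as.numeric(K2), 3)
  if (any(K1 <= 0) || any(K2 <= 0)) abort("gain diagonals must be positive")
  structure(list(sigma = sigma, eta = eta, rho = rho, K1 = K1, K2 = K2,
                 k1_min = min(K1), k2_min = min(K2)),
            class = "surface_params")
}

#' Terminal sliding variable
#'
#' `s_i = ie_i + sigma |e_i|^eta sign(e_i)`, where `ie` is the running
#' integral of the tracking error.  Odd in `(e, ie)` and continuous.
#'
#' @param e tracking error (vectorised).
#' @param ie integral of the tracking error.
#' @param sigma,eta surface parameters (see [surface_params()]).
#' @export
sliding_surface <- function(e, ie, sigma, eta) {
  ie + sigma * abs(e)^eta * sgn(e)
}

# the shared bracket of the control laws:
# xdot_d + (1/(eta sigma)) |e|^(2-eta) sign(e) + K1 s + K2 |s|^rho sign(s)
reaching_bracket <- function(xdot_d, e, s, sp) {
  xdot_d + (1 / (sp$eta * sp$sigma)) * abs(e)^(2 - sp$eta) * sgn(e) +
    sp$K1 * s + sp$K2 * abs(s)^sp$rho * sgn(s)
}

#' Ideal-knowledge terminal sliding-mode control
#'
#' The control law under full knowledge of the plant:
#' `u = G^-1 (-f - f_tau - d + xdot_d + (1/(eta sigma)) |e|^(2-eta) sign(e)
#' + K1 s + K2 |s|^rho sign(s))`.  Substituted into the plant it cancels the
#' dynamics exactly, leaving the prescribed reaching law scaled by
#' `eta sigma diag(|e|^(eta-1))`.  Used only as a testing oracle for the
#' finite-time convergence guarantees; deployment never requires it.
#'
#' @param f,f_tau true non-delayed / delayed dynamics (3-vectors).
#' @param G true input-gain matrix (3 x 3, invertible).
#' @param d disturbance (3-vector).
#' @param xdot_d desired-trajectory derivative (3-vector).
#' @param e,s tracking error and sliding variable (3-vectors).
#' @param sp a [surface_params()].
#' @return control 3-vector.
#' @export
ideal_control <- function(f, f_tau, G, d, xdot_d, e, s, sp) {
  G <- as.matrix(G)
  if (abs(det(G)) < .Machine$double.eps) abort("G is singular")
  as.numeric(solve(G, -f - f_tau - d + reaching_bracket(xdot_d, e, s, sp)))
}

#' Certainty-equivalent control with regularized gain inversion
#'
#' Replaces the unknown dynamics by their fuzzy estimates and the exact
#' inverse by the regularized form
#' `u_c = Ghat' (eps0 I + Ghat Ghat')^-1 (bracket)`, which stays finite for
#' any estimated gain (including `Ghat = 0`) and is continuous in all
#' arguments.
#'
#' @param f_hat,f_tau_hat,G_hat fuzzy estimates of the dynamics.
#' @param xdot_d,e,s,sp as in [ideal_control()].
#' @param eps0 regularization parameter (> 0).
#' @export
certainty_control <- function(f_hat, f_tau_hat, G_hat, xdot_d, e, s, sp,
                              eps0) {
  if (eps0 <= 0) abort("eps0 must be positive")
  b <- -f_hat - f_tau_hat + reaching_bracket(xdot_d, e, s, sp)
  M <- eps0 * diag(3) + G_hat %*% t(G_hat)
  as.numeric(t(G_hat) %*% solve(M, b))
}

#' Regularization residual term
#'
#' `u0 = eps0 (eps0 I + Ghat Ghat')^-1 (bracket)`: the part of the bracket
#' that the regularized inverse fails to realise.  It vanishes as
#' `eps0 -> 0` and enters the robustifying term through its magnitude.
#'
#' @inheritParams certainty_control
#' @export
u0_term <- function(f_hat, f_tau_hat, G_hat, xdot_d, e, s, sp, eps0) {
  if (eps0 < 0) abort("eps0 must be non-negative")
  b <- -f_hat - f_tau_hat + reaching_bracket(xdot_d, e, s, sp)
  M <- eps0 * diag(3) + G_hat %*% t(G_hat)
  as.numeric(eps0 * solve(M, b))
}

#' Adaptive upper-bound state
#'
#' Containers for the online estimates of the bounds on the minimum fuzzy
#' approximation errors (`eps_f`, `eps_ftau`, scalar `eps_g`), the external
#' disturbance (`d_hat`) and the adaptive denominator parameter `upsilon`.
#' The bound estimates only grow along a run; `upsilon` only decreases and is
#' floored at `upsilon_min` to keep the robustifying term well defined.
#'
#' @param upsilon0 initial value of the adaptive denominator parameter.
#' @param upsilon_min positive floor for `upsilon`.
#' @param sigma0 fixed denominator weight (> 0).
#' @param kappa0,gamma0,gamma1,gamma2,gamma3 positive adaptation rates.
#' @return object of class `adaptive_bounds` (all estimates start at zero).
#' @export
adaptive_bounds <- function(upsilon0 = 1, upsilon_min = 1e-6, sigma0 = 1,
                            kappa0 = 0.1, gamma0 = 0.1, gamma1 = 0.1,
                            gamma2 = 0.1, gamma3 = 0.1) {
  rates <- c(kappa0, gamma0, gamma1, gamma2, gamma3)
  if (any(rates <= 0)) abort("adaptation rates must be positive")
  if (sigma0 <= 0 || upsilon0 <= 0 || upsilon_min <= 0)
    abort("sigma0, upsilon0 and upsilon_min must be positive")
  structure(list(eps_f = numeric(3), eps_ftau = numeric(3), eps_g = 0,
                 d_hat = numeric(3), upsilon = upsilon0,
                 upsilon_min = upsilon_min, sigma0 = sigma0,
                 kappa0 = kappa0, gamma0 = gamma0, gamma1 = gamma1,
                 gamma2 = gamma2, gamma3 = gamma3),
            class = "adaptive_bounds")
}

bound_sum_vec <- function(bounds, u_c, u0) {
  bounds$eps_f + bounds$eps_ftau + bounds$eps_g * abs(u_c) + bounds$d_hat +
    abs(u0)
}

#' Robustifying control term
#'
#' `u_r = s |s'| (eps_f + eps_ftau + eps_g |u_c| + d_hat + |u0|) /
#' (sigma0 ||s||^2 + upsilon)`: a continuous substitute for a switching term
#' whose magnitude is governed by the adaptive bound estimates.  It is zero
#' on the sliding surface and saturates near the bound sum far from it.
#'
#' @param s sliding variable (3-vector).
#' @param bounds an [adaptive_bounds()] state.
#' @param u_c,u0 certainty-equivalent control and regularization residual.
#' @export
robust_term <- function(s, bounds, u_c, u0) {
  if (bounds$upsilon <= 0) abort("upsilon must be positive")
  b <- bound_sum_vec(bounds, u_c, u0)
  s * sum(abs(s) * b) / (bounds$sigma0 * sum(s^2) + bounds$upsilon)
}

#' Adapt the upper-bound estimates
#'
#' Forward-Euler update of the bound estimates: each grows proportionally to
#' `eta sigma |e|^(eta-1) |s|` (times `|u_c|` for the gain-error bound) and
#' `upsilon` shrinks by the matching weighted robustifying magnitude, clamped
#' at its floor.
#'
#' @inheritParams robust_term
#' @param e tracking error (3-vector).
#' @param sigma,eta surface parameters.
#' @param dt step, ms.
#' @return updated `adaptive_bounds`.
#' @export
adapt_bounds <- function(bounds, e, s, u_c, u0, sigma, eta, dt) {
  w <- eta * sigma * abs(e)^(eta - 1)
  b <- bound_sum_vec(bounds, u_c, u0)
  bounds$eps_f <- bounds$eps_f + bounds$gamma0 * w * abs(s) * dt
  bounds$eps_ftau <- bounds$eps_ftau + bounds$gamma1 * w * abs(s) * dt
  bounds$eps_g <- bounds$eps_g +
    bounds$gamma2 * sum(abs(s) * w * abs(u_c)) * dt
  bounds$d_hat <- bounds$d_hat + bounds$gamma3 * w * abs(s) * dt
  bounds$upsilon <- max(
    bounds$upsilon - bounds$kappa0 *
      sum(abs(s) * w * b) / (bounds$sigma0 * sum(s^2) + bounds$upsilon) * dt,
    bounds$upsilon_min)
  bounds
}

#' Total control signal
#'
#' Sum of the certainty-equivalent and robustifying terms, with optional
#' amplitude saturation.
#'
#' @param u_c,u_r control components (3-vectors).
#' @param u_max optional saturation bound (`Inf` disables).
#' @export
total_control <- function(u_c, u_r, u_max = Inf) {
  pmin(pmax(u_c + u_r, -u_max), u_max)
}

#' Analytic finite-time bounds
#'
#' Computable consequences of the convergence guarantees: the reaching-time
#' bound
#' `t_r <= (1/(k1b (1-rho))) log((k1b V0^((1-rho)/2) + 2^((rho-1)/2) k2b) /
#' (2^((rho-1)/2) k2b))`,
#' the settling time on the surface
#' `t_s = (sigma eta / (eta - 1)) |x_tr|^(eta-1)`, and the steady-state
#' error bound `|e| <= (delta / sigma)^(1/eta)` for a sliding variable
#' confined to `||s|| <= delta`.
#'
#' @param sp a [surface_params()].
#' @param V0 initial Lyapunov value `0.5 ||s(0)||^2` (for `t_r`).
#' @param k1_bar,k2_bar minimum diagonal entries of the error-scaled gain
#'   matrices along the reaching phase (default: the raw gain minima).
#' @param x_tr error magnitude when the surface is reached (for `t_s`).
#' @param delta sliding-variable bound (for `e_bound`).
#' @return list with whichever of `t_r`, `t_s`, `e_bound` could be computed.
#' @export
time_bounds <- function(sp, V0 = NULL, k1_bar = sp$k1_min,
                        k2_bar = sp$k2_min, x_tr = NULL, delta = NULL) {
  if (k1_bar <= 0 || k2_bar <= 0) abort("gain minima must be positive")
  out <- list()
  if (!is.null(V0)) {
    if (V0 < 0) abort("V0 must be non-negative")
    a2 <- 2^((sp$rho - 1) / 2) * k2_bar
    out$t_r <- log((k1_bar * V0^((1 - sp$rho) / 2) + a2) / a2) /
      (k1_bar * (1 - sp$rho))
  }
  if (!is.null(x_tr))
    out$t_s <- sp$sigma * sp$eta / (sp$eta - 1) * abs(x_tr)^(sp$eta - 1)
  if (!is.null(delta)) {
    if (delta < 0) abort("delta must be non-negative")
    out$e_bound <- (delta / sp$sigma)^(1 / sp$eta)
  }
  out
}

#' Classical adaptive fuzzy sliding-mode baseline (one step)
#'
#' The comparison controller: linear surface `s = e + lambda ie`, exponential
#' reaching law with a discontinuous switching term `k_sw sign(s)`, and the
#' same fuzzy estimators for the unknown dynamics, with the input gain taken
#' as known (identity) in the classical manner.  The sign term makes this
#' baseline chatter by construction.
#'
#' @param f_hat,f_tau_hat fuzzy estimates of the dynamics.
#' @param xdot_d desired derivative (3-vector).
#' @param e,ie error and its integral (3-vectors).
#' @param lambda surface slope (> 0).
#' @param k_sw switching gain (> 0).
#' @param k1_lin proportional reaching gain (exponential reaching law).
#' @return list with `u` and the surface value `s`.
#' @export
afsmc_control <- function(f_hat, f_tau_hat, xdot_d, e, ie,
                          lambda, k_sw, k1_lin = 10) {
  if (lambda <= 0 || k_sw <= 0) abort("lambda and k_sw must be positive")
  s <- e + lambda * ie
  list(u = -f_hat - f_tau_hat + xdot_d + lambda * e + k1_lin * s +
         k_sw * sgn(s),
       s = s)
}

#' Super-twisting sliding-mode baseline (one step)
#'
#' Standard per-channel super-twisting law
#' `u = a |s|^(1/2) sign(s) + w`, `dw/dt = b sign(s)`: continuous control
#' with an integral switching state, requiring no model knowledge.
#'
#' @param s sliding variable (vectorised).
#' @param w integral state (same length).
#' @param a,b positive gains.
#' @param dt step, ms.
#' @return list with `u` and the advanced integral state `w`.
#' @export
stsmc_control <- function(s, w, a, b, dt) {
  if (a <= 0 || b <= 0) abort("super-twisting gains must be positive")
  list(u = a * sqrt(abs(s)) * sgn(s) + w, w = w + b * sgn(s) * dt)
}

#' Finite-time reaching demonstration on a scalar toy plant
#'
#' Integrates the ideal-knowledge terminal controller on the known scalar
#' plant `dx/dt = sin(x) + u` tracking `x_d(t) = a sin(omega t)`, recording
#' the sliding variable, error and Lyapunov value.  Exercises the
#' finite-time reaching and settling guarantees with every quantity known in
#' closed form.
#'
#' @param sp a [surface_params()] (only the first diagonal entries are used).
#' @param x0 initial state.
#' @param duration,dt integration horizon and step.
#' @param a,omega desired-trajectory amplitude and angular frequency.
#' @return tibble with columns `t`, `x`, `x_d`, `e`, `s`, `V`, `u`.
#' @export
simulate_ideal_tsm <- function(sp, x0 = 1, duration = 3, dt = 1e-4,
                               a = 0.5, omega = 2) {
  n <- round(duration / dt)
  x <- x0; ie <- 0
  out <- matrix(NA_real_, n + 1, 7)
  for (i in 0:n) {
    t <- i * dt
    xd <- a * sin(omega * t)
    e <- xd - x
    s <- sliding_surface(e, ie, sp$sigma, sp$eta)
    u <- ideal_control(sin(x), 0, matrix(1), 0, a * omega * cos(omega * t),
                       e, s, sp_scalar(sp))
    out[i + 1, ] <- c(t, x, xd, e, s, 0.5 * s * s, u)
    if (i == n) break
    # RK4 on the augmented (x, ie) system with u frozen over the step
    f <- function(xv) sin(xv) + u
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ie <- ie + e * dt
  }
  colnames(out) <- c("t", "x", "x_d", "e", "s", "V", "u")
  as_tibble(out)
}

# reduce a 3-channel surface_params to its scalar (first-channel) version
sp_scalar <- function(sp) {
  structure(list(sigma = sp$sigma, eta = sp$eta, rho = sp$rho,
                 K1 = sp$K1[1], K2 = sp$K2[1],
                 k1_min = sp$K1[1], k2_min = sp$K2[1]),
            class = "surface_params")
}
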