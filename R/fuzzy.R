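# Gaussian-membership fuzzy logic systems: the universal approximators that
# stand in for the unknown plant dynamics inside the adaptive controllers.

#' Membership function specification
#'
#' Five Gaussian membership functions per input voltage, shared by all
#' estimators.  The default centers (-60, -40, 0, 40, 60) mV span the
#' physiological voltage range; the default width of 1 mV follows the
#' published design (see the methods vignette for its conditioning
#' implications and the wider alternative).
#'
#' @param centers numeric vector of 5 centers, mV.
#' @param delta membership width, mV (> 0).
#' @return object of class `membership_spec`.
#' @export
membership_spec <- function(centers = c(-60, -40, 0, 40, 60), delta = 1) {
  if (length(centers) != 5) abort("exactly five centers per input are required")
  if (delta <= 0) abort("membership width must be positive")
  structure(list(centers = as.numeric(centers), delta = as.numeric(delta)),
            class = "membership_spec")
}

#' Gaussian membership grade
#'
#' `mu(x) = exp(-((x - c) / delta)^2 / 2)`: 1 at the center, symmetric,
#' strictly positive everywhere.
#'
#' @param x input, mV (vectorised).
#' @param c center, mV.
#' @param delta width, mV (> 0).
#' @export
membership <- function(x, c, delta) {
  if (any(delta <= 0)) abort("membership width must be positive")
  exp(-0.5 * ((x - c) / delta)^2)
}

#' Normalized fuzzy basis vector
#'
#' Product-inference basis over the 5 x 5 x 5 rule grid: component `k` is the
#' product of the three per-input membership grades of rule `k`, normalized to
#' sum to one.  Evaluated in the log domain so the vector stays well defined
#' even where all raw products underflow (with the default 1 mV width the
#' Gaussians are near-disjoint).
#'
#' @param x numeric 3-vector of input voltages, mV.
#' @param spec a [membership_spec()].
#' @return simplex vector of length 125 (non-negative, sums to 1).  Rule
#'   order: index of input 1 varies slowest, input 3 fastest.
#' @export
fuzzy_basis <- function(x, spec = membership_spec()) {
  cpp_fuzzy_basis(as.numeric(x), spec$centers, spec$delta)
}

#' Fuzzy logic system output
#'
#' Center-average defuzzified output `psi' zeta` for one estimator: linear in
#' the adjustable parameters and, since `zeta` lies on the simplex, bounded
#' by `[min(psi), max(psi)]`.
#'
#' @param zeta basis vector (length 125, see [fuzzy_basis()]).
#' @param psi adjustable-parameter vector (length 125).
#' @export
fls_eval <- function(zeta, psi) {
  if (length(zeta) != length(psi))
    abort("basis and parameter vectors must have equal length")
  sum(zeta * psi)
}

#' Bank of fuzzy estimators for the plant dynamics
#'
#' Fifteen fuzzy logic systems sharing one membership specification: three
#' approximate the non-delayed dynamics f (inputs: current voltages), three
#' the delayed dynamics f_tau (inputs: delayed voltages), and nine the
#' entries of the input-gain matrix G (inputs: current voltages).
#'
#' @param spec a [membership_spec()].
#' @param psi0 optional 15 x 125 matrix of initial weights; by default drawn
#'   i.i.d. uniform on `[0, 1]` from the current RNG state.
#' @return object of class `estimator_bank` with elements `psi` (15 x 125
#'   matrix; rows 1-3 f, 4-6 f_tau, 7-15 G row-major) and `spec`.
#' @export
estimator_bank <- function(spec = membership_spec(), psi0 = NULL) {
  psi <- psi0 %||% matrix(runif(15 * 125), nrow = 15)
  if (!all(dim(psi) == c(15, 125))) abort("psi0 must be a 15 x 125 matrix")
  if (!all(is.finite(psi))) abort("initial weights must be finite")
  structure(list(psi = psi, spec = spec), class = "estimator_bank")
}

#' Evaluate the estimator bank
#'
#' @param bank an [estimator_bank()].
#' @param x current voltages (3-vector, mV).
#' @param x_tau delayed voltages (3-vector, mV).
#' @return list with `f_hat`, `f_tau_hat` (3-vectors) and `G_hat`
#'   (3 x 3 matrix).
#' @export
bank_eval <- function(bank, x, x_tau = x) {
  zx <- fuzzy_basis(x, bank$spec)
  zt <- fuzzy_basis(x_tau, bank$spec)
  f_hat <- as.numeric(bank$psi[1:3, , drop = FALSE] %*% zx)
  ft_hat <- as.numeric(bank$psi[4:6, , drop = FALSE] %*% zt)
  G_hat <- matrix(as.numeric(bank$psi[7:15, , drop = FALSE] %*% zx),
                  nrow = 3, byrow = TRUE)
  list(f_hat = f_hat, f_tau_hat = ft_hat, G_hat = G_hat)
}

#' Terminal-gradient weight adaptation
#'
#' One forward-Euler update of all adjustable parameters with the
#' terminal-gradient laws: for channel i,
#' `dpsi_f/dt  = -kappa_f  * sigma * eta * |e_i|^(eta-1) * zeta(x)     * s_i`,
#' `dpsi_ftau/dt = -kappa_ftau * sigma * eta * |e_i|^(eta-1) * zeta(x_tau) * s_i`,
#' and for gain entry (i, j)
#' `dpsi_g/dt = -kappa_g * sigma * eta * |e_i|^(eta-1) * zeta(x) * s_i * u_c_j`.
#' Updates vanish as the tracking error or the sliding variable reach zero.
#'
#' @param bank an [estimator_bank()].
#' @param e tracking error 3-vector, mV.
#' @param s sliding-variable 3-vector.
#' @param u_c certainty-equivalent control 3-vector.
#' @param x,x_tau estimator inputs (current / delayed voltages).
#' @param sigma,eta terminal surface parameters (sigma > 0, 1 < eta < 2).
#' @param kappa_f,kappa_ftau,kappa_g positive adaptation gains.
#' @param dt step, ms.
#' @return the updated bank.
#' @export
adapt_weights <- function(bank, e, s, u_c, x, x_tau = x,
                          sigma, eta, kappa_f, kappa_ftau, kappa_g, dt) {
  if (any(c(kappa_f, kappa_ftau, kappa_g) <= 0))
    abort("adaptation gains must be positive")
  if (eta <= 1 || eta >= 2) abort("eta must lie in (1, 2)")
  zx <- fuzzy_basis(x, bank$spec)
  zt <- fuzzy_basis(x_tau, bank$spec)
  w <- sigma * eta * abs(e)^(eta - 1)
  psi <- bank$psi
  for (i in 1:3) {
    psi[i, ] <- psi[i, ] - kappa_f * w[i] * s[i] * zx * dt
    psi[3 + i, ] <- psi[3 + i, ] - kappa_ftau * w[i] * s[i] * zt * dt
    for (j in 1:3)
      psi[6 + (i - 1) * 3 + j, ] <-
        psi[6 + (i - 1) * 3 + j, ] - kappa_g * w[i] * s[i] * u_c[j] * zx * dt
  }
  if (!all(is.finite(psi))) abort("estimator weights became non-finite")
  bank$psi <- psi
  bank
}
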