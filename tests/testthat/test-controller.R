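# Terminal sliding-mode control laws, adaptive bounds, analytic time bounds
# and the baseline controllers.

sp_toy <- surface_params(sigma = 1, eta = 1.5, rho = 0.5,
                         K1 = rep(2, 3), K2 = rep(1, 3))

test_that("the terminal sliding variable is odd, continuous and matches examples", {
  expect_equal(sliding_surface(4, 0, sigma = 1, eta = 1.5), 8)  # 4^1.5
  expect_equal(sliding_surface(0, 0, 1, 1.5), 0)
  e <- c(-2.3, 0, 1.7); ie <- c(0.5, -1, 0.2)
  expect_equal(sliding_surface(-e, -ie, 0.03, 1.5),
               -sliding_surface(e, ie, 0.03, 1.5))
})

test_that("surface parameters are validated at construction", {
  expect_error(surface_params(sigma = -1), "sigma")
  expect_error(surface_params(eta = 2.5), "eta")
  expect_error(surface_params(rho = 1.2), "rho")
  expect_error(surface_params(K1 = c(-1, 1, 1)), "positive")
})

test_that("ideal control is pure feedforward at zero error", {
  f <- c(1, -2, 3); ft <- c(0.5, 0, -0.5); G <- diag(c(1, 2, 4))
  d <- c(0.1, 0.2, -0.1); xd <- c(5, 6, 7)
  u <- ideal_control(f, ft, G, d, xd, e = c(0, 0, 0), s = c(0, 0, 0), sp_toy)
  expect_equal(u, as.numeric(solve(G, xd - f - ft - d)))
  expect_error(ideal_control(f, ft, matrix(0, 3, 3), d, xd,
                             c(0, 0, 0), c(0, 0, 0), sp_toy), "singular")
})

test_that("regularized inversion is finite for any gain estimate", {
  xd <- c(1, 1, 1); e <- c(2, -1, 0.5)
  s <- sliding_surface(e, c(0, 0, 0), sp_toy$sigma, sp_toy$eta)
  f <- c(10, -5, 2); ft <- c(1, 1, 1)
  # Ghat = 0: control collapses to zero instead of blowing up
  u0g <- certainty_control(f, ft, matrix(0, 3, 3), xd, e, s, sp_toy, 1)
  expect_equal(u0g, c(0, 0, 0))
  # Ghat = I, eps0 = 1: exactly half the bracket, and u_c + u_0 = bracket
  uc <- certainty_control(f, ft, diag(3), xd, e, s, sp_toy, 1)
  u0 <- u0_term(f, ft, diag(3), xd, e, s, sp_toy, 1)
  expect_equal(uc, u0)
  bracket <- uc + u0
  uc_small <- certainty_control(f, ft, diag(3), xd, e, s, sp_toy, 1e-12)
  expect_equal(uc_small, bracket, tolerance = 1e-9)
  expect_equal(u0_term(f, ft, diag(3), xd, e, s, sp_toy, 0), c(0, 0, 0))
})

test_that("the robustifying term vanishes on the surface and saturates off it", {
  b <- adaptive_bounds()
  b$eps_f <- rep(1, 3); b$d_hat <- rep(0.5, 3)
  expect_equal(robust_term(c(0, 0, 0), b, c(1, 1, 1), c(0, 0, 0)), c(0, 0, 0))
  # scalar-direction saturation: for ||s|| large, |u_r| -> bound sum / sigma0
  bsum <- 1.5  # eps_f + d_hat per channel
  for (sc in c(1, 10, 100)) {
    s <- c(sc, 0, 0)
    ur <- robust_term(s, b, c(0, 0, 0), c(0, 0, 0))
    expect_equal(ur[1], sc^2 * bsum / (b$sigma0 * sc^2 + b$upsilon))
  }
  ur_inf <- robust_term(c(1e6, 0, 0), b, c(0, 0, 0), c(0, 0, 0))
  expect_equal(ur_inf[1], bsum / b$sigma0, tolerance = 1e-6)
})

test_that("bound estimates grow monotonically and upsilon only shrinks", {
  withr::with_seed(31, {
    b <- adaptive_bounds()
    for (i in 1:200) {
      e <- runif(3, -2, 2); s <- runif(3, -1, 1)
      b2 <- adapt_bounds(b, e, s, u_c = runif(3, -10, 10),
                         u0 = runif(3, -1, 1), sigma = 0.03, eta = 1.5,
                         dt = 1e-3)
      expect_true(all(b2$eps_f >= b$eps_f))
      expect_true(all(b2$eps_ftau >= b$eps_ftau))
      expect_true(all(b2$d_hat >= b$d_hat))
      expect_gte(b2$eps_g, b$eps_g)
      expect_lte(b2$upsilon, b$upsilon)
      expect_gte(b2$upsilon, b$upsilon_min)
      b <- b2
    }
    # zero error freezes every bound
    b3 <- adapt_bounds(b, c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), c(0, 0, 0),
                       0.03, 1.5, 1e-3)
    expect_equal(b3$eps_f, b$eps_f)
    expect_equal(b3$upsilon, b$upsilon)
  })
})

test_that("total control sums the terms and saturation clips symmetrically", {
  expect_equal(total_control(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(total_control(c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  expect_equal(total_control(c(5, -7, 1), c(1, -1, 0), u_max = 4),
               c(4, -4, 1))
})

test_that("analytic time bounds behave as stated at their edge cases", {
  expect_equal(time_bounds(sp_toy, V0 = 0)$t_r, 0)
  # t_s = sigma eta / (eta - 1) |x|^(eta - 1)
  expect_equal(time_bounds(sp_toy, x_tr = 1)$t_s, 1 * 1.5 / 0.5)
  expect_equal(time_bounds(sp_toy, delta = 0)$e_bound, 0)
  # monotone decreasing in the gains
  t_lo <- time_bounds(sp_toy, V0 = 2)$t_r
  t_hi <- time_bounds(sp_toy, V0 = 2, k1_bar = 10, k2_bar = 10)$t_r
  expect_lt(t_hi, t_lo)
  expect_error(time_bounds(sp_toy, V0 = 1, k1_bar = -1), "positive")
})

test_that("ideal control reaches the surface and settles within the analytic bounds", {
  tr <- simulate_ideal_tsm(sp_toy, x0 = 1, duration = 3, dt = 1e-4)
  i_r <- which(abs(tr$s) < 1e-6)[1]
  expect_false(is.na(i_r))
  t_reach <- tr$t[i_r]
  # the reaching bound uses the error-scaled gain minima over the phase
  phase <- tr[1:i_r, ]
  k1b <- min(sp_toy$eta * sp_toy$sigma * abs(phase$e)^(sp_toy$eta - 1)) *
    sp_toy$K1[1]
  k2b <- min(sp_toy$eta * sp_toy$sigma * abs(phase$e)^(sp_toy$eta - 1)) *
    sp_toy$K2[1]
  expect_lt(t_reach, time_bounds(sp_toy, V0 = phase$V[1],
                                 k1_bar = k1b, k2_bar = k2b)$t_r)
  # after reaching, the error settles within the terminal-phase bound
  t_s <- time_bounds(sp_toy, x_tr = abs(tr$e[i_r]))$t_s
  i_e <- which(abs(tr$e) < 1e-4 & tr$t >= t_reach)[1]
  expect_false(is.na(i_e))
  expect_lte(tr$t[i_e] - t_reach, t_s)
  # Lyapunov decrease V' <= -2 k1b V - 2^((1+rho)/2) k2b V^((1+rho)/2)
  dV <- diff(phase$V) / 1e-4
  Vr <- phase$V[-1]
  bound <- -2 * k1b * Vr - 2^((1 + sp_toy$rho) / 2) * k2b *
    Vr^((1 + sp_toy$rho) / 2)
  expect_lt(max(dV - bound), 1e-6)
})

test_that("the super-twisting baseline rejects a constant matched disturbance", {
  # scalar integrator dx/dt = d - u_st with s = x: the integral state w
  # learns the disturbance and s reaches zero in finite time
  a <- 5; b <- 10; d <- 2
  x <- 1; w <- 0; dt <- 1e-4
  s_hist <- numeric(30000)
  for (i in seq_along(s_hist)) {
    st <- stsmc_control(x, w, a, b, dt)
    w <- st$w
    x <- x + dt * (d - st$u)
    s_hist[i] <- x
  }
  expect_lt(abs(s_hist[length(s_hist)]), 1e-3)
  expect_error(stsmc_control(1, 0, -1, 1, 1e-3), "positive")
})

test_that("the AFSMC reaching law jumps by twice the switching gain across s = 0", {
  f <- c(0, 0, 0)
  u_plus <- afsmc_control(f, f, xdot_d = c(0, 0, 0), e = c(1e-9, 0, 0),
                          ie = c(0, 0, 0), lambda = 1, k_sw = 20)$u
  u_minus <- afsmc_control(f, f, xdot_d = c(0, 0, 0), e = c(-1e-9, 0, 0),
                           ie = c(0, 0, 0), lambda = 1, k_sw = 20)$u
  expect_equal(u_plus[1] - u_minus[1], 2 * 20, tolerance = 1e-6)
  # zero error history reduces to the feedforward estimate
  u0 <- afsmc_control(c(1, 2, 3), c(0.5, 0, 0), xdot_d = c(4, 4, 4),
                      e = c(0, 0, 0), ie = c(0, 0, 0), lambda = 1,
                      k_sw = 20)$u
  expect_equal(u0, c(4, 4, 4) - c(1, 2, 3) - c(0.5, 0, 0))
})
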