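# Gaussian memberships, the normalized rule basis and weight adaptation.

test_that("membership grade peaks at the center with the Gaussian profile", {
  expect_equal(membership(-40, -40, 1), 1)
  expect_equal(membership(-39, -40, 1), exp(-0.5))
  expect_equal(membership(-41, -40, 1), exp(-0.5))
  expect_equal(membership(5, 0, 1e9), 1, tolerance = 1e-12)
  expect_gt(membership(-55, -60, 1), 0)  # positive away from the center
  expect_error(membership(0, 0, -1), "positive")
})

test_that("basis vector is a simplex for any input", {
  spec <- membership_spec()
  withr::with_seed(21, {
    for (i in 1:200) {
      z <- fuzzy_basis(runif(3, -90, 60), spec)
      expect_equal(sum(z), 1, tolerance = 1e-12)
      expect_true(all(z >= 0))
    }
  })
})

test_that("basis normalization error stays below 1e-12 at 1e4 random points", {
  spec <- membership_spec()
  withr::with_seed(99, {
    x <- matrix(runif(3e4, -90, 60), ncol = 3)
    worst <- max(abs(apply(x, 1, function(r) sum(fuzzy_basis(r, spec)) - 1)))
    expect_lt(worst, 1e-12)
  })
})

test_that("a grid vertex with a narrow width gives a one-hot basis", {
  spec <- membership_spec(delta = 1)
  z <- fuzzy_basis(c(-60, -60, -60), spec)
  expect_equal(z[1], 1, tolerance = 1e-12)
  expect_lt(max(z[-1]), 1e-12)
})

test_that("consistently permuted inputs permute the basis identically", {
  spec <- membership_spec()
  x <- c(-45, 10, 37)
  z1 <- fuzzy_basis(x, spec)
  z2 <- fuzzy_basis(x[c(2, 3, 1)], spec)
  # rule (i1, i2, i3) of the permuted input equals rule (i3, i1, i2)
  idx <- function(i1, i2, i3) (i1 - 1) * 25 + (i2 - 1) * 5 + i3
  for (i1 in 1:5) for (i2 in 1:5) for (i3 in 1:5)
    expect_equal(z2[idx(i2, i3, i1)], z1[idx(i1, i2, i3)], tolerance = 1e-12)
})

test_that("the FLS output is linear in the weights and simplex-bounded", {
  spec <- membership_spec(delta = 20)
  z <- fuzzy_basis(c(-50, -10, 30), spec)
  expect_equal(fls_eval(z, rep(3.7, 125)), 3.7, tolerance = 1e-12)
  withr::with_seed(5, {
    p1 <- runif(125); p2 <- runif(125)
    expect_equal(fls_eval(z, 2 * p1 - 3 * p2),
                 2 * fls_eval(z, p1) - 3 * fls_eval(z, p2),
                 tolerance = 1e-12)
    expect_lte(fls_eval(z, p1), max(p1))
    expect_gte(fls_eval(z, p1), min(p1))
  })
  expect_error(fls_eval(z, numeric(10)), "length")
})

test_that("weight adaptation vanishes at zero error or zero sliding variable", {
  withr::with_seed(8, {
    bank <- estimator_bank()
    b1 <- adapt_weights(bank, e = c(0, 0, 0), s = c(1, -2, 3),
                        u_c = c(1, 1, 1), x = c(-50, -40, -30),
                        sigma = 0.03, eta = 1.5,
                        kappa_f = 10, kappa_ftau = 10, kappa_g = 0.1,
                        dt = 1e-3)
    expect_identical(b1$psi, bank$psi)
    b2 <- adapt_weights(bank, e = c(1, 2, 3), s = c(0, 0, 0),
                        u_c = c(1, 1, 1), x = c(-50, -40, -30),
                        sigma = 0.03, eta = 1.5,
                        kappa_f = 10, kappa_ftau = 10, kappa_g = 0.1,
                        dt = 1e-3)
    expect_identical(b2$psi, bank$psi)
  })
})

test_that("adaptation increments scale linearly with the gains and oppose zeta * s", {
  withr::with_seed(9, {
    bank <- estimator_bank()
    args <- list(e = c(2, -1, 0.5), s = c(0.4, -0.2, 0.1),
                 u_c = c(5, -3, 1), x = c(-55, -35, -25),
                 sigma = 0.03, eta = 1.5, dt = 1e-3)
    b1 <- do.call(adapt_weights, c(list(bank), args,
                                   kappa_f = 1, kappa_ftau = 1, kappa_g = 1))
    b2 <- do.call(adapt_weights, c(list(bank), args,
                                   kappa_f = 2, kappa_ftau = 2, kappa_g = 2))
    d1 <- b1$psi - bank$psi
    d2 <- b2$psi - bank$psi
    expect_equal(d2, 2 * d1, tolerance = 1e-12)
    # sign: the f-row increment opposes zeta * s_i
    z <- fuzzy_basis(args$x, bank$spec)
    expect_true(all(sign(d1[1, z > 1e-6]) == -sign(args$s[1])))
  })
})

test_that("the bank evaluates all fifteen estimators with shared structure", {
  withr::with_seed(12, {
    bank <- estimator_bank()
    ev <- bank_eval(bank, x = c(-50, -40, -30), x_tau = c(-60, -45, -30))
    expect_length(ev$f_hat, 3)
    expect_length(ev$f_tau_hat, 3)
    expect_equal(dim(ev$G_hat), c(3, 3))
    # row 7 of psi is entry (1,1) of G
    z <- fuzzy_basis(c(-50, -40, -30), bank$spec)
    expect_equal(ev$G_hat[1, 1], sum(bank$psi[7, ] * z))
  })
  expect_error(estimator_bank(psi0 = matrix(0, 3, 3)), "15 x 125")
})
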