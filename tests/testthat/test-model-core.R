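# Conductance-based plant: transmitter release, synapse kinetics, currents,
# the canonical dynamics split, the RK4/method-of-steps integrator and the
# preset spiking regimes.

test_that("transmitter release follows the sigmoid with its limits", {
  expect_equal(neurotransmitter_release(2), 2.84 / 2)
  expect_equal(neurotransmitter_release(1e4), 2.84, tolerance = 1e-12)
  # deep hyperpolarization: 2.84 / (1 + e^12.4)
  expect_equal(neurotransmitter_release(-60), 2.84 / (1 + exp(12.4)),
               tolerance = 1e-12)
  expect_lt(neurotransmitter_release(-60), 1.2e-5)
  # strictly increasing
  v <- seq(-90, 60, by = 1)
  expect_true(all(diff(neurotransmitter_release(v)) > 0))
  expect_error(neurotransmitter_release(NaN), "finite")
})

test_that("first-order gate kinetics decay, saturate and hit the fixed point", {
  expect_equal(synapse_kinetics(0.3, 0, 0.94, 0.18), -0.18 * 0.3)
  # derivative preserves [0, 1]
  expect_gte(synapse_kinetics(0, 2.84, 0.94, 0.18), 0)
  expect_lte(synapse_kinetics(1, 2.84, 0.94, 0.18), 0)
  # algebraic fixed point alpha T / (alpha T + beta)
  s_star <- 0.94 * 2.84 / (0.94 * 2.84 + 0.18)
  expect_equal(s_star, 0.9368, tolerance = 1e-4)
  expect_equal(synapse_kinetics(s_star, 2.84, 0.94, 0.18), 0,
               tolerance = 1e-12)
  expect_error(synapse_kinetics(0.5, 1, -1, 0.18), "positive")
})

test_that("GABA_B cascade has the stated fixed-point ratio", {
  # at T = 0 the equilibrium G-protein level is (0.18/0.034) r
  r <- 0.4
  k <- gabab_kinetics(0.18 / 0.034 * r, r, 0)
  expect_equal(k$ds, 0, tolerance = 1e-12)
  expect_equal(k$dr, -0.0012 * r)
})

test_that("synaptic currents vanish for closed gates and at reversal", {
  p <- plant_params("cae")
  x <- plant_state(-65, -65, -65, p)
  x[21:27] <- 0
  expect_equal(unname(synaptic_currents(x, p)), c(0, 0, 0))
  # half-activation of the cooperative GABA_B conductance: s^4 = Kd
  x2 <- plant_state(-65, -65, -65, p)
  x2[21:27] <- 0
  x2[["s_gabab"]] <- 100^(1 / 4)
  i_syn <- synaptic_currents(x2, p)
  expect_equal(unname(i_syn[["TC"]]),
               p$syn$gabab_rt_tc[["g"]] / 2 * (-65 - (-95)))
  # AMPA at its reversal potential carries no current
  x3 <- plant_state(0, -65, -65, p)  # V_TC = E_AMPA = 0
  x3[21:27] <- 0
  x3[["s_ampa_ct_tc"]] <- 0.7
  expect_equal(unname(synaptic_currents(x3, p)[["TC"]]), 0)
})

test_that("ionic currents are zero at reversal or with zero conductance", {
  p <- plant_params("cae")
  x <- plant_state(-90, -65, -65, p)  # V_TC at E_K
  ic <- ionic_currents(x, p, "TC")
  expect_equal(ic$current[ic$channel == "K"], 0)
  p0 <- p
  for (ch in names(p0$ionic$RT)) p0$ionic$RT[[ch]]["g"] <- 0
  ic0 <- ionic_currents(x, p0, "RT")
  expect_equal(sum(ic0$current), 0)
})

test_that("gating initialised at steady state has near-zero kinetics", {
  p <- plant_params("normal")
  x <- plant_state(-68, -64, -71, p)
  d <- attr(membrane_derivative(x, p), "dstate")
  # all gating variables (not voltages, and not the delayed-transmitter gates
  # which see the instantaneous approximation) are at their fixed points
  expect_lt(max(abs(d[4:20])), 1e-12)
})

test_that("control and disturbance enter additively through the capacitance", {
  p <- plant_params("cae")
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- random_valid_state()
      b <- membrane_derivative(x, p)
      bu <- membrane_derivative(x, p, u = c(2, -1, 0.5))
      expect_equal(as.numeric(bu) - as.numeric(b),
                   c(2, -1, 0.5) / unname(p$C), tolerance = 1e-10)
    }
  })
})

test_that("canonical split recombines to the membrane derivative exactly", {
  p <- plant_params("cae")
  withr::with_seed(7, {
    for (i in 1:1000) {
      x <- random_valid_state()
      vct <- runif(1, -90, 40)
      vtc <- runif(1, -90, 40)
      u <- runif(3, -5, 5)
      d <- runif(3, -2, 2)
      sp <- true_dynamics_split(x, p, vct, vtc)
      dv <- membrane_derivative(x, p, vct, vtc, u = u, d = d)
      recomb <- sp$f + sp$f_tau + as.numeric(sp$G %*% u) + d
      expect_equal(as.numeric(dv), unname(recomb), tolerance = 1e-14)
    }
  })
  # G is the constant diagonal capacitance inverse, bounded below by chi0
  sp <- true_dynamics_split(plant_state(-65, -65, -65, p), p)
  expect_equal(sp$G, diag(1 / unname(p$C)))
  expect_equal(sp$chi0, 1 / max(p$C))
})

test_that("zero delays make delayed and instantaneous drives identical", {
  p <- plant_params("cae", tau1 = 0, tau2 = 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- random_valid_state()
      sp <- true_dynamics_split(x, p, x[["V_CT"]], x[["V_TC"]])
      # the delayed-pathway term evaluated at the current state matches the
      # same expression computed directly from the instantaneous voltages
      i_ct_tc <- p$syn$ampa_ct_tc[["g"]] * x[["s_ampa_ct_tc"]] *
        (x[["V_TC"]] - p$syn$ampa_ct_tc[["E"]])
      i_tc_ct <- p$syn$ampa_tc_ct[["g"]] * x[["s_ampa_tc_ct"]] *
        (x[["V_CT"]] - p$syn$ampa_tc_ct[["E"]])
      expect_equal(unname(sp$f_tau), c(-i_ct_tc, -i_tc_ct, 0) / unname(p$C))
    }
  })
})

test_that("one RK4 step is deterministic and fixed points stay fixed", {
  p <- plant_params("cae")
  x <- plant_state(-65, -65, -65, p)
  a <- step_plant(x, p, 0.01, v_ct_delayed = -65, v_tc_delayed = -65)
  b <- step_plant(x, p, 0.01, v_ct_delayed = -65, v_tc_delayed = -65)
  expect_identical(a, b)
  expect_error(step_plant(x, p, -1), "positive")
})

test_that("the integrator shows fourth-order convergence", {
  p <- plant_params("cae")
  # settle onto the attractor first so derivative discontinuities from the
  # constant pre-history have decayed
  tr <- simulate_plant(p, duration = 500, dt = 0.005,
                       record_every = round(500 / 0.005))
  xs <- as.numeric(tr[nrow(tr), state_names()])
  seg <- function(dt) {
    r <- simulate_plant(p, duration = 10, dt = dt, init = xs,
                        record_every = round(10 / dt))
    as.numeric(r[nrow(r), c("V_TC", "V_CT", "V_RT")])
  }
  e1 <- seg(0.02); e2 <- seg(0.01); e3 <- seg(0.005)
  order <- log2(sqrt(sum((e1 - e2)^2)) / sqrt(sum((e2 - e3)^2)))
  expect_gt(order, 3.5)
  expect_lt(order, 4.5)
})

test_that("uncoupled neurons with no external drive settle to rest", {
  p <- plant_params("normal", I_ext_TC = 0)
  for (sn in names(p$syn)) p$syn[[sn]]["g"] <- 0
  tr <- simulate_plant(p, duration = 8000, dt = 0.01,
                       record_every = round(8000 / 0.01))
  xe <- as.numeric(tr[nrow(tr), state_names()])
  dv <- membrane_derivative(stats::setNames(xe, state_names()), p,
                            xe[2], xe[1])
  expect_lt(max(abs(dv)), 1e-6)
})

test_that("simulated gates and gating variables respect their ranges", {
  p <- plant_params("cae")
  tr <- simulate_plant(p, duration = 1000, dt = 0.01, init = c(-40, -55, -30))
  gating <- as.matrix(tr[, state_names()[4:20]])
  expect_true(all(gating >= 0 & gating <= 1))
  first_order <- as.matrix(tr[, c("s_ampa_ct_tc", "s_gabaa_rt_tc", "r_gabab",
                                  "s_ampa_tc_ct", "s_gabaa_rt_rt",
                                  "s_ampa_tc_rt")])
  expect_true(all(first_order >= 0 & first_order <= 1))
  expect_true(all(tr$s_gabab >= 0))
})

test_that("the CAE preset spikes faster than the normal preset", {
  rates <- sapply(c("normal", "cae"), function(pr) {
    p <- plant_params(pr)
    tr <- simulate_plant(p, duration = 2500, dt = 0.01, init = c(-65, -65, -65))
    w <- tr$t_ms > 500
    spike_statistics(tr$V_TC[w], tr$t_ms[w])$rate_hz
  })
  expect_gt(rates[["cae"]], 1.2 * rates[["normal"]])
  expect_gt(rates[["normal"]], 1)
})

test_that("trajectory length scales with duration and delays must sit on the grid", {
  p <- plant_params("cae")
  t1 <- simulate_plant(p, duration = 50, dt = 0.01, record_every = 10)
  t2 <- simulate_plant(p, duration = 100, dt = 0.01, record_every = 10)
  expect_equal(nrow(t2) - 1, 2 * (nrow(t1) - 1))
  expect_error(simulate_plant(plant_params("cae", tau1 = 10.005),
                              duration = 10, dt = 0.01),
               "multiple")
})
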