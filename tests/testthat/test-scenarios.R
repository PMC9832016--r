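# Disturbance trains, parameter drift, random initial conditions, metrics
# and the trial/batch harness.

test_that("gamma pulse trains have the configured geometry and rate", {
  tr <- gamma_pulse_train(14, 1.75, 1, 100000, seed = 4)
  # empirical onset rate over 100 s within the 95% CI of a gamma renewal
  # process with mean interval 1/14 s and shape 2 (interval sd = mean/sqrt(2))
  n <- length(tr$onsets_ms)
  expect_gt(n, 1200)
  se <- 14 / sqrt(2) / sqrt(100000 / 1000 * 14)
  expect_lt(abs(n / 100 - 14), 1.96 * se * 1.5)
  # sampled signal takes exactly the amplitude inside a pulse
  t_in <- tr$onsets_ms[10] + 0.5
  expect_equal(pulse_signal(tr, t_in), 1.75)
  expect_equal(pulse_signal(tr, tr$onsets_ms[10] + 1.001), 0)
  # pulses are 1 ms wide on the sampled grid
  grid <- seq(tr$onsets_ms[10] - 0.5, tr$onsets_ms[10] + 1.5, by = 0.01)
  on <- pulse_signal(tr, grid) > 0
  expect_equal(sum(on) * 0.01, 1, tolerance = 0.05)
})

test_that("degenerate pulse trains are handled", {
  expect_length(gamma_pulse_train(0, 1, 1, 1000)$onsets_ms, 0)
  expect_error(gamma_pulse_train(14, 1, 100, 1000), "active")
  expect_identical(gamma_pulse_train(14, 1, 1, 2000, seed = 3)$onsets_ms,
                   gamma_pulse_train(14, 1, 1, 2000, seed = 3)$onsets_ms)
})

test_that("parameter drift respects its amplitude bound at every time", {
  d <- parameter_drift(0.25, 200000, seed = 6)
  expect_true(all(d$multipliers >= 0.75 & d$multipliers <= 1.25))
  expect_equal(dim(d$multipliers)[2], 28)
  d0 <- parameter_drift(0, 1000)
  expect_true(all(d0$multipliers == 1))
  expect_error(parameter_drift(0.6, 1000), "0, 0.5")
})

test_that("drift power concentrates below twice the filter frequency", {
  d <- parameter_drift(0.5, 200000, seed = 7, dt_ms = 10)
  x <- d$multipliers[, 1] - mean(d$multipliers[, 1])
  sp <- stats::spec.pgram(stats::ts(x, deltat = 0.010), plot = FALSE,
                          taper = 0)
  below <- sum(sp$spec[sp$freq <= 0.1]) / sum(sp$spec)
  expect_gt(below, 0.95)
})

test_that("random initial conditions respect the stated ranges and replay", {
  ic <- random_initial_conditions(seed = 123)
  expect_true(all(ic$v_actual >= -60 & ic$v_actual <= -20))
  expect_true(all(ic$v_desired >= -60 & ic$v_desired <= -20))
  expect_true(all(ic$psi0 >= 0 & ic$psi0 <= 1))
  expect_equal(dim(ic$psi0), c(15, 125))
  expect_identical(ic, random_initial_conditions(seed = 123))
})

test_that("rmse matches hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 3), c(1, 2)), 1)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("chattering index separates constant from switching signals", {
  expect_equal(chattering_index(rep(2, 100), 0.01), 0)
  # alternating +-A every step attains the maximal 1/dt reference
  u <- rep(c(1, -1), 50)
  expect_equal(chattering_index(u, 0.01), (2 * 99 / 99) / (0.01 * 2))
  expect_error(chattering_index(1, 0.01), "two samples")
})

test_that("a trial is exactly reproducible from its configuration", {
  cfg <- short_cfg(duration = 50, seed = 42,
                   disturbance = disturbance_spec(amplitude = 1.75),
                   uncertainty = uncertainty_spec(0.25))
  t1 <- run_trial(cfg)
  t2 <- run_trial(cfg)
  expect_identical(t1$trajectory, t2$trajectory)
  expect_identical(t1$metrics, t2$metrics)
})

test_that("an uncontrolled plant identical to the desired one has zero RMSE", {
  cfg <- trial_config(duration = 50, dt = 0.01, seed = 2, controller = "none",
                      plant = plant_params("normal"),
                      desired = plant_params("normal"))
  # same preset and same initial voltages: force identical draws
  cfg$init_range <- c(-44, -44)
  tr <- run_trial(cfg)
  expect_equal(unname(tr$metrics$rmse), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the uncontrolled CAE plant keeps its tonic spiking pattern", {
  cfg <- trial_config(duration = 1500, dt = 0.01, seed = 5,
                      controller = "none")
  tr <- run_trial(cfg)
  st <- spike_statistics(tr$trajectory$V_TC, tr$trajectory$t_ms)
  expect_gt(st$rate_hz, 20)
  expect_gt(min(tr$metrics$rmse), 1)  # uncontrolled tracking error is large
})

test_that("batches summarise trials with population statistics", {
  cfg <- trial_config(duration = 50, dt = 0.01, seed = 10,
                      controller = "stsmc")
  b1 <- batch_experiment(cfg, n_trials = 1)
  expect_equal(unique(b1$sd_rmse_mv), 0)
  expect_equal(unique(b1$n), 1L)
  b3 <- batch_experiment(cfg, n_trials = 3)
  # population sd of the per-trial RMSEs
  one <- sapply(10:12, function(sd) {
    cfg$seed <- sd
    run_trial(cfg)$metrics$rmse[["TC"]]
  })
  row <- dplyr::filter(b3, .data$neuron == "TC")
  expect_equal(row$mean_rmse_mv, mean(one))
  expect_equal(row$sd_rmse_mv, sqrt(mean((one - mean(one))^2)))
  # disjoint seed sets give different statistics
  b_other <- batch_experiment(cfg, n_trials = 3, seeds = c(100, 101, 102))
  expect_false(isTRUE(all.equal(row$mean_rmse_mv,
                                dplyr::filter(b_other,
                                              .data$neuron == "TC")$mean_rmse_mv)))
})

test_that("condition grids expand into per-condition summaries", {
  cfg <- trial_config(duration = 30, dt = 0.01, seed = 20,
                      controller = "stsmc")
  grid <- tibble::tibble(controller = c("stsmc", "none"))
  b <- batch_experiment(cfg, n_trials = 2, conditions = grid)
  expect_equal(nrow(b), 2 * 3)
  expect_setequal(unique(b$controller), c("stsmc", "none"))
})
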