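test_that("gating rate functions handle singular points and saturate", {
  # removable singularities replaced by analytic limits
  r40 <- gating_rates(-40)
  expect_equal(r40$alpha_m, 1, tolerance = 1e-6)
  r55 <- gating_rates(-55)
  expect_equal(r55$alpha_n, 0.1, tolerance = 1e-6)
  # continuity around the singular points
  eps <- 1e-5
  expect_equal(gating_rates(-40 + eps)$alpha_m, gating_rates(-40 - eps)$alpha_m,
               tolerance = 1e-4)
  # saturation limits of the steady states
  g_hi <- steady_gates(120)
  expect_gt(g_hi$m, 0.999)
  expect_lt(g_hi$h, 1e-4)
  # steady states monotone in U over the physiological range
  u <- seq(-90, 20, by = 1)
  g <- steady_gates(u)
  expect_true(all(diff(g$m) > 0))
  expect_true(all(diff(g$n) > 0))
  expect_true(all(diff(g$h) < 0))
})

test_that("ionic currents vanish at their reversal potentials", {
  p <- neuron_params()
  expect_equal(unname(ionic_currents(membrane_state(p$E_L), p)["I_L"]), 0)
  expect_equal(unname(ionic_currents(membrane_state(p$E_K), p)["I_K"]), 0)
  # leak current at -65 mV with the fitted passive parameters
  i <- ionic_currents(membrane_state(-65), neuron_params())
  expect_equal(unname(i["I_L"]), 5.84 * (-65 - (-52.26)), tolerance = 1e-12)
  expect_equal(unname(i["I_L"]), -74.4016, tolerance = 1e-6)
})

test_that("the quiet cell sits at a fixed point and returns to it", {
  p <- neuron_params()
  rest <- resting_state(p)
  # fixed point: summed ionic currents vanish, gates at steady state
  expect_lt(abs(sum(ionic_currents(rest, p))), 1e-6)
  # long quiet integration stays flat at the same potential
  sim <- simulate_mn(config = sim_config(duration = 200),
                     synapse = synapse_params(g_INs = 0))
  expect_lt(max(abs(sim$U - rest$U)), 1e-6)
  # subthreshold perturbation decays back to rest
  sim2 <- simulate_mn(config = sim_config(duration = 100),
                      synapse = synapse_params(g_INs = 0),
                      I_inj = function(t) ifelse(t >= 5 & t < 5.5, 30, 0))
  expect_gt(max(sim2$U), rest$U + 1) # perturbation was real
  expect_lt(abs(sim2$U[length(sim2$U)] - rest$U), 1e-3)
})

test_that("a single Heun step is second-order accurate on the leak membrane", {
  # pure leak cell: exact solution is exponential relaxation to E_L
  p <- neuron_params(gbar_Na = 0, gbar_K = 0, g_L = 5, E_L = -52)
  u0 <- -70
  exact <- function(dt) p$E_L + (u0 - p$E_L) * exp(-p$g_L * dt / p$C_MN)
  err <- function(dt) {
    st <- step_heun(membrane_state(u0), function(t, u) 0, 0, dt, p)
    abs(st$U - exact(dt))
  }
  e1 <- err(0.02)
  e2 <- err(0.01)
  # halving dt cuts the one-step error ~8x (third-order local error)
  expect_gt(e1 / e2, 6)
  expect_lt(e1 / e2, 10)
  # and Heun beats the explicit Euler step by far
  euler <- u0 + 0.02 * (-p$g_L * (u0 - p$E_L)) / p$C_MN
  expect_lt(e1, abs(euler - exact(0.02)) / 10)
})

test_that("compiled core reproduces the pure-R Heun reference", {
  vol <- volley_spec(n_haltere = 8, n_wing = 8, sigma = 0.5)
  syn <- synapse_params()
  u_ref <- r_reference_sim(volley = vol, visual_u = -35, duration = 5)
  sim <- simulate_mn(synapse = syn, volley = vol,
                     visual = visual_signal("constant", U_base = -35),
                     config = sim_config(duration = 5))
  expect_equal(sim$U, u_ref, tolerance = 1e-10)
})

test_that("noisy runs are reproducible from the seed and gates stay bounded", {
  vol <- volley_spec(n_haltere = 60, n_wing = 60, sigma = 1.0)
  cfg <- sim_config(duration = 100, sigma_noise = 0.25, rng_seed = 42)
  s1 <- simulate_mn(volley = vol, visual = visual_signal("constant", U_base = -35),
                    config = cfg, record_gates = TRUE)
  s2 <- simulate_mn(volley = vol, visual = visual_signal("constant", U_base = -35),
                    config = cfg, record_gates = TRUE)
  expect_identical(s1$U, s2$U)
  for (g in c("m", "h", "n")) {
    expect_true(all(s1[[g]] >= 0 & s1[[g]] <= 1))
  }
  # a different seed gives a different trace
  cfg2 <- sim_config(duration = 100, sigma_noise = 0.25, rng_seed = 43)
  s3 <- simulate_mn(volley = vol, visual = visual_signal("constant", U_base = -35),
                    config = cfg2)
  expect_gt(max(abs(s3$U - s1$U)), 0)
})

test_that("spike counts and times are stable under time-step refinement", {
  vol <- volley_spec(n_haltere = 77, n_wing = 77, sigma = 1.0)
  vis <- visual_signal("constant", U_base = -35)
  sims <- lapply(c(0.02, 0.01, 0.005), function(dt) {
    detect_spikes(simulate_mn(volley = vol, visual = vis,
                              config = sim_config(dt = dt, duration = 500)))
  })
  counts <- vapply(sims, nrow, integer(1))
  expect_true(all(counts == counts[1]))
  # halving dt from 0.01 to 0.005 moves spike times by < 1% of a cycle
  shift <- max(abs(sims[[2]]$time - sims[[3]]$time))
  expect_lt(shift, 0.1)
})

test_that("invalid configurations and states are rejected", {
  expect_error(neuron_params(E_L = -90), "E_Na > E_L > E_K")
  expect_error(sim_config(dt = 0.1), "validated range")
  expect_error(step_heun(membrane_state(-65), function(t, u) 0, 0, 0.1,
                         neuron_params()), "validated range")
  st <- membrane_state(-65)
  st$U <- NaN
  expect_error(step_heun(st, function(t, u) 0, 0, 0.01, neuron_params()),
               "non-finite")
})
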