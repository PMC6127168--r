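test_that("sensilla sweep spans quiescence to 1:1 locking", {
  sw <- sensilla_sweep(pairs = c(5, 80), cycles_discard = 30,
                       cycles_analyze = 60)
  expect_equal(sw$mode[1], "quiescence")
  expect_equal(sw$mode[2], "locked")
  expect_equal(c(sw$p[2], sw$q[2]), c(1L, 1L))
  expect_equal(sw$F_MN[2], 100)
})

test_that("a zero-height visual step leaves phase and amplitude unchanged", {
  r <- visual_step_response(U_base = -40, U_level = -40,
                            settle_cycles = 40, post_cycles = 20)
  expect_equal(r$dphase, 0, tolerance = 0.15)
  expect_equal(r$damplitude, 0, tolerance = 0.1)
  expect_equal(r$locking_pre$mode, "locked")
})

test_that("visual step keeps 1:1 locking and reaches a steady state", {
  r <- visual_step_response(settle_cycles = 60, post_cycles = 30)
  expect_equal(c(r$locking_pre$p, r$locking_pre$q), c(1L, 1L))
  expect_equal(c(r$locking_post$p, r$locking_post$q), c(1L, 1L))
  expect_false(is.na(r$cycles_to_steady))
})

test_that("frequency response reports the steady state as 100% by definition", {
  fr <- frequency_response(freqs = 0, steady_mod = 3.21)
  expect_equal(fr$attenuation, 100)
  expect_equal(fr$modulation, 3.21)
})

test_that("membrane noise degrades but does not destroy 1:1 phase locking", {
  quiet <- noise_phase_stability(sigma_noise = 0, seeds = 1,
                                 cycles_discard = 20, cycles_analyze = 60)
  expect_lt(quiet$pooled_sd, 0.1)
  noisy <- noise_phase_stability(sigma_noise = 0.25, seeds = 1:2,
                                 cycles_discard = 20, cycles_analyze = 60)
  expect_gt(noisy$pooled_sd, quiet$pooled_sd)
  # still one spike per cycle on average
  expect_equal(mean(noisy$per_seed$n_spikes), 60, tolerance = 0.1)
})

test_that("subthreshold input plus noise produces intermittent stochastic firing", {
  # a volley just below this parameterisation's firing threshold
  vol <- volley_spec(n_haltere = 30, n_wing = 30, sigma = 1.0)
  quiet <- run_locking(volley = vol, visual = visual_signal("constant", U_base = -35),
                       cycles_discard = 20, cycles_analyze = 60)
  expect_equal(quiet$report$mode, "quiescence")
  noisy <- run_locking(volley = vol, visual = visual_signal("constant", U_base = -35),
                       sigma_noise = 0.25, rng_seed = 5,
                       cycles_discard = 20, cycles_analyze = 60)
  n <- noisy$report$n_spikes
  expect_gt(n, 0)
  expect_lt(n, 60) # intermittent, not every cycle
  isi <- diff(noisy$spikes$time)
  expect_gt(sd(isi), 1) # random interspike intervals
})

test_that("paired pulses separate beyond the relative refractory period recover fully", {
  amp <- 600
  pulses <- function(tp) {
    function(t) {
      out <- numeric(length(t))
      for (p0 in tp) out[t >= p0 & t < p0 + 0.2] <- amp
      out
    }
  }
  syn0 <- synapse_params(g_INs = 0)
  far <- detect_spikes(simulate_mn(synapse = syn0,
                                   config = sim_config(duration = 60),
                                   I_inj = pulses(c(5, 25))))
  expect_equal(nrow(far), 2)
  expect_equal(far$amplitude[2] / far$amplitude[1], 1, tolerance = 0.02)
  near <- detect_spikes(simulate_mn(synapse = syn0,
                                    config = sim_config(duration = 40),
                                    I_inj = pulses(c(5, 6))))
  expect_equal(nrow(near), 1) # 1 ms interval lies inside absolute refractoriness
})

test_that("bisection and linear scan agree on the refractory interval", {
  rb <- refractory_periods(dt = 0.02)
  rs <- refractory_periods(dt = 0.02, method = "scan")
  expect_lt(abs(rb$absolute - rs$absolute), 0.05)
  expect_gt(rb$relative, rb$absolute)
})

test_that("gating scenarios switch the cell between silence and firing", {
  # raised-sodium variant: quiescent until the visual input depolarises
  g3 <- gating_scenario("gating_high_na", cycles_discard = 30,
                        cycles_analyze = 60)
  expect_equal(g3$baseline$mode, "quiescence")
  expect_gt(g3$depolarized$F_MN, 50)
  expect_false(g3$depolarized$mode == "quiescence")

  # physiological variant: depolarisation switches the locking mode to 1:1
  g1 <- gating_scenario("mode_switch", cycles_discard = 30,
                        cycles_analyze = 60)
  expect_equal(c(g1$depolarized$p, g1$depolarized$q), c(1L, 1L))
  expect_false(identical(c(g1$baseline$p, g1$baseline$q), c(1L, 1L)))
})

test_that("presets encode the reference parameter bundles", {
  expect_error(preset("nope"), "valid presets")
  p <- preset("locking_50pct")
  expect_equal(c(p$volley$n_haltere, p$volley$n_wing), c(55L, 55L))
  expect_equal(p$volley$sigma, 1.0)
  expect_equal(p$volley$tau, 0.625)
  expect_equal(p$visual$U_base, -35)
  p5 <- preset("gating_high_na")
  expect_null(p5$volley)
  expect_equal(p5$neuron$gbar_Na, 240)
  expect_equal(p5$neuron$g_L, 5.86)
  p4 <- preset("phase_step")
  expect_equal(p4$volley$sigma, 0.2)
  expect_equal(p4$volley$n_haltere + p4$volley$n_wing, 92) # 42% of 220
})
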