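test_that("exponential pulse peaks at its nominal amplitude", {
  t <- seq(0, 40, by = 0.01)
  p <- exp_pulse(t, A = 0.3, t0 = 2, rise = 1.2, decay = 6)
  expect_equal(max(p), 0.3, tolerance = 1e-6)
  expect_true(all(p[t <= 2] == 0))
  # peak position: t0 + rise * log(1 + decay/rise)
  expect_equal(t[which.max(p)], 2 + 1.2 * log(1 + 6 / 1.2), tolerance = 0.02)
})

test_that("a pure exponential pulse decomposes into chemical only", {
  t <- seq(0, 30, by = 0.01)
  tr <- data.frame(time = t, v = exp_pulse(t, 0.4, 2.5, 1.2, 6))
  sc <- split_components(tr)
  expect_lt(max(abs(sc$electrical$v)), 0.004) # < 1% of the pulse height
  expect_equal(max(sc$chemical$v), 0.4, tolerance = 0.01)
})

test_that("surrogate EPSP decomposition recovers the chemical component", {
  tr <- epsp_surrogate()
  # fast electrical peak dominates the summed trace
  expect_equal(max(tr$v), max(attr(tr, "electrical")), tolerance = 0.1)
  true_chem <- attr(tr, "chemical")
  sc <- split_components(tr)
  # chemical peak recovered within 5%
  expect_equal(max(sc$chemical$v), max(true_chem), tolerance = 0.05)
  # decomposition residual unbiased around zero
  resid <- tr$v - sc$chemical$v - sc$electrical$v
  expect_equal(max(abs(resid)), 0, tolerance = 1e-12) # exact by construction
  late <- tr$time > 8
  bias <- mean(sc$chemical$v[late] - true_chem[late])
  expect_lt(abs(bias), 0.02)
})

test_that("passive-parameter fit recovers the generator round trip", {
  tr <- epsp_model(g_H = 0.16, g_L = 5.84, E_L = -52.26)
  fit <- fit_passive(tr, n_starts = 8, rng_seed = 2)
  expect_equal(fit$g_H, 0.16, tolerance = 0.01)
  expect_equal(fit$g_L, 5.84, tolerance = 0.01)
  expect_equal(fit$E_L, -52.26, tolerance = 0.01)
  # minimiser contract: returned loss no worse than every start's outcome
  expect_true(all(fit$loss <= fit$losses + 1e-15))

  # recovery under 5% additive noise stays within 10%
  set.seed(9)
  trn <- tr
  trn$v <- trn$v + rnorm(nrow(tr), 0, 0.05 * max(tr$v))
  fitn <- fit_passive(trn, n_starts = 8, rng_seed = 3)
  expect_equal(fitn$g_H, 0.16, tolerance = 0.1)
  expect_equal(fitn$g_L, 5.84, tolerance = 0.1)
  expect_equal(fitn$E_L, -52.26, tolerance = 0.015)
})

test_that("suprathreshold traces are rejected by the passive fit", {
  vol <- volley_spec(n_haltere = 50, n_wing = 0, sigma = 0.2)
  sim <- simulate_mn(volley = vol, config = sim_config(duration = 10),
                     synapse = synapse_params(g_INs = 0))
  tr <- data.frame(time = sim$time, v = sim$U - sim$rest)
  expect_error(fit_passive(tr), "suprathreshold")
})

test_that("sodium-conductance calibration brackets the spike-height jump", {
  g <- calibrate_gna(target = 37.5, interval = c(100, 300))
  lo <- spike_amplitude(g - 2)
  hi <- spike_amplitude(g + 2)
  expect_lt(lo, 37.5)
  expect_gt(hi, 37.5)
  # spike amplitude is nondecreasing in gbar_Na
  amps <- spike_amplitude(c(25, 80, 120, 165, 200, 240))
  expect_true(all(diff(amps) > -1e-6))
})

test_that("chemical fatigue fit reproduces the decay constants", {
  y <- fatigue_series(130, a = 0.706, b = -0.018)
  ft <- fatigue_fit(y)
  expect_equal(ft$a, 0.706, tolerance = 1e-6)
  expect_equal(ft$b, -0.018, tolerance = 1e-6)
  expect_equal(ft$R2, 1, tolerance = 1e-9)
  # transmission falls below 10% within ~130 strokes, ~1.3 s of flight
  expect_equal(ft$strokes_to_10pct, log(10) / 0.018, tolerance = 1e-6)
  expect_equal(ft$strokes_to_10pct, 128, tolerance = 0.01)
  expect_equal(ft$flight_time_s, 1.28, tolerance = 0.01)
  # noisy series still identifies the decay rate
  yn <- fatigue_series(130, noise_sd = 0.02, rng_seed = 4)
  ftn <- fatigue_fit(yn)
  expect_equal(ftn$b, -0.018, tolerance = 0.15)
  expect_lt(ftn$R2, 1)
})
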