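test_that("waveform template is a positive pulse between rest levels", {
  w <- waveform_template()
  t <- seq(-1, 3, by = 0.001)
  v <- sensilla_waveform(t, w)
  expect_equal(sensilla_waveform(-0.5, w), -65)
  expect_equal(sensilla_waveform(w$support + 0.01, w), -65)
  expect_equal(max(v), -15, tolerance = 1e-9) # rest + 50 mV amplitude
  expect_equal(sensilla_waveform(w$rise, w), -15, tolerance = 1e-9)
  area <- sum(v - w$rest) * 0.001
  expect_gt(area, 0)
  expect_true(is.finite(area))
})

test_that("volley times follow the Gaussian-quantile layout", {
  # a single sensillum sits exactly at the mean volley phase
  v1 <- volley_spec(n_haltere = 1, n_wing = 1, sigma = 0.7)
  tt <- volley_times(v1)
  expect_equal(tt$time[tt$nerve == "haltere"], 2.5)
  # wing volley delayed by tau: 25% + 0.625/10 = 31.25% of the cycle
  expect_equal(tt$time[tt$nerve == "wing"] / 10 * 100, 31.25)

  # quantile placement: symmetric about the mean, SD -> sigma for large N
  vN <- volley_spec(n_haltere = 110, n_wing = 0, sigma = 1.3)
  th <- volley_times(vN)$time
  expect_equal(mean(th), 2.5, tolerance = 1e-9)
  # oracle: sd of Gaussian quantiles at (i-0.5)/N approaches sigma
  qs <- 1.3 * qnorm((1:5000 - 0.5) / 5000)
  expect_equal(sd(qs), 1.3, tolerance = 0.01)
  expect_equal(sd(th), sd(1.3 * qnorm((1:110 - 0.5) / 110)), tolerance = 1e-9)

  # per-sensillum times recur at fixed phases in every cycle
  t0 <- volley_times(vN, 0)$time
  t5 <- volley_times(vN, 5)$time
  expect_equal(t5 - t0, rep(50, length(t0)))

  # seeded random placement reproduces identical volleys
  vr <- volley_spec(n_haltere = 20, n_wing = 20, sigma = 1, placement = "random",
                    rng_seed = 11)
  expect_identical(volley_times(vr), volley_times(vr))

  expect_error(volley_spec(n_haltere = 111, n_wing = 0), "0..110")
})

test_that("drive profiles are flat at rest without active sensilla", {
  v0 <- volley_spec(n_haltere = 0, n_wing = 0, sigma = 1)
  prof <- drive_profiles(v0)
  expect_equal(ncol(prof$haltere), 0)
  sim <- simulate_mn(volley = v0, config = sim_config(duration = 30),
                     synapse = synapse_params(g_INs = 0))
  expect_lt(max(abs(diff(sim$U))), 1e-9)
})

test_that("the periodic drive produces strictly periodic responses", {
  vol <- volley_spec(n_haltere = 8, n_wing = 8, sigma = 0.8)
  sim <- simulate_mn(volley = vol, config = sim_config(duration = 80),
                     synapse = synapse_params(g_INs = 0))
  # after the first cycles the subthreshold response repeats each period
  S <- 1000
  a <- sim$U[(3 * S + 1):(4 * S)]
  b <- sim$U[(6 * S + 1):(7 * S)]
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("a narrow 50-sensilla haltere volley evokes one spike per stimulus", {
  vol <- volley_spec(n_haltere = 50, n_wing = 0, sigma = 0.2)
  sim <- simulate_mn(volley = vol, config = sim_config(duration = 30),
                     synapse = synapse_params(g_INs = 0))
  sp <- detect_spikes(sim)
  expect_equal(nrow(sp), 3) # one per cycle
  expect_true(all(diff(sp$time) > 9 & diff(sp$time) < 11))
})

test_that("visual signal traces match their definitions", {
  flat <- visual_trace(visual_signal("constant", U_base = -40), 20, 0.01)
  expect_true(all(flat == -40))
  st <- visual_trace(visual_signal("step", t_step = 10), 20, 0.01)
  expect_equal(sort(unique(st)), c(-40, -30)) # exact 10 mV jump
  expect_equal(st[999], -40)
  expect_equal(st[1002], -30)
  sn <- visual_trace(visual_signal("sine", frequency = 4), 1000, 0.01)
  expect_equal(range(sn), c(-40, -30), tolerance = 1e-9)
  expect_equal(sn[1], -40) # starts continuously from the baseline
})

test_that("percent-active convention splits 220 sensilla across both nerves", {
  expect_equal(active_counts(50), c(haltere = 55L, wing = 55L))
  expect_equal(active_counts(60), c(haltere = 66L, wing = 66L))
  expect_equal(active_counts(70), c(haltere = 77L, wing = 77L))
  expect_equal(active_counts(42), c(haltere = 46L, wing = 46L))
  # odd rounded totals put the extra sensillum on the haltere nerve
  expect_equal(active_counts(15), c(haltere = 17L, wing = 16L))
})
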