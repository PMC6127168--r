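test_that("spike detector finds peaks, applies lockout, ignores flat traces", {
  t <- seq(0, 20, by = 0.01)
  rest <- -55
  expect_equal(nrow(detect_spikes(rep(rest, length(t)), time = t, period = 10,
                                  rest = rest)), 0)
  # one clean spike: timestamp at the peak, amplitude above rest
  u <- rest + 60 * exp(-((t - 7) / 0.4)^2)
  sp <- detect_spikes(u, time = t, period = 10, rest = rest)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$time, 7, tolerance = 0.011)
  expect_equal(sp$amplitude, 60, tolerance = 0.01)
  expect_equal(sp$phase, 70, tolerance = 0.2)
  # two crossings 0.5 ms apart collapse into one spike (1 ms lockout)
  u2 <- rest + 60 * exp(-((t - 7) / 0.12)^2) + 60 * exp(-((t - 7.5) / 0.12)^2)
  sp2 <- detect_spikes(u2, time = t, period = 10, rest = rest)
  expect_equal(nrow(sp2), 1)
  # but 2 ms apart stay separate
  u3 <- rest + 60 * exp(-((t - 7) / 0.12)^2) + 60 * exp(-((t - 9) / 0.12)^2)
  expect_equal(nrow(detect_spikes(u3, time = t, period = 10, rest = rest)), 2)
})

test_that("phase statistics are circular and period-invariant", {
  ph <- c(99.5, 0.5) # wraps around the cycle origin
  expect_equal(phase_mean(ph), 0, tolerance = 1e-9)
  expect_lt(phase_sd(ph), 1)
  # adding whole periods to spike times leaves phases unchanged
  tt <- c(12.3, 47.1, 83.4)
  tr1 <- make_train(tt)
  tr2 <- make_train(tt + 7 * 10)
  expect_equal(tr1$phase, tr2$phase)
})

test_that("locking classifier identifies p:q patterns", {
  # one spike per cycle at constant phase -> 1:1
  r11 <- classify_locking(make_train(seq(0, 299) * 10 + 6.5), n_cycles = 30)
  expect_equal(r11$mode, "locked")
  expect_equal(c(r11$p, r11$q), c(1L, 1L))
  expect_equal(r11$mean_phase, 65)
  expect_equal(r11$F_MN, 100)

  # alternating spike / no spike -> 1:2 at half the stroke frequency
  r12 <- classify_locking(make_train(seq(0, 299, by = 2) * 10 + 4.2),
                          n_cycles = 30)
  expect_equal(c(r12$p, r12$q), c(1L, 2L))
  expect_equal(r12$F_MN, 50)

  # 2:3 pattern with two alternating phase slots; both slots reported
  base <- rep(seq(0, 99) * 30, each = 2) + c(4.5, 16.8)
  r23 <- classify_locking(make_train(base), n_cycles = 30)
  expect_equal(c(r23$p, r23$q), c(2L, 3L))
  expect_equal(nrow(r23$slots), 2)
  expect_setequal(round(r23$slots$mean_phase, 1), c(45, 68))

  # quiescence and irregular firing
  rq <- classify_locking(make_train(numeric(0)), n_cycles = 30)
  expect_equal(rq$mode, "quiescence")
  set.seed(3)
  rir <- classify_locking(make_train(sort(runif(40, 0, 300))), n_cycles = 30)
  expect_equal(rir$mode, "irregular")

  # drifting phases are not locked even with a periodic count sequence
  drift <- classify_locking(make_train(seq(0, 29) * 10 + seq(2, 8, length.out = 30)),
                            n_cycles = 30)
  expect_equal(drift$mode, "irregular")

  expect_error(classify_locking(make_train(5), n_cycles = 2), "at least 3")
})

test_that("deterministic locked runs have sub-0.1% phase jitter", {
  r <- run_locking(volley = volley_spec(n_haltere = 77, n_wing = 77, sigma = 1),
                   visual = visual_signal("constant", U_base = -35),
                   cycles_discard = 30, cycles_analyze = 60)
  expect_equal(r$report$mode, "locked")
  expect_lt(max(r$report$slots$sd_phase), 0.1)
})
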