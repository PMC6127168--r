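#' Run the model to steady state and classify its locking mode
#'
#' Convenience wrapper around [simulate_mn()], [detect_spikes()] and
#' [classify_locking()]: simulates `cycles_discard + cycles_analyze` stroke
#' cycles, discards the transient, and classifies the remainder.
#'
#' @param neuron,synapse,volley,visual,waveform Model inputs, as in
#'   [simulate_mn()].
#' @param dt Integration step (ms).
#' @param cycles_discard,cycles_analyze Transient and analysis windows, in
#'   stroke cycles.
#' @param sigma_noise,rng_seed Membrane-voltage noise SD (mV) and seed.
#' @param tol_phase Locking phase tolerance (% cycle).
#' @param keep_sim Keep the full voltage trace in the result?
#' @return List with `report` (a `locking_report`), `spikes`
#'   (a `spike_train`), and `sim` (if `keep_sim`).
#' @export
run_locking <- function(neuron = neuron_params(), synapse = synapse_params(),
                        volley = NULL, visual = NULL,
                        waveform = waveform_template(), dt = 0.01,
                        cycles_discard = 50, cycles_analyze = 100,
                        sigma_noise = 0, rng_seed = NULL, tol_phase = 1,
                        keep_sim = FALSE) {
  period <- if (is.null(volley)) 10 else volley$period
  cfg <- sim_config(dt = dt, duration = (cycles_discard + cycles_analyze) * period,
                    sigma_noise = sigma_noise, rng_seed = rng_seed,
                    transient_discard = cycles_discard)
  sim <- simulate_mn(neuron, synapse, volley, visual, cfg, waveform)
  spikes <- detect_spikes(sim)
  report <- classify_locking(spikes, period = period,
                             t_start = cycles_discard * period,
                             n_cycles = cycles_analyze, tol_phase = tol_phase)
  out <- list(report = report, spikes = spikes)
  if (keep_sim) out$sim <- sim
  out
}

#' Sweep the number of active sensilla
#'
#' Increases the active-sensilla fraction in single-sensillum-pair steps and
#' records the locking mode, phase and firing frequency at each level. With
#' the reference stimulus (sigma = 1.0 ms, tau = 0.625 ms, U_IN = -35 mV,
#' no noise) the model passes from quiescence through 1:2 and 2:3 locking to
#' 1:1 locking, with irregular transition bands in between.
#'
#' @param pairs Per-nerve sensilla counts to test (1..110); each count n
#'   means n haltere + n wing sensilla, i.e. a fraction of `2n / 220`.
#' @param sigma Volley SD (ms).
#' @param tau Wing-after-haltere delay (ms).
#' @param U_IN Constant visual-interneuron potential (mV).
#' @param ... Passed to [run_locking()] (e.g. `cycles_analyze`, `dt`).
#' @return Data frame with one row per count: `n_per_nerve`, `fraction`
#'   (% of 220), `mode`, `p`, `q`, `mean_phase`, `phase_sd`, `F_MN`.
#' @export
sensilla_sweep <- function(pairs = 1:110, sigma = 1.0, tau = 0.625,
                           U_IN = -35, ...) {
  rows <- lapply(pairs, function(n) {
    r <- run_locking(volley = volley_spec(n_haltere = n, n_wing = n,
                                          sigma = sigma, tau = tau),
                     visual = visual_signal("constant", U_base = U_IN),
                     ...)$report
    data.frame(n_per_nerve = n, fraction = 2 * n / 220 * 100,
               mode = r$mode, p = r$p, q = r$q,
               mean_phase = r$mean_phase, phase_sd = r$phase_sd,
               F_MN = r$F_MN)
  })
  do.call(rbind, rows)
}

circ_diff <- function(a, b) ((a - b + 50) %% 100) - 50

#' Steady-state spike phase as a function of visual-interneuron potential
#'
#' Runs the model at constant `U_IN` levels and reports the mean 1:1 spike
#' phase at each; the phase decreases (advances) monotonically with
#' depolarisation. An exponential curve `y = a * exp(-x / b)` is fitted to
#' phase (as a fraction of the cycle) versus depolarisation `x` above the
#' most hyperpolarised grid level (mV).
#'
#' @param U_grid Visual potentials to test (mV).
#' @param volley A [volley_spec()]; defaults to the narrow-volley 42 %
#'   preset under which the cell locks 1:1 across the whole range.
#' @param fit Fit the exponential curve?
#' @param ... Passed to [run_locking()].
#' @return List with `curve` (data frame `U_IN`, `mode`, `mean_phase`) and,
#'   if `fit`, `fit` (list `a`, `b`, `R2`).
#' @export
steady_phase_vs_uin <- function(U_grid = seq(-40, -30, by = 1),
                                volley = preset("phase_step")$volley,
                                fit = TRUE, ...) {
  rows <- lapply(U_grid, function(u) {
    r <- run_locking(volley = volley,
                     visual = visual_signal("constant", U_base = u), ...)$report
    data.frame(U_IN = u, mode = r$mode, p = r$p, q = r$q,
               mean_phase = r$mean_phase)
  })
  curve <- do.call(rbind, rows)
  out <- list(curve = curve)
  if (fit) {
    d <- curve[curve$mode == "locked", ]
    x <- d$U_IN - min(U_grid)
    y <- d$mean_phase / 100
    ft <- try(stats::nls(y ~ a * exp(-x / b),
                         start = list(a = y[1], b = 20),
                         control = stats::nls.control(maxiter = 200)),
              silent = TRUE)
    if (!inherits(ft, "try-error")) {
      co <- stats::coef(ft)
      r2 <- 1 - sum(stats::resid(ft)^2) / sum((y - mean(y))^2)
      out$fit <- list(a = unname(co["a"]), b = unname(co["b"]), R2 = r2)
    }
  }
  out
}

#' Response of spike phase to a step in visual input
#'
#' Simulates a step of `U_IN` between two levels during 1:1 locking and
#' tracks the per-cycle spike phase and amplitude around the transition.
#' Steady state after the step is reached at the first cycle from which 5
#' consecutive per-cycle phases stay within `tol` of the final mean.
#'
#' @param volley A [volley_spec()].
#' @param U_base,U_level Pre- and post-step visual potentials (mV).
#' @param settle_cycles Cycles simulated before the step.
#' @param post_cycles Cycles simulated after the step.
#' @param tol Steady-state tolerance (% cycle).
#' @param neuron,synapse,waveform,dt As in [simulate_mn()].
#' @return List: `by_cycle` (data frame `cycle`, `time`, `phase`,
#'   `amplitude`; cycle 0 is the step cycle), `pre_phase`, `post_phase`,
#'   `dphase` (signed, post minus pre), `cycles_to_steady`, `damplitude`
#'   (mV), and the pre/post `locking_report`s.
#' @export
visual_step_response <- function(volley = preset("phase_step")$volley,
                                 U_base = -40, U_level = -30,
                                 settle_cycles = 100, post_cycles = 50,
                                 tol = 0.5, neuron = neuron_params(),
                                 synapse = synapse_params(),
                                 waveform = waveform_template(), dt = 0.01) {
  period <- volley$period
  t_step <- settle_cycles * period
  cfg <- sim_config(dt = dt, duration = (settle_cycles + post_cycles) * period)
  vis <- visual_signal("step", U_base = U_base, U_level = U_level,
                       t_step = t_step)
  sim <- simulate_mn(neuron, synapse, volley, vis, cfg, waveform)
  sp <- detect_spikes(sim)

  cyc <- floor(sp$time / period) - settle_cycles
  by_cycle <- data.frame(cycle = cyc, time = sp$time, phase = sp$phase,
                         amplitude = sp$amplitude)

  pre_win <- min(50, settle_cycles - 20)
  if (pre_win < 10) stop("settle_cycles must allow at least 30 cycles")
  rep_pre <- classify_locking(sp, period = period,
                              t_start = t_step - pre_win * period,
                              n_cycles = pre_win)
  rep_post <- classify_locking(sp, period = period,
                               t_start = t_step + 10 * period,
                               n_cycles = post_cycles - 10)

  pre <- by_cycle[by_cycle$cycle %in% -20:-1, ]
  post_tail <- by_cycle[by_cycle$cycle >= post_cycles - 10, ]
  pre_phase <- phase_mean(pre$phase)
  post_phase <- phase_mean(post_tail$phase)

  cycles_to_steady <- NA_integer_
  post <- by_cycle[by_cycle$cycle >= 0, ]
  if (nrow(post) >= 5) {
    dev <- abs(circ_diff(post$phase, post_phase))
    for (i in seq_len(nrow(post) - 4)) {
      if (all(dev[i:(i + 4)] < tol)) { cycles_to_steady <- post$cycle[i] + 1L; break }
    }
  }

  list(by_cycle = by_cycle,
       pre_phase = pre_phase, post_phase = post_phase,
       dphase = circ_diff(post_phase, pre_phase),
       cycles_to_steady = cycles_to_steady,
       damplitude = mean(post_tail$amplitude) - mean(pre$amplitude),
       locking_pre = rep_pre, locking_post = rep_post)
}

#' Two-dimensional phase map over volley width and active sensilla
#'
#' Classifies the locking mode of every (sigma, active-fraction) cell at a
#' hyperpolarised visual level, then repeats the grid at a depolarised level
#' and reports the vision-induced changes in spike phase (cells locked 1:1
#' at both levels) and firing frequency (cells locked at both levels).
#'
#' @param sigmas Volley SDs (ms).
#' @param fractions Active-sensilla percentages (of 220 total).
#' @param U_levels Length-2 vector: hyperpolarised and depolarised visual
#'   potentials (mV).
#' @param tau Wing-after-haltere delay (ms).
#' @param progress Print a line per sigma?
#' @param ... Passed to [run_locking()].
#' @return Data frame with one row per cell: `sigma`, `fraction`, mode /
#'   `p` / `q` / `phase` / `F_MN` at each level (suffixes `_lo`, `_hi`),
#'   `dphase` (% cycle, signed, `NA` unless 1:1 at both levels) and `dF`
#'   (Hz, `NA` unless locked at both levels).
#' @export
phase_map <- function(sigmas = seq(0.1, 2.5, by = 0.1),
                      fractions = seq(30, 100, by = 2 / 220 * 200),
                      U_levels = c(-40, -30), tau = 0.625,
                      progress = FALSE, ...) {
  cells <- expand.grid(sigma = sigmas, fraction = fractions)
  one <- function(sigma, fraction, u) {
    cnt <- active_counts(fraction)
    run_locking(volley = volley_spec(n_haltere = cnt["haltere"],
                                     n_wing = cnt["wing"],
                                     sigma = sigma, tau = tau),
                visual = visual_signal("constant", U_base = u), ...)$report
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lo <- one(cells$sigma[i], cells$fraction[i], U_levels[1])
    hi <- one(cells$sigma[i], cells$fraction[i], U_levels[2])
    both_11 <- lo$mode == "locked" && hi$mode == "locked" &&
      lo$p == 1 && lo$q == 1 && hi$p == 1 && hi$q == 1
    both_locked <- lo$mode == "locked" && hi$mode == "locked"
    rows[[i]] <- data.frame(
      sigma = cells$sigma[i], fraction = cells$fraction[i],
      mode_lo = lo$mode, p_lo = lo$p, q_lo = lo$q,
      phase_lo = lo$mean_phase, F_lo = lo$F_MN,
      mode_hi = hi$mode, p_hi = hi$p, q_hi = hi$q,
      phase_hi = hi$mean_phase, F_hi = hi$F_MN,
      dphase = if (both_11) circ_diff(hi$mean_phase, lo$mean_phase) else NA_real_,
      dF = if (both_locked) hi$F_MN - lo$F_MN else NA_real_)
    if (progress && i %% length(fractions) == 0)
      message(sprintf("phase_map: sigma %.2f done", cells$sigma[i]))
  }
  do.call(rbind, rows)
}

#' Frequency response of vision-induced phase modulation
#'
#' Applies sinusoidal visual stimulation spanning `U_levels` and measures
#' the peak-to-peak per-cycle phase modulation relative to the steady-state
#' modulation (the phase difference between constant runs at the two
#' levels). The motoneuron behaves like a low-pass filter: modulation
#' collapses progressively at elevated stimulus frequencies.
#'
#' @param freqs Stimulus frequencies (Hz); 0 denotes the steady-state
#'   reference and reports 100 by definition.
#' @param volley A [volley_spec()] under which both levels lock 1:1.
#' @param U_levels Length-2 vector of visual potentials (mV).
#' @param settle Settling time before the sinusoid starts (ms).
#' @param n_periods Stimulus periods simulated.
#' @param measure_periods Trailing periods used for the measurement.
#' @param steady_mod Steady-state modulation (% cycle); computed from two
#'   constant runs when `NULL`.
#' @param ... Passed to [run_locking()] for the steady-state runs.
#' @return Data frame `frequency`, `modulation` (% cycle, peak-to-peak) and
#'   `attenuation` (% of steady-state response).
#' @export
frequency_response <- function(freqs = c(2, 4, 8, 16),
                               volley = preset("phase_step")$volley,
                               U_levels = c(-40, -30), settle = 1000,
                               n_periods = 5, measure_periods = 3,
                               steady_mod = NULL, ...) {
  if (is.null(steady_mod)) {
    lo <- run_locking(volley = volley,
                      visual = visual_signal("constant", U_base = U_levels[1]),
                      ...)$report
    hi <- run_locking(volley = volley,
                      visual = visual_signal("constant", U_base = U_levels[2]),
                      ...)$report
    steady_mod <- abs(circ_diff(hi$mean_phase, lo$mean_phase))
  }
  rows <- lapply(freqs, function(f) {
    if (f == 0)
      return(data.frame(frequency = 0, modulation = steady_mod,
                        attenuation = 100))
    t_per <- 1000 / f
    duration <- settle + n_periods * t_per
    cfg <- sim_config(duration = duration)
    vis <- visual_signal("sine", U_base = U_levels[1], U_level = U_levels[2],
                         frequency = f, t_on = settle)
    sim <- simulate_mn(volley = volley, visual = vis, config = cfg)
    sp <- detect_spikes(sim)
    t0 <- settle + (n_periods - measure_periods) * t_per
    ph <- sp$phase[sp$time >= t0]
    m <- if (length(ph) > 2) diff(range(ph)) else NA_real_
    data.frame(frequency = f, modulation = m,
               attenuation = m / steady_mod * 100)
  })
  structure(do.call(rbind, rows), steady_mod = steady_mod)
}

#' Phase stability of 1:1 locking under membrane-voltage noise
#'
#' Repeats a 1:1-locked run across seeds with additive Gaussian voltage
#' noise and pools the spike phases of all analysed cycles.
#'
#' @param sigma_noise Noise SD (mV, referenced to the 0.01 ms step).
#' @param seeds Integer seeds, one run per seed.
#' @param volley,U_IN Stimulus; default is the 70 %-active, sigma = 1 ms
#'   volley that locks 1:1.
#' @param cycles_discard,cycles_analyze Windows per run (cycles).
#' @param ... Passed to [run_locking()].
#' @return List with `pooled_sd` (% cycle), `per_seed` data frame, the
#'   pooled `phases`, and `n_cycles` analysed in total.
#' @export
noise_phase_stability <- function(sigma_noise = 0.1, seeds = 1:5,
                                  volley = volley_spec(n_haltere = 77,
                                                       n_wing = 77,
                                                       sigma = 1.0),
                                  U_IN = -35, cycles_discard = 50,
                                  cycles_analyze = 100, ...) {
  phases <- list()
  per_seed <- lapply(seeds, function(s) {
    r <- run_locking(volley = volley,
                     visual = visual_signal("constant", U_base = U_IN),
                     sigma_noise = sigma_noise, rng_seed = s,
                     cycles_discard = cycles_discard,
                     cycles_analyze = cycles_analyze, ...)
    t0 <- cycles_discard * volley$period
    ph <- r$spikes$phase[r$spikes$time >= t0]
    phases[[as.character(s)]] <<- ph
    data.frame(seed = s, n_spikes = length(ph), sd = phase_sd(ph),
               mean_phase = phase_mean(ph))
  })
  all_ph <- unlist(phases, use.names = FALSE)
  list(pooled_sd = phase_sd(all_ph), per_seed = do.call(rbind, per_seed),
       phases = all_ph, n_cycles = length(seeds) * cycles_analyze)
}

pulse_train_current <- function(time, t_pulses, width, amplitude) {
  out <- numeric(length(time))
  for (tp in t_pulses)
    out[time >= tp & time < tp + width] <- amplitude
  out
}

count_pulse_spikes <- function(neuron, t_pulses, width, amplitude, dt,
                               duration) {
  cfg <- sim_config(dt = dt, duration = duration)
  sim <- simulate_mn(neuron = neuron, synapse = synapse_params(g_INs = 0),
                     config = cfg,
                     I_inj = function(t) pulse_train_current(t, t_pulses,
                                                             width, amplitude))
  detect_spikes(sim)
}

#' Refractory periods from a paired-pulse protocol
#'
#' Measures the absolute and relative refractory period of the model cell
#' with two identical suprathreshold current pulses. The pulse amplitude is
#' `pulse_factor` times the single-pulse threshold amplitude (found by
#' bisection). The absolute refractory period is the shortest inter-pulse
#' interval at which the second pulse still elicits a spike; the relative
#' refractory period is the shortest interval at which the second spike
#' recovers the amplitude of an isolated spike to within 2 %.
#'
#' @param neuron A [neuron_params()].
#' @param pulse_width Pulse duration (ms).
#' @param pulse_factor Amplitude relative to the single-pulse threshold.
#' @param dt Integration step (ms); also the resolution of the interval
#'   search.
#' @param method `"bisect"` (default) or `"scan"` (exhaustive sweep at
#'   resolution `dt`, slower; used as a cross-check).
#' @param max_interval Largest interval searched (ms).
#' @return List with `absolute` and `relative` refractory periods (ms), the
#'   pulse `amplitude` (uA cm^-2) and the isolated spike amplitude
#'   `spike_amplitude` (mV above rest).
#' @export
refractory_periods <- function(neuron = neuron_params(), pulse_width = 0.2,
                               pulse_factor = 5, dt = 0.01,
                               method = c("bisect", "scan"),
                               max_interval = 30) {
  method <- match.arg(method)
  t1 <- 5
  dur1 <- 40

  fires <- function(amplitude) {
    nrow(count_pulse_spikes(neuron, t1, pulse_width, amplitude, dt, dur1)) >= 1
  }
  lo <- 1; hi <- 5000
  if (!fires(hi)) stop("no spike even at the maximum test amplitude")
  while (hi / lo > 1.005) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  amp <- pulse_factor * hi

  iso <- count_pulse_spikes(neuron, t1, pulse_width, amp, dt, dur1)
  a1 <- iso$amplitude[1]

  second_spike <- function(delta) {
    sp <- count_pulse_spikes(neuron, c(t1, t1 + delta), pulse_width, amp, dt,
                             t1 + delta + 30)
    if (nrow(sp) < 2) return(NA_real_)
    sp$amplitude[2]
  }
  search <- function(ok) {
    # smallest interval (to resolution dt) satisfying ok(delta)
    if (method == "scan") {
      for (d in seq(dt * 10, max_interval, by = dt * 10))
        if (ok(d)) {
          for (dd in seq(max(d - dt * 10, dt), d, by = dt))
            if (ok(dd)) return(dd)
        }
      return(NA_real_)
    }
    lo <- dt; hi <- max_interval
    if (!ok(hi)) return(NA_real_)
    while (hi - lo > dt) {
      mid <- (lo + hi) / 2
      if (ok(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  absolute <- search(function(d) !is.na(second_spike(d)))
  relative <- search(function(d) {
    a2 <- second_spike(d)
    !is.na(a2) && a2 >= 0.98 * a1
  })
  list(absolute = absolute, relative = relative, amplitude = amp,
       spike_amplitude = a1, pulse_width = pulse_width)
}

#' Visual-gating and mode-switching scenarios
#'
#' Runs one of three published-style scenarios, each comparing the model at
#' a hyperpolarised (-40 mV) versus depolarised (-30 mV) visual level:
#'
#' * `"mode_switch"`: physiological cell, 42 % sensilla, sigma = 0.72 ms;
#'   depolarisation switches 2:3 firing to 1:1.
#' * `"gating_low_leak"`: reduced leak (g_L = 3.6 mS cm^-2), 15 % sensilla,
#'   sigma = 0.5 ms; depolarisation gates the silent cell into 1:4 locking.
#' * `"gating_high_na"`: raised excitability (gbar_Na = 240 mS cm^-2,
#'   g_L = 5.86 mS cm^-2), no sensilla; depolarisation drives tonic,
#'   non-phase-locked firing near 76 Hz.
#'
#' @param scenario Scenario name (see above).
#' @param ... Passed to [run_locking()] (e.g. `cycles_analyze`).
#' @return List with `baseline` and `depolarized` `locking_report`s and the
#'   parameter bundle used.
#' @export
gating_scenario <- function(scenario = c("mode_switch", "gating_low_leak",
                                         "gating_high_na"), ...) {
  scenario <- match.arg(scenario)
  ps <- preset(switch(scenario,
                      mode_switch = "mode_switch",
                      gating_low_leak = "gating_low_leak",
                      gating_high_na = "gating_high_na"))
  run <- function(u)
    run_locking(neuron = ps$neuron, synapse = ps$synapse, volley = ps$volley,
                visual = visual_signal("constant", U_base = u), ...)$report
  list(baseline = run(-40), depolarized = run(-30), params = ps)
}

#' Sweep the wing-after-haltere delay
#'
#' For each delay `tau`, measures the steady-state phase difference between
#' the depolarised and hyperpolarised visual levels (the model's
#' vision-induced phase response) and reports the delay at which it peaks.
#'
#' @param taus Delays to test (ms).
#' @param volley Base [volley_spec()]; its `tau` is replaced per run.
#' @param U_levels Visual potentials (mV).
#' @param ... Passed to [run_locking()].
#' @return List with `sweep` (data frame `tau`, `phase_lo`, `phase_hi`,
#'   `response`) and `tau_max`, the delay maximising the response.
#' @export
tau_sweep <- function(taus = seq(0, 2, by = 0.0625),
                      volley = preset("phase_step")$volley,
                      U_levels = c(-40, -30), ...) {
  rows <- lapply(taus, function(tau) {
    v <- volley
    v$tau <- tau
    lo <- run_locking(volley = v,
                      visual = visual_signal("constant", U_base = U_levels[1]),
                      ...)$report
    hi <- run_locking(volley = v,
                      visual = visual_signal("constant", U_base = U_levels[2]),
                      ...)$report
    ok <- lo$mode == "locked" && hi$mode == "locked"
    data.frame(tau = tau, phase_lo = lo$mean_phase, phase_hi = hi$mean_phase,
               response = if (ok) abs(circ_diff(hi$mean_phase, lo$mean_phase))
                          else NA_real_)
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep,
       tau_max = sweep$tau[which.max(sweep$response)])
}
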