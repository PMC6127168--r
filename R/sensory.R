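#' Sensilla spike waveform template
#'
#' Parametric stand-in for the intracellular campaniform-sensilla action
#' potential: a smooth unimodal pulse with a raised-cosine rise and an
#' exponential decay that is tapered to reach the resting level exactly at
#' the end of its support. The default template has the physiological
#' amplitude (50 mV above a -65 mV rest) and a total duration of 1.5 ms,
#' matching the duration of extracellular sensilla potentials; with the
#' fitted haltere junction conductance it produces a single-sensillum
#' electrical EPSP of ~0.67 mV in the model cell (see
#' [calibrate_waveform()] for the time-scale calibration utility and the
#' methods vignette for why the template is frozen at the physiological
#' duration rather than rescaled to the measured EPSP peak).
#'
#' @param rest Baseline potential (mV).
#' @param amplitude Peak height above rest (mV).
#' @param rise Time from pulse onset to peak (ms).
#' @param decay Fall time constant (ms).
#' @param support Total pulse duration (ms); the trace equals `rest`
#'   outside `[0, support]`.
#' @return An object of class `waveform_template`.
#' @export
waveform_template <- function(rest = -65, amplitude = 50,
                              rise = 0.3, decay = 0.4,
                              support = 1.5) {
  stopifnot(amplitude > 0, rise > 0, decay > 0, support > rise)
  structure(list(rest = rest, amplitude = amplitude, rise = rise,
                 decay = decay, support = support),
            class = "waveform_template")
}

#' Evaluate the sensilla spike waveform
#'
#' @param t Time since pulse onset (ms); vectorised.
#' @param w A [waveform_template()].
#' @return Presynaptic membrane potential (mV): `rest` outside
#'   `[0, support]`, peaking at `rest + amplitude` at `t = rise`.
#' @examples
#' w <- waveform_template()
#' max(sensilla_waveform(seq(0, 2, 0.001), w)) # -65 + 50
#' @export
sensilla_waveform <- function(t, w) {
  s <- numeric(length(t))
  up <- t >= 0 & t <= w$rise
  s[up] <- (1 - cos(pi * t[up] / w$rise)) / 2
  dn <- t > w$rise & t <= w$support
  if (any(dn)) {
    e_end <- exp(-(w$support - w$rise) / w$decay)
    s[dn] <- (exp(-(t[dn] - w$rise) / w$decay) - e_end) / (1 - e_end)
  }
  w$rest + w$amplitude * s
}

#' Per-sensillum spike times of one stroke cycle
#'
#' Haltere spike times are spread around the mean volley phase with standard
#' deviation `sigma`; the wing volley repeats the same structure shifted by
#' `tau`. Every sensillum keeps its within-cycle time in all cycles, so the
#' drive is strictly periodic.
#'
#' @param spec A [volley_spec()].
#' @param cycle_index Zero-based cycle number; spike times are shifted by
#'   `cycle_index * period`.
#' @return Data frame with columns `nerve` (`"haltere"` / `"wing"`),
#'   `sensillum` (1-based id) and `time` (ms, spike peak time).
#' @export
volley_times <- function(spec, cycle_index = 0) {
  stopifnot(inherits(spec, "volley_spec"))
  mean_h <- spec$mean_phase_haltere / 100 * spec$period
  if (spec$placement == "quantile") {
    offs <- function(n) {
      if (n == 0) numeric(0) else spec$sigma * stats::qnorm((seq_len(n) - 0.5) / n)
    }
    oh <- offs(spec$n_haltere)
    ow <- offs(spec$n_wing)
  } else {
    # one shared draw so the wing volley repeats the haltere structure
    if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
    pool <- spec$sigma * stats::rnorm(max(spec$n_haltere, spec$n_wing))
    oh <- pool[seq_len(spec$n_haltere)]
    ow <- pool[seq_len(spec$n_wing)]
  }
  base <- cycle_index * spec$period
  rbind(
    data.frame(nerve = rep("haltere", spec$n_haltere),
               sensillum = seq_len(spec$n_haltere),
               time = base + mean_h + oh),
    data.frame(nerve = rep("wing", spec$n_wing),
               sensillum = seq_len(spec$n_wing),
               time = base + mean_h + spec$tau + ow)
  )
}

#' Periodic presynaptic voltage profiles
#'
#' Samples each sensillum's membrane potential over one stroke cycle on the
#' integration grid. Because every sensillum fires at a fixed within-cycle
#' time, one cycle fully describes the periodic drive; the simulator indexes
#' these profiles modulo the cycle length. Pulses wrap around the cycle
#' boundary.
#'
#' @param spec A [volley_spec()].
#' @param w A [waveform_template()].
#' @param dt Grid step (ms); must divide the stroke period.
#' @return List with matrices `haltere` and `wing` (rows = cycle samples,
#'   columns = sensilla), the sample count `S`, and `dt`.
#' @export
drive_profiles <- function(spec, w = waveform_template(), dt = 0.01) {
  stopifnot(inherits(spec, "volley_spec"), inherits(w, "waveform_template"))
  S <- round(spec$period / dt)
  if (abs(S * dt - spec$period) > 1e-9)
    stop("dt must divide the stroke period")
  if (dt > w$rise / 3)
    warning("dt is coarse relative to the waveform rise time")
  tgrid <- (seq_len(S) - 1) * dt
  tt <- volley_times(spec, 0)
  prof <- function(times) {
    m <- matrix(w$rest, nrow = S, ncol = length(times))
    for (i in seq_along(times)) {
      onset <- times[i] - w$rise
      trel <- (tgrid - onset) %% spec$period
      m[, i] <- sensilla_waveform(trel, w)
    }
    m
  }
  list(haltere = prof(tt$time[tt$nerve == "haltere"]),
       wing = prof(tt$time[tt$nerve == "wing"]),
       S = S, dt = dt)
}

#' Visual-interneuron voltage trace
#'
#' @param sig A [visual_signal()].
#' @param duration Total duration (ms).
#' @param dt Grid step (ms).
#' @return Numeric vector of `U_IN` (mV) on the time grid
#'   (`duration / dt + 1` samples).
#' @examples
#' v <- visual_trace(visual_signal("step", t_step = 5), 10, 0.01)
#' range(v) # -40 to -30
#' @export
visual_trace <- function(sig, duration, dt) {
  stopifnot(inherits(sig, "visual_signal"))
  t <- seq(0, by = dt, length.out = round(duration / dt) + 1)
  switch(sig$kind,
    constant = rep(sig$U_base, length(t)),
    step = ifelse(t < sig$t_step, sig$U_base, sig$U_level),
    sine = {
      mid <- (sig$U_base + sig$U_level) / 2
      amp <- (sig$U_level - sig$U_base) / 2
      out <- rep(sig$U_base, length(t))
      on <- t >= sig$t_on
      # starts continuously from U_base at t_on
      out[on] <- mid - amp * cos(2 * pi * sig$frequency * (t[on] - sig$t_on) / 1000)
      out
    })
}
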