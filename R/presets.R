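#' Named parameter presets for the experiment suite
#'
#' Frozen parameter bundles for the reference experiments, each a complete
#' set of neuron, synapse, volley and visual parameters plus a simulation
#' configuration:
#'
#' * `"epsp_single"`: one haltere sensillum, subthreshold EPSP recording.
#' * `"spike_calibration"`: narrow volley of 50 haltere sensilla
#'   (sigma = 0.2 ms), used to calibrate `gbar_Na` against the measured
#'   spike amplitude.
#' * `"locking_50pct"`, `"locking_60pct"`, `"locking_70pct"`: 55/66/77
#'   sensilla per nerve, sigma = 1.0 ms, U_IN = -35 mV; the 1:2, 2:3 and
#'   1:1 locking reference runs.
#' * `"subthreshold_33pct"`: 33 % active sensilla, same stimulus; quiescent
#'   without noise.
#' * `"phase_step"`: narrow volley (sigma = 0.2 ms), 42 % active sensilla,
#'   visual step from -40 to -30 mV; the visual phase-control experiment.
#' * `"mode_switch"`: sigma = 0.72 ms, 42 % active; a 10 mV visual
#'   depolarisation switches 2:3 to 1:1 locking.
#' * `"gating_low_leak"`: g_L = 3.6 mS cm^-2, 15 % active sensilla,
#'   sigma = 0.5 ms; visually gated 1:4 firing.
#' * `"gating_high_na"`: gbar_Na = 240 mS cm^-2, g_L = 5.86 mS cm^-2, no
#'   sensilla; visually gated tonic (non-locked) firing.
#'
#' @param name Preset name.
#' @return List with elements `name`, `neuron`, `synapse`, `volley`
#'   (possibly `NULL`), `visual` and `config`.
#' @examples
#' preset("locking_50pct")$volley$n_haltere # 55
#' @export
preset <- function(name) {
  if (!name %in% preset_names())
    stop("unknown preset '", name, "'; valid presets: ",
         paste(preset_names(), collapse = ", "))
  cnt42 <- active_counts(42)
  cnt33 <- active_counts(33)
  cnt15 <- active_counts(15)
  base <- list(neuron = neuron_params(), synapse = synapse_params(),
               config = sim_config(duration = 1500))
  p <- switch(name,
    epsp_single = list(
      neuron = neuron_params(), synapse = synapse_params(g_INs = 0),
      volley = volley_spec(n_haltere = 1, n_wing = 0, sigma = 0.1),
      visual = NULL, config = sim_config(duration = 10)),
    spike_calibration = list(
      neuron = neuron_params(), synapse = synapse_params(g_INs = 0),
      volley = volley_spec(n_haltere = 50, n_wing = 0, sigma = 0.2),
      visual = NULL, config = sim_config(duration = 10)),
    locking_50pct = list(
      volley = volley_spec(n_haltere = 55, n_wing = 55, sigma = 1.0),
      visual = visual_signal("constant", U_base = -35)),
    locking_60pct = list(
      volley = volley_spec(n_haltere = 66, n_wing = 66, sigma = 1.0),
      visual = visual_signal("constant", U_base = -35)),
    locking_70pct = list(
      volley = volley_spec(n_haltere = 77, n_wing = 77, sigma = 1.0),
      visual = visual_signal("constant", U_base = -35)),
    subthreshold_33pct = list(
      volley = volley_spec(n_haltere = cnt33["haltere"],
                           n_wing = cnt33["wing"], sigma = 1.0),
      visual = visual_signal("constant", U_base = -35)),
    phase_step = list(
      volley = volley_spec(n_haltere = cnt42["haltere"],
                           n_wing = cnt42["wing"], sigma = 0.2),
      visual = visual_signal("step", U_base = -40, U_level = -30,
                             t_step = 1000)),
    mode_switch = list(
      volley = volley_spec(n_haltere = cnt42["haltere"],
                           n_wing = cnt42["wing"], sigma = 0.72),
      visual = visual_signal("step", U_base = -40, U_level = -30,
                             t_step = 1000)),
    gating_low_leak = list(
      neuron = neuron_params(g_L = 3.6),
      volley = volley_spec(n_haltere = cnt15["haltere"],
                           n_wing = cnt15["wing"], sigma = 0.5),
      visual = visual_signal("step", U_base = -40, U_level = -30,
                             t_step = 1000)),
    gating_high_na = list(
      neuron = neuron_params(gbar_Na = 240, g_L = 5.86),
      volley = NULL,
      visual = visual_signal("step", U_base = -40, U_level = -30,
                             t_step = 1000)))
  out <- utils::modifyList(base, p, keep.null = TRUE)
  out$name <- name
  if (!"volley" %in% names(p)) out$volley <- NULL
  if (!"visual" %in% names(p)) out$visual <- NULL
  out[c("name", "neuron", "synapse", "volley", "visual", "config")]
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("epsp_single", "spike_calibration", "locking_50pct", "locking_60pct",
    "locking_70pct", "subthreshold_33pct", "phase_step", "mode_switch",
    "gating_low_leak", "gating_high_na")
}
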