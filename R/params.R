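#' Membrane parameters of the model motoneuron
#'
#' Bundles the Hodgkin-Huxley membrane constants of the MN.b1 model cell.
#' Passive parameters (`g_L`, `E_L`) and the maximum sodium conductance
#' default to the values estimated from single-sensillum EPSP recordings and
#' from the measured spike amplitude (see [fit_passive()] and
#' [calibrate_gna()]). Capacitance, potassium conductance and the sodium /
#' potassium reversal potentials are not constrained by those recordings and
#' default to the original squid-axon values in the modern convention
#' (rest near -65 mV).
#'
#' @param C_MN Membrane capacitance per unit area (uF cm^-2).
#' @param gbar_Na Maximum sodium conductance (mS cm^-2).
#' @param gbar_K Maximum potassium conductance (mS cm^-2).
#' @param g_L Leak conductance (mS cm^-2).
#' @param E_Na,E_K,E_L Reversal potentials (mV). Must satisfy
#'   `E_Na > E_L > E_K`.
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()
#' p$g_L / p$gbar_Na # leak-to-sodium conductance ratio of the fitted cell
#' @export
neuron_params <- function(C_MN = 1, gbar_Na = 165, gbar_K = 36, g_L = 5.84,
                          E_Na = 50, E_K = -77, E_L = -52.26) {
  stopifnot(is.numeric(C_MN), C_MN > 0,
            is.numeric(gbar_Na), gbar_Na >= 0,
            is.numeric(gbar_K), gbar_K >= 0,
            is.numeric(g_L), g_L >= 0)
  if (!(E_Na > E_L && E_L > E_K))
    stop("reversal potentials must satisfy E_Na > E_L > E_K")
  structure(list(C_MN = C_MN, gbar_Na = gbar_Na, gbar_K = gbar_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L),
            class = "neuron_params")
}

#' Electrical-synapse conductances
#'
#' Per-sensillum gap-junction conductances for haltere (`g_H`) and wing
#' (`g_W`) campaniform afferents, and the lumped conductance of all
#' descending visual interneuron junctions (`g_INs`). `g_W` defaults to half
#' of `g_H`, reflecting that wing-nerve stimulation evokes roughly half the
#' electrical response of haltere-nerve stimulation. `g_INs` absorbs both the
#' interneuron junctions and the dendritic path, summed over all active
#' interneurons.
#'
#' @param g_H Haltere per-sensillum conductance (mS cm^-2).
#' @param g_W Wing per-sensillum conductance (mS cm^-2); default `g_H / 2`.
#' @param g_INs Total visual-interneuron conductance (mS cm^-2).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(g_H = 0.16, g_W = g_H / 2, g_INs = 1.0) {
  stopifnot(g_H >= 0, g_W >= 0, g_INs >= 0)
  structure(list(g_H = g_H, g_W = g_W, g_INs = g_INs),
            class = "synapse_params")
}

#' Simulation configuration
#'
#' @param dt Integration time step (ms). The fixed-step Heun scheme is
#'   validated for steps between 0.02 and 0.005 ms; the reference step is
#'   0.01 ms.
#' @param duration Total simulated time (ms).
#' @param sigma_noise Standard deviation of the additive Gaussian
#'   membrane-voltage noise (mV), referenced to the 0.01 ms step. At other
#'   steps the per-step kick is scaled by `sqrt(dt / 0.01)` so that trace
#'   statistics are step-size invariant.
#' @param rng_seed Integer seed for noisy or randomly placed runs; `NULL`
#'   leaves the R RNG state untouched.
#' @param transient_discard Number of initial stroke cycles excluded from
#'   steady-state analyses.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 1500, sigma_noise = 0,
                       rng_seed = NULL, transient_discard = 50) {
  stopifnot(dt > 0, duration > 0, sigma_noise >= 0, transient_discard >= 0)
  if (dt < 0.005 - 1e-12 || dt > 0.02 + 1e-12)
    stop("dt must lie in the validated range [0.005, 0.02] ms")
  structure(list(dt = dt, duration = duration, sigma_noise = sigma_noise,
                 rng_seed = rng_seed, transient_discard = transient_discard),
            class = "sim_config")
}

#' Per-stroke sensilla volley specification
#'
#' Describes the spike volleys that wing and haltere campaniform sensilla
#' deliver in every stroke cycle. Each active sensillum fires exactly one
#' spike per cycle at a fixed within-cycle time; haltere spike times are
#' spread around the mean volley phase with standard deviation `sigma`, and
#' the wing volley repeats the same structure delayed by `tau`.
#'
#' With the default deterministic `"quantile"` placement the i-th of n
#' sensilla sits at the Gaussian quantile `(i - 0.5) / n`, which makes the
#' drive strictly periodic and locking thresholds reproducible. `"random"`
#' placement draws the per-sensillum offsets once (seeded) and keeps them
#' fixed across cycles.
#'
#' @param n_haltere,n_wing Number of active sensilla per nerve (0..110 each).
#' @param sigma Volley standard deviation (ms).
#' @param tau Wing-after-haltere delay (ms).
#' @param mean_phase_haltere Mean haltere volley phase (% stroke cycle).
#' @param period Stroke period (ms); 10 ms corresponds to the 100 Hz
#'   wingbeat.
#' @param placement `"quantile"` (deterministic) or `"random"`.
#' @param rng_seed Seed used by `"random"` placement.
#' @return An object of class `volley_spec`.
#' @seealso [active_counts()] for the percent-active convention.
#' @export
volley_spec <- function(n_haltere = 55, n_wing = 55, sigma = 1.0,
                        tau = 0.625, mean_phase_haltere = 25, period = 10,
                        placement = c("quantile", "random"), rng_seed = NULL) {
  placement <- match.arg(placement)
  if (n_haltere < 0 || n_haltere > 110 || n_wing < 0 || n_wing > 110)
    stop("per-nerve sensilla counts must lie in 0..110")
  stopifnot(sigma > 0, period > 0, tau >= 0)
  structure(list(n_haltere = as.integer(unname(n_haltere)),
                 n_wing = as.integer(unname(n_wing)),
                 sigma = sigma, tau = tau,
                 mean_phase_haltere = mean_phase_haltere,
                 period = period, placement = placement,
                 rng_seed = rng_seed),
            class = "volley_spec")
}

#' Convert a percent-active fraction into per-nerve sensilla counts
#'
#' "x % spiking sensilla" always refers to x % of the 220 modelled sensilla
#' (110 wing + 110 haltere), split equally between the two nerves. When the
#' rounded total is odd, the haltere nerve receives the extra sensillum.
#'
#' @param fraction Percentage of the 220 sensilla that are active.
#' @return Named integer vector with elements `haltere` and `wing`.
#' @examples
#' active_counts(50) # 55 + 55
#' active_counts(42) # 46 + 46
#' @export
active_counts <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 100)
  total <- round(fraction / 100 * 220)
  c(haltere = as.integer(ceiling(total / 2)),
    wing = as.integer(floor(total / 2)))
}

#' Graded visual-interneuron signal
#'
#' The lumped, non-spiking membrane potential of the descending visual
#' interneurons, `U_IN(t)`. Three stimulus kinds cover the experiment suite:
#' a constant level, a step between two levels at `t_step`, and a sinusoid
#' spanning the two levels (starting at `U_base`).
#'
#' @param kind `"constant"`, `"step"` or `"sine"`.
#' @param U_base Baseline potential (mV); the only level used by
#'   `"constant"`.
#' @param U_level Second potential level (mV) for `"step"` and `"sine"`.
#' @param t_step Step time (ms), for `"step"`.
#' @param frequency Stimulus frequency (Hz), for `"sine"`.
#' @param t_on Time (ms) at which the sinusoid starts; the signal holds
#'   `U_base` before `t_on`.
#' @return An object of class `visual_signal`.
#' @export
visual_signal <- function(kind = c("constant", "step", "sine"),
                          U_base = -40, U_level = -30, t_step = 0,
                          frequency = NULL, t_on = 0) {
  kind <- match.arg(kind)
  if (kind == "sine" && (is.null(frequency) || frequency <= 0))
    stop("sine signals need a positive frequency")
  structure(list(kind = kind, U_base = U_base, U_level = U_level,
                 t_step = t_step, frequency = frequency, t_on = t_on),
            class = "visual_signal")
}
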