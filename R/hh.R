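#' Gating rate constants
#'
#' Voltage-dependent opening/closing rates of the sodium activation (m),
#' sodium inactivation (h) and potassium activation (n) gates, in the modern
#' squid-axon convention (resting potential near -65 mV). The removable
#' singularities of the alpha_m and alpha_n expressions at U = -40 and
#' U = -55 mV are replaced by their analytic limits.
#'
#' @param U Membrane potential (mV); vectorised.
#' @return A data frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n` (ms^-1).
#' @export
gating_rates <- function(U) {
  stopifnot(all(is.finite(U)))
  xm <- U + 40
  am <- ifelse(abs(xm) < 1e-7, 1, 0.1 * xm / (1 - exp(-xm / 10)))
  xn <- U + 55
  an <- ifelse(abs(xn) < 1e-7, 0.1, 0.01 * xn / (1 - exp(-xn / 10)))
  data.frame(alpha_m = am,
             beta_m = 4 * exp(-(U + 65) / 18),
             alpha_h = 0.07 * exp(-(U + 65) / 20),
             beta_h = 1 / (1 + exp(-(U + 35) / 10)),
             alpha_n = an,
             beta_n = 0.125 * exp(-(U + 65) / 80))
}

#' Steady-state gating values
#'
#' @param U Membrane potential (mV); vectorised.
#' @return Data frame with columns `m`, `h`, `n` (the voltage-clamp
#'   steady states m_inf, h_inf, n_inf).
#' @export
steady_gates <- function(U) {
  r <- gating_rates(U)
  data.frame(m = r$alpha_m / (r$alpha_m + r$beta_m),
             h = r$alpha_h / (r$alpha_h + r$beta_h),
             n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Membrane state constructor
#'
#' @param U Membrane potential (mV).
#' @param m,h,n Gating variables in `[0, 1]`. Default to their steady-state
#'   values at `U`.
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(U, m = NULL, h = NULL, n = NULL) {
  g <- steady_gates(U)
  m <- if (is.null(m)) g$m else m
  h <- if (is.null(h)) g$h else h
  n <- if (is.null(n)) g$n else n
  stopifnot(m >= 0, m <= 1, h >= 0, h <= 1, n >= 0, n <= 1)
  structure(list(U = U, m = m, h = h, n = n), class = "membrane_state")
}

#' Ionic membrane currents
#'
#' @param state A [membrane_state()].
#' @param params A [neuron_params()].
#' @return Named vector of current densities (uA cm^-2): `I_Na`, `I_K`,
#'   `I_L`. Outward (hyperpolarising at positive driving force) currents are
#'   positive.
#' @examples
#' s <- membrane_state(-65)
#' p <- neuron_params()
#' ionic_currents(membrane_state(p$E_L), p)["I_L"] # zero at reversal
#' @export
ionic_currents <- function(state, params) {
  c(I_Na = params$gbar_Na * state$m^3 * state$h * (state$U - params$E_Na),
    I_K = params$gbar_K * state$n^4 * (state$U - params$E_K),
    I_L = params$g_L * (state$U - params$E_L))
}

hh_derivs <- function(state, I_ext, params) {
  ion <- ionic_currents(state, params)
  r <- gating_rates(state$U)
  list(U = (I_ext - sum(ion)) / params$C_MN,
       m = r$alpha_m * (1 - state$m) - r$beta_m * state$m,
       h = r$alpha_h * (1 - state$h) - r$beta_h * state$h,
       n = r$alpha_n * (1 - state$n) - r$beta_n * state$n)
}

#' One Heun (explicit second-order Runge-Kutta) integration step
#'
#' Reference single-step implementation of the fixed-step scheme used by
#' [simulate_mn()]; the compiled simulation core performs the identical
#' update. Additive voltage noise, when requested, is applied to the
#' membrane potential after the update.
#'
#' @param state A [membrane_state()].
#' @param I_ext_fn Function `(t, U) ->` external current density
#'   (uA cm^-2); evaluated at both Heun stages with the stage's own
#'   membrane potential, so rectifying synaptic currents see the
#'   instantaneous postsynaptic voltage.
#' @param t Current time (ms).
#' @param dt Step (ms), within the validated range `[0.005, 0.02]`.
#' @param params A [neuron_params()].
#' @param noise Voltage perturbation added to `U` after the update (mV).
#' @return The updated [membrane_state()].
#' @export
step_heun <- function(state, I_ext_fn, t, dt, params, noise = 0) {
  if (dt < 0.005 - 1e-12 || dt > 0.02 + 1e-12)
    stop("dt must lie in the validated range [0.005, 0.02] ms")
  if (!all(is.finite(c(state$U, state$m, state$h, state$n))))
    stop("non-finite membrane state")
  k1 <- hh_derivs(state, I_ext_fn(t, state$U), params)
  pred <- list(U = state$U + dt * k1$U, m = state$m + dt * k1$m,
               h = state$h + dt * k1$h, n = state$n + dt * k1$n)
  k2 <- hh_derivs(pred, I_ext_fn(t + dt, pred$U), params)
  clamp01 <- function(x) pmin(1, pmax(0, x))
  structure(list(U = state$U + dt / 2 * (k1$U + k2$U) + noise,
                 m = clamp01(state$m + dt / 2 * (k1$m + k2$m)),
                 h = clamp01(state$h + dt / 2 * (k1$h + k2$h)),
                 n = clamp01(state$n + dt / 2 * (k1$n + k2$n))),
            class = "membrane_state")
}

# allocation-free steady-state gates and resting potential, for inner
# optimisation loops (identical math to steady_gates()/resting_state())
fast_gates <- function(U) {
  xm <- U + 40
  am <- if (abs(xm) < 1e-7) 1 else 0.1 * xm / (1 - exp(-xm / 10))
  bm <- 4 * exp(-(U + 65) / 18)
  ah <- 0.07 * exp(-(U + 65) / 20)
  bh <- 1 / (1 + exp(-(U + 35) / 10))
  xn <- U + 55
  an <- if (abs(xn) < 1e-7) 0.1 else 0.01 * xn / (1 - exp(-xn / 10))
  bn <- 0.125 * exp(-(U + 65) / 80)
  c(m = am / (am + bm), h = ah / (ah + bh), n = an / (an + bn))
}

fast_rest <- function(params, interval = c(-90, -35)) {
  f <- function(U) {
    g <- fast_gates(U)
    -(params$gbar_Na * g[["m"]]^3 * g[["h"]] * (U - params$E_Na) +
        params$gbar_K * g[["n"]]^4 * (U - params$E_K) +
        params$g_L * (U - params$E_L))
  }
  stats::uniroot(f, interval = interval, tol = 1e-9)$root
}

#' Resting state of the model cell
#'
#' Finds the fixed point of the membrane equation with all synaptic input
#' silenced (root of the summed ionic currents, gates at steady state).
#' Simulations start from this state.
#'
#' @param params A [neuron_params()].
#' @param interval Search interval for the resting potential (mV).
#' @return A [membrane_state()] at the resting potential.
#' @export
resting_state <- function(params, interval = c(-90, -35)) {
  f <- function(U) -sum(ionic_currents(membrane_state(U), params))
  root <- stats::uniroot(f, interval = interval, tol = 1e-10)
  membrane_state(root$root)
}

#' Simulate the model motoneuron
#'
#' Integrates the Hodgkin-Huxley membrane equation of the model cell with
#' the fixed-step Heun scheme, driven by rectifying electrical-synapse
#' currents from sensilla volleys and/or a graded visual-interneuron signal,
#' plus an optional directly injected current.
#'
#' The run starts from the cell's resting state (synapses silenced) unless
#' `init` is given. With `sigma_noise > 0` a Gaussian voltage perturbation
#' of per-step SD `sigma_noise * sqrt(dt / 0.01)` is added to the membrane
#' potential after every step; the run is reproducible when
#' `config$rng_seed` is set.
#'
#' @param neuron A [neuron_params()].
#' @param synapse A [synapse_params()].
#' @param volley A [volley_spec()], or `NULL` for no sensilla input.
#' @param visual A [visual_signal()], or `NULL` for no visual input.
#' @param config A [sim_config()].
#' @param waveform A [waveform_template()] for the sensilla spike shape.
#' @param I_inj Optional injected current density: either a vector of
#'   length `n_steps + 1` on the time grid or a function of time (ms).
#' @param record_gates Keep the gating-variable traces?
#' @param init Optional [membrane_state()] initial condition.
#' @return An object of class `mn_sim`: list with `time`, `U`, optionally
#'   `m`, `h`, `n`, the resting potential `rest`, the stroke `period`, and
#'   the input objects.
#' @examples
#' cfg <- sim_config(duration = 50)
#' sim <- simulate_mn(volley = volley_spec(n_haltere = 55, n_wing = 55),
#'                    visual = visual_signal("constant", U_base = -35),
#'                    config = cfg)
#' range(sim$U)
#' @export
simulate_mn <- function(neuron = neuron_params(), synapse = synapse_params(),
                        volley = NULL, visual = NULL,
                        config = sim_config(), waveform = waveform_template(),
                        I_inj = NULL, record_gates = FALSE, init = NULL) {
  stopifnot(inherits(neuron, "neuron_params"), inherits(synapse, "synapse_params"),
            inherits(config, "sim_config"))
  dt <- config$dt
  n_steps <- round(config$duration / dt)
  time <- seq(0, by = dt, length.out = n_steps + 1)

  if (!is.null(volley)) {
    prof <- drive_profiles(volley, waveform, dt)
    halt <- prof$haltere
    wing <- prof$wing
    period <- volley$period
  } else {
    halt <- matrix(numeric(0), nrow = 1, ncol = 0)
    wing <- matrix(numeric(0), nrow = 1, ncol = 0)
    period <- 10
  }

  if (!is.null(visual)) {
    u_in <- visual_trace(visual, config$duration, dt)
    g_ins <- synapse$g_INs
  } else {
    u_in <- 0
    g_ins <- 0
  }

  inj <- numeric(0)
  if (!is.null(I_inj)) {
    inj <- if (is.function(I_inj)) I_inj(time) else I_inj
    if (length(inj) != n_steps + 1)
      stop("I_inj must supply n_steps + 1 samples")
  }

  if (is.null(init)) init <- resting_state(neuron)
  noise_step <- config$sigma_noise * sqrt(dt / 0.01)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  res <- .hh_sim_cpp(unclass(neuron), dt, n_steps, halt, wing,
                     synapse$g_H, synapse$g_W, u_in, g_ins, inj,
                     init$U, init$m, init$h, init$n,
                     noise_step, record_gates)

  out <- list(time = time, U = res$U, rest = resting_state(neuron)$U,
              period = period, neuron = neuron, synapse = synapse,
              volley = volley, visual = visual, config = config,
              waveform = waveform)
  if (record_gates) {
    out$m <- res$m
    out$h <- res$h
    out$n <- res$n
  }
  structure(out, class = "mn_sim")
}

#' @export
print.mn_sim <- function(x, ...) {
  cat("Model motoneuron simulation\n")
  cat(sprintf("  duration %.6g ms at dt = %g ms; rest = %.2f mV\n",
              x$config$duration, x$config$dt, x$rest))
  cat(sprintf("  membrane potential range [%.2f, %.2f] mV\n",
              min(x$U), max(x$U)))
  invisible(x)
}
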