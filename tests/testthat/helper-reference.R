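# Independent pure-R reference integrator: steps the membrane equation with
# step_heun() and the R-level synaptic current, mirroring what the compiled
# core computes. Only used on short traces.
r_reference_sim <- function(neuron = neuron_params(),
                            synapse = synapse_params(),
                            volley = NULL, visual_u = NULL,
                            duration = 5, dt = 0.01,
                            waveform = waveform_template()) {
  prof <- if (!is.null(volley)) drive_profiles(volley, waveform, dt)
  n_steps <- round(duration / dt)
  S <- if (!is.null(prof)) prof$S else 1L
  i_ext <- function(t, u) {
    k <- (round(t / dt) %% S) + 1
    uh <- if (!is.null(prof) && ncol(prof$haltere) > 0) prof$haltere[k, ] else numeric(0)
    uw <- if (!is.null(prof) && ncol(prof$wing) > 0) prof$wing[k, ] else numeric(0)
    total_external_current(u, uh, uw, visual_u, synapse)
  }
  st <- resting_state(neuron)
  U <- numeric(n_steps + 1)
  U[1] <- st$U
  for (k in seq_len(n_steps)) {
    st <- step_heun(st, i_ext, (k - 1) * dt, dt, neuron)
    U[k + 1] <- st$U
  }
  U
}

# Synthetic spike train with the spike_train attributes, for exercising the
# locking classifier without a simulation.
make_train <- function(times, period = 10, rest = -55) {
  structure(data.frame(time = times,
                       phase = (times %% period) / period * 100,
                       amplitude = rep(50, length(times))),
            period = period, rest = rest,
            class = c("spike_train", "data.frame"))
}
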