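---
title: "A conductance-based model of spike-phase control in the fly wing-steering motoneuron MN.b1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of spike-phase control in the fly wing-steering motoneuron MN.b1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnb1sim)
```

## The biological problem

Flies beat their wings roughly every 10 ms, and the mechanical power of a
wing-steering muscle depends sharply on *when* within the stroke cycle its
motoneuron fires. The first basalare muscle M.b1 is innervated by a single
motoneuron, MN.b1, which receives two very different kinds of input:

* **Campaniform sensilla** on the wing and haltere fire one precisely
  phase-locked action potential per stroke cycle, arriving as a *volley* of
  spikes through rectifying electrical synapses (gap junctions). We model
  110 sensilla per nerve, 220 in total.
* **Descending visual interneurons** deliver a graded (non-spiking)
  potential, `U_IN`, in the range -40 to -30 mV, through a lumped
  rectifying electrical junction.

This package implements a single-compartment Hodgkin-Huxley model of MN.b1
driven by these two pathways, together with the analysis protocols
(mode-locking classification, phase maps, step and sinusoid responses,
noise runs, refractory measurement, gating scenarios) and the
parameter-estimation pipeline that ties the passive membrane and junction
conductances to single-sensillum EPSP traces.

## The membrane model

The membrane potential follows

$$C_\mathrm{MN}\,\frac{dU_\mathrm{MN}}{dt} =
  I_\mathrm{ext} - \bar g_\mathrm{Na} m^3 h\,(U_\mathrm{MN}-E_\mathrm{Na})
  - \bar g_\mathrm{K} n^4\,(U_\mathrm{MN}-E_\mathrm{K})
  - g_L\,(U_\mathrm{MN}-E_L),$$

with the gating variables $m,h,n$ obeying the classical squid-axon rate
equations in the modern convention (rest near -65 mV). The external current
is the sum of rectified gap-junction terms,

$$I_\mathrm{ext} = \sum_i g_H\,[U_{CS,i} - U_\mathrm{MN}]^+ +
  \sum_j g_W\,[U_{CS,j} - U_\mathrm{MN}]^+ +
  g_\mathrm{INs}\,[U_\mathrm{IN} - U_\mathrm{MN}]^+, $$

where $[x]^+ = \max(x, 0)$: current flows only from the sensory side into
the motoneuron, so all synaptic input is excitatory and the motoneuron
never drives its afferents. Rectification is applied against the
*instantaneous* postsynaptic potential, so the junctions shut transiently
during the spike upstroke.

### Parameters and defaults

| Parameter | Default | Unit | Origin |
|---|---|---|---|
| `C_MN` | 1 | uF cm^-2 | squid-axon value (not constrained by recordings) |
| `gbar_Na` | 165 | mS cm^-2 | calibrated to the measured spike height (see below) |
| `gbar_K` | 36 | mS cm^-2 | squid-axon value |
| `g_L` | 5.84 | mS cm^-2 | fitted to the single-sensillum EPSP |
| `E_L` | -52.26 | mV | fitted to the single-sensillum EPSP |
| `E_Na`, `E_K` | +50, -77 | mV | squid-axon values |
| `g_H` | 0.16 | mS cm^-2 | fitted to the single-sensillum EPSP |
| `g_W` | `g_H / 2` | mS cm^-2 | wing responses are about half the haltere ones |
| `g_INs` | 1.0 | mS cm^-2 | total visual-interneuron junction conductance |

The fitted leak is ~20x the squid value, which makes the model cell far
less excitable than a textbook Hodgkin-Huxley neuron; with the visual
pathway silenced the fixed point sits near -55.7 mV, and the computed
resting state is the initial condition of every run.

## Synthetic inputs: what they emulate and what they do not

All inputs are generated in code; the package bundles no recordings.

**Sensilla volleys.** Each active sensillum fires once per 10 ms stroke
cycle at a fixed within-cycle time. Haltere spike times are spread around
the mean volley phase (25 % cycle) with standard deviation `sigma`; the
wing volley repeats the same structure `tau` = 0.625 ms later (mean phase
31.25 %). By default the per-sensillum times are deterministic Gaussian
quantiles at $(i-0.5)/n$, which makes the drive strictly periodic so that
locking thresholds are exactly reproducible; seeded random placement is
available for robustness studies. "x % active sensilla" always means x %
of the 220 total, split equally, with the odd sensillum going to the
haltere nerve. Counts are held constant across cycles; cycle-to-cycle
variation in the number of active sensilla, as real flies likely produce,
is not modelled. Sensilla membrane noise is likewise not modelled — noise
enters only on the motoneuron membrane.

**The sensilla spike waveform.** The presynaptic action-potential shape is
a smooth template: raised-cosine rise, exponential decay, tapered to reach
rest exactly at the end of its support, with rest -65 mV and amplitude
50 mV. Its time scale is the one genuinely open quantity of the whole
model, and it matters: the per-spike charge it carries sets every
volley-driven threshold. Two anchors compete for it:

* the *measured single-sensillum EPSP* (~0.5 mV peak). Because the fitted
  membrane is very fast (time constant ~0.13 ms), the EPSP peak tracks the
  instantaneous synaptic current almost statically; matching a ~0.45 mV
  peak with `g_H` = 0.16 forces a pulse so brief (~0.65 ms support) that
  sensilla volleys carry too little charge to entrain the cell at all —
  under that template the model never reaches 1:1 locking at any active
  fraction, contradicting every published locking result.
* the *measured duration of extracellular sensilla potentials* (~1.5 ms),
  which is what the original study rescaled its digitized waveform to; the
  junction conductance was then *fitted* to the EPSP with the waveform
  held fixed.

We follow the second anchor: the default template is frozen at the
physiological duration (rise 0.3 ms, decay 0.4 ms, support 1.5 ms) with
the fitted `g_H` = 0.16. The price, stated openly: the model's own
single-sensillum EPSP peaks near 0.67 mV rather than ~0.5 mV, and the
quantities that inherit the waveform's uncertainty (locking thresholds,
steady phases, the operating point of the visual phase-control
experiments) shift relative to the published values — the acceptance suite
measures exactly how far. `calibrate_waveform()` implements the
peak-matching alternative and documents its trade-off.

**Visual signals.** Constant, step and sinusoidal `U_IN` traces between
-40 and -30 mV, the range of graded interneuron potentials during
vision-guided flight.

**EPSP surrogates.** The fitting pipeline is exercised on synthetic traces
(`epsp_surrogate()`): the forward-simulated electrical EPSP plus an
exponential-pulse "chemical" component. These are labelled synthetic
throughout; passing the round-trip tests shows the estimators are
consistent with the package's own forward model, not that they would
recover parameters from a real recording with unmodelled noise sources.

## Numerical scheme

Integration uses an explicit second-order Runge-Kutta (Heun) scheme at a
fixed step of 0.01 ms (validated range 0.005-0.02 ms; the suite checks
that spike counts are unchanged and spike times move by far less than 1 %
of a cycle when the step is halved). The scheme is deliberately fixed-step
to mirror the published integrator. Gating variables are clamped to
[0, 1] after each update, a guard against the tiny overshoots an explicit
scheme can produce. The per-cycle drive is precomputed once on the cycle
grid and indexed modulo the stroke period, which is exact because the
drive is strictly periodic.

**Membrane-voltage noise** is an additive Gaussian perturbation applied to
`U_MN` after each update. The published description specifies the noise SD
but not its time-step convention; we interpret `sigma_noise` as the
per-step kick at the reference step 0.01 ms and scale it by
`sqrt(dt/0.01)` at other steps so that trace statistics are step-size
invariant. An alternative reading — that the quoted SDs describe the
*stationary* voltage fluctuation, which would make the per-step kick
several times smaller — would scale down all noise-driven phase jitter by
a similar factor; the acceptance suite reports the jitter this convention
produces.

**Spike detection** registers an upward crossing of -40 mV (the model
cell's threshold), timestamps the spike at the subsequent voltage maximum
and then ignores crossings for 1 ms. Spike phase is the peak time modulo
the stroke period; the classifier's phases are therefore peak-based, which
may differ from threshold-based phases by a small systematic offset.

**Locking classification** searches for the smallest pattern length
`q <= 8` such that the per-cycle spike-count sequence is `q`-periodic and
each within-pattern slot keeps a circular phase SD below 1 % cycle
(deterministic runs achieve far less). No admissible `q` means irregular
firing; no spikes means quiescence. Steady-state analyses discard the
first 50 cycles and analyse the next 100 (500 pooled cycles for noise
statistics); step transients count as settled after 5 consecutive cycles
within 0.5 % of the final mean.

**Refractory protocol.** The paired-pulse stimulus is two identical 0.2 ms
current pulses at 5x the single-pulse threshold amplitude (found by
bisection). The 5x factor puts the measurement in the regime where the
absolute refractory interval no longer depends on stimulus strength
(between 5x and 8x it changes by only a few percent); weaker pulses
measure an "effective" refractory period that can be several times longer.
The relative refractory period is the shortest interval at which the
second spike recovers the isolated spike amplitude within 2 %. Interval
searches run by bisection at the integration-step resolution, with an
exhaustive linear scan available as a cross-check.

**EPSP decomposition.** The classical procedure fits an exponential pulse
to the slow chemical component and subtracts it. A bare two-pulse fit is
biased here because the electrical EPSP is not a positive pulse: gating
dynamics give it a small undershoot after the fast peak, comparable in
size to the chemical hump. `split_components()` therefore represents the
electrical part by the forward-simulated EPSP itself (fitted over
`g_H`, `g_L`, `E_L`) and alternates it with the chemical-pulse fit before
a joint polish; the returned electrical component is still
`trace - chemical`, so the two components sum to the data. A trace that a
single exponential pulse explains with R^2 > 0.999 is classified as
purely chemical outright.

**Multi-start fitting.** `fit_passive()` minimises the mean squared error
between the forward-simulated single-sensillum EPSP and the trace over
(`g_L`, `E_L`, `g_H`), using derivative-free simplex minimisation from 100
random starts drawn uniformly in `g_L` in [0.5, 20], `E_L` in [-70, -40],
`g_H` in [0.01, 1] (conductances are optimised on the log scale, with a
penalty wall well outside the physical range where the explicit integrator
would destabilise). On clean surrogates the great majority of starts reach
the global basin and the recovery is exact to numerical precision.

**Exponential fatigue fit.** Chemical transmission fades over strokes;
`fatigue_fit()` performs a least-squares fit of `y = a * exp(b*x)` and
reports `log(0.1)/b`, the stroke count at which transmission falls below
10 % of its initial value (about 128 strokes, i.e. ~1.3 s of flight, at
the published decay rate; the fit on an exact exponential is recovered to
machine precision). The printed form of that fit in the source literature
(`y = a^(b*x)`) is read as `a*exp(b*x)` — the only reading that reproduces
its own quoted stroke count.

## Experiment suite and problem sizes

The bundled protocols reproduce the study's in-silico experiments at desk
scale: sensilla sweeps in single-pair steps; the two-dimensional phase map
over volley width (0.1-2.5 ms in 0.1 ms steps) and active fraction
(30-100 % in two-pair steps), each cell simulated for 150 cycles at two
visual levels (~2,000 simulations, a few minutes on one CPU); visual step
responses; sinusoidal frequency responses (five stimulus periods after a
1 s settle, measured on the last three); noise runs pooling 500 cycles
across five seeds; and the three gating scenarios (mode switch at
physiological parameters; reduced leak `g_L` = 3.6 with 15 % sensilla;
raised sodium conductance 240 mS cm^-2 with no sensilla). Named parameter
bundles for all of these are in `preset()`.

## Known limitations

* Single compartment; no A-type currents, no temperature dependence, no
  chemical synaptic transmission in the dynamic model (only the fatigue
  *fit* is implemented), no contralateral haltere.
* The sensilla waveform is a parametric stand-in for an unpublished
  digitized recording; every sensilla-count threshold inherits its
  uncertainty. With the physiological-duration default the locking
  cascade (quiescence, 1:2, 2:3-like patterns, 1:1) and visual gating all
  reproduce qualitatively, but the thresholds sit at lower active
  fractions than the published ones, and the visual phase-control band
  sits closer to the 1:1 border than the published operating point. In
  particular, the 42 %/0.2 ms preset lies deep inside this model's 1:1
  region, where visual depolarisation barely moves the spike phase; the
  published phase-control numbers arise just inside the border.
* Spike amplitude in this parameterisation is nearly all-or-none: the
  graded-amplitude regime through which the sodium-conductance calibration
  passes is a jump here, so `calibrate_gna()` returns the location of that
  jump rather than a point on a smooth amplitude curve.
* The noise convention (per-step kick vs stationary SD) is genuinely
  ambiguous in the source description; see above.
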