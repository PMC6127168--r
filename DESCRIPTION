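Package: mnb1sim
Title: Spike-Phase Control in a Fly Wing-Steering Motoneuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) simulation of spike initiation
    in the blowfly wing-steering motoneuron MN.b1. The model cell is driven
    through rectifying electrical synapses by per-stroke volleys of campaniform
    sensilla spikes from wing and haltere nerves and by graded potentials of
    descending visual interneurons. The package provides the fixed-step Heun
    integrator with additive membrane-voltage noise, generators for sensilla
    spike volleys and visual signals, spike detection and p:q mode-locking
    classification, an in-silico experiment suite (sensilla sweeps,
    two-dimensional phase maps, visual step and sinusoid responses, noise runs,
    refractory measurement, visual-gating scenarios), and a parameter-fitting
    pipeline that estimates passive membrane and gap-junction parameters from
    single-sensillum EPSP traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Config/testthat/start-first: hh_core, synapses, sensory_inputs, spikes,
    protocols, fitting, io
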