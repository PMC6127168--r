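#' Current through one rectifying electrical junction
#'
#' All synapses onto the model cell are rectifying gap junctions: current
#' flows only from the sensory side to the motoneuron, i.e. when the
#' presynaptic potential exceeds the instantaneous postsynaptic potential.
#' The motoneuron therefore never drives its afferents, and all synaptic
#' input is excitatory.
#'
#' @param U_pre Presynaptic potential (mV); vectorised.
#' @param U_post Postsynaptic (motoneuron) potential (mV).
#' @param g Junction conductance (mS cm^-2).
#' @return Current density (uA cm^-2): `g * (U_pre - U_post)` where
#'   `U_pre > U_post`, else 0.
#' @examples
#' rectified_current(-15, -65, 0.16) # peak sensilla spike against rest
#' rectified_current(-70, -60, 0.16) # hyperpolarised input passes nothing
#' @export
rectified_current <- function(U_pre, U_post, g) {
  stopifnot(all(is.finite(U_pre)), all(is.finite(U_post)), g >= 0)
  g * pmax(U_pre - U_post, 0)
}

#' Total external current into the motoneuron
#'
#' Sum of the rectified gap-junction currents from every haltere sensillum,
#' every wing sensillum and the lumped visual-interneuron pathway, all
#' evaluated against the same instantaneous motoneuron potential. This is
#' the reference (pure R) form of the drive term used at every integration
#' stage by the compiled core.
#'
#' @param U_MN Motoneuron membrane potential (mV).
#' @param U_halt,U_wing Vectors of presynaptic sensilla potentials (mV).
#' @param U_IN Visual-interneuron potential (mV), or `NULL` for none.
#' @param synapse A [synapse_params()].
#' @return Total current density (uA cm^-2), always `>= 0`.
#' @export
total_external_current <- function(U_MN, U_halt = numeric(0),
                                   U_wing = numeric(0), U_IN = NULL,
                                   synapse = synapse_params()) {
  out <- sum(rectified_current(U_halt, U_MN, synapse$g_H)) +
    sum(rectified_current(U_wing, U_MN, synapse$g_W))
  if (!is.null(U_IN))
    out <- out + rectified_current(U_IN, U_MN, synapse$g_INs)
  out
}
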