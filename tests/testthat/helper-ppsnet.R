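# deterministic noise-free stimulus helpers used across test files

quiet_stim <- function(modality, center, ...) {
  stimulus_spec(modality, center, sigma = 1.5, noise_frac = 0, ...)
}

# steady-state multisensory response to a noise-free unimodal sound at a
# given hand-to-sound distance
ms_response_at <- function(net, d) {
  hand_edge <- net$params$hand$x[2]
  sim <- simulate_network(reset_network(net),
                          quiet_stim("auditory", c(hand_edge + d, 5)))
  sim$y_m_final
}

# a network whose recurrent pathways are silenced (no laterals, no
# feedback, no feedforward drive): isolates single-neuron dynamics
isolated_net <- function() {
  p <- network_params(
    tactile = list(lateral = list(L_ex = 0, L_in = 0)),
    auditory = list(lateral = list(L_ex = 0, L_in = 0)),
    synapses = list(feedback_t = 0, feedback_a = 0))
  net <- build_network(p)
  net$W_t[] <- 0
  net$W_a[] <- 0
  net
}
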