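#' Hebbian update of the feedforward synapses
#'
#' Per synapse j:
#' `dW_j = dt * y_post * [gamma_pot * y_pre_j * (W_max - W_j)
#' - gamma_forget * W_j * (1 - y_pre_j)]`.
#' Correlated pre/post activity potentiates up to the saturation ceiling
#' `W_max`; a silent presynaptic neuron facing an active postsynaptic unit
#' slowly loses weight (forgetting). Weights stay in `[0, W_max]` for any
#' admissible activities.
#'
#' @param W list with matrices `W_t`, `W_a`.
#' @param pre_t,pre_a presynaptic activity maps in `[0, 1]`.
#' @param post multisensory (postsynaptic) activity, scalar in `[0, 1]`.
#' @param p a [hebb_params()].
#' @param dt time step, ms.
#' @return list with updated `W_t`, `W_a`.
#' @export
hebbian_update <- function(W, pre_t, pre_a, post, p, dt) {
  W$W_t <- W$W_t + dt * post *
    (p$gamma_pot * pre_t * (p$W_max - W$W_t) -
       p$gamma_forget * W$W_t * (1 - pre_t))
  W$W_a <- W$W_a + dt * post *
    (p$gamma_pot * pre_a * (p$W_max - W$W_a) -
       p$gamma_forget * W$W_a * (1 - pre_a))
  W$W_t <- pmin(pmax(W$W_t, 0), p$W_max)
  W$W_a <- pmin(pmax(W$W_a, 0), p$W_max)
  W
}

#' Audio-tactile training protocol
#'
#' Describes the stimulation schedule that emulates tool use at the sensory
#' level: a tactile stimulus on the hand paired with an auditory stimulus
#' far from the hand (default (100, 5) cm, i.e. 80 cm from the hand), for
#' `n_presentations` presentations. In the synchronous mode both stimuli
#' share onset and duration; in the asynchronous mode every presentation
#' draws a signed, non-null stimulus onset asynchrony (SOA) from
#' `soa_range`, so the stimuli are randomly partially superimposed or
#' completely separated.
#'
#' @param n_presentations number of paired presentations (default 30).
#' @param soa_mode `"synchronous"` or `"asynchronous"`.
#' @param duration stimulus duration, ms (both modalities).
#' @param soa_range absolute-SOA range, ms, for the asynchronous mode; the
#'   sign is drawn uniformly.
#' @param tactile_center,auditory_center stimulus positions, cm.
#' @param stim_sigma,intensity,noise_frac stimulus shape and noise (both
#'   modalities; the two stimuli have the same spatial extension).
#' @return a `training_protocol` object.
#' @export
training_protocol <- function(n_presentations = 30,
                              soa_mode = c("synchronous", "asynchronous"),
                              duration = 300, soa_range = c(280, 880),
                              tactile_center = c(10, 5),
                              auditory_center = c(100, 5),
                              stim_sigma = 1.5, intensity = 10,
                              noise_frac = 0.2) {
  soa_mode <- match.arg(soa_mode)
  if (n_presentations < 0) stop("configuration error: n_presentations < 0")
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (soa_mode == "asynchronous" &&
      (any(soa_range <= 0) || soa_range[2] <= soa_range[1]))
    stop("configuration error: soa_range must be an increasing positive interval")
  structure(list(n_presentations = n_presentations, soa_mode = soa_mode,
                 duration = duration, soa_range = soa_range,
                 tactile_center = tactile_center,
                 auditory_center = auditory_center,
                 stim_sigma = stim_sigma, intensity = intensity,
                 noise_frac = noise_frac),
            class = "training_protocol")
}

#' Draw a stimulus onset asynchrony for an asynchronous presentation
#'
#' Signed SOA (auditory onset minus tactile onset): magnitude uniform on
#' `soa_range`, sign uniform. Never zero; both partial-overlap
#' (|SOA| < duration) and fully separated draws occur with nonzero
#' probability under the default range.
#'
#' @param protocol a [training_protocol()] in asynchronous mode.
#' @return SOA in ms.
#' @export
sample_soa <- function(protocol) {
  if (protocol$soa_mode != "asynchronous")
    stop("protocol error: SOA is only drawn in asynchronous mode")
  mag <- stats::runif(1, protocol$soa_range[1], protocol$soa_range[2])
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  sgn * mag
}

#' Run an audio-tactile training phase
#'
#' Presents the protocol's stimulus pairs to the network, applying the
#' Hebbian rule to the feedforward synapses at every integration step while
#' stimuli are on. The network starts each presentation from rest (no
#' carryover across the inter-presentation gap). Feedback synapses are not
#' plastic. After synchronous training the auditory feedforward weights in
#' the neighborhood of the trained far-space location approach saturation;
#' after asynchronous training they change only marginally, because pre-
#' and postsynaptic activity rarely coincide.
#'
#' @param net a `pps_network`.
#' @param protocol a [training_protocol()].
#' @param hebb a [hebb_params()]; defaults to [hebb_params()] with the
#'   network's `W_max`.
#' @return the trained network.
#' @export
run_training <- function(net, protocol = training_protocol(), hebb = NULL) {
  if (is.null(hebb)) hebb <- hebb_params(W_max = net$params$synapses$W_max)
  n <- protocol$n_presentations
  if (n == 0) return(net)
  for (i in seq_len(n)) {
    soa <- if (protocol$soa_mode == "synchronous") 0 else sample_soa(protocol)
    t_on <- max(0, -soa)  # tactile onset; auditory leads when soa < 0
    a_on <- max(0, soa)
    stims <- list(
      stimulus_spec("tactile", protocol$tactile_center,
                    sigma = protocol$stim_sigma,
                    intensity = protocol$intensity,
                    noise_frac = protocol$noise_frac,
                    onset = t_on, duration = protocol$duration),
      stimulus_spec("auditory", protocol$auditory_center,
                    sigma = protocol$stim_sigma,
                    intensity = protocol$intensity,
                    noise_frac = protocol$noise_frac,
                    onset = a_on, duration = protocol$duration)
    )
    window <- max(t_on, a_on) + protocol$duration
    net <- reset_network(net)
    sim <- simulate_network(net, stims, duration = window, hebb = hebb)
    net <- sim$net
  }
  net <- reset_network(net)
  net$trained <- TRUE
  net
}
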