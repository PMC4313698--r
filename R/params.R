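#' Default network parameterization
#'
#' Builds the full parameter set of the audio-tactile peripersonal-space
#' network: geometry and dynamics of the two unisensory grids, the
#' multisensory unit, the Mexican-hat lateral kernels, the feedforward and
#' feedback synapse scales, the intensity-noise model and the integrator
#' settings. All values are in cm, ms and dimensionless input units.
#'
#' The defaults encode the reference model configuration: a 20 x 10 cm
#' tactile sheet sampled at 0.5 cm (41 x 21 neurons, receptive-field sd
#' 0.5 cm) and a 200 x 30 cm auditory space sampled at 2 cm (101 x 16
#' neurons, receptive-field sd 6 cm, reflecting the coarse spatial
#' resolution of hearing). The hand occupies [0, 20] x [0, 10] cm of the
#' auditory frame, so the distance of a sound at (x, y) from the hand is
#' the Euclidean distance to that rectangle. Basal auditory feedforward
#' weights are maximal on and near the hand and fall off with that distance
#' along a logistic edge (`wa_center`, `wa_width`), which places the
#' untrained multisensory auditory receptive-field boundary in the 50-60 cm
#' range.
#'
#' @param ... named overrides, nested lists merged over the defaults, e.g.
#'   `network_params(ms = list(theta = 1.2))`.
#' @return an object of class `pps_params` (a nested list).
#' @examples
#' p <- network_params()
#' p$auditory$rf_sigma
#' p2 <- network_params(noise = list(intensity_frac = 0))
#' @export
network_params <- function(...) {
  p <- list(
    tactile = list(
      extent   = c(20, 10),   # cm
      spacing  = 0.5,         # cm
      rf_sigma = 0.5,         # cm
      tau      = 20,          # ms
      slope    = 2,
      theta    = 4,
      lateral  = list(L_ex = 0.15, sigma_ex = 1, L_in = 0.05, sigma_in = 3)
    ),
    auditory = list(
      extent   = c(200, 30),
      spacing  = 2,
      rf_sigma = 6,
      tau      = 20,
      slope    = 2,
      theta    = 4,
      lateral  = list(L_ex = 0.12, sigma_ex = 3, L_in = 0.015, sigma_in = 10)
    ),
    ms = list(tau = 40, slope = 3, theta = 2),
    synapses = list(
      W_max      = 0.1,
      wa_center  = 57,   # cm; distance of the basal auditory-weight falloff
      wa_width   = 6,    # cm; steepness of that falloff
      feedback_t = 1.5,  # peak feedback strength onto tactile neurons
      feedback_a = 1.5   # peak feedback strength onto auditory neurons
    ),
    hand = list(x = c(0, 20), y = c(0, 10)),
    stimulus = list(intensity = 10, sigma = 1.5),  # default external stimulus
    noise = list(intensity_frac = 0.2),
    integration = list(dt = 0.5, ss_tol = 1e-5, max_duration = 1000)
  )
  p <- modify_list_deep(p, list(...))
  validate_params(p)
  class(p) <- "pps_params"
  p
}

# recursive version of utils::modifyList keeping unnamed defaults intact
modify_list_deep <- function(base, over) {
  if (length(over) == 0) return(base)
  stopifnot(is.list(over), !is.null(names(over)))
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

validate_params <- function(p) {
  for (area in c("tactile", "auditory")) {
    a <- p[[area]]
    if (any(a$extent <= 0) || a$spacing <= 0)
      stop("configuration error: non-positive grid geometry for ", area, " area")
    if (a$spacing > min(a$extent))
      stop("configuration error: spacing exceeds extent for ", area, " area")
    if (a$rf_sigma <= 0) stop("configuration error: rf_sigma must be > 0")
    lk <- a$lateral
    if (lk$sigma_in <= lk$sigma_ex)
      stop("configuration error: lateral sigma_in must exceed sigma_ex ",
           "(near excitation, far inhibition)")
    if (a$tau <= 0) stop("configuration error: tau must be > 0")
  }
  if (p$auditory$rf_sigma <= p$tactile$rf_sigma)
    stop("configuration error: auditory RFs must be larger than tactile RFs")
  if (p$synapses$W_max <= 0 || p$synapses$wa_center <= 0 ||
      p$synapses$wa_width <= 0)
    stop("configuration error: synapse scales must be > 0")
  if (p$integration$dt <= 0)
    stop("configuration error: dt must be > 0")
  if (p$integration$dt > min(p$tactile$tau, p$auditory$tau, p$ms$tau) / 5)
    stop("configuration error: dt too large for the neuron time constants ",
         "(stability guard dt <= tau/5)")
  if (p$noise$intensity_frac < 0 || p$noise$intensity_frac >= 1)
    stop("configuration error: intensity_frac must be in [0, 1)")
  invisible(p)
}

#' Hebbian learning-rule parameters
#'
#' Potentiation rate, forgetting rate and saturation ceiling of the
#' Hebbian-like rule applied to the feedforward synapses during training.
#' The defaults are calibrated so that 30 synchronous 300-ms pairings drive
#' the far-space auditory weights essentially to saturation, while the
#' scarce correlated activity under the asynchronous protocol leaves them
#' within a few percent of basal.
#'
#' @param gamma_pot potentiation rate (1/ms per unit pre x post activity).
#' @param gamma_forget forgetting rate (1/ms), acting on active-postsynaptic,
#'   silent-presynaptic synapses.
#' @param W_max saturation value; defaults to the network's feedforward scale.
#' @return an object of class `hebb_params`.
#' @export
hebb_params <- function(gamma_pot = 4e-4, gamma_forget = 1e-6, W_max = 0.1) {
  if (gamma_pot < 0 || gamma_forget < 0 || W_max <= 0)
    stop("configuration error: Hebbian rates must be >= 0 and W_max > 0")
  structure(list(gamma_pot = gamma_pot, gamma_forget = gamma_forget,
                 W_max = W_max), class = "hebb_params")
}
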