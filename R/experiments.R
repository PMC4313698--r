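#' Map the auditory receptive field of the multisensory unit
#'
#' Presents a unimodal auditory stimulus at each hand-to-sound distance,
#' `n_rep` times with independent intensity noise, starting from rest every
#' time, and records the steady-state activation of the multisensory unit.
#'
#' @param net a `pps_network`.
#' @param distances hand-to-sound distances, cm (sound placed at
#'   `x = hand_edge + d`, `y = 5` in the auditory frame).
#' @param n_rep repetitions per distance (default 30).
#' @param intensity,stim_sigma,noise_frac auditory stimulus parameters
#'   (defaults from the network's parameter set).
#' @return a `pps_rfmap`: data.frame `reps` (distance, rep, activation) plus
#'   a `summary` data.frame with mean and SEM per distance.
#' @export
map_auditory_rf <- function(net, distances = seq(0, 140, by = 10), n_rep = 30,
                            intensity = net$params$stimulus$intensity,
                            stim_sigma = net$params$stimulus$sigma,
                            noise_frac = net$params$noise$intensity_frac) {
  hand_edge <- net$params$hand$x[2]
  y_mid <- mean(net$params$hand$y)
  reps <- expand.grid(rep = seq_len(n_rep), distance = distances)[, 2:1]
  reps$activation <- NA_real_
  for (i in seq_len(nrow(reps))) {
    stim <- stimulus_spec("auditory",
                          center = c(hand_edge + reps$distance[i], y_mid),
                          sigma = stim_sigma, intensity = intensity,
                          noise_frac = noise_frac)
    sim <- simulate_network(reset_network(net), stim)
    reps$activation[i] <- sim$y_m_final
  }
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  means <- tapply(reps$activation, reps$distance, mean)
  sems <- tapply(reps$activation, reps$distance, sem)
  out <- list(reps = reps,
              summary = data.frame(distance = as.numeric(names(means)),
                                   mean = as.numeric(means),
                                   sem = as.numeric(sems)))
  class(out) <- "pps_rfmap"
  out
}

#' Receptive-field extent at a fractional threshold
#'
#' Largest tested distance whose mean multisensory activation is at or
#' above `threshold` times the maximum mean activation over distances.
#'
#' @param map a `pps_rfmap` from [map_auditory_rf()].
#' @param threshold fraction of the maximum mean activation (default 0.5).
#' @return distance in cm.
#' @export
rf_extent <- function(map, threshold = 0.5) {
  s <- map$summary
  if (nrow(s) == 0 || max(s$mean) <= 0)
    stop("degenerate input: receptive-field map has no activation")
  max(s$distance[s$mean >= threshold * max(s$mean)])
}

#' Network tactile reaction time for one audio-tactile presentation
#'
#' Presents a tactile stimulus on the hand simultaneously with an auditory
#' stimulus at the given hand-to-sound distance, integrates to steady state
#' and returns the first time at which the aggregate tactile activity (sum
#' over tactile neurons) reaches 90 percent of its final value. A sound
#' inside the multisensory auditory receptive field pre-activates the
#' multisensory unit, whose feedback speeds the tactile rise; a sound
#' outside it leaves the unimodal tactile response unaffected.
#'
#' @param net a `pps_network`.
#' @param sound_distance hand-to-sound distance, cm.
#' @param intensity,stim_sigma,noise_frac stimulus parameters shared by the
#'   two modalities (the stimuli have the same spatial extension).
#' @param rt_fraction fraction of the final aggregate activation defining
#'   the reaction time (default 0.9).
#' @return list with `rt` (ms; linear interpolation between integration
#'   steps) and `censored` (TRUE when no steady state was reached within
#'   the maximum duration).
#' @export
network_rt <- function(net, sound_distance,
                       intensity = net$params$stimulus$intensity,
                       stim_sigma = net$params$stimulus$sigma,
                       noise_frac = net$params$noise$intensity_frac,
                       rt_fraction = 0.9) {
  hand_edge <- net$params$hand$x[2]
  y_mid <- mean(net$params$hand$y)
  tac_center <- c(mean(net$params$hand$x), y_mid)
  stims <- list(
    stimulus_spec("tactile", tac_center, sigma = stim_sigma,
                  intensity = intensity, noise_frac = noise_frac),
    stimulus_spec("auditory", c(hand_edge + sound_distance, y_mid),
                  sigma = stim_sigma, intensity = intensity,
                  noise_frac = noise_frac)
  )
  sim <- simulate_network(reset_network(net), stims)
  final <- sim$tact_sum[length(sim$tact_sum)]
  if (final <= 0) stop("undefined reaction time: zero final tactile activation")
  target <- rt_fraction * final
  i <- which(sim$tact_sum >= target)[1]
  rt <- if (i == 1) sim$time[1] else {
    t0 <- sim$time[i - 1]; a0 <- sim$tact_sum[i - 1]
    t0 + (sim$time[i] - t0) * (target - a0) / (sim$tact_sum[i] - a0)
  }
  list(rt = rt, censored = !sim$converged)
}

#' Reaction-time-versus-distance test battery
#'
#' Runs [network_rt()] at each sound distance, `n_rep` repetitions with
#' independent intensity noise, from a fresh resting state every time.
#' Defaults reproduce the standard battery: 15 distances from 140 cm down
#' to 0 cm in 10-cm steps, 30 repetitions each.
#'
#' @inheritParams network_rt
#' @param distances hand-to-sound distances, cm.
#' @param n_rep repetitions per distance.
#' @return a `pps_rtcurve`: data.frame `reps` (distance, rep, rt, censored)
#'   and `summary` (distance, mean, sem).
#' @export
rt_vs_distance <- function(net, distances = seq(140, 0, by = -10), n_rep = 30,
                           intensity = net$params$stimulus$intensity,
                           stim_sigma = net$params$stimulus$sigma,
                           noise_frac = net$params$noise$intensity_frac) {
  reps <- expand.grid(rep = seq_len(n_rep), distance = distances)[, 2:1]
  reps$rt <- NA_real_; reps$censored <- FALSE
  for (i in seq_len(nrow(reps))) {
    r <- network_rt(net, reps$distance[i], intensity = intensity,
                    stim_sigma = stim_sigma, noise_frac = noise_frac)
    reps$rt[i] <- r$rt; reps$censored[i] <- r$censored
  }
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  means <- tapply(reps$rt, reps$distance, mean)
  sems <- tapply(reps$rt, reps$distance, sem)
  out <- list(reps = reps,
              summary = data.frame(distance = as.numeric(names(means)),
                                   mean = as.numeric(means),
                                   sem = as.numeric(sems)))
  class(out) <- "pps_rtcurve"
  out
}
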