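#' Build an untrained (basal) audio-tactile network
#'
#' Assembles the two unisensory areas, the multisensory unit and all synapse
#' sets from a parameter object. Tactile feedforward weights are uniform at
#' `W_max`; auditory feedforward weights start at `W_max` on the hand and
#' fall off with the distance of each neuron's receptive-field center from
#' the hand along a logistic edge (near-maximal within the basal
#' peripersonal zone, weak beyond it). Feedback weights mirror the basal feedforward
#' arrangement (scaled to `feedback_t` / `feedback_a`) and stay fixed
#' during training.
#'
#' @param params a `pps_params` object from [network_params()].
#' @return an object of class `pps_network`.
#' @examples
#' net <- build_network(network_params())
#' range(net$W_t)  # uniform at W_max
#' @export
build_network <- function(params = network_params()) {
  validate_params(params)
  net <- list(params = params)
  for (area in c("tactile", "auditory")) {
    a <- params[[area]]
    g <- spatial_grid(a$extent, a$spacing)
    lk <- a$lateral
    net[[area]] <- list(
      grid = g,
      # separable difference-of-Gaussians lateral operator
      Gx_ex = axis_gaussian(g$x, lk$sigma_ex),
      Gy_ex = axis_gaussian(g$y, lk$sigma_ex),
      Gx_in = axis_gaussian(g$x, lk$sigma_in),
      Gy_in = axis_gaussian(g$y, lk$sigma_in),
      L_ex = lk$L_ex, L_in = lk$L_in,
      k0 = lk$L_ex - lk$L_in,      # self-connection, removed from the sum
      tau = a$tau, slope = a$slope, theta = a$theta,
      z = matrix(0, g$nx, g$ny)
    )
  }
  s <- params$synapses
  aud <- net$auditory$grid
  dist_hand <- distance_from_hand(aud$X, aud$Y, params$hand)
  dim(dist_hand) <- dim(aud$X)
  net$dist_hand <- dist_hand
  net$W_t <- matrix(s$W_max, net$tactile$grid$nx, net$tactile$grid$ny)
  net$W_a <- s$W_max * stats::plogis(-(dist_hand - s$wa_center) / s$wa_width)
  net$B_t <- s$feedback_t * net$W_t / s$W_max
  net$B_a <- s$feedback_a * net$W_a / s$W_max
  net$ms <- list(z = 0, tau = params$ms$tau, slope = params$ms$slope,
                 theta = params$ms$theta)
  net$trained <- FALSE
  class(net) <- "pps_network"
  net
}

#' @export
print.pps_network <- function(x, ...) {
  cat("Audio-tactile peripersonal-space network\n")
  cat(sprintf("  tactile : %d x %d neurons (%g cm spacing, RF sd %g cm)\n",
              x$tactile$grid$nx, x$tactile$grid$ny,
              x$params$tactile$spacing, x$params$tactile$rf_sigma))
  cat(sprintf("  auditory: %d x %d neurons (%g cm spacing, RF sd %g cm)\n",
              x$auditory$grid$nx, x$auditory$grid$ny,
              x$params$auditory$spacing, x$params$auditory$rf_sigma))
  cat(sprintf("  feedforward W_max %g; auditory falloff at %g cm; %s\n",
              x$params$synapses$W_max, x$params$synapses$wa_center,
              if (x$trained) "trained" else "untrained (basal)"))
  invisible(x)
}

# logistic activation, saturating at 1
activation <- function(z, slope, theta) 1 / (1 + exp(-slope * (z - theta)))

area_activity <- function(area) activation(area$z, area$slope, area$theta)

ms_activity <- function(ms) activation(ms$z, ms$slope, ms$theta)

# lateral input to an area given its current activity matrix
lateral_input <- function(area, Y) {
  area$L_ex * (area$Gx_ex %*% Y %*% area$Gy_ex) -
    area$L_in * (area$Gx_in %*% Y %*% area$Gy_in) -
    area$k0 * Y
}

#' Spatially localized external stimulus
#'
#' @param modality `"tactile"` or `"auditory"`.
#' @param center length-2 (x, y) position in the modality's frame, cm.
#' @param sigma spatial extent (Gaussian sd), cm.
#' @param intensity nominal intensity I0, input units (>= 0).
#' @param noise_frac multiplicative intensity noise half-width a: each
#'   presentation draws I ~ I0 * U(1 - a, 1 + a).
#' @param onset,duration stimulus window, ms (`duration = Inf` keeps the
#'   stimulus on until the end of the simulation).
#' @return a `stimulus_spec` object.
#' @export
stimulus_spec <- function(modality = c("tactile", "auditory"), center, sigma = 1,
                          intensity = 10, noise_frac = 0.2, onset = 0,
                          duration = Inf) {
  modality <- match.arg(modality)
  if (intensity < 0) stop("configuration error: intensity must be >= 0")
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (noise_frac < 0 || noise_frac >= 1)
    stop("configuration error: noise_frac must be in [0, 1)")
  structure(list(modality = modality, center = center, sigma = sigma,
                 intensity = intensity, noise_frac = noise_frac,
                 onset = onset, duration = duration),
            class = "stimulus_spec")
}

#' External input map evoked by a stimulus in its unisensory area
#'
#' Each neuron receives `I * exp(-||c_j - center||^2 / (2 (rf_sigma^2 +
#' sigma^2)))`, the Gaussian stimulus profile filtered by the neuron's
#' receptive field; `I` is drawn once per presentation from the
#' multiplicative noise model. Because auditory receptive fields are much
#' wider than tactile ones, the same physical stimulus extent activates a
#' broader footprint in the auditory map.
#'
#' @param net a `pps_network`.
#' @param stim a [stimulus_spec()].
#' @return matrix of per-neuron external input (nx x ny of the area's grid).
#' @export
unisensory_input <- function(net, stim) {
  area <- net[[stim$modality]]
  rf <- net$params[[stim$modality]]$rf_sigma
  s2 <- rf^2 + stim$sigma^2
  intensity <- stim$intensity
  if (stim$noise_frac > 0)
    intensity <- intensity * stats::runif(1, 1 - stim$noise_frac,
                                          1 + stim$noise_frac)
  g <- area$grid
  intensity * exp(-((g$X - stim$center[1])^2 + (g$Y - stim$center[2])^2) /
                    (2 * s2))
}

#' Advance the network by one Euler step
#'
#' First-order update of `tau dz/dt = -z + u`, `y = phi(z)` for every
#' neuron. Unisensory input `u` sums external input, lateral Mexican-hat
#' input and multisensory feedback; the multisensory unit receives the
#' weighted sums of the two unisensory activities.
#'
#' @param net a `pps_network`.
#' @param E_t,E_a external input matrices (or 0) for the two areas.
#' @param dt time step, ms; must satisfy `dt <= min(tau)/5`.
#' @return list with the updated network (`net`), current activities
#'   (`Y_t`, `Y_a`, `y_m`) and the largest per-ms activity change
#'   (`delta`).
#' @export
step_network <- function(net, E_t = 0, E_a = 0, dt = net$params$integration$dt) {
  if (dt <= 0 || dt > min(net$tactile$tau, net$auditory$tau, net$ms$tau) / 5)
    stop("configuration error: dt must be positive and <= tau/5")
  Y_t <- area_activity(net$tactile)
  Y_a <- area_activity(net$auditory)
  y_m <- ms_activity(net$ms)

  u_t <- E_t + lateral_input(net$tactile, Y_t) + net$B_t * y_m
  u_a <- E_a + lateral_input(net$auditory, Y_a) + net$B_a * y_m
  u_m <- sum(net$W_t * Y_t) + sum(net$W_a * Y_a)

  net$tactile$z  <- net$tactile$z  + dt / net$tactile$tau  * (u_t - net$tactile$z)
  net$auditory$z <- net$auditory$z + dt / net$auditory$tau * (u_a - net$auditory$z)
  net$ms$z       <- net$ms$z       + dt / net$ms$tau       * (u_m - net$ms$z)

  Y_t2 <- area_activity(net$tactile)
  Y_a2 <- area_activity(net$auditory)
  y_m2 <- ms_activity(net$ms)
  delta <- max(max(abs(Y_t2 - Y_t)), max(abs(Y_a2 - Y_a)), abs(y_m2 - y_m)) / dt
  list(net = net, Y_t = Y_t2, Y_a = Y_a2, y_m = y_m2, delta = delta)
}

#' Simulate the network response to a set of stimuli
#'
#' Integrates the network from its current state (rest, unless a previous
#' state is carried over) under the given stimuli. Intensity noise is drawn
#' once per stimulus at entry. The simulation stops early once all stimulus
#' onsets/offsets have passed and the largest per-ms activity change falls
#' below the steady-state tolerance; otherwise it runs to `duration` and
#' the result is flagged as not converged.
#'
#' @param net a `pps_network`.
#' @param stimuli a single [stimulus_spec()] or a list of them.
#' @param duration maximum simulated time, ms (default
#'   `params$integration$max_duration`).
#' @param dt integration step, ms.
#' @param hebb optional [hebb_params()]; when supplied, the feedforward
#'   weights `W_t`, `W_a` are updated by the Hebbian rule at every step
#'   while the stimuli are being presented (used by [run_training()]).
#' @param record `"summary"` (time courses of the multisensory activity and
#'   of the summed tactile activity) or `"full"` (additionally the full
#'   activity maps every `record_every` ms).
#' @param record_every sampling interval for full-map recording, ms.
#' @return an object of class `pps_sim`: a list with `time`, `y_m`,
#'   `tact_sum`, final activity maps `Y_t`, `Y_a`, final `y_m_final`,
#'   `converged` flag, and the (possibly weight-updated) `net`.
#' @export
simulate_network <- function(net, stimuli, duration = NULL,
                             dt = net$params$integration$dt, hebb = NULL,
                             record = c("summary", "full"), record_every = 5) {
  record <- match.arg(record)
  if (inherits(stimuli, "stimulus_spec")) stimuli <- list(stimuli)
  if (is.null(duration)) duration <- net$params$integration$max_duration
  stopifnot(duration > 0)

  # draw per-presentation inputs once
  maps <- lapply(stimuli, function(s) unisensory_input(net, s))
  onsets  <- vapply(stimuli, `[[`, numeric(1), "onset")
  offsets <- onsets + vapply(stimuli, `[[`, numeric(1), "duration")
  last_event <- max(0, onsets, offsets[is.finite(offsets)])

  nsteps <- ceiling(duration / dt)
  time <- numeric(nsteps); y_m <- numeric(nsteps); tact_sum <- numeric(nsteps)
  full <- if (record == "full") list() else NULL
  tol <- net$params$integration$ss_tol
  converged <- FALSE
  Y_t <- area_activity(net$tactile); Y_a <- area_activity(net$auditory)
  n_done <- 0

  for (i in seq_len(nsteps)) {
    t_now <- (i - 1) * dt
    E_t <- 0; E_a <- 0
    for (j in seq_along(stimuli)) {
      if (t_now >= onsets[j] && t_now < offsets[j]) {
        if (stimuli[[j]]$modality == "tactile") E_t <- E_t + maps[[j]]
        else E_a <- E_a + maps[[j]]
      }
    }
    st <- step_network(net, E_t, E_a, dt)
    if (!is.null(hebb)) {
      W <- hebbian_update(list(W_t = net$W_t, W_a = net$W_a),
                          pre_t = st$Y_t, pre_a = st$Y_a, post = st$y_m,
                          p = hebb, dt = dt)
      st$net$W_t <- W$W_t
      st$net$W_a <- W$W_a
    }
    net <- st$net
    time[i] <- t_now + dt; y_m[i] <- st$y_m; tact_sum[i] <- sum(st$Y_t)
    n_done <- i
    if (record == "full" && (i %% max(1, round(record_every / dt)) == 0))
      full[[length(full) + 1]] <- list(time = time[i], Y_t = st$Y_t,
                                       Y_a = st$Y_a, y_m = st$y_m)
    if (time[i] > last_event && st$delta < tol) { converged <- TRUE; break }
  }
  idx <- seq_len(n_done)
  out <- list(time = time[idx], y_m = y_m[idx], tact_sum = tact_sum[idx],
              Y_t = area_activity(net$tactile),
              Y_a = area_activity(net$auditory),
              y_m_final = ms_activity(net$ms),
              converged = converged, net = net)
  class(out) <- "pps_sim"
  out
}

#' Reset a network to its resting state
#'
#' Zeroes all internal state variables; weights are untouched.
#' @param net a `pps_network`.
#' @return the network at rest.
#' @export
reset_network <- function(net) {
  net$tactile$z[] <- 0
  net$auditory$z[] <- 0
  net$ms$z <- 0
  net
}

#' Export steady-state activity maps as a data frame
#'
#' One row per neuron: area, x_cm, y_cm, activity; suitable for writing as
#' delimited text.
#' @param sim a `pps_sim` result.
#' @return data.frame.
#' @export
activity_maps <- function(sim) {
  gt <- sim$net$tactile$grid; ga <- sim$net$auditory$grid
  rbind(
    data.frame(area = "tactile", x_cm = as.vector(gt$X),
               y_cm = as.vector(gt$Y), activity = as.vector(sim$Y_t)),
    data.frame(area = "auditory", x_cm = as.vector(ga$X),
               y_cm = as.vector(ga$Y), activity = as.vector(sim$Y_a)),
    data.frame(area = "multisensory", x_cm = NA_real_, y_cm = NA_real_,
               activity = sim$y_m_final)
  )
}
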