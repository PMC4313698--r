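test_that("basal network construction matches the wiring assumptions", {
  net <- build_network(network_params())
  W_max <- net$params$synapses$W_max

  # tactile feedforward weights are uniform at the saturation value
  expect_true(all(net$W_t == W_max))

  # auditory weights: ~W_max for RFs on the hand, much weaker far away
  on_hand <- net$dist_hand == 0
  far <- net$dist_hand >= 80
  expect_true(all(net$W_a[on_hand] > 0.99 * W_max))
  expect_true(all(net$W_a[far] < 0.05 * W_max))
  expect_true(all(diff(net$W_a[, 3]) <= 1e-12))  # non-increasing along x at fixed y

  # feedback mirrors the feedforward arrangement
  expect_equal(net$B_a / max(net$B_a), net$W_a / max(net$W_a))

  # grid shapes consistent
  expect_equal(dim(net$W_a), c(net$auditory$grid$nx, net$auditory$grid$ny))
  expect_equal(dim(net$W_t), c(net$tactile$grid$nx, net$tactile$grid$ny))
  expect_equal(net$auditory$grid$nx, 101)
  expect_equal(net$tactile$grid$nx, 41)
})

test_that("invalid geometry raises configuration errors", {
  expect_error(network_params(tactile = list(spacing = 0)), "configuration")
  expect_error(network_params(auditory = list(spacing = 500)), "configuration")
  expect_error(network_params(integration = list(dt = 10)), "stability|tau")
  expect_error(network_params(auditory = list(rf_sigma = 0.3)), "larger")
})

test_that("lateral kernel is a Mexican hat", {
  k <- network_params()$auditory$lateral
  expect_gt(lateral_kernel(0, k), 0)              # net near excitation
  expect_lt(lateral_kernel(1e4, k), 1e-12)        # vanishing tail
  # direct evaluation of the closed form on a grid: a sign change exists
  d <- seq(0, 60, by = 0.5)
  w <- k$L_ex * exp(-d^2 / (2 * k$sigma_ex^2)) -
    k$L_in * exp(-d^2 / (2 * k$sigma_in^2))
  expect_equal(lateral_kernel(d, k), w)
  expect_true(any(w > 0) && any(w < 0))
  expect_error(lateral_kernel(-1, k))
})

test_that("distance from the hand follows the rectangle geometry", {
  hand <- list(x = c(0, 20), y = c(0, 10))
  expect_equal(distance_from_hand(50, 5, hand), 30)
  expect_equal(distance_from_hand(100, 5, hand), 80)
  expect_equal(distance_from_hand(20, 5, hand), 0)
  expect_equal(distance_from_hand(10, 5, hand), 0)   # interior
  expect_equal(distance_from_hand(23, 14, hand), 5)  # corner 3-4-5 triangle
  expect_error(distance_from_hand(300, 5, hand, grid_extent = c(200, 30)),
               "domain")
})

test_that("external input maps follow RF-filtered Gaussian profiles", {
  net <- build_network(network_params())
  et <- unisensory_input(net, quiet_stim("tactile", c(10, 5)))
  ea <- unisensory_input(net, quiet_stim("auditory", c(10, 5)))
  # same stimulus extent: auditory footprint wider (in cm) than tactile
  ta <- sum(et >= max(et) / 2) * net$params$tactile$spacing^2
  aa <- sum(ea >= max(ea) / 2) * net$params$auditory$spacing^2
  expect_gt(aa, ta)  # cm^2 of half-max footprint

  expect_true(all(unisensory_input(net,
    stimulus_spec("auditory", c(50, 5), intensity = 0, noise_frac = 0)) == 0))

  e1 <- unisensory_input(net, quiet_stim("auditory", c(50, 5)))
  e2 <- unisensory_input(net, quiet_stim("auditory", c(50, 5)))
  expect_identical(e1, e2)  # no noise -> deterministic
})

test_that("an isolated neuron settles at the closed-form fixed point", {
  net <- isolated_net()
  E <- unisensory_input(net, quiet_stim("tactile", c(10, 5)))
  for (i in 1:4000) net <- step_network(net, E_t = E, dt = 0.5)$net
  # z -> u = E, y -> phi(E)
  expect_equal(net$tactile$z, E, tolerance = 1e-6)
  p <- net$params$tactile
  y <- 1 / (1 + exp(-p$slope * (net$tactile$z - p$theta)))
  expect_equal(y, 1 / (1 + exp(-p$slope * (E - p$theta))), tolerance = 1e-6)
})

test_that("integration agrees with a fine-step oracle and rejects bad dt", {
  net <- build_network(network_params(noise = list(intensity_frac = 0)))
  stim <- quiet_stim("tactile", c(10, 5))
  s_coarse <- simulate_network(reset_network(net), stim, duration = 80, dt = 0.5)
  s_fine <- simulate_network(reset_network(net), stim, duration = 80, dt = 0.05)
  at <- function(s, t) s$y_m[which.min(abs(s$time - t))]
  for (t in c(20, 40, 80))
    expect_equal(at(s_coarse, t), at(s_fine, t), tolerance = 0.02)
  expect_error(step_network(net, dt = 20), "dt")
})

test_that("rest is a fixed point and activities stay bounded", {
  net <- build_network(network_params())
  s <- simulate_network(reset_network(net), list(), duration = 100)
  expect_lt(max(s$Y_t), 1e-3)
  expect_lt(s$y_m_final, 0.01)

  # arbitrary admissible inputs keep every activity in [0, 1]
  set.seed(11)
  for (i in 1:5) {
    stims <- list(
      stimulus_spec("tactile", c(runif(1, 0, 20), runif(1, 0, 10)),
                    sigma = runif(1, 0.5, 3), intensity = runif(1, 0, 40)),
      stimulus_spec("auditory", c(runif(1, 0, 200), runif(1, 0, 30)),
                    sigma = runif(1, 0.5, 3), intensity = runif(1, 0, 40)))
    s <- simulate_network(reset_network(net), stims, duration = 120)
    expect_true(all(s$Y_t >= 0 & s$Y_t <= 1))
    expect_true(all(s$Y_a >= 0 & s$Y_a <= 1))
    expect_true(s$y_m_final >= 0 && s$y_m_final <= 1)
  }
})

test_that("steady state satisfies the fixed-point equations", {
  net <- build_network(network_params())
  stim <- quiet_stim("tactile", c(10, 5))
  E <- unisensory_input(net, stim)
  s <- simulate_network(reset_network(net), stim)
  expect_true(s$converged)
  n2 <- s$net
  # residual: z must equal the input recomputed from the settled activities
  lat <- n2$tactile$L_ex * (n2$tactile$Gx_ex %*% s$Y_t %*% n2$tactile$Gy_ex) -
    n2$tactile$L_in * (n2$tactile$Gx_in %*% s$Y_t %*% n2$tactile$Gy_in) -
    n2$tactile$k0 * s$Y_t
  u <- E + lat + n2$B_t * s$y_m_final
  expect_lt(max(abs(n2$tactile$z - u)), 0.02)
})

test_that("multisensory unit is selective for sounds near the hand", {
  net <- build_network(network_params())
  s_t <- simulate_network(reset_network(net), quiet_stim("tactile", c(10, 5)))
  expect_gt(s_t$y_m_final, 0.9)   # touch alone drives the unit
  expect_gt(ms_response_at(net, 30), 0.9)
  expect_lt(ms_response_at(net, 80), 0.05)
})

test_that("auditory activation is translation-covariant across the grid", {
  net <- build_network(network_params())
  s1 <- simulate_network(reset_network(net), quiet_stim("auditory", c(100, 12)))
  s2 <- simulate_network(reset_network(net), quiet_stim("auditory", c(100, 18)))
  shift <- 6 / net$params$auditory$spacing   # nodes along y
  inner <- 8:13                              # central rows, away from edges
  expect_equal(s2$Y_a[, inner], s1$Y_a[, inner - shift], tolerance = 1e-3)
  expect_equal(max(s1$Y_a), max(s2$Y_a), tolerance = 1e-3)
})

test_that("activity maps export one row per neuron", {
  net <- build_network(network_params())
  s <- simulate_network(reset_network(net), quiet_stim("tactile", c(10, 5)),
                        duration = 60)
  m <- activity_maps(s)
  expect_equal(nrow(m), 41 * 21 + 101 * 16 + 1)
  expect_true(all(m$activity >= 0 & m$activity <= 1))
})
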