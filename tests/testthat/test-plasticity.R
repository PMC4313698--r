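test_that("Hebbian rule: vanishing terms, saturation and bounds", {
  p <- hebb_params(gamma_pot = 1e-3, gamma_forget = 1e-3, W_max = 0.1)
  W0 <- list(W_t = matrix(0.05, 3, 3), W_a = matrix(0.02, 4, 4))

  # silent pre and post: nothing changes
  W1 <- hebbian_update(W0, pre_t = matrix(0, 3, 3), pre_a = matrix(0, 4, 4),
                       post = 0, p = p, dt = 1)
  expect_identical(W1, W0)

  # at saturation with fully correlated activity: stays at W_max
  Ws <- list(W_t = matrix(0.1, 3, 3), W_a = matrix(0.1, 4, 4))
  W2 <- hebbian_update(Ws, pre_t = matrix(1, 3, 3), pre_a = matrix(1, 4, 4),
                       post = 1, p = p, dt = 5)
  expect_true(all(W2$W_t <= p$W_max) && all(W2$W_a <= p$W_max))
  expect_equal(W2$W_t, Ws$W_t)

  # sustained post activity with silent pre: decays toward zero
  W <- list(W_t = matrix(0.05, 2, 2), W_a = matrix(0.05, 2, 2))
  for (i in 1:5000)
    W <- hebbian_update(W, pre_t = matrix(0, 2, 2), pre_a = matrix(0, 2, 2),
                        post = 1, p = p, dt = 1)
  expect_lt(max(W$W_a), 0.0005)
  expect_true(all(W$W_a >= 0))

  # arbitrary activity sequences keep weights in [0, W_max]
  set.seed(5)
  W <- list(W_t = matrix(runif(9, 0, 0.1), 3, 3),
            W_a = matrix(runif(9, 0, 0.1), 3, 3))
  for (i in 1:500) {
    W <- hebbian_update(W, pre_t = matrix(runif(9), 3, 3),
                        pre_a = matrix(runif(9), 3, 3), post = runif(1),
                        p = hebb_params(gamma_pot = 5e-3, gamma_forget = 5e-3,
                                        W_max = 0.1), dt = 2)
    expect_true(all(W$W_t >= 0 & W$W_t <= 0.1))
    expect_true(all(W$W_a >= 0 & W$W_a <= 0.1))
  }
})

test_that("SOA sampling honours the protocol contract", {
  sync <- training_protocol(soa_mode = "synchronous")
  expect_error(sample_soa(sync), "protocol")

  asyn <- training_protocol(soa_mode = "asynchronous")
  set.seed(9)
  draws <- replicate(1000, sample_soa(asyn))
  expect_true(all(draws != 0))
  expect_true(all(abs(draws) >= asyn$soa_range[1] &
                    abs(draws) <= asyn$soa_range[2]))
  # both overlap classes occur: partial superposition and full separation
  expect_gt(sum(abs(draws) < asyn$duration), 0)
  expect_gt(sum(abs(draws) >= asyn$duration), 0)
  # both signs occur (sound leading and trailing)
  expect_gt(sum(draws > 0), 0)
  expect_gt(sum(draws < 0), 0)
})

test_that("zero presentations leave the network untouched", {
  net <- build_network(network_params())
  tr <- run_training(net, training_protocol(n_presentations = 0))
  expect_identical(tr$W_a, net$W_a)
  expect_identical(tr$W_t, net$W_t)
})

test_that("synchronous training potentiates far-space auditory synapses only", {
  net <- build_network(network_params())
  set.seed(42)
  proto <- training_protocol(soa_mode = "synchronous")
  tr <- run_training(net, proto)
  W_max <- net$params$synapses$W_max

  # strong potentiation around the trained location (100, 5)
  g <- net$auditory$grid
  near_stim <- sqrt((g$X - 100)^2 + (g$Y - 5)^2) <= 10
  fold <- mean(tr$W_a[near_stim]) / mean(net$W_a[near_stim])
  expect_gt(fold, 5)
  expect_gt(max(tr$W_a - net$W_a), 0.8 * W_max)

  # locality: weights on/near the hand and tactile weights unchanged
  near_hand <- net$dist_hand <= 10
  expect_lt(max(abs(tr$W_a[near_hand] - net$W_a[near_hand]) /
                  net$W_a[near_hand]), 0.02)
  expect_lt(max(abs(tr$W_t - net$W_t)) / W_max, 0.02)

  # bounds after training
  expect_true(all(tr$W_a >= 0 & tr$W_a <= W_max))

  # monotonicity in pairing count: fewer pairings, less potentiation
  set.seed(42)
  tr5 <- run_training(net, training_protocol(n_presentations = 5,
                                             soa_mode = "synchronous"))
  m0 <- mean(net$W_a[near_stim]); m5 <- mean(tr5$W_a[near_stim])
  m30 <- mean(tr$W_a[near_stim])
  expect_true(m0 < m5 && m5 < m30)
})
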