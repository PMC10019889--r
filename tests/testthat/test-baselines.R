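test_that("one-hot TD update touches only the source row", {
  M <- fftd_network(3)
  M2 <- fftd_update_onehot(M, 1, 2, gamma = 0.5, eta = 1)
  expect_equal(M2[1, ], c(1, 0, 0))
  expect_equal(M2[2:3, ], matrix(0, 2, 3))

  # expected update vanishes at the SR fixed point
  Tm <- true_transition_matrix(ring_env(6), forward_bias_actions())$T
  Mstar <- sr_from_T(Tm, 0.6)
  expected <- matrix(0, 6, 6)
  for (snext in 1:6) {
    expected <- expected +
      Tm[2, snext] * (fftd_update_onehot(Mstar, 2, snext, 0.6, 1) - Mstar)
  }
  expect_equal(expected, matrix(0, 6, 6), tolerance = 1e-12)
})

test_that("feature TD update reduces to the one-hot rule", {
  set.seed(5)
  M <- matrix(runif(25), 5, 5)
  phi <- as.numeric(1:5 == 2); phin <- as.numeric(1:5 == 4)
  expect_equal(fftd_update_features(M, phi, phin, 0.7, 0.1),
               fftd_update_onehot(M, 2, 4, 0.7, 0.1))

  expect_equal(fftd_update_features(M, rep(0, 5), phin, 0.7, 0.1), M)

  # from zero weights the update is the outer product phi phi^T
  Z <- matrix(0, 5, 5)
  phi2 <- runif(5)
  expect_equal(fftd_update_features(Z, phi2, phin, 0.7, 1),
               outer(phi2, phi2))
})

test_that("the learning-rate grid search returns the argmin", {
  w <- simulate_walk(ring_env(10), ring_actions(), 800, seed = 2)
  oracle <- sr_from_T(true_transition_matrix(ring_env(10), ring_actions()),
                      0.6)
  single <- fftd_lr_search(w, 0.6, eta_grid = 0.05, oracle_M = oracle)
  expect_equal(single$best_eta, 0.05)

  res <- fftd_lr_search(w, 0.6, eta_grid = c(1e-3, 1e-2, 1e-1),
                        oracle_M = oracle)
  expect_equal(res$best_eta, res$errors$eta[which.min(res$errors$error)])
  res2 <- fftd_lr_search(w, 0.6, eta_grid = c(1e-3, 1e-2, 1e-1),
                         oracle_M = oracle)
  expect_identical(res$errors, res2$errors)
})

test_that("FF-TD converges to the true SR on long uniform walks", {
  env <- ring20()
  oracle <- sr_from_T(true_transition_matrix(env, ring_actions()), 0.6)
  for (seed in 1:3) {
    w <- simulate_walk(env, ring_actions(), 5e4, seed = seed)
    fit <- fftd_lr_search(w, 0.6, oracle_M = oracle)
    expect_lt(mae_matrix(fit$best_M, oracle), 0.05)
  }
})

test_that("independent normalization equals the core rule on one-hot input", {
  w <- simulate_walk(ring_env(10), forward_bias_actions(), 400, seed = 8)
  cfg <- rnn_config(gamma_b = 0)
  a <- run_session(w, cfg = cfg, rule = "decorrelative",
                   keep_activity = FALSE, log_every = 1e9)
  b <- run_session(w, cfg = cfg, rule = "independent",
                   keep_activity = FALSE, log_every = 1e9)
  expect_lt(max(abs(a$state$J - b$state$J)), 1e-12)

  # the rules differ on dense activity
  x_prev <- c(0.5, 0.5); x_t <- c(1, 0); J <- matrix(0.3, 2, 2)
  expect_false(isTRUE(all.equal(
    independent_norm_update(J, x_t, x_prev, 1),
    weight_update(J, x_t, x_prev, 1))))
})

test_that("random control networks match the reference moments", {
  expect_equal(random_network(matrix(0, 4, 4), seed = 1), matrix(0, 4, 4))

  set.seed(3)
  ref <- matrix(rnorm(196^2, 0.1, 0.05), 196, 196)
  rnd <- random_network(ref, seed = 2)
  expect_lt(abs(mean(rnd) - mean(ref)) / abs(mean(ref)), 0.05)
  expect_lt(abs(sd(rnd) - sd(ref)) / sd(ref), 0.05)
  expect_identical(random_network(ref, seed = 2), rnd)
})
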