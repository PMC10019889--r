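test_that("sr_from_T matches the geometric-series oracle", {
  expect_equal(sr_from_T(matrix(c(.9, .1, .4, .6), 2, byrow = TRUE), 0), diag(1, 2))

  T2 <- matrix(0.5, 2, 2)
  # independent 2x2 inversion oracle
  expect_equal(sr_from_T(T2, 0.5), matrix(c(1.5, 0.5, 0.5, 1.5), 2))

  Tm <- true_transition_matrix(ring_env(12), forward_bias_actions())
  M <- sr_from_T(Tm, 0.6)
  expect_equal(unname(rowSums(M)), rep(2.5, 12), tolerance = 1e-6)
  expect_true(all(diag(M) >= 1))
})

test_that("steady-state solvers agree and flag instability", {
  expect_equal(steady_state_linear(matrix(0, 3, 3), 0, c(1, 2, 3)), c(1, 2, 3))

  T2 <- matrix(0.5, 2, 2)
  x <- steady_state_linear(t(T2), 0.5, c(1, 0))
  expect_equal(x, unname(sr_from_T(T2, 0.5)[1, ]))

  expect_error(steady_state_linear(2 * diag(1, 3), 0.6, rep(1, 3)),
               class = "srnn_instability_error")

  # truncated series matches the closed form within the geometric tail bound
  set.seed(7)
  for (i in 1:5) {
    J <- matrix(runif(36, 0, 0.12), 6, 6)
    phi <- runif(6)
    gamma <- runif(1, 0.3, 0.9)
    tm <- choose_tmax(gamma)
    tail_bound <- gamma^(tm + 1) / (1 - gamma) * max(abs(phi)) * 10
    expect_lt(max(abs(steady_state_truncated(J, gamma, phi, tm) -
                        steady_state_linear(J, gamma, phi))),
              max(tail_bound, 1e-3))
  }

  expect_equal(steady_state_truncated(diag(0.5, 3), 0.9, c(1, 1, 1), 0),
               c(1, 1, 1))
  expect_equal(steady_state_truncated(matrix(0, 2, 2), 0.9, c(2, 3), 10),
               c(2, 3))
})

test_that("choose_tmax returns the smallest sufficient horizon", {
  expect_equal(choose_tmax(0.5, 1e-4), 14)
  expect_equal(choose_tmax(0.9, 1e-4), 88)
  expect_equal(choose_tmax(0, 1e-4), 1L)
  expect_equal(choose_tmax(0.7, 1), 1L)
  expect_error(choose_tmax(1), "gamma")
})

test_that("tanh iteration matches linear dynamics at small activity", {
  expect_equal(steady_state_tanh(matrix(0, 3, 3), 0.5, c(1, 2, 3), 1),
               c(1, 2, 3))
  set.seed(8)
  J <- matrix(runif(25, 0, 0.1), 5, 5)
  phi <- rep(0.02, 5)
  xt <- steady_state_tanh(J, 0.6, phi, choose_tmax(0.6))
  xl <- steady_state_truncated(J, 0.6, phi, choose_tmax(0.6))
  expect_lt(max(abs(xt - xl)), 1e-3)
  expect_equal(steady_state_tanh(J, 0, phi, 1), phi)
})

test_that("the weight update implements the STDP + normalization rule", {
  J <- matrix(0, 3, 3)
  expect_equal(weight_update(J, c(1, 0, 0), rep(0, 3), 1), matrix(0, 3, 3))

  dJ <- weight_update(J, c(0, 1, 0), c(1, 0, 0), 1)
  expect_equal(dJ[2, 1], 1)
  expect_equal(sum(abs(dJ)), 1)

  # fixed point: column already equal to the empirical next-state
  # distribution receives zero expected update under one-hot activity
  Tm <- true_transition_matrix(ring_env(5), forward_bias_actions())$T
  Jt <- t(Tm)
  expected <- matrix(0, 5, 5)
  for (i in 1:5) {
    x_prev <- as.numeric(1:5 == 2)
    x_t <- as.numeric(1:5 == i)
    expected <- expected + Tm[2, i] * weight_update(Jt, x_t, x_prev, 1)
  }
  expect_equal(expected, matrix(0, 5, 5), tolerance = 1e-12)

  # eta is applied per presynaptic column
  dJ2 <- weight_update(matrix(0, 2, 2), c(1, 1), c(1, 1), c(0.5, 0.25))
  expect_equal(dJ2, matrix(c(0.5, 0.5, 0.25, 0.25), 2))
})

test_that("the activity trace yields the adaptive running-average rate", {
  tr <- update_trace(c(0, 0), c(1, 0), lambda = 1)
  expect_equal(tr$eta, c(1, 1))
  expect_equal(tr$n, c(1, 0))

  n <- c(0, 0)
  for (k in 1:5) {
    tr <- update_trace(n, c(1, 0), lambda = 1)
    n <- tr$n
    expect_equal(tr$eta[1], 1 / k)
  }
  # inactive neurons keep their trace under lambda = 1
  expect_equal(n[2], 0)
  tr2 <- update_trace(c(4, 1), c(0, 0), lambda = 1)
  expect_equal(tr2$n, c(4, 1))
})

test_that("a single learning step performs one-shot association", {
  cfg <- rnn_config(gamma_b = 0)
  st <- rnn_network(3)
  st <- step_learn(st, c(1, 0, 0), cfg)$state   # first step: no x_prev
  expect_equal(st$J, matrix(0, 3, 3))
  st <- step_learn(st, c(0, 1, 0), cfg)$state
  expect_equal(st$J[2, 1], 1)
  expect_equal(sum(st$J), 1)

  # zero input leaves the weights untouched
  res <- step_learn(st, rep(0, 3), cfg)
  expect_equal(res$state$J, st$J)
  expect_equal(res$x, rep(0, 3))
})

test_that("learned weights equal the empirical transition transpose", {
  # exact equality on stay-free walks (the Appendix-style oracle)
  env <- ring_env(15)
  for (seed in 1:3) {
    w <- simulate_walk(env, ring_actions(0.7, 0, 0.3), 1500, seed = seed)
    sess <- run_session(w, cfg = rnn_config(gamma_b = 0),
                        keep_activity = FALSE, log_every = 1e9)
    expect_lt(max(abs(sess$state$J - t(empirical_transition_matrix(w)$T))),
              1e-9)
  }
  # with self-transitions the running average converges to the same limit
  w2 <- simulate_walk(env, forward_bias_actions(), 5000, seed = 4)
  sess2 <- run_session(w2, cfg = rnn_config(gamma_b = 0),
                       keep_activity = FALSE, log_every = 1e9)
  expect_lt(mae_matrix(t(sess2$state$J), empirical_transition_matrix(w2)$T),
            1e-3)
})

test_that("column sums converge to 1 once every state has been left", {
  w <- simulate_walk(ring20(), forward_bias_actions(), 600, seed = 2)
  sess <- run_session(w, cfg = rnn_config(gamma_b = 0),
                      keep_activity = FALSE, log_every = 100)
  final <- tail(sess$log$row_sum_mean, 1)
  expect_lt(abs(final - 1), 0.02)
})

test_that("retrieval reproduces SR rows at any gain after exact learning", {
  env <- ring_env(10)
  Tm <- true_transition_matrix(env, forward_bias_actions())
  st <- rnn_network(10)
  st$J <- t(Tm$T)
  for (gr in seq(0.1, 0.9, by = 0.2)) {
    cfg <- rnn_config(gamma_b = 0, gamma_r = gr)
    M <- sr_from_T(Tm, gr)
    for (j in c(1, 5, 10)) {
      phi <- as.numeric(1:10 == j)
      expect_equal(step_retrieve(st, phi, cfg), unname(M[j, ]),
                   tolerance = 1e-6)
    }
  }
  # retrieval is pure: repeated calls leave the state unchanged
  before <- st
  invisible(step_retrieve(st, as.numeric(1:10 == 3), rnn_config()))
  expect_identical(st, before)
})

test_that("run_session dispatches modes and preserves J under retrieval", {
  w <- simulate_walk(ring_env(8), ring_actions(), 50, seed = 3)
  sess <- run_session(w, cfg = rnn_config(gamma_b = 0, gamma_r = 0.5),
                      schedule = rep(1L, 51))
  expect_equal(sess$state$J, matrix(0, 8, 8))
  expect_equal(dim(sess$activity), c(51, 8))

  expect_error(run_session(w, cfg = rnn_config(), schedule = c(0, 1)),
               "schedule")
})

test_that("adaptive learning beats every static rate at matched steps", {
  tbl <- compare_learning_speed(n_steps = 1500, n_seeds = 3, seed = 9)
  agg <- tbl |>
    dplyr::group_by(model, eta) |>
    dplyr::summarise(mae = mean(mae_M), .groups = "drop")
  adaptive <- agg$mae[agg$model == "rnn_adaptive"]
  expect_true(all(adaptive < agg$mae[agg$model == "rnn_static"]))
})
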