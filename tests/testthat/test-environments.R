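test_that("ground-truth transition matrices encode the action model", {
  # uniform ring: three entries of 1/3 per row
  Tm <- true_transition_matrix(ring_env(20), ring_actions())$T
  expect_row_stochastic(Tm)
  expect_equal(sort(unique(round(Tm[Tm > 0], 12))), 1 / 3)
  expect_equal(unname(rowSums(Tm > 0)), rep(3, 20))

  # deterministic forward motion is the cyclic permutation
  Tp <- true_transition_matrix(ring_env(5), ring_actions(1, 0, 0))$T
  P <- matrix(0, 5, 5)
  for (j in 1:5) P[j, j %% 5 + 1] <- 1
  expect_equal(Tp, P)

  # 3x3 grid corner: stay + 2 in-bounds neighbours, each 1/3
  Tg <- true_transition_matrix(grid_env(3, 3), grid_actions())$T
  expect_row_stochastic(Tg)
  corner <- Tg[1, ]
  expect_equal(sum(corner > 0), 3)
  expect_equal(unname(corner[corner > 0]), rep(1 / 3, 3))
  # centre state keeps all five moves
  expect_equal(sum(Tg[5, ] > 0), 5)
})

test_that("geometry mismatches and invalid probabilities are rejected", {
  expect_error(true_transition_matrix(ring_env(5), grid_actions()), "mismatch")
  expect_error(ring_actions(0.5, 0.5, 0.5), "sum to 1")
  expect_error(ring_actions(-0.1, 0.6, 0.5), "0, 1")
})

test_that("simulate_walk is reproducible and respects the chain", {
  env <- ring_env(4)
  w <- simulate_walk(env, ring_actions(1, 0, 0), 4, start = 1)
  expect_equal(w$states, c(1L, 2L, 3L, 4L, 1L))

  w1 <- simulate_walk(ring20(), forward_bias_actions(), 500, seed = 42)
  w2 <- simulate_walk(ring20(), forward_bias_actions(), 500, seed = 42)
  expect_identical(w1$states, w2$states)

  # every consecutive pair is an allowed transition
  Tm <- true_transition_matrix(ring20(), forward_bias_actions())$T
  idx <- cbind(head(w1$states, -1), tail(w1$states, -1))
  expect_true(all(Tm[idx] > 0))

  expect_error(simulate_walk(ring20(), forward_bias_actions(), 10, start = 99),
               "start")
})

test_that("empirical transition counts match direct counting", {
  emp <- empirical_transition_matrix(c(1, 2, 3, 1), n_states = 3)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  expect_equal(emp$T, P)

  emp2 <- empirical_transition_matrix(c(1, 1, 2), n_states = 3)
  expect_equal(emp2$T[1, ], c(0.5, 0.5, 0))
  expect_false(emp2$visited[3])
  expect_equal(emp2$T[3, ], rep(0, 3))

  emp3 <- empirical_transition_matrix(c(3, 3), n_states = 3)
  expect_equal(emp3$T[3, ], c(0, 0, 1))
  expect_equal(sum(emp3$visited), 1)
})

test_that("long-walk empirical estimates converge to the ground truth", {
  env <- ring20()
  for (actions in list(ring_actions(), forward_bias_actions(),
                       ring_actions(0.25, 0.5, 0.25))) {
    for (seed in 1:3) {
      w <- simulate_walk(env, actions, 5e4, seed = seed)
      emp <- empirical_transition_matrix(w)
      expect_true(all(emp$visited))
      expect_lt(mae_matrix(emp$T, true_transition_matrix(env, actions)$T),
                0.01)
    }
  }
})

test_that("trajectory discretization decimates, bins, and checks coverage", {
  traj <- simulate_foraging(duration_min = 28, fps = 30, seed = 11)
  w <- discretize_trajectory(traj, 14, 14, target_fps = 3,
                             min_coverage = 0.85)
  expect_equal(length(w$states), floor(nrow(traj) / 10))
  expect_gte(walk_coverage(w), 0.85)
  expect_true(all(w$states >= 1 & w$states <= 196))

  # confined trajectory trips the coverage error
  confined <- dplyr::filter(traj, x < 20, y < 20)
  confined$t <- seq(0, by = 1 / 30, length.out = nrow(confined))
  expect_error(
    discretize_trajectory(confined, 14, 14, min_coverage = 0.85,
                          xlim = c(0, 70), ylim = c(0, 70)),
    class = "srnn_coverage_error")

  expect_error(discretize_trajectory(traj[0, ], 14, 14), "empty")
})
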