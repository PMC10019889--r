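# shared small fixtures, built in code

ring20 <- function() ring_env(20)

# deterministic forward cycle on a small ring
cycle_walk <- function(n = 4, steps = n) {
  simulate_walk(ring_env(n), ring_actions(1, 0, 0), steps, seed = 1)
}

# manual walk object from a state vector
walk_from_states <- function(states, env) {
  srnn:::new_walk(as.integer(states), env)
}

expect_row_stochastic <- function(Tm, tol = 1e-9) {
  expect_true(all(Tm >= -tol & Tm <= 1 + tol))
  expect_equal(rowSums(Tm), rep(1, nrow(Tm)), tolerance = tol)
}
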