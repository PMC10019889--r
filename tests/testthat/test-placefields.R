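test_that("rate maps are occupancy-normalized and flag empty bins", {
  env <- ring_env(10)
  w <- walk_from_states(rep(1:5, each = 4), env)
  rm1 <- rate_map(rep(1, 20), w, smoothing_sigma = 1)
  expect_equal(rm1$map[rm1$visited], rep(1, 5))
  expect_true(all(is.na(rm1$map[!rm1$visited])))
  expect_equal(sum(rm1$visited), 5)

  # indicator activity with no smoothing isolates one bin
  w2 <- cycle_walk(6, 30)
  act <- as.numeric(w2$states == 3)
  rm2 <- rate_map(act, w2, smoothing_sigma = 0)
  expect_equal(rm2$map, as.numeric(1:6 == 3))

  expect_error(rate_map(1:3, w2), "length")
})

test_that("field detection finds constructed bumps and needs permutations", {
  env <- grid_env(14, 14)
  w <- simulate_walk(env, grid_actions(), 5040, seed = 4)
  bump <- as.numeric(w$states == 100) * 5
  det <- detect_fields(bump, w, seed = 9)
  expect_true(det$is_place_cell)
  expect_equal(det$n_fields, 1L)
  expect_true(100 %in% det$fields[[1]])
  expect_true(det$field_sizes[1] > 0 && det$field_sizes[1] <= 1)

  expect_error(detect_fields(bump, w, n_perm = 50), "100")

  # all-zero activity is a non-place cell, not an error
  det0 <- detect_fields(rep(0, length(w$states)), w)
  expect_false(det0$is_place_cell)
  expect_equal(det0$n_fields, 0L)
})

test_that("spatially uniform neurons are flagged at about the alpha rate", {
  env <- grid_env(10, 10)
  w <- simulate_walk(env, grid_actions(), 3000, seed = 7)
  act <- srnn:::with_seed(21, matrix(stats::rexp(length(w$states) * 40),
                                     ncol = 40))
  summaries <- detect_fields_population(act, w, n_perm = 150, seed = 22)
  se <- sqrt(0.05 * 0.95 / 40)
  expect_lte(mean(summaries$is_place_cell), 0.05 + 3 * se)
})

test_that("field statistics histograms count correctly", {
  summaries <- tibble::tibble(
    neuron = 1:10,
    is_place_cell = c(rep(FALSE, 3), rep(TRUE, 7)),
    n_fields = c(0, 0, 0, 1, 1, 1, 1, 1, 2, 2),
    field_sizes = list(numeric(0), numeric(0), numeric(0),
                       0.12, 0.12, 0.12, 0.12, 0.12, c(0.12, 0.3),
                       c(0.12, 0.3)),
    mean_field_size = c(NA, NA, NA, rep(0.12, 5), 0.21, 0.21)
  )
  fs <- field_statistics(summaries)
  expect_equal(fs$count_hist$prop[1:3], c(0.3, 0.5, 0.2))
  expect_equal(fs$fieldless_fraction, 0.3)
  expect_equal(fs$place_cell_fraction, 0.7)
  expect_equal(sum(fs$size_hist$count), 9)   # fields of place cells only
  # all sizes of a single-field population land in one bin
  mono <- dplyr::mutate(summaries,
                        field_sizes = purrr::map(n_fields, ~rep(0.22, .x)))
  fsm <- field_statistics(mono)
  expect_equal(sum(fsm$size_hist$prop > 0), 1)
})

test_that("KL divergence matches hand-computed values and is non-negative", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log2(2) + 0.5 * log2(2 / 3))
  expect_gte(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)), 0)
  expect_error(kl_divergence(c(1, 0), c(0.2, 0.3, 0.5)), "bins")
})

test_that("combined and split-half divergences behave as limits demand", {
  summaries <- tibble::tibble(
    neuron = 1:600, is_place_cell = TRUE, n_fields = 1L,
    field_sizes = purrr::map(1:600, ~0.15), mean_field_size = 0.15)
  fs <- field_statistics(summaries)
  expect_equal(combined_kl(fs, fs, pseudo = 0), 0)

  sh <- split_half_kl(summaries, n_splits = 10, seed = 1)
  expect_equal(nrow(sh), 10)
  # a large homogeneous population has near-zero split-half divergence
  # (bounded by the reference pseudo-count, which vanishes as n grows)
  expect_lt(median(sh$kl_bits), 0.05)
  sh2 <- split_half_kl(summaries, n_splits = 10, seed = 1)
  expect_identical(sh, sh2)
  expect_error(split_half_kl(summaries[1:3, ]), "4 neurons")
})

test_that("peak shifts use minimal circular distances with sign", {
  env <- ring_env(20)
  states <- rep(1:20, 12)
  w <- walk_from_states(states, env)
  n_steps <- length(states)
  early <- 1:120; late <- 121:240

  # identical tuning in both windows: zero shift
  act <- matrix(0, n_steps, 2)
  act[, 1] <- as.numeric(states == 7)
  act[, 2] <- as.numeric(states == 15)
  ps <- peak_shift(act, w, early, late)
  expect_equal(ps$shift_cm, c(0, 0))

  # late map rotated backward one bin: -5 cm
  act2 <- matrix(0, n_steps, 1)
  act2[early, 1] <- as.numeric(states[early] == 7)
  act2[late, 1] <- as.numeric(states[late] == 6)
  expect_equal(peak_shift(act2, w, early, late)$shift_cm, -5)

  # wrap-around: peak 1 -> peak 20 is -5 cm, not +95
  act3 <- matrix(0, n_steps, 1)
  act3[early, 1] <- as.numeric(states[early] == 1)
  act3[late, 1] <- as.numeric(states[late] == 20)
  expect_equal(peak_shift(act3, w, early, late)$shift_cm, -5)

  # silent neurons in a window are excluded
  act4 <- cbind(act2, 0)
  expect_equal(nrow(peak_shift(act4, w, early, late)), 1)
  expect_error(peak_shift(act, w, integer(0), late), "non-empty")
})

test_that("lap maps split a circular walk into completed circuits", {
  w <- cycle_walk(4, 8)   # two full laps, ends at start
  act <- as.numeric(w$states == 3)
  lm <- lap_activity_map(act, w)
  expect_equal(nrow(lm), 2)
  expect_equal(lm[1, ], c(0, 0, 1, 0))

  act2 <- as.numeric(w$states == 3)
  act2[w$states == 3 & seq_along(w$states) > 4] <- 2
  lm2 <- lap_activity_map(act2, w)
  expect_equal(lm2[2, ], 2 * lm2[1, ])

  short <- cycle_walk(10, 5)
  expect_error(lap_activity_map(rep(1, 6), short), "lap")
  grid_w <- simulate_walk(grid_env(3, 3), grid_actions(), 20, seed = 1)
  expect_error(lap_activity_map(rep(1, 21), grid_w), "circular")
})

test_that("field size grows with the spatial correlation of the input", {
  # sparse features (about two active states each) keep fields localized;
  # the blur scale then sets the spatial spread of the retrieved activity
  env <- grid_env(10, 10)
  for (seed in 1:2) {
    w <- simulate_walk(env, grid_actions(), 2500, seed = 40 + seed)
    mean_size <- vapply(c(2.5, 7.5, 15), function(sigma) {
      fs <- generate_features(env, p = 0.02, sigma = sigma, seed = 60 + seed)
      sess <- run_session(w, fs, cfg = rnn_config(gamma_b = 0),
                          keep_activity = FALSE, log_every = 1e9)
      X <- srnn:::phi_stream(w, fs) %*%
        t(solve(diag(1, 100) - 0.75 * sess$state$J))
      sizes <- vapply(seq_len(ncol(X)), function(i) {
        if (all(X[, i] == 0)) return(NA_real_)
        det <- detect_fields(X[, i], w, n_perm = 100, seed = 80 + i)
        if (det$n_fields == 0) NA_real_ else mean(det$field_sizes)
      }, numeric(1))
      mean(sizes, na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(mean_size) > 0))
  }
})
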