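#' Stability sweep over the learning gain
#'
#' Runs seeded forward-biased random walks at each learning gain
#' `gamma_b` and flags a run unstable when the maximum real eigenvalue of
#' `gamma_b * J` reaches 1 at any logged checkpoint (or the dynamics
#' diverge between checkpoints). With linear dynamics the stable regime
#' ends above `gamma_b = 0.6`; a tanh nonlinearity in the recurrent
#' dynamics extends it to `gamma_b = 0.8`.
#'
#' @param gammas learning gains to sweep.
#' @param n_seeds walks per gain.
#' @param nonlinearity `"linear"` or `"tanh"`.
#' @param env,actions environment and action model (defaults: 20-state
#'   ring, forward bias).
#' @param n_steps walk length (default 5400: a half-hour session at 3
#'   steps/s).
#' @param seed base seed; per-run seeds are derived from it.
#' @param log_every stability-check cadence in steps.
#' @return A tibble: `gamma_b`, `seed`, `unstable`, `first_unstable_step`,
#'   `max_real_eig` (final logged value).
#' @export
stability_sweep <- function(gammas, n_seeds = 5,
                            nonlinearity = c("linear", "tanh"),
                            env = ring_env(20),
                            actions = forward_bias_actions(),
                            n_steps = 5400, seed = 1, log_every = 100) {
  nonlinearity <- match.arg(nonlinearity)
  seeds <- split_seed(seed, n_seeds)
  grid <- expand.grid(gamma_b = gammas, run = seq_len(n_seeds))
  rows <- pmap(grid, function(gamma_b, run) {
    cfg <- rnn_config(gamma_b = gamma_b, nonlinearity = nonlinearity)
    walk <- simulate_walk(env, actions, n_steps, seed = seeds[run])
    sess <- run_session(walk, cfg = cfg, keep_activity = FALSE,
                        log_every = log_every, halt_on_instability = TRUE)
    unstable <- !is.null(sess$instability) || any(sess$log$unstable)
    tibble(
      gamma_b = gamma_b, seed = seeds[run], unstable = unstable,
      first_unstable_step = if (unstable) {
        s <- sess$log$step[sess$log$unstable]
        if (length(s)) min(s) else sess$instability
      } else NA_integer_,
      max_real_eig = tail(sess$log$max_real_eig, 1)
    )
  })
  bind_rows(rows)
}

#' Largest gain at which every sweep run stayed stable
#'
#' @param sweep tibble from [stability_sweep()].
#' @return The largest `gamma_b` whose runs were all stable (`NA` if
#'   none).
#' @export
largest_stable_gamma <- function(sweep) {
  ok <- sweep |>
    group_by(.data$gamma_b) |>
    summarise(all_stable = !any(.data$unstable), .groups = "drop") |>
    filter(.data$all_stable)
  if (nrow(ok) == 0) return(NA_real_)
  max(ok$gamma_b)
}

#' Learning-speed comparison: adaptive vs static vs FF-TD
#'
#' Trains the recurrent model with the adaptive learning rate, the
#' recurrent model at each static rate in `static_grid`, and FF-TD at
#' each rate in `fftd_grid`, all on the same forward-biased walks, and
#' scores each by mean absolute error to the true SR matrix at discount
#' `gamma` after the full walk.
#'
#' @param n_steps walk length.
#' @param gamma SR discount at which `M` is compared.
#' @param static_grid static learning rates for the recurrent model.
#' @param fftd_grid FF-TD learning rates.
#' @param n_seeds number of walks.
#' @param env,actions study conditions (defaults: 20-state ring, forward
#'   bias).
#' @param seed base seed.
#' @return A tibble: `model`, `eta` (`NA` for adaptive), `seed`, `mae_M`.
#' @export
compare_learning_speed <- function(n_steps = 5400, gamma = 0.6,
                                   static_grid = 10^c(-3, -2.5, -2, -1.5, -1),
                                   fftd_grid = 10^seq(-3, -0.5, length.out = 6),
                                   n_seeds = 3, env = ring_env(20),
                                   actions = forward_bias_actions(),
                                   seed = 1) {
  seeds <- split_seed(seed, n_seeds)
  true_M <- sr_from_T(true_transition_matrix(env, actions), gamma)
  rows <- list()
  for (k in seq_len(n_seeds)) {
    walk <- simulate_walk(env, actions, n_steps, seed = seeds[k])
    mae_of_J <- function(J) {
      mae_matrix(t(solve(diag(1, nrow(J)) - gamma * J)), true_M)
    }
    sess <- run_session(walk, cfg = rnn_config(gamma_b = 0),
                        keep_activity = FALSE, log_every = n_steps)
    rows[[length(rows) + 1L]] <- tibble(
      model = "rnn_adaptive", eta = NA_real_, seed = seeds[k],
      mae_M = mae_of_J(sess$state$J))
    for (eta in static_grid) {
      cfg <- rnn_config(gamma_b = 0, lr_mode = "static", eta_static = eta)
      s2 <- run_session(walk, cfg = cfg, keep_activity = FALSE,
                        log_every = n_steps)
      rows[[length(rows) + 1L]] <- tibble(
        model = "rnn_static", eta = eta, seed = seeds[k],
        mae_M = mae_of_J(s2$state$J))
    }
    for (eta in fftd_grid) {
      M <- fftd_learn(walk, gamma, eta)
      rows[[length(rows) + 1L]] <- tibble(
        model = "fftd", eta = eta, seed = seeds[k],
        mae_M = mae_matrix(M, true_M))
    }
  }
  bind_rows(rows)
}

#' Place-field peak-shift experiment
#'
#' The backward-shift protocol on a circular track: learn (gain 0,
#' adaptive rate) over a forward-biased walk while reading out the
#' retrieval activity at `gamma_r` (tanh dynamics, the configuration
#' used for non-one-hot input features) with the weights as they stand
#' at each step. Early rate maps are built from the first window of the session
#' (weights still immature, fields anchored to each neuron's input
#' tuning) and late maps from the final window (weights converged,
#' fields carry the learned predictive component); per-neuron circular
#' peak shifts are averaged per walk. With dense spatially correlated
#' features the average shift is backward (negative); with one-hot input
#' it is centred on zero.
#'
#' @param n_walks number of simulated walks.
#' @param p,sigma feature parameters; `NULL` `p` means one-hot input.
#' @param gamma_r retrieval gain.
#' @param n_steps session length in steps.
#' @param early_steps length of the early window (default 360 = two
#'   minutes at 3 steps/s); the late window is the final `early_steps`
#'   steps.
#' @param max_track_cm field-tracking radius passed to [peak_shift()]
#'   (default a quarter of the default track).
#' @param env,actions study conditions.
#' @param seed base seed.
#' @return A tibble with one row per walk: `walk`, `mean_shift_cm`,
#'   `n_neurons`.
#' @export
peak_shift_experiment <- function(n_walks = 20, p = 0.1, sigma = 7.5,
                                  gamma_r = 0.8, n_steps = 5400,
                                  early_steps = 360, max_track_cm = 25,
                                  env = ring_env(20),
                                  actions = forward_bias_actions(),
                                  seed = 1) {
  seeds <- split_seed(seed, 2 * n_walks)
  rows <- map(seq_len(n_walks), function(k) {
    walk <- simulate_walk(env, actions, n_steps, seed = seeds[k])
    feats <- if (is.null(p)) NULL
             else generate_features(env, p = p, sigma = sigma,
                                    seed = seeds[n_walks + k])
    Phi <- phi_stream(walk, feats)
    Tsteps <- nrow(Phi)
    early <- seq_len(early_steps)
    late <- seq(Tsteps - early_steps + 1L, Tsteps)
    cfg <- rnn_config(gamma_b = 0, gamma_r = gamma_r, nonlinearity = "tanh")
    n <- ncol(Phi)
    X <- matrix(0, Tsteps, n)
    state <- rnn_network(n)
    windows <- c(early, late)
    for (t in seq_len(Tsteps)) {
      res <- step_learn(state, Phi[t, ], cfg)
      state <- res$state
      if (t %in% windows) X[t, ] <- step_retrieve(state, Phi[t, ], cfg)
    }
    shifts <- peak_shift(X, walk, early, late,
                         max_track_cm = max_track_cm)
    tibble(walk = k, mean_shift_cm = mean(shifts$shift_cm),
           n_neurons = nrow(shifts))
  })
  bind_rows(rows)
}

#' False-positive calibration of the place-field pipeline
#'
#' Feeds spatially uniform synthetic neurons (i.i.d. positive noise,
#' independent of position) through the permutation-test field detector
#' and reports the fraction flagged as place cells, which should not
#' exceed the significance level up to binomial error.
#'
#' @param n_neurons number of synthetic neurons.
#' @param walk the walk providing occupancy; defaults to a uniform
#'   14 x 14 foraging walk.
#' @param n_perm,alpha detector settings.
#' @param seed base seed.
#' @return A list: `flag_rate`, `n_neurons`, `alpha`, and the summary
#'   tibble.
#' @export
calibrate_field_detector <- function(n_neurons = 200, walk = NULL,
                                     n_perm = 250, alpha = 0.05, seed = 1) {
  if (is.null(walk)) {
    env <- grid_env(14, 14)
    walk <- simulate_walk(env, grid_actions(), 5040, seed = seed)
  }
  Tsteps <- length(walk$states)
  seeds <- split_seed(seed, 2)
  act <- with_seed(seeds[1],
                   matrix(stats::rexp(Tsteps * n_neurons), Tsteps, n_neurons))
  summaries <- detect_fields_population(act, walk, n_perm = n_perm,
                                        alpha = alpha, seed = seeds[2])
  list(flag_rate = mean(summaries$is_place_cell), n_neurons = n_neurons,
       alpha = alpha, summaries = summaries)
}
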