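#' Feedforward temporal-difference SR learner (FF-TD)
#'
#' The canonical SR algorithm as a feedforward network: the SR matrix `M`
#' (RL orientation, `M[j, i]` indexed source state `j`, predicted state
#' `i`) lives in the input-to-output weights and is updated by temporal
#' difference learning.
#'
#' @param n number of states/features.
#' @return An `N x N` zero matrix of class `fftd_state`.
#' @export
fftd_network <- function(n) {
  structure(matrix(0, n, n), class = c("fftd_state", "matrix", "array"))
}

#' One-hot FF-TD update
#'
#' For an observed transition `s -> s_next`, only row `s` of `M` changes:
#' `dM[s, i] = eta * (1{i = s} + gamma * M[s_next, i] - M[s, i])`.
#'
#' @param M current SR estimate (`fftd_network()` or matrix).
#' @param s,s_next observed source and destination state indices.
#' @param gamma SR discount.
#' @param eta learning rate.
#' @return Updated matrix.
#' @export
fftd_update_onehot <- function(M, s, s_next, gamma, eta) {
  delta <- gamma * M[s_next, ] - M[s, ]
  delta[s] <- delta[s] + 1
  M[s, ] <- M[s, ] + eta * delta
  M
}

#' Feature-based FF-TD update
#'
#' `dM^T = eta * (phi + gamma M^T phi_next - M^T phi) phi^T`; reduces to
#' [fftd_update_onehot()] exactly for one-hot inputs.
#'
#' @inheritParams fftd_update_onehot
#' @param phi,phi_next observed consecutive feature vectors.
#' @return Updated matrix.
#' @export
fftd_update_features <- function(M, phi, phi_next, gamma, eta) {
  phi <- as.numeric(phi); phi_next <- as.numeric(phi_next)
  td_err <- phi + gamma * drop(crossprod(M, phi_next)) - drop(crossprod(M, phi))
  M + eta * outer(phi, td_err)
}

#' Train FF-TD over a walk
#'
#' @param walk an `srnn_walk` or integer state vector.
#' @param gamma SR discount.
#' @param eta learning rate.
#' @param features optional `feature_set`; one-hot when `NULL`.
#' @param M optional warm-start matrix.
#' @return The learned `M` matrix.
#' @export
fftd_learn <- function(walk, gamma, eta, features = NULL, M = NULL) {
  states <- if (inherits(walk, "srnn_walk")) walk$states else as.integer(walk)
  if (is.null(features)) {
    n <- if (inherits(walk, "srnn_walk")) walk$env$n_states else max(states)
    if (is.null(M)) M <- matrix(0, n, n)
    for (t in seq_len(length(states) - 1L)) {
      M <- fftd_update_onehot(M, states[t], states[t + 1L], gamma, eta)
    }
  } else {
    Phi <- phi_stream(walk, features)
    if (is.null(M)) M <- matrix(0, ncol(Phi), ncol(Phi))
    for (t in seq_len(nrow(Phi) - 1L)) {
      M <- fftd_update_features(M, Phi[t, ], Phi[t + 1L, ], gamma, eta)
    }
  }
  M
}

#' Grid search over the FF-TD learning rate
#'
#' Trains FF-TD at each rate in the grid and returns the rate minimizing
#' the objective: mean absolute error to the true SR for one-hot input
#' (when `oracle_M` is given), TD loss on sampled transitions otherwise.
#'
#' @param walk training walk.
#' @param gamma SR discount.
#' @param eta_grid candidate learning rates (default 6 log-spaced points
#'   from `1e-3` to `10^-0.5`).
#' @param features optional `feature_set`.
#' @param oracle_M true SR matrix (one-hot objective).
#' @param n_samples transitions sampled for the TD-loss objective.
#' @param seed seed for transition sampling.
#' @return A list: `best_eta`, `best_M`, and the `errors` tibble.
#' @export
fftd_lr_search <- function(walk, gamma,
                           eta_grid = 10^seq(-3, -0.5, length.out = 6),
                           features = NULL, oracle_M = NULL,
                           n_samples = 1000, seed = NULL) {
  stopifnot(length(eta_grid) >= 1)
  fits <- map(eta_grid, function(eta) fftd_learn(walk, gamma, eta, features))
  errs <- map_dbl(seq_along(eta_grid), function(i) {
    if (!is.null(oracle_M)) {
      mae_matrix(fits[[i]], oracle_M)
    } else {
      smp <- sample_transitions(walk, features, n = n_samples, seed = seed)
      td_loss(fits[[i]], smp, gamma)
    }
  })
  best <- which.min(errs)
  list(best_eta = eta_grid[best], best_M = fits[[best]],
       errors = tibble(eta = eta_grid, error = errs))
}

#' Independent (Oja-like) normalization update
#'
#' The simpler per-synapse normalization control:
#' `dJ[i, j] = eta_j * (x_t[i] x_prev[j] - J[i, j] x_prev[j]^2)`.
#' Identical to [weight_update()] on one-hot activity; with dense
#' correlated features it lacks the decorrelative cross terms.
#'
#' @inheritParams weight_update
#' @return The weight change `dJ`.
#' @export
independent_norm_update <- function(J, x_t, x_prev, eta) {
  x_t <- as.numeric(x_t); x_prev <- as.numeric(x_prev)
  dJ <- outer(x_t, x_prev) - J * rep(x_prev^2, each = nrow(J))
  scale_columns(dJ, eta)
}

# one learning step under the independent-normalization rule
step_learn_independent <- function(state, phi_t, cfg) {
  x_t <- compute_activity(state$J, cfg$gamma_b, phi_t, cfg)
  tr <- update_trace(state$n, x_t, cfg$lambda, cfg$alpha_n)
  eta <- if (cfg$lr_mode == "adaptive") tr$eta else cfg$eta_static
  state$J <- state$J + independent_norm_update(state$J, x_t, state$x_prev, eta)
  if (cfg$nonneg) state$J[state$J < 0] <- 0
  state$n <- tr$n
  state$x_prev <- x_t
  state$t <- state$t + 1L
  list(state = state, x = x_t)
}

#' Random network matched in weight magnitude
#'
#' Control network with i.i.d. normal weights matching the elementwise
#' mean and standard deviation of a learned reference matrix.
#'
#' @param reference_J learned synaptic matrix to match.
#' @param seed optional integer seed.
#' @return A matrix of the same dimension.
#' @export
random_network <- function(reference_J, seed = NULL) {
  J <- as.matrix(reference_J)
  m <- mean(J); s <- stats::sd(as.vector(J))
  if (!is.finite(s) || s == 0) return(matrix(m, nrow(J), ncol(J)))
  with_seed(seed, matrix(rnorm(length(J), m, s), nrow(J), ncol(J)))
}
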