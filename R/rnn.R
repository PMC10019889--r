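#' RNN configuration
#'
#' Collects the tunable parameters of the recurrent successor network.
#' `gamma_b` is the network gain during learning and `gamma_r` the gain
#' during retrieval; both act as the SR discount of the computed steady
#' state. `lambda` discounts the per-neuron activity trace that drives the
#' adaptive learning rate `eta_j = min(1 / n_j, 1)`. With `nonlinearity =
#' "tanh"` the steady state is found by iterating the rate dynamics;
#' with linear dynamics it is available in closed form or as a truncated
#' power series.
#'
#' @param gamma_b learning-phase gain, in `[0, 1)`.
#' @param gamma_r retrieval-phase gain, in `[0, 1)`.
#' @param lambda trace discount, in `(0, 1]`.
#' @param lr_mode `"adaptive"` (per-neuron `min(1/n, 1)`) or `"static"`.
#' @param eta_static learning rate used in static mode (default `10^-1.5`).
#' @param nonlinearity `"linear"` or `"tanh"`.
#' @param dynamics steady-state solver: `"closed_form"` (linear only),
#'   `"truncated"` power series, or `"iterative"` (required for tanh).
#'   Defaults to `"closed_form"` for linear and `"iterative"` for tanh.
#' @param tol_tmax tail tolerance used by [choose_tmax()].
#' @param alpha_n trace scale (kernel rule variant).
#' @param nonneg constrain synapses to be nonnegative (excitatory
#'   recurrent weights); weight updates are clipped at zero.
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(gamma_b = 0, gamma_r = 0.9, lambda = 1,
                       lr_mode = c("adaptive", "static"),
                       eta_static = 10^-1.5,
                       nonlinearity = c("linear", "tanh"),
                       dynamics = NULL, tol_tmax = 1e-4, alpha_n = 1,
                       nonneg = TRUE) {
  lr_mode <- match.arg(lr_mode)
  nonlinearity <- match.arg(nonlinearity)
  if (is.null(dynamics))
    dynamics <- if (nonlinearity == "tanh") "iterative" else "closed_form"
  dynamics <- match.arg(dynamics, c("closed_form", "truncated", "iterative"))
  stopifnot(gamma_b >= 0, gamma_b < 1, gamma_r >= 0, gamma_r < 1,
            lambda > 0, lambda <= 1, eta_static > 0, tol_tmax > 0, alpha_n > 0)
  if (dynamics == "closed_form" && nonlinearity != "linear")
    abort("closed_form dynamics require the linear nonlinearity")
  if (nonlinearity == "tanh" && dynamics != "iterative")
    abort("tanh dynamics must use the iterative solver")
  structure(
    list(gamma_b = gamma_b, gamma_r = gamma_r, lambda = lambda,
         lr_mode = lr_mode, eta_static = eta_static,
         nonlinearity = nonlinearity, dynamics = dynamics,
         tol_tmax = tol_tmax, alpha_n = alpha_n,
         nonneg = isTRUE(nonneg)),
    class = "rnn_config"
  )
}

#' Fresh network state
#'
#' Synaptic matrix `J` (entry `[i, j]` is the weight from neuron `j` to
#' neuron `i`) initialized to zero, zero activity trace, zero previous
#' activity. With one-hot inputs, `gamma_b = 0` and `lambda = 1` the trace
#' `n_j` counts the visits to state `j`.
#'
#' @param n number of neurons (= states for one-hot input).
#' @return An object of class `rnn_state`.
#' @export
rnn_network <- function(n) {
  stopifnot(n >= 1)
  structure(
    list(J = matrix(0, n, n), n = numeric(n), x_prev = numeric(n), t = 0L),
    class = "rnn_state"
  )
}

#' @export
print.rnn_state <- function(x, ...) {
  cat(sprintf("<rnn_state> %d neurons, %d steps seen, mean |J| = %.4g\n",
              nrow(x$J), x$t, mean(abs(x$J))))
  invisible(x)
}

#' @export
tidy.rnn_state <- function(x, ...) {
  n <- nrow(x$J)
  tibble(
    post = rep(seq_len(n), times = n),
    pre = rep(seq_len(n), each = n),
    weight = as.vector(x$J)
  )
}

#' @export
glance.rnn_state <- function(x, ...) {
  tibble(
    n_neurons = nrow(x$J), steps = x$t,
    row_sum_mean = mean(colSums(x$J)),
    max_real_eig = max_real_eig(x$J)
  )
}

#' Ground-truth successor representation
#'
#' `M = (I - gamma T)^-1 = sum_t gamma^t T^t`, the discounted expected
#' future occupancy of each state from each start state. Serves as the
#' oracle in all recovery-error evaluations. For row-stochastic `T` every
#' row of `M` sums to `1 / (1 - gamma)`.
#'
#' @param T a `transition_matrix` or a row-stochastic matrix.
#' @param gamma discount, `0 <= gamma < 1`.
#' @return A matrix of the same dimension.
#' @export
sr_from_T <- function(T, gamma) {
  Tm <- as_T_matrix(T)
  stopifnot(gamma >= 0, gamma < 1)
  solve(diag(1, nrow(Tm)) - gamma * Tm)
}

#' Steady-state activity of the linear network
#'
#' `x = (I - gamma J)^-1 phi`. With `J = t(T)` and a one-hot `phi = e_j`
#' this retrieves row `j` of the SR matrix at discount `gamma`.
#'
#' @param J synaptic matrix.
#' @param gamma network gain.
#' @param phi input vector.
#' @param check verify stability (max real eigenvalue of `gamma J` below 1)
#'   before solving; inner loops disable this and monitor at a cadence.
#' @return Activity vector.
#' @export
steady_state_linear <- function(J, gamma, phi, check = TRUE) {
  if (check && gamma > 0 && gamma * max_real_eig(J) >= 1)
    abort("unstable dynamics: max real eigenvalue of gamma*J >= 1",
          class = "srnn_instability_error")
  if (gamma == 0) return(as.numeric(phi))
  drop(solve(diag(1, nrow(J)) - gamma * J, phi))
}

#' Number of recurrent steps needed for a given tail tolerance
#'
#' Smallest `t` with `gamma^t < tol`, floored at 1 so at least one
#' recurrent application occurs; `gamma = 0` returns 1.
#'
#' @param gamma gain in `[0, 1)`.
#' @param tol tail tolerance (default `1e-4`).
#' @return A positive integer.
#' @export
choose_tmax <- function(gamma, tol = 1e-4) {
  stopifnot(tol > 0)
  if (gamma < 0 || gamma >= 1) abort("choose_tmax() needs 0 <= gamma < 1")
  if (gamma == 0) return(1L)
  t <- ceiling(log(tol) / log(gamma))
  # guard rounding at the boundary
  while (gamma^t >= tol) t <- t + 1
  while (t > 1 && gamma^(t - 1) < tol) t <- t - 1
  max(1L, as.integer(t))
}

#' Truncated power-series steady state
#'
#' `x = sum_{t=0}^{t_max} gamma^t J^t phi`, accumulated by iterated
#' matrix-vector products (no explicit matrix powers). With `t_max =
#' choose_tmax(gamma)` this matches [steady_state_linear()] within the
#' geometric tail bound.
#'
#' @inheritParams steady_state_linear
#' @param t_max number of series terms beyond the zeroth (>= 0).
#' @return Activity vector.
#' @export
steady_state_truncated <- function(J, gamma, phi, t_max) {
  stopifnot(t_max >= 0)
  x <- as.numeric(phi)
  term <- x
  if (t_max >= 1) {
    for (t in seq_len(t_max)) {
      term <- gamma * drop(J %*% term)
      x <- x + term
    }
  }
  x
}

#' Iterative tanh steady state
#'
#' Iterates the saturating rate dynamics `x <- gamma J tanh(x) + phi`
#' (unit step size, starting from zero) for `t_max` steps and returns the
#' final activity. In the small-activity regime this agrees with the
#' linear solvers to cubic order.
#'
#' @inheritParams steady_state_truncated
#' @export
steady_state_tanh <- function(J, gamma, phi, t_max) {
  stopifnot(t_max >= 1)
  x <- numeric(nrow(J))
  phi <- as.numeric(phi)
  for (t in seq_len(t_max)) {
    x <- gamma * drop(J %*% tanh(x)) + phi
  }
  if (any(!is.finite(x)))
    abort("non-finite activity in tanh dynamics",
          class = "srnn_instability_error")
  x
}

# dispatch on the configured dynamics at the given gain
compute_activity <- function(J, gamma, phi, cfg, check = FALSE) {
  if (gamma == 0) return(as.numeric(phi))
  switch(cfg$dynamics,
    closed_form = steady_state_linear(J, gamma, phi, check = check),
    truncated = steady_state_truncated(J, gamma, phi,
                                       choose_tmax(gamma, cfg$tol_tmax)),
    iterative = steady_state_tanh(J, gamma, phi,
                                  choose_tmax(gamma, cfg$tol_tmax))
  )
}

#' Local synaptic weight update
#'
#' The core plasticity rule: a temporally asymmetric potentiation term
#' pairing presynaptic activity at `t-1` with postsynaptic activity at
#' `t`, and a decorrelative anti-Hebbian normalization proportional to the
#' network's own prediction:
#' `dJ[i, j] = eta_j * (x_t[i] x_prev[j] - x_prev[j] * sum_k J[i, k] x_prev[k])`.
#' The learning rate is indexed by the presynaptic neuron `j`
#' (column-wise), so each column of `J` is normalized independently into a
#' probability-like distribution.
#'
#' @param J synaptic matrix.
#' @param x_t current activity.
#' @param x_prev previous activity.
#' @param eta scalar or per-presynaptic-neuron learning rate vector in
#'   `[0, 1]`.
#' @return The weight change `dJ` (learning rate already applied).
#' @export
weight_update <- function(J, x_t, x_prev, eta) {
  x_t <- as.numeric(x_t); x_prev <- as.numeric(x_prev)
  dJ <- outer(x_t, x_prev) - outer(drop(J %*% x_prev), x_prev)
  scale_columns(dJ, eta)
}

# column-wise learning-rate application: dJ[, j] * eta[j]
scale_columns <- function(dJ, eta) {
  if (length(eta) == 1) return(eta * dJ)
  dJ * rep(eta, each = nrow(dJ))
}

#' Activity trace and adaptive learning rate
#'
#' The trace accumulates a discounted history of each neuron's activity,
#' updated before the weight change as `n <- alpha_n x(t) + lambda n`
#' (the current step included). The adaptive rate for this step is
#' `eta_j = min(1 / n_j, 1)` from the updated trace, with `eta_j = 1`
#' for zero trace, so the first update out of a neuron is essentially
#' one-shot learning. With `lambda = 1` and one-hot activity the trace
#' counts state visits and `eta_j` decays as one over the visit count,
#' the running-average schedule that normalizes each column of `J` into
#' the observed next-state distribution.
#'
#' @param n stored trace (discounted activity through the previous step).
#' @param x_t current activity.
#' @param lambda trace discount in `(0, 1]`.
#' @param alpha_n trace scale.
#' @return A list with the updated trace `n` and the rate vector `eta`
#'   used at this step.
#' @export
update_trace <- function(n, x_t, lambda, alpha_n = 1) {
  stopifnot(all(n >= 0), lambda > 0, lambda <= 1, alpha_n > 0)
  n_new <- alpha_n * as.numeric(x_t) + lambda * n
  eta <- pmin(1 / n_new, 1)
  eta[n_new == 0] <- 1
  list(n = n_new, eta = eta)
}

#' One learning step
#'
#' Computes the steady-state activity for the input under the learning
#' gain `gamma_b`, updates the activity trace and (in adaptive mode) the
#' per-neuron learning rates, applies [weight_update()] (clipping
#' synapses at zero when `cfg$nonneg` is set), and advances the stored
#' previous activity. The very first step makes no weight change
#' (`x_prev` starts at zero: no fictitious predecessor state).
#'
#' @param state an [rnn_network()] state.
#' @param phi_t input vector.
#' @param cfg an [rnn_config()].
#' @return A list with the updated `state` and the activity `x`.
#' @export
step_learn <- function(state, phi_t, cfg) {
  x_t <- compute_activity(state$J, cfg$gamma_b, phi_t, cfg)
  tr <- update_trace(state$n, x_t, cfg$lambda, cfg$alpha_n)
  eta <- if (cfg$lr_mode == "adaptive") tr$eta else cfg$eta_static
  state$J <- state$J + weight_update(state$J, x_t, state$x_prev, eta)
  if (cfg$nonneg) state$J[state$J < 0] <- 0
  state$n <- tr$n
  state$x_prev <- x_t
  state$t <- state$t + 1L
  list(state = state, x = x_t)
}

#' One retrieval step
#'
#' Pure function of the state: returns the steady-state activity at the
#' retrieval gain `gamma_r` without touching `J`, the trace, or the
#' stored previous activity. Modulating `gamma_r` changes the predictive
#' horizon of the retrieved SR without any relearning.
#'
#' @inheritParams step_learn
#' @return Activity vector.
#' @export
step_retrieve <- function(state, phi_t, cfg) {
  compute_activity(state$J, cfg$gamma_r, phi_t, cfg, check = FALSE)
}

#' Run a learning/retrieval session
#'
#' Drives the network through an input stream, dispatching each step to
#' [step_learn()] or [step_retrieve()] according to the mode schedule
#' (0 = learn, 1 = retrieve). Stability (max real eigenvalue of the
#' effective-gain-scaled `J`), column sums, and oracle errors are logged
#' every `log_every` steps; if instability is detected the session halts
#' with the state preserved and the event recorded.
#'
#' @param walk an `srnn_walk`, an integer state vector, or a steps-by-N
#'   input matrix (rows are `phi(t)`).
#' @param features optional `feature_set`; one-hot encoding when `NULL`.
#' @param cfg an [rnn_config()].
#' @param schedule integer/logical vector of modes per step (0 learn /
#'   1 retrieve); defaults to all-learning.
#' @param state optional starting [rnn_network()] state.
#' @param oracle_T optional ground-truth transition matrix: enables
#'   `mae_T` / `mae_M` columns in the log (`mae_M` at gain `gamma_r`).
#' @param rule plasticity rule: the full decorrelative rule
#'   (`"decorrelative"`), the Oja-like `"independent"` normalization, or
#'   `"kernel"` (requires `kernel`).
#' @param kernel a [plasticity_kernel()] when `rule = "kernel"`.
#' @param log_every logging/stability-check cadence in steps.
#' @param keep_activity store the full activity matrix (steps x N).
#' @param halt_on_instability stop learning at the first logged
#'   instability.
#' @return An object of class `rnn_session`: list with `state`, `log`
#'   (tibble), `activity` (matrix or NULL), and `instability` (NULL or the
#'   step at which instability was flagged).
#' @export
run_session <- function(walk, features = NULL, cfg = rnn_config(),
                        schedule = NULL, state = NULL, oracle_T = NULL,
                        rule = c("decorrelative", "independent", "kernel"),
                        kernel = NULL, log_every = 100,
                        keep_activity = TRUE, halt_on_instability = TRUE) {
  rule <- match.arg(rule)
  if (rule == "kernel" && is.null(kernel))
    abort("rule = 'kernel' requires a plasticity_kernel")
  Phi <- if (is.matrix(walk) && !inherits(walk, "srnn_walk")) walk
         else phi_stream(walk, features)
  Tsteps <- nrow(Phi)
  N <- ncol(Phi)
  if (is.null(schedule)) schedule <- rep(0L, Tsteps)
  if (length(schedule) != Tsteps)
    abort("schedule must have one mode flag per input step")
  if (is.null(state)) state <- rnn_network(N)
  oracle_Tm <- if (!is.null(oracle_T)) as_T_matrix(oracle_T)
  oracle_M <- if (!is.null(oracle_T)) sr_from_T(oracle_Tm, cfg$gamma_r)
  X <- if (keep_activity) matrix(0, Tsteps, N)
  buffer <- if (rule == "kernel") matrix(0, kernel$t_k + 1L, N)
  logs <- list()
  instability <- NULL

  log_row <- function(step) {
    me <- max_real_eig(state$J)
    gamma_eff <- max(cfg$gamma_b, if (any(schedule == 1L)) cfg$gamma_r else 0)
    row <- tibble(
      step = step,
      row_sum_mean = mean(colSums(state$J)),
      max_real_eig = me,
      unstable = !is.finite(me) || cfg$gamma_b * me >= 1
    )
    if (!is.null(oracle_Tm)) {
      row$mae_T <- mae_matrix(t(state$J), oracle_Tm)
      mae_m <- tryCatch(
        mae_matrix(t(solve(diag(1, N) - cfg$gamma_r * state$J)), oracle_M),
        error = function(e) NA_real_)
      row$mae_M <- mae_m
    }
    row
  }

  for (t in seq_len(Tsteps)) {
    phi_t <- Phi[t, ]
    if (schedule[t] == 1L) {
      x <- step_retrieve(state, phi_t, cfg)
    } else {
      res <- tryCatch(
        switch(rule,
          decorrelative = step_learn(state, phi_t, cfg),
          independent = step_learn_independent(state, phi_t, cfg),
          kernel = {
            out <- step_learn_kernel(state, phi_t, cfg, kernel, buffer)
            buffer <- out$buffer
            out
          }),
        srnn_instability_error = function(e) e,
        error = function(e) e)
      if (!inherits(res, "error") && any(!is.finite(res$x)))
        res <- simpleError("non-finite activity")
      if (inherits(res, "error")) {
        instability <- t
        logs[[length(logs) + 1L]] <- tibble(
          step = t, row_sum_mean = mean(colSums(state$J)),
          max_real_eig = NA_real_, unstable = TRUE)
        break
      }
      state <- res$state
      x <- res$x
    }
    if (keep_activity) X[t, ] <- x
    if (t %% log_every == 0 || t == Tsteps) {
      row <- log_row(t)
      logs[[length(logs) + 1L]] <- row
      if (row$unstable) {
        instability <- t
        if (halt_on_instability) break
      }
    }
  }

  structure(
    list(state = state,
         log = if (length(logs)) bind_rows(logs) else
           tibble(step = integer(), row_sum_mean = double(),
                  max_real_eig = double(), unstable = logical()),
         activity = if (keep_activity) X[seq_len(min(Tsteps, if (is.null(instability)) Tsteps else instability)), , drop = FALSE],
         schedule = schedule,
         cfg = cfg,
         instability = instability),
    class = "rnn_session"
  )
}

#' @export
print.rnn_session <- function(x, ...) {
  cat(sprintf("<rnn_session> %d logged checkpoints, %s\n",
              nrow(x$log),
              if (is.null(x$instability)) "stable"
              else sprintf("instability at step %d", x$instability)))
  invisible(x)
}

#' @export
tidy.rnn_session <- function(x, ...) x$log

#' @export
glance.rnn_session <- function(x, ...) {
  last <- if (nrow(x$log)) x$log[nrow(x$log), ] else NULL
  tibble(
    steps = x$state$t,
    row_sum_mean = if (!is.null(last)) last$row_sum_mean else NA_real_,
    max_real_eig = if (!is.null(last)) last$max_real_eig else NA_real_,
    unstable = !is.null(x$instability)
  )
}
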