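#' Plasticity kernels
#'
#' Generalizes the lag-1 STDP pairing of the core rule to a convolution of
#' presynaptic history with exponential kernels. The pre->post side
#' `K+(t) = A_plus * exp(-t / tau_plus)` potentiates; the post->pre side
#' `K-(t) = A_minus * exp(-t / tau_minus)` may potentiate or depress
#' (`A_minus` is sign-free, `A_plus` must be positive). `alpha_d` scales
#' updates to self-synapses and `alpha_n` the learning-rate trace; `t_k`
#' is the temporal support of the kernel in steps.
#'
#' `delta_kernel()` builds the kernel supported at a single lag with unit
#' weight, the explicit construction under which the kernel rule reduces
#' to the core lag-1 rule.
#'
#' @param A_plus,tau_plus pre->post amplitude (> 0) and time constant
#'   (steps, > 0).
#' @param A_minus,tau_minus post->pre amplitude (sign free) and time
#'   constant (> 0).
#' @param alpha_d self-synapse scale.
#' @param alpha_n learning-rate trace scale.
#' @param t_k support length in steps (>= 1, default 20, chosen so
#'   `exp(-t_k / tau)` is negligible for the time constants of interest).
#' @return An object of class `plasticity_kernel` carrying the evaluated
#'   lag-weight vectors `w_plus`, `w_minus` over lags `0..t_k`.
#' @export
plasticity_kernel <- function(A_plus, tau_plus, A_minus = 0, tau_minus = 1,
                              alpha_d = 1, alpha_n = 1, t_k = 20) {
  stopifnot(tau_plus > 0, tau_minus > 0, t_k >= 1, alpha_n > 0)
  if (A_plus <= 0) abort("A_plus must be positive")
  lags <- 0:t_k
  structure(
    list(A_plus = A_plus, tau_plus = tau_plus,
         A_minus = A_minus, tau_minus = tau_minus,
         alpha_d = alpha_d, alpha_n = alpha_n, t_k = as.integer(t_k),
         w_plus = kernel_eval(A_plus, tau_plus, lags),
         w_minus = kernel_eval(A_minus, tau_minus, lags)),
    class = "plasticity_kernel"
  )
}

#' @rdname plasticity_kernel
#' @param lag the single supported lag (default 1).
#' @param weight weight at that lag.
#' @export
delta_kernel <- function(lag = 1, weight = 1, alpha_d = 1, alpha_n = 1,
                         t_k = 20) {
  stopifnot(lag >= 0, lag <= t_k)
  w_plus <- numeric(t_k + 1)
  w_plus[lag + 1] <- weight
  structure(
    list(A_plus = weight, tau_plus = NA_real_, A_minus = 0,
         tau_minus = NA_real_, alpha_d = alpha_d, alpha_n = alpha_n,
         t_k = as.integer(t_k),
         w_plus = w_plus, w_minus = numeric(t_k + 1)),
    class = "plasticity_kernel"
  )
}

#' @export
print.plasticity_kernel <- function(x, ...) {
  cat(sprintf(
    "<plasticity_kernel> A+ = %.3g (tau+ = %.3g), A- = %.3g (tau- = %.3g), t_k = %d\n",
    x$A_plus, x$tau_plus, x$A_minus, x$tau_minus, x$t_k))
  invisible(x)
}

#' Evaluate an exponential kernel side
#'
#' `A * exp(-t / tau)` at integer lag(s) `t >= 0`.
#'
#' @param A amplitude.
#' @param tau time constant in steps.
#' @param t lag(s).
#' @return Kernel weight(s).
#' @export
kernel_eval <- function(A, tau, t) {
  stopifnot(all(t >= 0))
  A * exp(-t / tau)
}

#' Kernel-convolution weight update
#'
#' Convolves the buffered activity history (lags `0..t_k`, newest first)
#' with the kernel sides: `k+ = sum_t' K+(t') x(t - t')` and likewise
#' `k-`. The Hebbian contribution is `x(t) k+^T + k- x(t)^T`, with
#' diagonal (self-synapse) entries replaced by the `alpha_d`-scaled
#' pre->post term, and the same decorrelative normalization
#' `(J x(t-1)) x(t-1)^T` as the core rule is subtracted. The learning
#' rate applies column-wise as usual.
#'
#' @param J synaptic matrix.
#' @param buffer activity buffer, `(t_k + 1) x N`, row 1 = lag 0.
#' @param x_prev previous activity (normalization argument).
#' @param kernel a [plasticity_kernel()].
#' @param eta scalar or per-presynaptic-neuron rate.
#' @return The weight change `dJ`.
#' @export
kernel_weight_update <- function(J, buffer, x_prev, kernel, eta = 1) {
  x_t <- buffer[1L, ]
  k_plus <- drop(crossprod(buffer, kernel$w_plus))
  k_minus <- drop(crossprod(buffer, kernel$w_minus))
  dJK <- outer(x_t, k_plus) + outer(k_minus, x_t)
  diag(dJK) <- kernel$alpha_d * x_t * k_plus
  dJ <- dJK - outer(drop(J %*% x_prev), x_prev)
  scale_columns(dJ, eta)
}

# one learning step under the kernel rule; returns updated buffer too
step_learn_kernel <- function(state, phi_t, cfg, kernel, buffer) {
  x_t <- compute_activity(state$J, cfg$gamma_b, phi_t, cfg)
  buffer <- rbind(x_t, buffer[-nrow(buffer), , drop = FALSE])
  tr <- update_trace(state$n, x_t, cfg$lambda, kernel$alpha_n)
  eta <- if (cfg$lr_mode == "adaptive") tr$eta else cfg$eta_static
  state$J <- state$J + kernel_weight_update(state$J, buffer, state$x_prev,
                                            kernel, eta)
  if (cfg$nonneg) state$J[state$J < 0] <- 0
  state$n <- tr$n
  state$x_prev <- x_t
  state$t <- state$t + 1L
  list(state = state, x = x_t, buffer = buffer)
}

#' Derivative-free search over plasticity-kernel parameters
#'
#' Grid search over the sign of the post->pre side and the two time
#' constants; within each grid cell the free amplitudes
#' (`A_plus`, `|A_minus|`, `alpha_d`, `alpha_n`) are optimized by a
#' pluggable derivative-free method from `n_inits` random initializations.
#' The objective is the mean squared error between the final learned `J`
#' and the empirical transition matrix (transposed) of each training
#' walk. Cells whose best-fit amplitude is negligibly small (below
#' `1e-3` of the grid's median learned amplitude) are set to a
#' high-error sentinel; a max-clipped error column is provided for
#' heatmap display.
#'
#' @param walks list of `srnn_walk`s (one-hot input streams).
#' @param tau_plus_grid,tau_minus_grid time constants (steps) to fix.
#' @param signs post->pre signs to try: any subset of `c(-1, 1)`.
#' @param n_inits random initializations per cell.
#' @param cfg an [rnn_config()]; its `gamma_b` governs learning-phase
#'   activity.
#' @param optimizer a `function(f, x0, seed)` returning
#'   `list(par, value)`; defaults to Nelder-Mead ([stats::optim()]).
#' @param include_delta also score the explicit lag-1 delta kernel (the
#'   core rule) as a reference row.
#' @param t_k kernel support.
#' @param maxit iteration budget per optimizer run.
#' @param clip errors are max-clipped at this value in `error_clipped`.
#' @param seed integer seed controlling the initializations.
#' @return A tibble with one row per grid cell: `sign_minus`,
#'   `tau_plus`, `tau_minus`, `min_error`, `error_clipped`, best-fit
#'   parameters, and a `delta` flag for the reference row.
#' @export
kernel_search <- function(walks, tau_plus_grid = c(1, 3),
                          tau_minus_grid = c(1, 3), signs = c(-1, 1),
                          n_inits = 3, cfg = rnn_config(),
                          optimizer = NULL, include_delta = FALSE,
                          t_k = 20, maxit = 60, clip = 0.03, seed = 1) {
  if (length(walks) == 0) abort("empty walk distribution")
  if (is.null(optimizer)) optimizer <- nm_optimizer(maxit = maxit)
  oracles <- map(walks, function(w) t(empirical_transition_matrix(w)$T))

  objective_for <- function(make_kernel) {
    function(theta) {
      k <- tryCatch(make_kernel(theta), error = function(e) NULL)
      if (is.null(k)) return(1e6)
      err <- tryCatch({
        errs <- map_dbl(seq_along(walks), function(i) {
          sess <- run_session(walks[[i]], cfg = cfg, rule = "kernel",
                              kernel = k, keep_activity = FALSE,
                              log_every = 1e9)
          if (!is.null(sess$instability)) return(1e6)
          mean((sess$state$J - oracles[[i]])^2)
        })
        mean(errs)
      }, error = function(e) 1e6)
      if (!is.finite(err)) 1e6 else err
    }
  }

  seeds <- split_seed(seed, 10000)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  cells <- expand.grid(sign_minus = signs, tau_plus = tau_plus_grid,
                       tau_minus = tau_minus_grid)
  rows <- pmap(cells, function(sign_minus, tau_plus, tau_minus) {
    make_kernel <- function(theta) {
      # theta = (log A+, log |A-|, alpha_d, alpha_n on log scale)
      plasticity_kernel(
        A_plus = exp(theta[1]), tau_plus = tau_plus,
        A_minus = sign_minus * exp(theta[2]), tau_minus = tau_minus,
        alpha_d = theta[3], alpha_n = exp(theta[4]), t_k = t_k)
    }
    f <- objective_for(make_kernel)
    best <- NULL
    for (i in seq_len(n_inits)) {
      s <- next_seed()
      x0 <- with_seed(s, c(rnorm(1, 0, 0.7), rnorm(1, -1, 0.7),
                           rnorm(1, 1, 0.3), rnorm(1, 0, 0.3)))
      res <- tryCatch(optimizer(f, x0, s), error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best)) {
      return(tibble(sign_minus = sign_minus, tau_plus = tau_plus,
                    tau_minus = tau_minus, min_error = NA_real_,
                    A_plus = NA_real_, A_minus = NA_real_,
                    alpha_d = NA_real_, alpha_n = NA_real_,
                    failed = TRUE, delta = FALSE))
    }
    tibble(sign_minus = sign_minus, tau_plus = tau_plus,
           tau_minus = tau_minus, min_error = best$value,
           A_plus = exp(best$par[1]),
           A_minus = sign_minus * exp(best$par[2]),
           alpha_d = best$par[3], alpha_n = exp(best$par[4]),
           failed = FALSE, delta = FALSE)
  })
  out <- bind_rows(rows)

  if (include_delta) {
    f <- objective_for(function(theta) {
      delta_kernel(lag = 1, weight = exp(theta[1]), alpha_d = theta[2],
                   alpha_n = exp(theta[3]), t_k = t_k)
    })
    best <- NULL
    for (i in seq_len(n_inits)) {
      s <- next_seed()
      x0 <- with_seed(s, c(rnorm(1, 0, 0.3), rnorm(1, 1, 0.2),
                           rnorm(1, 0, 0.2)))
      res <- tryCatch(optimizer(f, x0, s), error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (!is.null(best)) {
      out <- bind_rows(out, tibble(
        sign_minus = 0, tau_plus = NA_real_, tau_minus = NA_real_,
        min_error = best$value, A_plus = exp(best$par[1]),
        A_minus = 0, alpha_d = best$par[2], alpha_n = exp(best$par[3]),
        failed = FALSE, delta = TRUE))
    }
  }

  # negligibly-small-amplitude sentinel
  med_amp <- median(abs(out$A_plus), na.rm = TRUE)
  tiny <- !is.na(out$A_plus) & abs(out$A_plus) < 1e-3 * med_amp
  out$min_error[tiny] <- pmax(out$min_error[tiny], 1e6, na.rm = TRUE)
  out$error_clipped <- pmin(out$min_error, clip)
  out
}

# default derivative-free optimizer: Nelder-Mead via stats::optim
nm_optimizer <- function(maxit = 60) {
  function(f, x0, seed) {
    res <- optim(x0, f, method = "Nelder-Mead",
                 control = list(maxit = maxit))
    list(par = res$par, value = res$value)
  }
}
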