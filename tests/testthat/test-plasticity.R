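test_that("exponential kernel evaluation", {
  expect_equal(kernel_eval(2, 3, 0), 2)
  expect_equal(kernel_eval(2, 3, 3), 2 / exp(1))
  expect_equal(kernel_eval(1, 3, 6), exp(-2), tolerance = 1e-12)
  k <- plasticity_kernel(A_plus = 1, tau_plus = 2, A_minus = -0.5,
                         tau_minus = 4)
  expect_equal(k$w_plus, exp(-(0:20) / 2))
  expect_equal(k$w_minus, -0.5 * exp(-(0:20) / 4))
  expect_error(plasticity_kernel(A_plus = -1, tau_plus = 1), "positive")
})

test_that("kernel convolution update has the stated structure", {
  k <- plasticity_kernel(A_plus = 1, tau_plus = 2, A_minus = -0.4,
                         tau_minus = 3, t_k = 5)
  buf <- matrix(0, 6, 4)
  expect_equal(kernel_weight_update(diag(0.1, 4), buf, rep(0, 4), k, 1),
               matrix(0, 4, 4))

  # post->pre depression: e_i then e_j puts a negative term at [j_pre? -> J_ji]
  buf2 <- matrix(0, 6, 4)
  buf2[2, 1] <- 1          # x(t-1) = e_1
  buf2[1, 2] <- 1          # x(t)   = e_2
  dJ <- kernel_weight_update(matrix(0, 4, 4), buf2, c(1, 0, 0, 0), k, 1)
  # pre->post: J[2,1] gets A+ * exp(-1/tau+)
  expect_equal(dJ[2, 1], exp(-1 / 2))
  # post->pre (negative kernel): J[1,2] gets the depressing contribution
  expect_lt(dJ[1, 2], 0)

  # linearity in the kernel amplitudes at fixed history
  k2 <- plasticity_kernel(A_plus = 2, tau_plus = 2, A_minus = -0.8,
                          tau_minus = 3, t_k = 5)
  buf3 <- matrix(abs(sin(1:24)), 6, 4)
  d1 <- kernel_weight_update(matrix(0, 4, 4), buf3, buf3[2, ], k, 1)
  d2 <- kernel_weight_update(matrix(0, 4, 4), buf3, buf3[2, ], k2, 1)
  norm_term <- -outer(rep(0, 4), buf3[2, ])  # J = 0 so normalization is 0
  expect_equal(d2, 2 * d1 + norm_term, tolerance = 1e-12)
})

test_that("the lag-1 delta kernel reproduces the core rule exactly", {
  w <- simulate_walk(ring_env(8), forward_bias_actions(), 200, seed = 6)
  cfg <- rnn_config(gamma_b = 0)
  base <- run_session(w, cfg = cfg, keep_activity = FALSE, log_every = 1e9)
  dk <- delta_kernel(lag = 1)
  kern <- run_session(w, cfg = cfg, rule = "kernel", kernel = dk,
                      keep_activity = FALSE, log_every = 1e9)
  expect_lt(max(abs(base$state$J - kern$state$J)), 1e-6)
})

test_that("kernel support truncation error is bounded by the tail weight", {
  w <- simulate_walk(ring_env(6), ring_actions(), 80, seed = 2)
  cfg <- rnn_config(gamma_b = 0)
  for (tau in c(2, 5)) {
    k20 <- plasticity_kernel(A_plus = 1, tau_plus = tau, t_k = 20)
    k40 <- plasticity_kernel(A_plus = 1, tau_plus = tau, t_k = 40)
    s20 <- run_session(w, cfg = cfg, rule = "kernel", kernel = k20,
                       keep_activity = FALSE, log_every = 1e9)
    s40 <- run_session(w, cfg = cfg, rule = "kernel", kernel = k40,
                       keep_activity = FALSE, log_every = 1e9)
    # tail weight of the exponential beyond lag 20, times buffer sup (1),
    # accumulated over the walk
    bound <- exp(-20 / tau) * length(w$states) * 2
    expect_lt(max(abs(s20$state$J - s40$state$J)), bound)
  }
})

test_that("kernel search scores the delta configuration best on one-hot walks", {
  walks <- list(simulate_walk(ring_env(8), forward_bias_actions(), 250,
                              seed = 3))
  tbl <- kernel_search(walks, tau_plus_grid = c(1, 4), tau_minus_grid = 2,
                       signs = c(-1, 1), n_inits = 2, maxit = 40,
                       include_delta = TRUE, seed = 5)
  expect_true(any(tbl$delta))
  delta_err <- tbl$min_error[tbl$delta]
  expect_true(all(delta_err <= tbl$min_error[!tbl$delta] + 1e-10))
  expect_true(all(tbl$error_clipped <= 0.03 + 1e-12))

  # deterministic under a fixed seed
  tbl2 <- kernel_search(walks, tau_plus_grid = c(1, 4), tau_minus_grid = 2,
                        signs = c(-1, 1), n_inits = 2, maxit = 40,
                        include_delta = TRUE, seed = 5)
  expect_equal(tbl$min_error, tbl2$min_error)

  expect_error(kernel_search(list()), "empty")
})
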