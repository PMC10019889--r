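#' Mean absolute error between matrices
#'
#' Optionally masks rows (e.g. unvisited states of an empirical
#' transition matrix) so they are excluded from the average.
#'
#' @param A,B matrices of identical shape.
#' @param mask optional logical row flags; `FALSE` rows are excluded.
#' @return Scalar mean of `|A - B|` over unmasked entries.
#' @export
mae_matrix <- function(A, B, mask = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) abort("shape mismatch in mae_matrix()")
  if (!is.null(mask)) {
    A <- A[mask, , drop = FALSE]
    B <- B[mask, , drop = FALSE]
  }
  mean(abs(A - B))
}

#' Row sums of the transition-matrix estimate
#'
#' The network stores its transition estimate transposed (`J` estimates
#' `t(T)`), so the row sums of the estimated `T` are the column sums of
#' `J`. A correctly normalized estimate has every value at 1.
#'
#' @param J synaptic matrix.
#' @return A list with `mean` and the per-row vector `row_sums`.
#' @export
row_sum_T <- function(J) {
  stopifnot(nrow(J) == ncol(J))
  rs <- colSums(J)
  list(mean = mean(rs), row_sums = rs)
}

#' Temporal-difference loss of an SR estimate
#'
#' Mean over sampled transitions of the squared Euclidean norm of the TD
#' error vector `phi + gamma M^T phi_next - M^T phi`. `M` is in RL
#' orientation (`M[j, i]`: source `j`, predicted `i`). Zero exactly at
#' the TD fixed point on deterministic one-hot chains.
#'
#' @param M SR estimate.
#' @param samples a list with matrices `phi` and `phi_next` (rows are
#'   samples), as produced by [sample_transitions()].
#' @param gamma discount.
#' @return Scalar loss.
#' @export
td_loss <- function(M, samples, gamma) {
  Phi <- samples$phi; Phin <- samples$phi_next
  stopifnot(nrow(Phi) >= 1, all(dim(Phi) == dim(Phin)))
  E <- Phi + gamma * Phin %*% M - Phi %*% M
  mean(rowSums(E^2))
}

#' Sample observed transitions from a walk
#'
#' Draws (with replacement) random `(phi, phi_next)` pairs from the
#' transitions of a walk, the evaluation set for [td_loss()].
#'
#' @param walk an `srnn_walk` or state vector.
#' @param features optional `feature_set`; one-hot when `NULL`.
#' @param n number of samples (default 1000).
#' @param seed optional seed.
#' @return A list of matrices `phi` and `phi_next`.
#' @export
sample_transitions <- function(walk, features = NULL, n = 1000, seed = NULL) {
  Phi <- phi_stream(walk, features)
  Tsteps <- nrow(Phi)
  stopifnot(Tsteps >= 2)
  idx <- with_seed(seed, sample.int(Tsteps - 1L, n, replace = TRUE))
  list(phi = Phi[idx, , drop = FALSE], phi_next = Phi[idx + 1L, , drop = FALSE])
}

#' Spectral stability of the recurrent dynamics
#'
#' `max_real_eig()` returns the largest real part over the eigenvalue
#' spectrum of `J`; the linear dynamics at gain `gamma` are unstable iff
#' `gamma * max_real_eig(J) >= 1`. For a learned stochastic-matrix
#' transpose the leading eigenvalue is 1 (Perron-Frobenius), so any
#' `gamma < 1` retrieval is stable once learning is correct.
#'
#' @param J square synaptic matrix.
#' @param gamma gain at which stability is assessed.
#' @return `max_real_eig()`: scalar; `stability_flag()`: `TRUE` when
#'   stable.
#' @export
max_real_eig <- function(J) {
  if (any(!is.finite(J))) return(Inf)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' @rdname max_real_eig
#' @export
stability_flag <- function(J, gamma) {
  gamma * max_real_eig(J) < 1
}

#' Lagged second-moment matrices of an input stream
#'
#' Raw (uncentered, unnormalized) second moments
#' `R(tau)[i, j] = mean_t phi_i(t) phi_j(t + tau)` at lags 0 and -1,
#' both averaged over the same `T - 1` lagged pairs. The raw-moment
#' convention is what makes the closed-form weight oracle reduce to the
#' empirical transition matrix in the one-hot case.
#'
#' @param phi_series steps-by-N input matrix (rows are `phi(t)`).
#' @return A list with `R0`, `Rm1`, and `n_samples`.
#' @export
lagged_correlations <- function(phi_series) {
  Phi <- as.matrix(phi_series)
  Tsteps <- nrow(Phi)
  stopifnot(Tsteps >= 2)
  pre <- Phi[-Tsteps, , drop = FALSE]
  post <- Phi[-1L, , drop = FALSE]
  list(R0 = crossprod(pre) / (Tsteps - 1),
       Rm1 = crossprod(post, pre) / (Tsteps - 1),
       n_samples = Tsteps - 1L)
}

#' Closed-form steady-state weights
#'
#' The analytical fixed point of the decorrelative learning rule:
#' `J = R(-1) R(0)^-1`, an STDP-like map of decorrelated inputs to the
#' next-step expectation. For one-hot input streams this equals the
#' empirical transition matrix transposed. A singular `R0` falls back to
#' the Moore-Penrose pseudo-inverse (flagged) when allowed.
#'
#' @inheritParams lagged_correlations
#' @param allow_pseudo use the pseudo-inverse when `R0` is singular.
#' @return A matrix with attribute `pseudo_inverse` (logical flag).
#' @export
closed_form_J <- function(phi_series, allow_pseudo = TRUE) {
  R <- lagged_correlations(phi_series)
  pseudo <- FALSE
  Jhat <- tryCatch(
    t(solve(t(R$R0), t(R$Rm1))),
    error = function(e) {
      if (!allow_pseudo)
        abort("singular zero-lag moment matrix; pseudo-inverse not permitted",
              class = "srnn_singular_error")
      pseudo <<- TRUE
      R$Rm1 %*% ginv(R$R0)
    })
  attr(Jhat, "pseudo_inverse") <- pseudo
  Jhat
}
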