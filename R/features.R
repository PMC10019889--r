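#' Feature encodings of states
#'
#' Per-state input vectors `phi` driving the network. For `N` states the
#' encoding is `N`-dimensional: `one_hot_features()` gives the identity
#' (each state drives a unique input neuron); `generate_features()` draws
#' dense, spatially correlated encodings by thresholded binary draws
#' followed by a Gaussian blur over the state geometry.
#'
#' @name features
NULL

new_feature_set <- function(Phi, env, p, sigma, seed = NULL,
                            degenerate = rep(FALSE, ncol(Phi))) {
  s <- median(rowSums(abs(Phi)) / ncol(Phi))
  structure(
    list(Phi = Phi, env = env, p = p, sigma = sigma, s = s,
         seed = seed, degenerate = degenerate),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> %d states x %d features (p = %.3g, sigma = %.3g cm, sparsity = %.3g)\n",
    nrow(x$Phi), ncol(x$Phi), x$p, x$sigma, x$s))
  invisible(x)
}

#' @describeIn features identity encoding; sparsity `1/n_states`.
#' @param env an environment, or (for `one_hot_features`) a state count.
#' @export
one_hot_features <- function(env) {
  n <- if (inherits(env, "srnn_env")) env$n_states else as.integer(env)
  stopifnot(n >= 1)
  e <- if (inherits(env, "srnn_env")) env else ring_env(max(n, 2))
  fs <- new_feature_set(diag(1, n), e, p = 1 / n, sigma = 0)
  fs
}

# Gaussian smoothing operator over the state geometry, as a dense
# n_states x n_states matrix S: smoothed = S %*% values. Ring wraps;
# grid uses reflective boundaries. Kernel truncated at `radius_sd`
# standard deviations and renormalized.
smoothing_operator <- function(env, sigma_bins, radius_sd = 1) {
  n <- env$n_states
  if (sigma_bins <= 0) return(diag(1, n))
  r <- floor(sigma_bins * radius_sd)
  if (r < 1) return(diag(1, n))
  S <- matrix(0, n, n)
  if (env$geometry == "ring") {
    offs <- -r:r
    w <- exp(-offs^2 / (2 * sigma_bins^2))
    w <- w / sum(w)
    for (j in seq_len(n)) {
      tgt <- (j - 1 + offs) %% n + 1
      for (k in seq_along(offs)) S[j, tgt[k]] <- S[j, tgt[k]] + w[k]
    }
  } else {
    offs <- expand.grid(dr = -r:r, dc = -r:r)
    d2 <- offs$dr^2 + offs$dc^2
    keep <- sqrt(d2) <= sigma_bins * radius_sd
    offs <- offs[keep, , drop = FALSE]
    w <- exp(-(offs$dr^2 + offs$dc^2) / (2 * sigma_bins^2))
    w <- w / sum(w)
    reflect <- function(i, m) {
      # reflective boundary: 0 -> 1, m+1 -> m, etc.
      i <- ifelse(i < 1L, 2L - i, i)
      ifelse(i > m, 2L * m - i, i)
    }
    for (j in seq_len(n)) {
      rc <- grid_rc(j, env)
      r2 <- reflect(rc[1] + offs$dr, env$h)
      c2 <- reflect(rc[2] + offs$dc, env$w)
      tgt <- grid_state(r2, c2, env)
      for (k in seq_along(tgt)) S[j, tgt[k]] <- S[j, tgt[k]] + w[k]
    }
  }
  S
}

#' @describeIn features random binary draws at probability `p`, blurred by a
#'   Gaussian of standard deviation `sigma` (cm, converted to bins; support
#'   truncated at one standard deviation), then per-feature min-subtracted
#'   and max-normalized into `[0, 1]`. Features that come out constant are
#'   flagged degenerate and zeroed.
#' @param p probability that a raw feature entry is on (0 < p <= 1).
#' @param sigma spatial blur scale in cm (standard deviation).
#' @param seed optional integer seed.
#' @export
generate_features <- function(env, p, sigma, seed = NULL) {
  stopifnot(inherits(env, "srnn_env"))
  if (p <= 0) abort("p must be positive: p = 0 yields no active features")
  if (p > 1 || sigma < 0) abort("need 0 < p <= 1 and sigma >= 0")
  n <- env$n_states
  Phi <- with_seed(seed, matrix(rbinom(n * n, 1, p), n, n))
  S <- smoothing_operator(env, sigma / env$bin_size, radius_sd = 1)
  Phi <- S %*% Phi
  degenerate <- logical(n)
  for (f in seq_len(n)) {
    col <- Phi[, f] - min(Phi[, f])
    m <- max(col)
    if (m <= .Machine$double.eps) {
      degenerate[f] <- TRUE
      Phi[, f] <- 0
    } else {
      Phi[, f] <- col / m
    }
  }
  new_feature_set(Phi, env, p = p, sigma = sigma, seed = seed,
                  degenerate = degenerate)
}

#' Median sparsity of a feature set
#'
#' The sparsity of one state's encoding is its L1 norm divided by the
#' number of features; the set's sparsity is the median over states
#' (midpoint convention for even counts).
#'
#' @param fs a `feature_set`.
#' @return A fraction in `[0, 1]`.
#' @export
measure_sparsity <- function(fs) {
  Phi <- if (inherits(fs, "feature_set")) fs$Phi else as.matrix(fs)
  stopifnot(length(Phi) > 0)
  median(rowSums(abs(Phi)) / ncol(Phi))
}

#' Spatial correlation profile of a feature set
#'
#' Mean Pearson correlation between the feature vectors of state pairs,
#' binned by the spatial distance between the states (circular distance on
#' the ring, Euclidean on the grid, in cm). Decreases with distance for
#' blurred features; the zero-distance bin is 1 by definition.
#'
#' @param fs a `feature_set` (its environment supplies the geometry).
#' @return A tibble with `distance_cm`, `mean_correlation`, `n_pairs`.
#' @export
spatial_correlation_profile <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  env <- fs$env
  Phi <- fs$Phi
  n <- nrow(Phi)
  sds <- apply(Phi, 1, stats::sd)
  ok <- sds > 0
  C <- suppressWarnings(cor(t(Phi)))
  if (env$geometry == "ring") {
    idx <- seq_len(n) - 1
    d <- outer(idx, idx, function(a, b) pmin(abs(a - b), n - abs(a - b)))
  } else {
    rc <- grid_rc(seq_len(n), env)
    d <- as.matrix(stats::dist(rc))
  }
  d <- d * env$bin_size
  pairs <- which(upper.tri(d, diag = TRUE), arr.ind = TRUE)
  keep <- ok[pairs[, 1]] & ok[pairs[, 2]]
  tibble(
    distance_cm = round(d[pairs][keep], 6),
    correlation = C[pairs][keep]
  ) |>
    group_by(.data$distance_cm) |>
    summarise(mean_correlation = mean(.data$correlation), n_pairs = n(),
              .groups = "drop") |>
    arrange(.data$distance_cm)
}

# phi stream for a walk: steps x n_features matrix, row t = phi(state_t)
phi_stream <- function(walk, features = NULL) {
  states <- if (inherits(walk, "srnn_walk")) walk$states else as.integer(walk)
  if (is.null(features)) {
    n <- if (inherits(walk, "srnn_walk")) walk$env$n_states else max(states)
    Phi <- diag(1, n)
  } else {
    Phi <- if (inherits(features, "feature_set")) features$Phi else as.matrix(features)
  }
  Phi[states, , drop = FALSE]
}
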