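#' Discrete-state environments
#'
#' An environment discretizes space into states the agent transitions
#' through. `ring_env()` is a 1D circular track of `n_states` bins;
#' `grid_env()` is a 2D rectangular arena of `h x w` bins enumerated
#' row-major. One timestep is `dt` seconds and adjacent bins are `bin_size`
#' cm apart, so the defaults (5 cm, 1/3 s) correspond to a 15 cm/s agent.
#'
#' @param n_states number of ring states (>= 2).
#' @param h,w grid height and width in bins (each >= 2).
#' @param bin_size spatial bin size in cm.
#' @param dt duration of one timestep in seconds.
#' @return An object of class `srnn_env`.
#' @examples
#' ring_env(20)
#' grid_env(14, 14)
#' @export
ring_env <- function(n_states, bin_size = 5, dt = 1 / 3) {
  stopifnot(n_states >= 2, bin_size > 0, dt > 0)
  structure(
    list(geometry = "ring", n_states = as.integer(n_states),
         bin_size = bin_size, dt = dt),
    class = "srnn_env"
  )
}

#' @rdname ring_env
#' @export
grid_env <- function(h, w = h, bin_size = 5, dt = 1 / 3) {
  stopifnot(h >= 2, w >= 2, bin_size > 0, dt > 0)
  structure(
    list(geometry = "grid", n_states = as.integer(h * w),
         h = as.integer(h), w = as.integer(w), bin_size = bin_size, dt = dt),
    class = "srnn_env"
  )
}

#' @export
print.srnn_env <- function(x, ...) {
  dims <- if (x$geometry == "grid") sprintf("%d x %d", x$h, x$w) else as.character(x$n_states)
  cat(sprintf("<srnn_env> %s, %s states, %.3g cm bins, dt = %.3g s\n",
              x$geometry, dims, x$bin_size, x$dt))
  invisible(x)
}

# row-major state <-> (row, col) conversions for grid environments
grid_rc <- function(state, env) {
  r <- (state - 1L) %/% env$w + 1L
  c <- (state - 1L) %% env$w + 1L
  cbind(r, c)
}
grid_state <- function(r, c, env) (r - 1L) * env$w + c

#' Action models
#'
#' On the ring the agent moves forward, stays, or moves backward with
#' probabilities `(p_fwd, p_stay, p_back)`. On the grid the move set is
#' stay plus the four axis neighbors; out-of-bounds moves are removed per
#' state and the remaining probabilities renormalized.
#'
#' @param p_fwd,p_stay,p_back ring action probabilities, must sum to 1.
#' @param p grid probabilities over (stay, up, down, left, right).
#' @return An object of class `srnn_actions`.
#' @examples
#' ring_actions()                    # uniform
#' ring_actions(0.5, 0.25, 0.25)     # forward bias
#' @export
ring_actions <- function(p_fwd = 1 / 3, p_stay = 1 / 3, p_back = 1 / 3) {
  p <- c(fwd = p_fwd, stay = p_stay, back = p_back)
  check_probs(p)
  structure(list(geometry = "ring", p = p), class = "srnn_actions")
}

#' @rdname ring_actions
#' @export
grid_actions <- function(p = rep(1 / 5, 5)) {
  stopifnot(length(p) == 5)
  p <- setNames(p, c("stay", "up", "down", "left", "right"))
  check_probs(p)
  structure(list(geometry = "grid", p = p), class = "srnn_actions")
}

check_probs <- function(p) {
  if (any(p < 0) || any(p > 1)) abort("action probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12) abort("action probabilities must sum to 1")
  invisible(p)
}

#' Forward-biased ring actions used throughout the learning experiments
#' (probability 0.5 forward, 0.25 stay, 0.25 backward).
#' @export
forward_bias_actions <- function() ring_actions(0.5, 0.25, 0.25)

#' Ground-truth transition matrix of an environment under an action model
#'
#' Builds the row-stochastic matrix `T` with `T[j, i] = P(next = i | current = j)`.
#' Ring neighbors wrap modulo `n_states`; on the grid, boundary-violating
#' moves are dropped and the per-state probabilities renormalized.
#'
#' @param env an [ring_env()] or [grid_env()].
#' @param actions a matching [ring_actions()] or [grid_actions()].
#' @return A `transition_matrix` object (fields `T`, `kind`, `visited`).
#' @export
true_transition_matrix <- function(env, actions) {
  if (!inherits(env, "srnn_env") || !inherits(actions, "srnn_actions"))
    abort("true_transition_matrix() needs an srnn_env and srnn_actions")
  if (env$geometry != actions$geometry)
    abort(sprintf("geometry mismatch: env is '%s', actions are '%s'",
                  env$geometry, actions$geometry))
  n <- env$n_states
  Tm <- matrix(0, n, n)
  if (env$geometry == "ring") {
    for (j in seq_len(n)) {
      Tm[j, j %% n + 1L] <- Tm[j, j %% n + 1L] + actions$p[["fwd"]]
      Tm[j, j] <- Tm[j, j] + actions$p[["stay"]]
      Tm[j, (j - 2L) %% n + 1L] <- Tm[j, (j - 2L) %% n + 1L] + actions$p[["back"]]
    }
  } else {
    for (j in seq_len(n)) {
      rc <- grid_rc(j, env)
      moves <- rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
      for (a in seq_len(5)) {
        r2 <- rc[1] + moves[a, 1]; c2 <- rc[2] + moves[a, 2]
        if (r2 >= 1 && r2 <= env$h && c2 >= 1 && c2 <= env$w)
          Tm[j, grid_state(r2, c2, env)] <- Tm[j, grid_state(r2, c2, env)] + actions$p[[a]]
      }
      Tm[j, ] <- Tm[j, ] / sum(Tm[j, ])
    }
  }
  new_transition_matrix(Tm, kind = "ground_truth", visited = rep(TRUE, n))
}

new_transition_matrix <- function(Tm, kind, visited) {
  structure(list(T = Tm, kind = kind, visited = visited),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s, %d states, %d unvisited rows\n",
              x$kind, nrow(x$T), sum(!x$visited)))
  invisible(x)
}

# coerce transition_matrix | matrix -> plain matrix
as_T_matrix <- function(x) {
  if (inherits(x, "transition_matrix")) x$T
  else if (is.matrix(x)) x
  else abort("expected a transition_matrix or a matrix")
}

#' Simulate a random walk
#'
#' Samples a state sequence of length `n_steps + 1` from the Markov chain
#' defined by the environment and action model. Identical seeds give
#' identical walks.
#'
#' @inheritParams true_transition_matrix
#' @param n_steps number of transitions to simulate (>= 1).
#' @param seed optional integer seed.
#' @param start starting state index (1-based).
#' @return An object of class `srnn_walk`; `tidy()` it for a step/state tibble.
#' @examples
#' w <- simulate_walk(ring_env(20), forward_bias_actions(), 100, seed = 1)
#' tidy(w)
#' @export
simulate_walk <- function(env, actions, n_steps, seed = NULL, start = 1L) {
  stopifnot(n_steps >= 1)
  if (start < 1 || start > env$n_states) abort("invalid start state index")
  Tm <- true_transition_matrix(env, actions)$T
  cum <- t(apply(Tm, 1, cumsum))
  states <- integer(n_steps + 1L)
  states[1L] <- as.integer(start)
  with_seed(seed, {
    u <- runif(n_steps)
    for (t in seq_len(n_steps)) {
      states[t + 1L] <- findInterval(u[t], cum[states[t], ], left.open = TRUE) + 1L
    }
  })
  new_walk(states, env, seed = seed, actions = actions)
}

new_walk <- function(states, env, seed = NULL, actions = NULL) {
  structure(list(states = as.integer(states), env = env, seed = seed,
                 actions = actions),
            class = "srnn_walk")
}

#' @export
print.srnn_walk <- function(x, ...) {
  cat(sprintf("<srnn_walk> %d steps on a %s of %d states\n",
              length(x$states) - 1L, x$env$geometry, x$env$n_states))
  invisible(x)
}

#' @export
tidy.srnn_walk <- function(x, ...) {
  out <- tibble(step = seq_along(x$states) - 1L, state = x$states,
                time_s = (seq_along(x$states) - 1L) * x$env$dt)
  if (x$env$geometry == "grid") {
    rc <- grid_rc(x$states, x$env)
    out$row <- rc[, 1]; out$col <- rc[, 2]
  } else {
    out$pos_cm <- (x$states - 1L) * x$env$bin_size
  }
  out
}

#' Empirical transition matrix of a walk
#'
#' `T[j, i]` is the number of observed `j -> i` transitions divided by the
#' number of departures from `j`. Rows of states never left are all-zero and
#' flagged via the `visited` field; downstream error metrics exclude them.
#'
#' @param walk an [simulate_walk()] result, or an integer state vector.
#' @param n_states required when `walk` is a bare vector.
#' @return A `transition_matrix` of kind `"empirical"`.
#' @export
empirical_transition_matrix <- function(walk, n_states = NULL) {
  states <- if (inherits(walk, "srnn_walk")) walk$states else as.integer(walk)
  if (is.null(n_states))
    n_states <- if (inherits(walk, "srnn_walk")) walk$env$n_states else max(states)
  if (length(states) < 2) abort("walk must contain at least one transition")
  n <- as.integer(n_states)
  Tm <- matrix(0, n, n)
  src <- states[-length(states)]
  dst <- states[-1L]
  for (k in seq_along(src)) Tm[src[k], dst[k]] <- Tm[src[k], dst[k]] + 1
  departures <- rowSums(Tm)
  visited <- departures > 0
  Tm[visited, ] <- Tm[visited, , drop = FALSE] / departures[visited]
  new_transition_matrix(Tm, kind = "empirical", visited = visited)
}

#' Synthetic 2D foraging trajectory
#'
#' Generates a smooth correlated random walk (diffusing heading, reflecting
#' walls) emulating an animal randomly foraging in a square arena: the
#' synthetic stand-in used in place of behavioral tracking data. Positions
#' are in cm, sampled at `fps` frames per second.
#'
#' @param duration_min session length in minutes.
#' @param fps sampling rate of the raw trajectory, frames/s.
#' @param arena_cm side length of the square arena in cm.
#' @param speed_cm_s mean running speed.
#' @param heading_sd per-frame standard deviation of the heading increment
#'   (radians); larger values make the path more diffusive.
#' @param seed optional integer seed.
#' @return A tibble with columns `t` (s), `x`, `y` (cm).
#' @export
simulate_foraging <- function(duration_min = 28, fps = 30, arena_cm = 70,
                              speed_cm_s = 15, heading_sd = 0.4, seed = NULL) {
  n <- as.integer(round(duration_min * 60 * fps))
  dt <- 1 / fps
  with_seed(seed, {
    theta <- cumsum(rnorm(n, 0, heading_sd))
    speed <- pmax(rnorm(n, speed_cm_s, speed_cm_s / 4), 0)
    dx <- cos(theta) * speed * dt
    dy <- sin(theta) * speed * dt
    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 0.25, 0.75) * arena_cm
    y[1] <- runif(1, 0.25, 0.75) * arena_cm
    for (t in 2:n) {
      xn <- x[t - 1] + dx[t]; yn <- y[t - 1] + dy[t]
      # reflect off the walls
      if (xn < 0) xn <- -xn else if (xn > arena_cm) xn <- 2 * arena_cm - xn
      if (yn < 0) yn <- -yn else if (yn > arena_cm) yn <- 2 * arena_cm - yn
      x[t] <- min(max(xn, 0), arena_cm); y[t] <- min(max(yn, 0), arena_cm)
    }
    tibble(t = (seq_len(n) - 1) * dt, x = x, y = y)
  })
}

#' Discretize a continuous trajectory into a grid-state walk
#'
#' Downsamples a tracked `(t, x, y)` trajectory to `target_fps`, bins
#' positions onto an `grid_h x grid_w` grid (row-major states), and checks
#' arena coverage. If the fraction of distinct states visited falls below
#' `min_coverage`, a coverage error (condition class
#' `srnn_coverage_error`) is raised rather than silently resampling.
#'
#' @param traj data frame with increasing `t` (seconds) and positions `x`,
#'   `y` within the arena.
#' @param grid_h,grid_w grid dimensions.
#' @param target_fps output frame rate; the input is decimated by
#'   `round(input_fps / target_fps)` so the output length is
#'   `floor(n / k)`.
#' @param min_coverage minimum fraction of grid states that must be visited.
#' @param window_minutes optional truncation of the input to its first
#'   `window_minutes` minutes before downsampling.
#' @param xlim,ylim arena bounds; defaults to the data range.
#' @param bin_size passed to the resulting [grid_env()].
#' @return An `srnn_walk` over the `grid_h * grid_w` states.
#' @export
discretize_trajectory <- function(traj, grid_h = 14, grid_w = 14,
                                  target_fps = 3, min_coverage = 0.85,
                                  window_minutes = NULL,
                                  xlim = NULL, ylim = NULL, bin_size = NULL) {
  if (nrow(traj) == 0) abort("empty trajectory")
  if (any(diff(traj$t) <= 0)) abort("timestamps must be strictly increasing")
  if (!is.null(window_minutes)) {
    traj <- dplyr::filter(traj, .data$t - traj$t[1] < window_minutes * 60)
  }
  fps_in <- 1 / median(diff(traj$t))
  k <- max(1L, as.integer(round(fps_in / target_fps)))
  idx <- seq(k, nrow(traj), by = k)   # length floor(n / k)
  traj <- traj[idx, , drop = FALSE]
  if (is.null(xlim)) xlim <- range(traj$x)
  if (is.null(ylim)) ylim <- range(traj$y)
  if (any(traj$x < xlim[1] | traj$x > xlim[2] | traj$y < ylim[1] | traj$y > ylim[2]))
    abort("positions outside the stated arena bounds")
  col <- pmin(pmax(floor((traj$x - xlim[1]) / diff(xlim) * grid_w) + 1L, 1L), grid_w)
  row <- pmin(pmax(floor((traj$y - ylim[1]) / diff(ylim) * grid_h) + 1L, 1L), grid_h)
  if (is.null(bin_size)) bin_size <- diff(xlim) / grid_w
  env <- grid_env(grid_h, grid_w, bin_size = max(bin_size, .Machine$double.eps),
                  dt = 1 / target_fps)
  states <- grid_state(row, col, env)
  coverage <- length(unique(states)) / env$n_states
  if (coverage < min_coverage) {
    abort(sprintf("arena coverage %.3f below required %.3f", coverage, min_coverage),
          class = "srnn_coverage_error")
  }
  w <- new_walk(states, env)
  w$coverage <- coverage
  w
}

#' Arena coverage of a walk
#' @param walk an `srnn_walk`.
#' @return Fraction of states visited at least once.
#' @export
walk_coverage <- function(walk) {
  length(unique(walk$states)) / walk$env$n_states
}
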