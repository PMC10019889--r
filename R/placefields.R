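#' Occupancy-normalized rate map
#'
#' Per-bin mean rate of one neuron over a walk (sum of activity divided by
#' visits), Gaussian-smoothed over the state geometry. Bins with zero
#' occupancy are flagged and excluded from statistics rather than
#' zero-filled; smoothing renormalizes over visited bins.
#'
#' @param activity numeric vector of the neuron's rate at each walk step
#'   (aligned with `walk$states`).
#' @param walk an `srnn_walk`.
#' @param smoothing_sigma Gaussian smoothing scale in bins (default 1;
#'   kernel support 3 standard deviations).
#' @return An object of class `rate_map`: fields `map` (smoothed rates,
#'   `NA` at unvisited bins), `raw`, `occupancy`, `visited`, `env`.
#' @export
rate_map <- function(activity, walk, smoothing_sigma = 1) {
  states <- walk$states
  if (length(activity) != length(states))
    abort("activity and walk must have the same length")
  env <- walk$env
  n <- env$n_states
  occupancy <- tabulate(states, n)
  visited <- occupancy > 0
  sums <- numeric(n)
  rs <- rowsum(as.numeric(activity), states)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  raw <- ifelse(visited, sums / pmax(occupancy, 1), NA_real_)
  S <- smoothing_operator(env, smoothing_sigma, radius_sd = 3)
  num <- drop(S %*% ifelse(visited, raw, 0))
  den <- drop(S %*% as.numeric(visited))
  map <- ifelse(den > 0 & visited, num / den, NA_real_)
  structure(
    list(map = map, raw = raw, occupancy = occupancy, visited = visited,
         env = env, smoothing_sigma = smoothing_sigma),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d bins (%d unvisited), peak rate %.4g\n",
              length(x$map), sum(!x$visited), max(x$map, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.rate_map <- function(x, ...) {
  env <- x$env
  out <- tibble(state = seq_along(x$map), rate = x$map,
                occupancy = x$occupancy, visited = x$visited)
  if (env$geometry == "grid") {
    rc <- grid_rc(out$state, env)
    out$row <- rc[, 1]; out$col <- rc[, 2]
  } else {
    out$pos_cm <- (out$state - 1L) * env$bin_size
  }
  out
}

# connected components of a logical state mask (wrap on the ring,
# 4-connectivity on the grid); returns a list of state-index vectors
connected_components <- function(mask, env) {
  n <- env$n_states
  labels <- integer(n)
  comp <- 0L
  neighbours <- function(s) {
    if (env$geometry == "ring") {
      c(s %% n + 1L, (s - 2L) %% n + 1L)
    } else {
      rc <- grid_rc(s, env)
      out <- integer(0)
      if (rc[1] > 1L) out <- c(out, grid_state(rc[1] - 1L, rc[2], env))
      if (rc[1] < env$h) out <- c(out, grid_state(rc[1] + 1L, rc[2], env))
      if (rc[2] > 1L) out <- c(out, grid_state(rc[1], rc[2] - 1L, env))
      if (rc[2] < env$w) out <- c(out, grid_state(rc[1], rc[2] + 1L, env))
      out
    }
  }
  for (s in which(mask)) {
    if (labels[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (nb in neighbours(cur)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (comp == 0L) return(list())
  lapply(seq_len(comp), function(k) which(labels == k))
}

# batched rate maps for circularly shifted copies of an activity trace:
# returns n_states x n_perm matrix of smoothed maps (unvisited bins 0)
shifted_maps <- function(activity, states, offsets, P, S_num, occ_visited) {
  Tsteps <- length(activity)
  idx <- outer(seq_len(Tsteps) - 1L, offsets, function(a, b) (a + b) %% Tsteps) + 1L
  ActS <- matrix(activity[idx], Tsteps, length(offsets))
  sums <- as.matrix(P %*% ActS)
  rates <- sums / occ_visited$occ_safe
  rates[!occ_visited$visited, ] <- 0
  sm <- S_num %*% rates
  sm
}

#' Permutation-test place-field detection
#'
#' Candidate fields are contiguous supra-threshold regions of the smoothed
#' rate map (bins at or above `threshold_frac` of the map peak, at least
#' `min_bins` bins). The null distribution is built by circularly
#' time-shifting the activity trace relative to the position sequence by
#' uniform random offsets of at least `min_shift_s` seconds (preserving
#' the activity autocorrelation) and recording each null map's peak. A
#' field is significant when its peak exceeds the `1 - alpha` quantile of
#' the null peaks; a neuron with at least one significant field is a
#' place cell.
#'
#' @inheritParams rate_map
#' @param map optional precomputed [rate_map()]; recomputed when `NULL`.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level.
#' @param threshold_frac field boundary threshold as a fraction of the
#'   map peak.
#' @param min_bins minimum field extent in bins.
#' @param min_shift_s minimum circular shift in seconds.
#' @param seed optional seed for the null offsets.
#' @return A list: `is_place_cell`, `n_fields` (significant), `fields`
#'   (state-index vectors), `field_sizes` (fractions of arena area),
#'   `null_peaks`, `map`.
#' @export
detect_fields <- function(activity, walk, map = NULL, smoothing_sigma = 1,
                          n_perm = 250, alpha = 0.05, threshold_frac = 0.5,
                          min_bins = 4, min_shift_s = 30, seed = NULL) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  env <- walk$env
  n <- env$n_states
  Tsteps <- length(activity)
  if (Tsteps != length(walk$states))
    abort("activity and walk must have the same length")
  if (all(activity == 0)) {
    return(list(is_place_cell = FALSE, n_fields = 0L, fields = list(),
                field_sizes = numeric(0), null_peaks = rep(0, n_perm),
                map = map))
  }
  if (is.null(map)) map <- rate_map(activity, walk, smoothing_sigma)
  min_shift <- ceiling(min_shift_s / env$dt)
  if (2 * min_shift >= Tsteps)
    abort("walk too short for the requested minimum shift")
  offsets <- with_seed(seed,
    sample(seq(min_shift, Tsteps - min_shift), n_perm, replace = TRUE))

  P <- Matrix::sparseMatrix(i = walk$states, j = seq_len(Tsteps), x = 1,
                            dims = c(n, Tsteps))
  S <- smoothing_operator(env, smoothing_sigma, radius_sd = 3)
  visited <- map$visited
  den <- drop(S %*% as.numeric(visited))
  S_num <- S / ifelse(den > 0, den, 1)   # row-normalized over visited bins
  occ <- list(occ_safe = pmax(map$occupancy, 1), visited = visited)
  null_maps <- shifted_maps(as.numeric(activity), walk$states, offsets,
                            P, S_num, occ)
  null_maps[!visited, ] <- NA
  null_peaks <- apply(null_maps, 2, max, na.rm = TRUE)
  crit <- quantile(null_peaks, 1 - alpha, names = FALSE)

  vals <- map$map
  peak <- max(vals, na.rm = TRUE)
  mask <- !is.na(vals) & vals >= threshold_frac * peak
  comps <- connected_components(mask, env)
  comps <- comps[vapply(comps, length, 1L) >= min_bins]
  sig <- vapply(comps, function(cc) max(vals[cc]) > crit, TRUE)
  fields <- comps[sig]
  list(
    is_place_cell = length(fields) > 0,
    n_fields = length(fields),
    fields = fields,
    field_sizes = vapply(fields, length, 1L) / n,
    null_peaks = null_peaks,
    map = map
  )
}

#' Field detection across a population
#'
#' Runs [detect_fields()] for every neuron of an activity matrix and
#' returns the per-neuron summary used by [field_statistics()].
#'
#' @param activity steps-by-neurons activity matrix.
#' @param walk the shared `srnn_walk`.
#' @param ... passed to [detect_fields()].
#' @param seed seed from which independent per-neuron null offsets are
#'   derived.
#' @return A tibble: `neuron`, `is_place_cell`, `n_fields`,
#'   `field_sizes` (list column), `mean_field_size`.
#' @export
detect_fields_population <- function(activity, walk, ..., seed = NULL) {
  n_neurons <- ncol(activity)
  seeds <- if (is.null(seed)) rep(list(NULL), n_neurons)
           else as.list(split_seed(seed, n_neurons))
  rows <- map(seq_len(n_neurons), function(i) {
    det <- detect_fields(activity[, i], walk, ..., seed = seeds[[i]])
    tibble(neuron = i, is_place_cell = det$is_place_cell,
           n_fields = det$n_fields,
           field_sizes = list(det$field_sizes),
           mean_field_size = if (det$n_fields > 0) mean(det$field_sizes)
                             else NA_real_)
  })
  bind_rows(rows)
}

#' Population place-field statistics
#'
#' Normalized histograms of the number of significant fields per neuron
#' (integer bins `0 .. max_count+`) and of field sizes as fractions of
#' the arena (equal bins over `(0, 0.5]`, oversized fields folded into
#' the last bin), plus the place-cell and fieldless fractions. Fieldless
#' neurons contribute to the count histogram but not the size histogram.
#'
#' @param summaries tibble from [detect_fields_population()].
#' @param size_bins number of field-size bins over `(0, 0.5]`.
#' @param max_count largest dedicated field-count bin (last bin collects
#'   `max_count` and above).
#' @return An object of class `field_statistics` with `count_hist` and
#'   `size_hist` tibbles (proportions and counts), `place_cell_fraction`,
#'   `fieldless_fraction`, `n_neurons`.
#' @export
field_statistics <- function(summaries, size_bins = 10, max_count = 8) {
  stopifnot(nrow(summaries) >= 1)
  counts <- pmin(summaries$n_fields, max_count)
  count_tab <- tabulate(counts + 1L, max_count + 1L)
  count_hist <- tibble(
    n_fields = c(seq_len(max_count) - 1L, max_count),
    count = count_tab,
    prop = count_tab / sum(count_tab)
  )
  sizes <- unlist(summaries$field_sizes[summaries$is_place_cell])
  breaks <- seq(0, 0.5, length.out = size_bins + 1)
  size_tab <- if (length(sizes)) {
    tabulate(pmin(findInterval(sizes, breaks, left.open = TRUE,
                               rightmost.closed = TRUE), size_bins),
             size_bins)
  } else integer(size_bins)
  size_hist <- tibble(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    count = size_tab,
    prop = if (sum(size_tab) > 0) size_tab / sum(size_tab) else rep(0, size_bins)
  )
  structure(
    list(count_hist = count_hist, size_hist = size_hist,
         place_cell_fraction = mean(summaries$is_place_cell),
         fieldless_fraction = mean(summaries$n_fields == 0),
         n_neurons = nrow(summaries)),
    class = "field_statistics"
  )
}

#' @export
print.field_statistics <- function(x, ...) {
  cat(sprintf(
    "<field_statistics> %d neurons, %.1f%% place cells, %.1f%% fieldless\n",
    x$n_neurons, 100 * x$place_cell_fraction, 100 * x$fieldless_fraction))
  invisible(x)
}

#' Kullback-Leibler divergence between histograms (bits)
#'
#' `sum_i P_i log2(P_i / Q_i)` over the shared bins. The reference `Q`
#' may be Laplace-smoothed with a pseudo-count to avoid division by zero.
#' Non-negative; zero iff the distributions agree on the shared support.
#'
#' @param P,Q histogram vectors over matched bins (counts or
#'   proportions; both are renormalized).
#' @param pseudo pseudo-count added to every bin of `Q` before
#'   renormalizing.
#' @return Divergence in bits.
#' @export
kl_divergence <- function(P, Q, pseudo = 0) {
  if (length(P) != length(Q)) abort("unmatched bins in kl_divergence()")
  P <- P / sum(P)
  Q <- Q + pseudo
  Q <- Q / sum(Q)
  nz <- P > 0
  if (any(Q[nz] == 0)) return(Inf)
  sum(P[nz] * log2(P[nz] / Q[nz]))
}

#' Combined field-statistics divergence
#'
#' Sum of the KL divergences of the field-size distribution and the
#' field-count distribution between a model population and a reference
#' population (reference histograms Laplace-smoothed with pseudo-count
#' 0.5).
#'
#' @param model,reference `field_statistics` objects.
#' @param pseudo reference pseudo-count.
#' @return Total divergence in bits.
#' @export
combined_kl <- function(model, reference, pseudo = 0.5) {
  kl_divergence(model$size_hist$count, reference$size_hist$count, pseudo) +
    kl_divergence(model$count_hist$count, reference$count_hist$count, pseudo)
}

#' Split-half divergence of a population
#'
#' Randomly halves the population repeatedly and measures the combined
#' field-statistics divergence between halves: the sampling-noise floor
#' against which model-to-reference divergences are judged.
#'
#' @param summaries tibble from [detect_fields_population()] (>= 4
#'   neurons).
#' @param n_splits number of random halvings.
#' @param seed optional seed.
#' @return A tibble with `split` and `kl_bits`.
#' @export
split_half_kl <- function(summaries, n_splits = 50, seed = NULL) {
  n <- nrow(summaries)
  if (n < 4) abort("need at least 4 neurons for split-half analysis")
  with_seed(seed, {
    rows <- map(seq_len(n_splits), function(k) {
      idx <- sample.int(n, n %/% 2)
      a <- field_statistics(summaries[idx, ])
      b <- field_statistics(summaries[-idx, ])
      tibble(split = k, kl_bits = combined_kl(a, b))
    })
    bind_rows(rows)
  })
}

#' Place-field peak shifts between session windows
#'
#' For each neuron on a circular track, the circular difference (in cm)
#' between the rate-map peak in a late window and an early window of the
#' session. Negative values are backward shifts (opposite the travel
#' direction of a forward-biased walk). Ties in peak location break
#' toward the lower bin; shifts use the minimal circular distance.
#' Neurons with no activity in either window are excluded. With
#' `max_track_cm` set, the late peak is searched only within that
#' circular distance of the early peak, so the same field is tracked
#' across the session and wholesale remapping events (a peak jumping to
#' a distant second field) are not scored as shifts.
#'
#' @param activity steps-by-neurons activity matrix.
#' @param walk a ring `srnn_walk`.
#' @param early_window,late_window step-index vectors.
#' @param smoothing_sigma rate-map smoothing in bins.
#' @param max_track_cm optional field-tracking radius in cm (`NULL`
#'   compares global peaks).
#' @return A tibble: `neuron`, `early_peak`, `late_peak`, `shift_cm`.
#' @export
peak_shift <- function(activity, walk, early_window, late_window,
                       smoothing_sigma = 1, max_track_cm = NULL) {
  if (walk$env$geometry != "ring")
    abort("peak_shift() is defined for ring walks")
  if (!length(early_window) || !length(late_window))
    abort("both windows must be non-empty")
  n <- walk$env$n_states
  sub_walk <- function(win) new_walk(walk$states[win], walk$env)
  we <- sub_walk(early_window); wl <- sub_walk(late_window)
  track_bins <- if (is.null(max_track_cm)) NULL
                else max(1L, floor(max_track_cm / walk$env$bin_size))
  rows <- map(seq_len(ncol(activity)), function(i) {
    ae <- activity[early_window, i]; al <- activity[late_window, i]
    if (all(ae == 0) || all(al == 0)) return(NULL)
    pe <- which.max(rate_map(ae, we, smoothing_sigma)$map)
    ml <- rate_map(al, wl, smoothing_sigma)$map
    if (is.null(track_bins)) {
      pl <- which.max(ml)
    } else {
      cand <- (pe - 1L + (-track_bins:track_bins)) %% n + 1L
      pl <- cand[which.max(ml[cand])]
    }
    d <- (pl - pe) %% n
    if (d > n / 2) d <- d - n
    tibble(neuron = i, early_peak = pe, late_peak = pl,
           shift_cm = d * walk$env$bin_size)
  })
  bind_rows(rows)
}

#' Lap-by-position activity map
#'
#' Unwraps a circular-track walk into laps (a lap completes each time the
#' accumulated signed displacement passes a full circuit) and returns the
#' per-lap mean rate at each position bin. Errors when no lap is
#' completed or the walk is not on a ring.
#'
#' @param activity one neuron's rate at each walk step.
#' @param walk a ring `srnn_walk`.
#' @return A completed-laps by n_states matrix (`NA` for positions not
#'   visited within a lap).
#' @export
lap_activity_map <- function(activity, walk) {
  if (walk$env$geometry != "ring")
    abort("lap_activity_map() requires a circular track")
  states <- walk$states
  n <- walk$env$n_states
  d <- diff(states)
  signed <- ((d + n / 2) %% n) - n / 2   # minimal circular step
  unwrap <- cumsum(c(0, signed))
  lap <- floor(unwrap / n)
  n_complete <- max(lap)
  if (n_complete < 1) abort("fewer than 1 completed lap")
  out <- matrix(NA_real_, n_complete, n)
  for (l in seq_len(n_complete)) {
    in_lap <- lap == (l - 1L)
    if (!any(in_lap)) next
    rs <- rowsum(as.numeric(activity[in_lap]), states[in_lap])
    cnt <- rowsum(rep(1, sum(in_lap)), states[in_lap])
    out[l, as.integer(rownames(rs))] <- rs[, 1] / cnt[, 1]
  }
  out
}
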