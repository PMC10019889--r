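#' Walk and feature-set serialization
#'
#' Walks are written as a single-column CSV of integer states (1-based)
#' with a JSON sidecar recording the geometry, state count, bin size,
#' timestep, and seed. Feature sets are written as a states-by-features
#' CSV matrix with a sidecar recording `p`, `sigma`, the measured
#' sparsity, the seed, and the geometry.
#'
#' @param walk an `srnn_walk`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   reconstructed object.
#' @export
write_walk <- function(walk, path) {
  readr::write_csv(tibble(state = walk$states), path)
  env <- walk$env
  meta <- list(geometry = env$geometry, n_states = env$n_states,
               bin_size = env$bin_size, dt = env$dt,
               seed = walk$seed, indexing = "1-based")
  if (env$geometry == "grid") { meta$h <- env$h; meta$w <- env$w }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  states <- readr::read_csv(path, show_col_types = FALSE)$state
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  env <- if (meta$geometry == "grid") {
    grid_env(meta$h, meta$w, bin_size = meta$bin_size, dt = meta$dt)
  } else {
    ring_env(meta$n_states, bin_size = meta$bin_size, dt = meta$dt)
  }
  new_walk(states, env, seed = meta$seed)
}

#' @rdname write_walk
#' @param fs a `feature_set`.
#' @export
write_features <- function(fs, path) {
  df <- as.data.frame(fs$Phi)
  names(df) <- paste0("f", seq_len(ncol(df)))
  readr::write_csv(df, path)
  meta <- list(p = fs$p, sigma = fs$sigma, s = fs$s, seed = fs$seed,
               geometry = fs$env$geometry, n_states = fs$env$n_states,
               bin_size = fs$env$bin_size, dt = fs$env$dt,
               degenerate = which(fs$degenerate))
  if (fs$env$geometry == "grid") { meta$h <- fs$env$h; meta$w <- fs$env$w }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_features <- function(path) {
  Phi <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
  dimnames(Phi) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  env <- if (meta$geometry == "grid") {
    grid_env(meta$h, meta$w, bin_size = meta$bin_size, dt = meta$dt)
  } else {
    ring_env(meta$n_states, bin_size = meta$bin_size, dt = meta$dt)
  }
  degen <- rep(FALSE, ncol(Phi))
  degen[unlist(meta$degenerate)] <- TRUE
  fs <- new_feature_set(Phi, env, p = meta$p, sigma = meta$sigma,
                        seed = meta$seed, degenerate = degen)
  fs
}

#' Checkpoint a network state to a CSV bundle
#'
#' Writes `J.csv`, `trace.csv` (trace, previous activity, step counter),
#' and a config echo to a directory; `read_checkpoint()` restores the
#' state.
#'
#' @param state an `rnn_state`.
#' @param cfg the `rnn_config` used (echoed into the bundle).
#' @param dir bundle directory (created if needed).
#' @export
write_checkpoint <- function(state, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as.data.frame(state$J), file.path(dir, "J.csv"),
                   col_names = FALSE)
  readr::write_csv(tibble(n = state$n, x_prev = state$x_prev),
                   file.path(dir, "trace.csv"))
  jsonlite::write_json(c(unclass(cfg), list(t = state$t)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  J <- as.matrix(readr::read_csv(file.path(dir, "J.csv"),
                                 col_names = FALSE, show_col_types = FALSE))
  dimnames(J) <- NULL
  tr <- readr::read_csv(file.path(dir, "trace.csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  state <- rnn_network(nrow(J))
  state$J <- J
  state$n <- tr$n
  state$x_prev <- tr$x_prev
  state$t <- as.integer(meta$t)
  cfg_fields <- setdiff(names(meta), "t")
  cfg <- do.call(rnn_config, meta[intersect(
    cfg_fields, names(formals(rnn_config)))])
  list(state = state, cfg = cfg)
}

# ---- experiment driver ------------------------------------------------

default_experiment_config <- function() {
  list(
    env = list(geometry = "ring", n_states = 20, bin_size = 5, dt = 1 / 3),
    actions = list(p_fwd = 0.5, p_stay = 0.25, p_back = 0.25),
    walk = list(n_steps = 5400, start = 1),
    features = list(type = "one_hot", p = 0.1, sigma = 7.5),
    rnn = list(gamma_b = 0, gamma_r = 0.9, lambda = 1,
               lr_mode = "adaptive", eta_static = 10^-1.5,
               nonlinearity = "linear"),
    schedule = list(mode = "learn", retrieve_from = NULL),
    log_every = 100,
    seed = 1
  )
}

validate_config <- function(config) {
  base <- default_experiment_config()
  for (field in names(config)) {
    if (!field %in% names(base))
      abort(sprintf("unknown config field '%s'", field))
  }
  config <- modifyList(base, config)
  need <- function(cond, field) {
    if (!cond) abort(sprintf("invalid config field '%s'", field))
  }
  need(config$env$geometry %in% c("ring", "grid"), "env.geometry")
  need(is.numeric(config$walk$n_steps) && config$walk$n_steps >= 1,
       "walk.n_steps")
  need(config$features$type %in% c("one_hot", "generated"), "features.type")
  need(config$schedule$mode %in% c("learn", "learn_then_retrieve"),
       "schedule.mode")
  need(is.numeric(config$seed), "seed")
  config
}

#' Run a fully configured experiment
#'
#' Orchestrates environment, walk, features, learning/retrieval, and
#' metrics from one config (a YAML file path or a nested list), writing
#' the walk, feature set, metrics log, final weights, and a manifest to
#' `outdir`. A single global seed fans out to per-module child seeds, so
#' reruns of the same config are byte-identical.
#'
#' @param config YAML path or nested list; see
#'   `default_experiment_config()` internals for the schema.
#' @param outdir output directory.
#' @return Invisibly, a list with the session and the paths written.
#' @export
run_experiment <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(config$seed, 3)

  env <- if (config$env$geometry == "ring") {
    ring_env(config$env$n_states, config$env$bin_size, config$env$dt)
  } else {
    grid_env(config$env$h, config$env$w, config$env$bin_size, config$env$dt)
  }
  actions <- if (env$geometry == "ring") {
    ring_actions(config$actions$p_fwd, config$actions$p_stay,
                 config$actions$p_back)
  } else {
    grid_actions()
  }
  walk <- simulate_walk(env, actions, config$walk$n_steps,
                        seed = seeds[1], start = config$walk$start)
  feats <- if (config$features$type == "generated") {
    generate_features(env, config$features$p, config$features$sigma,
                      seed = seeds[2])
  } else NULL

  cfg <- rnn_config(gamma_b = config$rnn$gamma_b,
                    gamma_r = config$rnn$gamma_r,
                    lambda = config$rnn$lambda,
                    lr_mode = config$rnn$lr_mode,
                    eta_static = config$rnn$eta_static,
                    nonlinearity = config$rnn$nonlinearity)
  Tsteps <- length(walk$states)
  schedule <- rep(0L, Tsteps)
  if (config$schedule$mode == "learn_then_retrieve") {
    from <- config$schedule$retrieve_from
    if (is.null(from)) from <- floor(Tsteps / 2) + 1L
    schedule[seq(from, Tsteps)] <- 1L
  }
  oracle <- true_transition_matrix(env, actions)
  sess <- run_session(walk, feats, cfg = cfg, schedule = schedule,
                      oracle_T = oracle, log_every = config$log_every,
                      keep_activity = FALSE)

  paths <- list(
    walk = file.path(outdir, "walk.csv"),
    metrics = file.path(outdir, "metrics.csv"),
    weights = file.path(outdir, "J.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_walk(walk, paths$walk)
  if (!is.null(feats)) {
    paths$features <- file.path(outdir, "features.csv")
    write_features(feats, paths$features)
  }
  readr::write_csv(sess$log, paths$metrics)
  readr::write_csv(as.data.frame(sess$state$J), paths$weights,
                   col_names = FALSE)
  jsonlite::write_json(
    list(config = config, package_version = as.character(utils::packageVersion("srnn")),
         instability_step = sess$instability,
         final_row_sum_mean = mean(colSums(sess$state$J))),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(session = sess, paths = paths))
}

#' Generate the standard small fixture set
#'
#' Seeded, regenerable fixtures: 20-state ring walks at three action
#' biases (uniform, forward, sticky; 2000 steps each), a 14 x 14
#' synthetic foraging walk (28 minutes at 3 frames/s = 5040 steps,
#' resampled until arena coverage reaches 85%), and dense feature sets at
#' `(p, sigma)` of `(0.03, 10 cm)` and `(0.1, 7.5 cm)` on the ring.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Invisibly, the named list of file paths.
#' @export
make_fixtures <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(seed, 6)
  env <- ring_env(20)
  biases <- list(
    uniform = ring_actions(),
    forward = forward_bias_actions(),
    sticky = ring_actions(0.25, 0.5, 0.25)
  )
  paths <- list()
  for (nm in names(biases)) {
    w <- simulate_walk(env, biases[[nm]], 2000,
                       seed = seeds[match(nm, names(biases))])
    paths[[paste0("walk_", nm)]] <- file.path(dir, paste0("walk_", nm, ".csv"))
    write_walk(w, paths[[paste0("walk_", nm)]])
  }
  # 2D foraging walk: retry derived seeds until the coverage criterion holds
  forage <- NULL
  try_seeds <- split_seed(seeds[4], 50)
  for (s in try_seeds) {
    forage <- tryCatch(
      discretize_trajectory(
        simulate_foraging(duration_min = 28, fps = 30, seed = s),
        grid_h = 14, grid_w = 14, target_fps = 3, min_coverage = 0.85),
      srnn_coverage_error = function(e) NULL)
    if (!is.null(forage)) break
  }
  if (is.null(forage)) abort("could not reach the coverage criterion")
  paths$walk_foraging <- file.path(dir, "walk_foraging.csv")
  write_walk(forage, paths$walk_foraging)
  fs1 <- generate_features(env, p = 0.03, sigma = 10, seed = seeds[5])
  fs2 <- generate_features(env, p = 0.1, sigma = 7.5, seed = seeds[6])
  paths$features_sparse <- file.path(dir, "features_p03_s10.csv")
  paths$features_dense <- file.path(dir, "features_p10_s75.csv")
  write_features(fs1, paths$features_sparse)
  write_features(fs2, paths$features_dense)
  invisible(paths)
}
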