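#' Block-average smoothing of a learning curve
#'
#' Non-overlapping block means (the convention used for reported reward
#' and latency curves); a trailing partial block is dropped.
#'
#' @param raw numeric vector.
#' @param window block size, >= 1.
#' @return numeric vector of \code{floor(length(raw)/window)} block means.
#' @export
smooth_curve <- function(raw, window) {
  if (length(raw) == 0L) stop("smooth_curve(): empty input")
  stopifnot(window >= 1)
  n <- length(raw) %/% window
  if (n == 0L) stop("smooth_curve(): input shorter than one window")
  colMeans(matrix(raw[seq_len(n * window)], nrow = window))
}

#' Plateau episode of a latency curve
#'
#' Convergence is operationalized as the first episode index from which
#' the running mean of the curve stays within \code{tol} (relative) of the
#' mean over the final \code{final_window} episodes. The two windows
#' default to the same length, so the running mean's last value is the
#' final level itself and the comparison is between one estimator and its
#' own endpoint.
#'
#' @param curve numeric vector (e.g. mean escape latency per episode).
#' @param window running-mean window.
#' @param final_window window defining the final level.
#' @param tol relative tolerance.
#' @return the plateau episode index (\code{length(curve)} if the curve
#'   never settles).
#' @export
plateau_episode <- function(curve, window = 20L, final_window = 20L,
                            tol = 0.2) {
  n <- length(curve)
  stopifnot(n >= window, n >= final_window)
  final <- mean(utils::tail(curve, final_window))
  run <- stats::filter(curve, rep(1 / window, window), sides = 1)
  run <- run[window:n]  # running mean ending at episodes window..n
  ok <- abs(run - final) <= tol * abs(final)
  bad <- which(!ok)
  if (length(bad) == 0L) return(as.integer(window))
  start <- bad[length(bad)] + 1L
  if (start > length(ok)) return(as.integer(n))
  as.integer(window + start - 1L)
}

#' Hand-crafted state vector for the variable-targets world
#'
#' The straight-forward explicit encoding used as the "highly informative"
#' baseline input: agent position (2), orientation (1), identity coded as
#' +/-1 (1), and each object position (2 per object). Components are
#' scaled to approximately unit variance under the uniform initial-state
#' distribution (positions x sqrt(3)/half-width, angle x sqrt(3)/pi) so
#' the control network's sigmoids see comparable ranges.
#'
#' @param state a variable-targets \code{"world_state"}.
#' @return numeric vector of length \code{4 + 2 * n_objects}.
#' @export
encode_state_vector <- function(state) {
  s3 <- sqrt(3)
  c(state$agent_pos * s3,
    state$agent_angle * s3 / pi,
    if (state$agent_identity == "A") 1 else -1,
    unlist(lapply(state$objects, function(o) o$pos * s3)))
}

#' Linear decodability of a latent from a feature set
#'
#' R-squared of the ordinary least-squares regression of a latent variable
#' (e.g. agent x-position) on a feature matrix; used to probe what a
#' representation exposes linearly.
#'
#' @param features T x d feature matrix.
#' @param latent length-T latent vector.
#' @return R-squared in [0, 1].
#' @export
latent_probe_r2 <- function(features, latent) {
  fit <- stats::lm.fit(cbind(1, features), latent)
  1 - sum(fit$residuals^2) / sum((latent - mean(latent))^2)
}

#' Train the population Q-learning agent on the water maze
#'
#' Runs independent sets of episodes (one per seed): each step renders the
#' scene, projects it through the hierarchy, lets the Q population act,
#' advances the water-maze dynamics and applies the TD update. Performance
#' is the escape latency (steps to target) per episode.
#'
#' @param model trained [sfa_hierarchy()] (trained on a water-maze
#'   stream).
#' @param seeds integer vector, one independent run per seed.
#' @param n_episodes episodes per run.
#' @param n_features number of slowest features fed to the agent.
#' @param task_cfg,world_cfg task and world configuration (defaults:
#'   water-maze task at the model's resolution).
#' @param agent_args named list of overrides passed to [q_population()].
#' @param verbose print per-seed progress.
#' @return an object of class \code{"watermaze_result"}: \code{latencies}
#'   (episodes x seeds), \code{curve} (per-episode mean and sd across
#'   seeds), the final per-seed agents, and a reproducibility manifest.
#' @export
run_watermaze <- function(model, seeds = 1:10, n_episodes = 100L,
                          n_features = 16L,
                          task_cfg = task_config("watermaze"),
                          world_cfg = NULL, agent_args = list(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "sfa_hierarchy"))
  world_cfg <- world_cfg %||%
    world_config(resolution = model$config$image_side, n_objects = 0L)
  lat <- matrix(NA_real_, n_episodes, length(seeds))
  agents <- vector("list", length(seeds))
  for (s in seq_along(seeds)) {
    withr_seed(seeds[s], {
      pop <- do.call(q_population, c(list(n_features = n_features),
                                     agent_args))
      for (ep in seq_len(n_episodes)) {
        state <- init_episode(task_cfg, world_cfg)
        pop <- q_reset_trace(pop)
        f <- predict(model, render_scene(state, world_cfg), n_features)
        repeat {
          act <- q_act(pop, f)
          pop <- act$pop
          out <- watermaze_step(state, act$action, task_cfg, world_cfg)
          state <- out$state
          f2 <- predict(model, render_scene(state, world_cfg), n_features)
          pop <- q_learn(pop, out$reward, f2, done = out$info$goal)
          f <- f2
          if (out$done) break
        }
        lat[ep, s] <- state$steps
      }
      agents[[s]] <- pop
    })
    if (verbose) message("seed ", seeds[s], ": final latency ",
                         round(mean(utils::tail(lat[, s], 10))))
  }
  structure(list(
    latencies = lat,
    curve = data.frame(episode = seq_len(n_episodes),
                       mean = rowMeans(lat),
                       sd = apply(lat, 1, stats::sd)),
    agents = agents,
    manifest = run_manifest(seeds, list(n_episodes = n_episodes,
                                        n_features = n_features,
                                        task = task_cfg, world = world_cfg))),
    class = "watermaze_result")
}

#' @export
print.watermaze_result <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf("water-maze run: %d episodes x %d seeds\n", n,
              ncol(x$latencies)))
  cat(sprintf("  mean latency, first 10 episodes: %.1f steps\n",
              mean(x$curve$mean[seq_len(min(10, n))])))
  cat(sprintf("  mean latency, last 10 episodes:  %.1f steps\n",
              mean(utils::tail(x$curve$mean, 10))))
  cat(sprintf("  plateau episode: %d\n", plateau_episode(x$curve$mean)))
  invisible(x)
}

#' @rdname run_watermaze
#' @param x a \code{"watermaze_result"}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.watermaze_result <- function(x, ...) {
  graphics::plot(x$curve$episode, x$curve$mean, type = "l",
                 xlab = "episode", ylab = "escape latency (steps)", ...)
  graphics::lines(x$curve$episode, x$curve$mean + x$curve$sd, lty = 2)
  graphics::lines(x$curve$episode, pmax(x$curve$mean - x$curve$sd, 0),
                  lty = 2)
  invisible(x)
}

#' Greedy navigation map of a trained Q agent
#'
#' Probes a grid of positions: at each, the scene is rendered, projected
#' through the hierarchy and the population-vector (greedy, no
#' exploration) direction recorded.
#'
#' @param pop trained [q_population()].
#' @param model the hierarchy used during training.
#' @param grid_n probe positions per side.
#' @param n_features features used during training.
#' @param world_cfg world configuration of the run.
#' @param margin wall margin excluded from probing.
#' @return data frame (class \code{"navigation_map"}) with probe
#'   \code{x}, \code{y} and greedy \code{angle}.
#' @export
navigation_map <- function(pop, model, grid_n = 9L, n_features = 16L,
                           world_cfg = NULL, margin = 0.1) {
  world_cfg <- world_cfg %||%
    world_config(resolution = model$config$image_side, n_objects = 0L)
  b <- world_cfg$bounds
  xs <- seq(b[1] + margin, b[2] - margin, length.out = grid_n)
  out <- expand.grid(x = xs, y = xs)
  out$angle <- apply(out, 1, function(p) {
    state <- world_init(world_cfg, "watermaze")
    state$agent_pos <- c(p[["x"]], p[["y"]])
    f <- predict(model, render_scene(state, world_cfg), n_features)
    population_direction(q_forward(pop, f), pop$dirs)
  })
  class(out) <- c("navigation_map", class(out))
  out
}

#' @export
plot.navigation_map <- function(x, length = 0.05, scale = 0.08, ...) {
  graphics::plot(x$x, x$y, type = "n", xlab = "x", ylab = "y", asp = 1, ...)
  graphics::arrows(x$x, x$y, x$x + scale * cos(x$angle),
                   x$y + scale * sin(x$angle), length = length)
  invisible(x)
}

## feature extractors for the variable-targets controller
vt_features_fn <- function(features = c("sfa", "state_vector"), model,
                           n_features, world_cfg) {
  features <- match.arg(features)
  if (features == "state_vector") {
    function(state) encode_state_vector(state)
  } else {
    stopifnot(inherits(model, "sfa_hierarchy"))
    function(state) predict(model, render_scene(state, world_cfg),
                            n_features)
  }
}

#' Train a controller on the variable-targets task
#'
#' Batch training over parallel traces: one time step is simulated in
#' every trace with the current (shared) parameters, the per-trace
#' perturbation updates of the speed and angular neurons are averaged and
#' applied once, and finished traces are re-initialized while the others
#' continue. With \code{n_traces = 1} this reduces to plain sequential
#' training.
#'
#' @param features \code{"sfa"} (render + hierarchy projection) or
#'   \code{"state_vector"} (the explicit encoding of
#'   [encode_state_vector()]).
#' @param model trained [sfa_hierarchy()] (required for
#'   \code{features = "sfa"}).
#' @param controller \code{"branch"} (one dendritic-branch neuron per
#'   control variable: logistic soma for speed, tanh for angular velocity)
#'   or \code{"simple"} (a two-layer point-neuron network per variable).
#' @param n_updates number of batch update steps.
#' @param n_traces number of parallel traces.
#' @param n_features number of slowest hierarchy outputs used.
#' @param seed run seed.
#' @param task_cfg,world_cfg task and world configuration.
#' @param agent_args overrides for [branch_neuron()] / [simple_network()].
#' @param rbar_tau reward-baseline filter time constant.
#' @param reward_window smoothing window for the reported reward curve.
#' @param verbose print progress.
#' @return an object of class \code{"vt_result"}: per-step mean rewards
#'   and speed outputs, completed-episode latencies, smoothed curves, the
#'   trained agents and a manifest.
#' @export
run_variable_targets <- function(features = c("sfa", "state_vector"),
                                 model = NULL,
                                 controller = c("branch", "simple"),
                                 n_updates = 2000L, n_traces = 100L,
                                 n_features = 32L, seed = 1L,
                                 task_cfg = task_config("variable_targets"),
                                 world_cfg = NULL, agent_args = list(),
                                 rbar_tau = 50, reward_window = 200L,
                                 verbose = FALSE) {
  features <- match.arg(features)
  controller <- match.arg(controller)
  world_cfg <- world_cfg %||% world_config(
    resolution = if (!is.null(model)) model$config$image_side else 63L)
  fx <- vt_features_fn(features, model, n_features, world_cfg)

  withr_seed(seed, {
    d <- length(fx(init_episode(task_cfg, world_cfg)))
    make_agent <- function(soma) {
      if (controller == "branch") {
        do.call(branch_neuron, c(list(n_inputs = d, soma = soma),
                                 agent_args))
      } else {
        do.call(simple_network, c(list(n_inputs = d, soma = soma),
                                  agent_args))
      }
    }
    fwd <- if (controller == "branch") branch_forward else simple_forward
    upd <- if (controller == "branch") pg_update else simple_update
    speed <- make_agent("logistic")
    angular <- make_agent("tanh")
    ## one low-pass reward baseline per trace: each trace's updates are
    ## centered on that trace's own recent reward level
    rfs <- lapply(seq_len(n_traces), function(i) reward_filter(rbar_tau))

    traces <- lapply(seq_len(n_traces),
                     function(i) init_episode(task_cfg, world_cfg))
    rewards <- numeric(n_updates)
    speed_out <- numeric(n_updates)
    latencies <- integer(0)
    for (step in seq_len(n_updates)) {
      ds <- vector("list", n_traces)
      da <- vector("list", n_traces)
      r_step <- numeric(n_traces)
      v_step <- numeric(n_traces)
      for (i in seq_len(n_traces)) {
        st <- traces[[i]]
        f <- fx(st)
        fs <- fwd(speed, f)
        fa <- fwd(angular, f)
        out <- variable_targets_step(st, fs$y, fa$y, task_cfg, world_cfg)
        r_step[i] <- out$reward
        v_step[i] <- fs$y
        rbar <- if (is.na(rfs[[i]]$rbar)) out$reward else rfs[[i]]$rbar
        ds[[i]] <- upd(speed, fs, f, out$reward, rbar)
        da[[i]] <- upd(angular, fa, f, out$reward, rbar)
        rfs[[i]] <- rf_update(rfs[[i]], out$reward)
        traces[[i]] <- if (out$done) {
          latencies <- c(latencies, out$state$steps)
          init_episode(task_cfg, world_cfg)
        } else out$state
      }
      speed <- apply_deltas(speed, average_deltas(ds))
      angular <- apply_deltas(angular, average_deltas(da))
      rewards[step] <- mean(r_step)
      speed_out[step] <- mean(v_step)
      if (verbose && step %% 500L == 0L) {
        message("update ", step, ": mean reward ",
                round(mean(utils::tail(rewards[seq_len(step)], 200)), 3))
      }
    }
    structure(list(
      rewards = rewards, speed_out = speed_out, latencies = latencies,
      smoothed = smooth_curve(rewards, min(reward_window, n_updates)),
      agents = list(speed = speed, angular = angular),
      manifest = run_manifest(seed, list(
        features = features, controller = controller,
        n_updates = n_updates, n_traces = n_traces,
        n_features = n_features, task = task_cfg, world = world_cfg))),
      class = "vt_result")
  })
}

#' @export
print.vt_result <- function(x, ...) {
  cat(sprintf("variable-targets run (%s features, %s controller): %d updates x %d traces\n",
              x$manifest$config$features, x$manifest$config$controller,
              length(x$rewards), x$manifest$config$n_traces))
  cat(sprintf("  smoothed reward: first window %.3f, last window %.3f\n",
              x$smoothed[1], x$smoothed[length(x$smoothed)]))
  cat(sprintf("  completed episodes: %d\n", length(x$latencies)))
  invisible(x)
}

#' @export
plot.vt_result <- function(x, ...) {
  graphics::plot(seq_along(x$smoothed), x$smoothed, type = "l",
                 xlab = "window", ylab = "mean reward", ...)
  invisible(x)
}

#' Performance versus number of slow features used
#'
#' Trains an independent controller per feature count and tabulates the
#' final smoothed reward, probing how many slow components the control
#' task needs.
#'
#' @param model trained [sfa_hierarchy()].
#' @param counts feature counts to test (each must not exceed the model's
#'   top output dimension).
#' @param ... passed to [run_variable_targets()].
#' @return data frame with \code{n_features} and \code{final_reward},
#'   with the per-count runs attached as attribute \code{"runs"}.
#' @export
feature_count_sweep <- function(model, counts = c(16L, 22L, 28L, 32L, 64L),
                                ...) {
  stopifnot(inherits(model, "sfa_hierarchy"))
  if (any(counts > model$top_output_dim)) {
    stop("counts exceed the model's top output dimension (",
         model$top_output_dim, ")")
  }
  runs <- lapply(counts, function(k)
    run_variable_targets(features = "sfa", model = model,
                         n_features = k, ...))
  out <- data.frame(
    n_features = counts,
    final_reward = vapply(runs, function(r)
      r$smoothed[length(r$smoothed)], numeric(1)))
  attr(out, "runs") <- runs
  out
}

run_manifest <- function(seeds, config) {
  list(seeds = seeds, config = config,
       package = as.character(utils::packageVersion("slowrl")),
       timestamp = format(Sys.time(), tz = "UTC"))
}
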