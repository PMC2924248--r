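#' Configuration of the simulated 2D world
#'
#' A square arena with an agent (a fish sprite with two visually distinct
#' identities) and, for the variable-targets setting, two objects (a cross
#' and a disk). Velocities follow a bounded random walk: per step each
#' velocity component receives a uniform perturbation of at most
#' \code{max_speed_update} and is clamped to \code{max_speed} in magnitude;
#' the agent's in-plane angular velocity is treated likewise with its own
#' caps. The agent identity switches with probability
#' \code{identity_switch_prob} per step.
#'
#' @param bounds position interval per axis (world units).
#' @param resolution rendered image side in pixels.
#' @param agent_radius,object_radius sprite radii in world units.
#' @param max_speed,max_speed_update spatial velocity caps (per component,
#'   world units per step).
#' @param max_ang_speed,max_ang_update angular velocity caps (radians per
#'   step).
#' @param identity_switch_prob per-step probability of flipping the agent
#'   identity.
#' @param n_objects number of non-agent objects (0 for the water maze,
#'   2 for variable targets).
#' @return an object of class \code{"world_config"}.
#' @export
world_config <- function(bounds = c(-1, 1), resolution = 155,
                         agent_radius = 0.4, object_radius = 0.2,
                         max_speed = 0.06, max_speed_update = 0.01,
                         max_ang_speed = 0.04, max_ang_update = 0.01,
                         identity_switch_prob = 0.002, n_objects = 2L) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            resolution >= 8, agent_radius > 0, object_radius > 0,
            max_speed > 0, max_ang_speed > 0,
            identity_switch_prob >= 0, identity_switch_prob <= 1,
            n_objects %in% 0:2)
  if (2 * agent_radius >= diff(bounds)) stop("agent_radius does not fit bounds")
  structure(list(bounds = bounds, resolution = as.integer(resolution),
                 agent_radius = agent_radius, object_radius = object_radius,
                 max_speed = max_speed, max_speed_update = max_speed_update,
                 max_ang_speed = max_ang_speed, max_ang_update = max_ang_update,
                 identity_switch_prob = identity_switch_prob,
                 n_objects = as.integer(n_objects)),
            class = "world_config")
}

#' Draw an initial world state
#'
#' Positions and orientation are uniform within bounds; identity is
#' uniform over \{A, B\} (fixed to A for the water maze, whose agent is
#' also never rotated). Velocities start at zero.
#'
#' @param cfg a [world_config()].
#' @param kind \code{"variable_targets"} or \code{"watermaze"}.
#' @return an object of class \code{"world_state"}.
#' @export
world_init <- function(cfg, kind = c("variable_targets", "watermaze")) {
  kind <- match.arg(kind)
  n_obj <- if (kind == "watermaze") 0L else cfg$n_objects
  b <- cfg$bounds
  state <- list(
    kind = kind,
    agent_pos = stats::runif(2, b[1], b[2]),
    agent_angle = if (kind == "watermaze") 0 else stats::runif(1, -pi, pi),
    agent_identity = if (kind == "watermaze") "A" else
      sample(c("A", "B"), 1L),
    agent_vel = c(0, 0),
    ang_vel = 0,
    objects = if (n_obj > 0) {
      lapply(seq_len(n_obj),
             function(i) list(pos = stats::runif(2, b[1], b[2]),
                              vel = c(0, 0)))
    } else list(),
    steps = 0L
  )
  class(state) <- "world_state"
  state
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("world state (%s): agent (%.3f, %.3f) angle %.3f id %s, %d objects\n",
              x$kind, x$agent_pos[1], x$agent_pos[2], x$agent_angle,
              x$agent_identity, length(x$objects)))
  invisible(x)
}

## bounce a (position, velocity) pair off the interval walls
bounce_1d <- function(p, v, lo, hi) {
  p2 <- p + v
  if (p2 < lo) { p2 <- 2 * lo - p2; v <- -v }
  else if (p2 > hi) { p2 <- 2 * hi - p2; v <- -v }
  ## pathological overshoot (cannot occur with capped speeds, kept safe)
  p2 <- clamp(p2, lo, hi)
  c(p2, v)
}

#' Advance the random-walk stimulus dynamics by one step
#'
#' Adds a uniform perturbation to each spatial velocity component (capped
#' at \code{max_speed}) and to the agent's angular velocity (capped at
#' \code{max_ang_speed}), advances positions (entities bounce off the
#' walls and off each other when their center distance falls below the
#' sum of their radii), and flips the agent identity with probability
#' \code{identity_switch_prob}. Draws from the global RNG.
#'
#' @param state a [world_init()] state.
#' @param cfg a [world_config()].
#' @return the updated \code{"world_state"}.
#' @export
random_walk_step <- function(state, cfg) {
  b <- cfg$bounds
  upd <- function(v, du, cap) {
    clamp(v + stats::runif(length(v), -du, du), -cap, cap)
  }
  state$agent_vel <- upd(state$agent_vel, cfg$max_speed_update, cfg$max_speed)
  for (i in seq_along(state$objects)) {
    state$objects[[i]]$vel <- upd(state$objects[[i]]$vel,
                                  cfg$max_speed_update, cfg$max_speed)
  }
  if (state$kind != "watermaze") {
    state$ang_vel <- upd(state$ang_vel, cfg$max_ang_update, cfg$max_ang_speed)
  }

  ## pairwise bounce: reflect approaching velocities along the center line
  ents <- c(list(list(pos = state$agent_pos, vel = state$agent_vel,
                      r = cfg$agent_radius)),
            lapply(state$objects, function(o)
              list(pos = o$pos, vel = o$vel, r = cfg$object_radius)))
  n <- length(ents)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        dp <- ents[[j]]$pos - ents[[i]]$pos
        dist <- sqrt(sum(dp^2))
        if (dist < ents[[i]]$r + ents[[j]]$r && dist > 0) {
          nrm <- dp / dist
          dv <- ents[[j]]$vel - ents[[i]]$vel
          if (sum(dv * nrm) < 0) {  # approaching: reflect normal components
            vi <- ents[[i]]$vel - sum(ents[[i]]$vel * nrm) * nrm -
              abs(sum(ents[[i]]$vel * nrm)) * nrm
            vj <- ents[[j]]$vel - sum(ents[[j]]$vel * nrm) * nrm +
              abs(sum(ents[[j]]$vel * nrm)) * nrm
            ents[[i]]$vel <- clamp(vi, -cfg$max_speed, cfg$max_speed)
            ents[[j]]$vel <- clamp(vj, -cfg$max_speed, cfg$max_speed)
          }
        }
      }
    }
  }

  adv <- function(pos, vel) {
    x <- bounce_1d(pos[1], vel[1], b[1], b[2])
    y <- bounce_1d(pos[2], vel[2], b[1], b[2])
    list(pos = c(x[1], y[1]), vel = c(x[2], y[2]))
  }
  a <- adv(ents[[1]]$pos, ents[[1]]$vel)
  state$agent_pos <- a$pos
  state$agent_vel <- a$vel
  if (n > 1L) {
    for (i in seq(2L, n)) {
      o <- adv(ents[[i]]$pos, ents[[i]]$vel)
      state$objects[[i - 1L]]$pos <- o$pos
      state$objects[[i - 1L]]$vel <- o$vel
    }
  }

  if (state$kind != "watermaze") {
    state$agent_angle <- wrap_angle(state$agent_angle + state$ang_vel)
    if (stats::runif(1) < cfg$identity_switch_prob) {
      state$agent_identity <- if (state$agent_identity == "A") "B" else "A"
    }
  }
  state$steps <- state$steps + 1L
  state
}
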