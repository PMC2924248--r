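#' Configure a control task
#'
#' Two closed-loop tasks are supported. \strong{Water maze}: a single
#' directional command moves the non-rotated agent by \code{step_length}
#' per step toward an invisible fixed target; rewards are sparse (goal
#' reward on arrival, wall penalty when the position had to be clamped to
#' the arena, 0 otherwise). \strong{Variable targets}: speed and
#' angular-velocity commands steer a rotating agent toward whichever
#' object its identity designates (identity A -> cross, B -> disk; the
#' other object is a pure distractor); the reward is +1 when the step
#' strictly decreased the Euclidean distance to the target and -1
#' otherwise (a tie counts as "not closer"), scaled by
#' \code{reward_scale}.
#'
#' @param kind \code{"watermaze"} or \code{"variable_targets"}.
#' @param target_pos fixed target (water maze only).
#' @param goal_radius arrival radius around the target.
#' @param step_length water-maze step length (world units).
#' @param reward_goal,reward_wall water-maze goal reward and wall penalty.
#' @param speed_scale,ang_scale variable-targets scaling constants: the
#'   position advances by \code{speed_scale * v} along the heading and the
#'   heading by \code{ang_scale * omega}. The default angular gain lets
#'   the agent reorient within a step or two, which keeps the band of
#'   states whose reward responds to angular exploration wide enough for
#'   perturbation learning at reduced training budgets.
#' @param reward_scale magnitude of the +/-1 variable-targets reward.
#' @param min_separation minimum pairwise separation enforced at episode
#'   initialization (variable targets).
#' @param max_steps episode step budget.
#' @param boundary variable-targets boundary mode: \code{"mirror"}
#'   (movement reflected at the walls, the default) or \code{"clamp"}
#'   (outward movement cut off).
#' @return an object of class \code{"task_config"}.
#' @export
task_config <- function(kind = c("watermaze", "variable_targets"),
                        target_pos = c(0.5, 0.5), goal_radius = NULL,
                        step_length = 0.05,
                        reward_goal = 1, reward_wall = -0.1,
                        speed_scale = 0.05, ang_scale = 2,
                        reward_scale = 1, min_separation = 0.8,
                        max_steps = NULL,
                        boundary = c("mirror", "clamp")) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  goal_radius <- goal_radius %||% 0.25
  max_steps <- max_steps %||% if (kind == "watermaze") 500L else 200L
  stopifnot(goal_radius > 0, max_steps > 0, step_length > 0,
            speed_scale > 0, ang_scale > 0, min_separation >= 0)
  structure(list(kind = kind, target_pos = target_pos,
                 goal_radius = goal_radius, step_length = step_length,
                 reward_goal = reward_goal, reward_wall = reward_wall,
                 speed_scale = speed_scale, ang_scale = ang_scale,
                 reward_scale = reward_scale,
                 min_separation = min_separation,
                 max_steps = as.integer(max_steps), boundary = boundary),
            class = "task_config")
}

## target object index for the current identity (A -> cross = object 1,
## B -> disk = object 2)
target_index <- function(state) if (state$agent_identity == "A") 1L else 2L

#' Initialize a task episode
#'
#' Draws agent position, orientation and identity, and (variable targets)
#' the two object positions, uniformly within bounds; configurations with
#' any pairwise separation below \code{min_separation} are rejected and
#' redrawn, after which the object positions stay fixed for the episode.
#' Water-maze episodes reject agent positions already inside the goal.
#'
#' @param task_cfg a [task_config()].
#' @param world_cfg a [world_config()].
#' @return a \code{"world_state"} ready for stepping.
#' @export
init_episode <- function(task_cfg, world_cfg) {
  for (try in seq_len(10000L)) {
    state <- world_init(world_cfg, task_cfg$kind)
    if (task_cfg$kind == "watermaze") {
      if (sqrt(sum((state$agent_pos - task_cfg$target_pos)^2)) >
          task_cfg$goal_radius) {
        return(state)
      }
    } else {
      pts <- rbind(state$agent_pos,
                   t(vapply(state$objects, `[[`, numeric(2), "pos")))
      if (min(stats::dist(pts)) >= task_cfg$min_separation) return(state)
    }
  }
  stop("init_episode: could not satisfy min_separation = ",
       task_cfg$min_separation, " within 10000 draws")
}

#' Advance a water-maze episode by one step
#'
#' Moves the agent by \code{step_length} in the commanded direction, then
#' hard-clamps the position to the arena. Reaching the (invisible) target
#' yields \code{reward_goal} and ends the episode; a step that had to be
#' clamped yields \code{reward_wall}; all other steps yield 0. The episode
#' also ends when \code{max_steps} is exhausted.
#'
#' @param state current \code{"world_state"} (water-maze kind).
#' @param direction movement direction in radians.
#' @param task_cfg a [task_config()] of kind \code{"watermaze"}.
#' @param world_cfg a [world_config()].
#' @return a list with \code{state}, \code{reward}, \code{done} and
#'   \code{info} (wall-hit flag, distance to target).
#' @export
watermaze_step <- function(state, direction, task_cfg, world_cfg) {
  if (task_cfg$kind != "watermaze" || state$kind != "watermaze") {
    stop("watermaze_step() called with a non-watermaze task or state")
  }
  b <- world_cfg$bounds
  p <- state$agent_pos + task_cfg$step_length * c(cos(direction),
                                                  sin(direction))
  pc <- clamp(p, b[1], b[2])
  wall <- any(pc != p)
  state$agent_pos <- pc
  state$steps <- state$steps + 1L
  dist <- sqrt(sum((pc - task_cfg$target_pos)^2))
  goal <- dist <= task_cfg$goal_radius
  reward <- if (goal) task_cfg$reward_goal else
    if (wall) task_cfg$reward_wall else 0
  list(state = state, reward = reward,
       done = goal || state$steps >= task_cfg$max_steps,
       info = list(wall = wall, distance = dist, goal = goal))
}

#' Advance a variable-targets episode by one step
#'
#' Applies the controller commands: the heading advances by
#' \code{ang_scale * omega} and the position by \code{speed_scale * v}
#' along the new heading. At the walls the movement is mirrored (default)
#' or clamped. The reward is \code{+reward_scale} when the Euclidean
#' distance to the identity-designated target object strictly decreased,
#' \code{-reward_scale} otherwise; the distractor never affects the
#' outcome. The episode ends inside \code{goal_radius} of the target or
#' when the step budget is exhausted.
#'
#' @param state current \code{"world_state"} (variable-targets kind).
#' @param v speed command (from the logistic speed neuron, in (0, 1)).
#' @param omega angular command (from the tanh angular neuron, in (-1, 1)).
#' @param task_cfg a [task_config()] of kind \code{"variable_targets"}.
#' @param world_cfg a [world_config()].
#' @return a list with \code{state}, \code{reward}, \code{done} and
#'   \code{info} (distance to target, target index).
#' @export
variable_targets_step <- function(state, v, omega, task_cfg, world_cfg) {
  if (task_cfg$kind != "variable_targets" || state$kind != "variable_targets") {
    stop("variable_targets_step() called with a non-variable-targets task or state")
  }
  b <- world_cfg$bounds
  tgt <- state$objects[[target_index(state)]]$pos
  d0 <- sqrt(sum((state$agent_pos - tgt)^2))
  state$agent_angle <- wrap_angle(state$agent_angle + task_cfg$ang_scale * omega)
  step <- task_cfg$speed_scale * v *
    c(cos(state$agent_angle), sin(state$agent_angle))
  p <- state$agent_pos + step
  if (task_cfg$boundary == "mirror") {
    ## reflect the trajectory: position and heading component both mirror
    hx <- cos(state$agent_angle)
    hy <- sin(state$agent_angle)
    while (p[1] < b[1] || p[1] > b[2]) {
      p[1] <- if (p[1] < b[1]) 2 * b[1] - p[1] else 2 * b[2] - p[1]
      hx <- -hx
    }
    while (p[2] < b[1] || p[2] > b[2]) {
      p[2] <- if (p[2] < b[1]) 2 * b[1] - p[2] else 2 * b[2] - p[2]
      hy <- -hy
    }
    state$agent_angle <- atan2(hy, hx)
  } else {
    p <- clamp(p, b[1], b[2])
  }
  state$agent_pos <- p
  state$steps <- state$steps + 1L
  d1 <- sqrt(sum((p - tgt)^2))
  reward <- if (d1 < d0) task_cfg$reward_scale else -task_cfg$reward_scale
  goal <- d1 <= task_cfg$goal_radius
  list(state = state, reward = reward,
       done = goal || state$steps >= task_cfg$max_steps,
       info = list(distance = d1, target = target_index(state), goal = goal))
}
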