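#' Render a world state to a grayscale image
#'
#' Procedural sprites on a uniform black background, anti-aliased so that
#' pixel intensities vary continuously with pose (the temporal continuity
#' that slowness learning relies on). The agent is an oriented fish
#' (elliptic body plus triangular tail); identity B carries a stripe
#' pattern that makes the two identities visually distinct. Object 1 is a
#' cross, object 2 a filled disk. Coordinate convention: world x maps to
#' pixel columns (rightward), world y to pixel rows bottom-up (y up);
#' pixels are sampled at their centers. Values lie in [0, 1].
#'
#' For the water-maze setting only the non-rotated identity-A fish is
#' drawn (no target, no distractor).
#'
#' @param state a [world_init()] state.
#' @param cfg a [world_config()].
#' @return a resolution x resolution numeric matrix ([row, col], row 1 at
#'   the top).
#' @export
render_scene <- function(state, cfg) {
  res <- cfg$resolution
  g <- render_grid(cfg)
  img <- matrix(0, res, res)

  img <- pmax(img, fish_sprite(g$X, g$Y, state$agent_pos,
                               if (state$kind == "watermaze") 0
                               else state$agent_angle,
                               state$agent_identity, cfg$agent_radius,
                               edge = g$edge))
  if (state$kind != "watermaze" && length(state$objects) >= 1L) {
    img <- pmax(img, cross_sprite(g$X, g$Y, state$objects[[1L]]$pos,
                                  cfg$object_radius, edge = g$edge))
  }
  if (state$kind != "watermaze" && length(state$objects) >= 2L) {
    img <- pmax(img, disk_sprite(g$X, g$Y, state$objects[[2L]]$pos,
                                 cfg$object_radius, edge = g$edge))
  }
  img
}

## pixel-center world coordinates; X varies along columns, Y along rows
## (row 1 = top = largest y). edge: softening width ~ 1.2 pixels.
render_grid <- function(cfg) {
  res <- cfg$resolution
  b <- cfg$bounds
  w <- diff(b)
  xs <- b[1] + w * (seq_len(res) - 0.5) / res
  ys <- b[2] - w * (seq_len(res) - 0.5) / res
  list(X = matrix(xs, res, res, byrow = TRUE),
       Y = matrix(ys, res, res),
       edge = 1.2 * w / res)
}

soft <- function(margin, edge) clamp(margin / edge + 0.5, 0, 1)

fish_sprite <- function(X, Y, pos, angle, identity, radius, edge) {
  dx <- X - pos[1]
  dy <- Y - pos[2]
  ca <- cos(angle); sa <- sin(angle)
  u <- dx * ca + dy * sa      # along the body, head at +u
  v <- -dx * sa + dy * ca
  a <- 0.70 * radius          # body half-length
  bb <- 0.38 * radius         # body half-width
  body <- soft((1 - (u / a)^2 - (v / bb)^2) * 0.5 * bb, edge)
  ## tail: triangle behind the body, widening away from it
  tl0 <- -0.55 * radius
  tl1 <- -1.00 * radius
  half_w <- 0.45 * radius * (tl0 - u) / (tl0 - tl1)
  tail <- soft(pmin(half_w - abs(v), u - tl1, tl0 - u + 0.15 * radius), edge)
  spr <- pmax(body, tail)
  if (identity == "B") {
    ## identity B: dark transverse stripes across the body
    stripes <- 0.55 + 0.45 * cos(2 * pi * u / (0.45 * radius))
    spr <- spr * clamp(stripes, 0.25, 1)
  }
  spr
}

cross_sprite <- function(X, Y, pos, radius, edge) {
  dx <- abs(X - pos[1])
  dy <- abs(Y - pos[2])
  arm <- 0.30 * radius
  h <- soft(pmin(radius - dx, arm - dy), edge)
  v <- soft(pmin(radius - dy, arm - dx), edge)
  pmax(h, v)
}

disk_sprite <- function(X, Y, pos, radius, edge) {
  r <- sqrt((X - pos[1])^2 + (Y - pos[2])^2)
  soft(radius - r, edge)
}

#' Generate a random-walk training stream of rendered frames
#'
#' Iterates [random_walk_step()] from a fresh [world_init()] state and
#' renders each frame. This is the unsupervised training material for the
#' hierarchy: smooth bounded trajectories whose slowly varying latents are
#' the entity positions, the agent orientation and its identity.
#'
#' @param n number of frames.
#' @param cfg a [world_config()].
#' @param kind \code{"variable_targets"} (agent + cross + disk, identity
#'   switching, rotation) or \code{"watermaze"} (non-rotated identity-A
#'   agent only).
#' @param seed optional integer seed (restored afterwards); omit to draw
#'   from the current RNG state.
#' @param burn_in random-walk steps taken before the first rendered frame
#'   so velocities reach their stationary distribution.
#' @return an \code{n} x \code{resolution^2} matrix, one row-major frame
#'   per row, with the per-frame latent variables (positions, angle,
#'   identity) attached as attribute \code{"latents"} (a data frame).
#' @export
generate_training_stream <- function(n, cfg,
                                     kind = c("variable_targets", "watermaze"),
                                     seed = NULL, burn_in = 50L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  run <- function() {
    state <- world_init(cfg, kind)
    for (i in seq_len(burn_in)) state <- random_walk_step(state, cfg)
    out <- matrix(0, nrow = n, ncol = cfg$resolution^2)
    lat <- data.frame(x = numeric(n), y = numeric(n), angle = numeric(n),
                      identity = character(n),
                      o1x = NA_real_, o1y = NA_real_,
                      o2x = NA_real_, o2y = NA_real_)
    for (t in seq_len(n)) {
      state <- random_walk_step(state, cfg)
      out[t, ] <- as.vector(t(render_scene(state, cfg)))
      lat$x[t] <- state$agent_pos[1]
      lat$y[t] <- state$agent_pos[2]
      lat$angle[t] <- state$agent_angle
      lat$identity[t] <- state$agent_identity
      if (length(state$objects) >= 1L) {
        lat$o1x[t] <- state$objects[[1L]]$pos[1]
        lat$o1y[t] <- state$objects[[1L]]$pos[2]
      }
      if (length(state$objects) >= 2L) {
        lat$o2x[t] <- state$objects[[2L]]$pos[1]
        lat$o2y[t] <- state$objects[[2L]]$pos[2]
      }
    }
    attr(out, "latents") <- lat
    out
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}
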