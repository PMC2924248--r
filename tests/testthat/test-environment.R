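test_that("random-walk velocities respect the caps and identity switches at the stated rate", {
  cfg <- world_config(resolution = 24)
  set.seed(201)
  state <- world_init(cfg, "variable_targets")
  n <- 20000L
  max_v <- 0
  max_w <- 0
  switches <- 0L
  id <- state$agent_identity
  for (i in seq_len(n)) {
    state <- random_walk_step(state, cfg)
    vels <- c(state$agent_vel,
              unlist(lapply(state$objects, `[[`, "vel")))
    max_v <- max(max_v, abs(vels))
    max_w <- max(max_w, abs(state$ang_vel))
    if (state$agent_identity != id) switches <- switches + 1L
    id <- state$agent_identity
    ## positions always inside bounds
    expect_true(all(abs(state$agent_pos) <= 1))
  }
  expect_lte(max_v, cfg$max_speed)
  expect_lte(max_w, cfg$max_ang_speed)
  ## switch rate within 3 binomial standard errors of 0.002
  p <- cfg$identity_switch_prob
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(switches / n - p), 3 * se + 1e-12)
})

test_that("overlapping approaching entities bounce apart", {
  cfg <- world_config(resolution = 24)
  set.seed(202)
  state <- world_init(cfg, "variable_targets")
  state$agent_pos <- c(0, 0)
  state$objects[[1]]$pos <- c(0.5, 0)   # within 0.4 + 0.2 radius sum
  state$agent_vel <- c(0.05, 0)
  state$objects[[1]]$vel <- c(-0.05, 0) # approaching head-on
  state$objects[[2]]$pos <- c(-0.9, -0.9)
  d0 <- 0.5
  s2 <- random_walk_step(state, cfg)
  d1 <- sqrt(sum((s2$agent_pos - s2$objects[[1]]$pos)^2))
  expect_gte(d1, d0 - 1e-9)
})

test_that("training streams are deterministic, continuous and correctly sized", {
  cfg <- world_config(resolution = 24)
  s1 <- generate_training_stream(150, cfg, "variable_targets", seed = 5)
  s2 <- generate_training_stream(150, cfg, "variable_targets", seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(150L, 24L * 24L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  ## temporal continuity: adjacent frames much closer than distant frames
  s <- generate_training_stream(1200, cfg, "variable_targets", seed = 6)
  near <- mean(abs(s[2:101, ] - s[1:100, ]))
  far <- mean(abs(s[1002:1101, ] - s[2:101, ]))
  expect_lt(near / far, 0.3)
})

test_that("rendering distinguishes identities and orientations, and tracks position", {
  cfg <- world_config(resolution = 40)
  set.seed(203)
  state <- world_init(cfg, "variable_targets")
  state$agent_identity <- "A"
  imgA <- render_scene(state, cfg)
  expect_equal(length(imgA), 1600L)
  expect_true(all(imgA >= 0 & imgA <= 1))
  ## full-scale frame pixel count
  expect_equal(world_config()$resolution^2, 24025L)
  stateB <- state
  stateB$agent_identity <- "B"
  expect_gt(mean(abs(imgA - render_scene(stateB, cfg))), 0.01)
  stateR <- state
  stateR$agent_angle <- slowrl:::wrap_angle(state$agent_angle + pi)
  expect_gt(mean(abs(imgA - render_scene(stateR, cfg))), 0.001)
  ## agent pixel centroid moves monotonically with world x
  wc0 <- world_config(resolution = 40, n_objects = 0L)
  cent <- vapply(seq(-0.5, 0.5, length.out = 20), function(x) {
    st <- world_init(wc0, "watermaze")
    st$agent_pos <- c(x, 0)
    img <- render_scene(st, wc0)
    cols <- matrix(rep(seq_len(40), each = 40), 40)
    sum(img * cols) / sum(img)
  }, numeric(1))
  expect_true(all(diff(cent) > 0))
})

test_that("episode initialization respects separation, balance and reproducibility", {
  tc <- task_config("variable_targets")
  wc <- world_config(resolution = 24)
  set.seed(204)
  ids <- character(400)
  for (i in 1:400) {
    st <- init_episode(tc, wc)
    pts <- rbind(st$agent_pos, st$objects[[1]]$pos, st$objects[[2]]$pos)
    expect_gte(min(dist(pts)), tc$min_separation)
    ids[i] <- st$agent_identity
  }
  frac_A <- mean(ids == "A")
  expect_lt(abs(frac_A - 0.5), 3 * sqrt(0.25 / 400))
  set.seed(9)
  a <- init_episode(tc, wc)
  set.seed(9)
  b <- init_episode(tc, wc)
  expect_identical(a, b)
})

test_that("water-maze rewards are sparse: goal, wall penalty, else zero", {
  tc <- task_config("watermaze")
  wc <- world_config(resolution = 24, n_objects = 0L)
  set.seed(205)
  st <- world_init(wc, "watermaze")
  ## goal arrival
  st$agent_pos <- tc$target_pos - c(tc$goal_radius - 0.02, 0)
  out <- watermaze_step(st, 0, tc, wc)
  expect_true(out$done)
  expect_equal(out$reward, tc$reward_goal)
  ## wall clamping
  st$agent_pos <- c(0.999, -0.5)
  out <- watermaze_step(st, 0, tc, wc)
  expect_equal(out$reward, tc$reward_wall)
  expect_lte(out$state$agent_pos[1], 1)
  ## interior step far from goal
  st$agent_pos <- c(-0.5, -0.5)
  out <- watermaze_step(st, pi / 4, tc, wc)
  expect_equal(out$reward, 0)
  expect_false(out$done)
  ## wrong task kind
  expect_error(watermaze_step(st, 0, task_config("variable_targets"), wc),
               "non-watermaze")
})

test_that("variable-targets rewards encode strict distance decrease and mirror at walls", {
  tc <- task_config("variable_targets")
  wc <- world_config(resolution = 24)
  set.seed(206)
  st <- init_episode(tc, wc)
  st$agent_identity <- "A"  # target = cross = object 1
  tgt <- st$objects[[1]]$pos
  st$agent_angle <- atan2(tgt[2] - st$agent_pos[2], tgt[1] - st$agent_pos[1])
  out <- variable_targets_step(st, 1, 0, tc, wc)
  expect_equal(out$reward, tc$reward_scale)
  ## zero speed: distance unchanged counts as "not closer"
  out0 <- variable_targets_step(st, 0, 0, tc, wc)
  expect_equal(out0$reward, -tc$reward_scale)
  ## distractor does not define the reward: moving toward object 2 while
  ## identity A is penalized unless it also approaches object 1
  st2 <- st
  st2$agent_identity <- "B"
  outB <- variable_targets_step(st2, 1, 0, tc, wc)
  d_disk0 <- sqrt(sum((st2$agent_pos - st2$objects[[2]]$pos)^2))
  d_disk1 <- sqrt(sum((outB$state$agent_pos - outB$state$objects[[2]]$pos)^2))
  expect_equal(outB$reward,
               if (d_disk1 < d_disk0) tc$reward_scale else -tc$reward_scale)
  ## mirrored boundary keeps positions inside and reflects heading
  st$agent_pos <- c(0.999, 0)
  st$agent_angle <- 0
  outm <- variable_targets_step(st, 1, 0, tc, wc)
  expect_true(all(abs(outm$state$agent_pos) <= 1))
  expect_lt(cos(outm$state$agent_angle), 0)  # now heading leftward
  ## clamp mode cuts movement off instead
  tcc <- task_config("variable_targets", boundary = "clamp")
  outc <- variable_targets_step(st, 1, 0, tcc, wc)
  expect_equal(outc$state$agent_pos[1], 1)
})

test_that("episodes terminate within the step budget", {
  tc <- task_config("variable_targets", max_steps = 25)
  wc <- world_config(resolution = 24)
  set.seed(207)
  st <- init_episode(tc, wc)
  done <- FALSE
  for (i in 1:25) {
    out <- variable_targets_step(st, 1, 0.3, tc, wc)
    st <- out$state
    if (out$done) { done <- TRUE; break }
  }
  expect_true(done)
  expect_lte(st$steps, 25)
})
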