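## Shared fixtures, built once per test run and cached.
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

## Smoke-scale hierarchy (40 px, three layers) trained on a water-maze
## random-walk stream; shared by the hierarchy, experiment and acceptance
## tests.
smoke_world_wm <- function() world_config(resolution = 40, n_objects = 0L)

smoke_hierarchy_wm <- function() {
  fixture("smoke_hierarchy_wm", function() {
    wc <- smoke_world_wm()
    sfa_hierarchy(function(n, seed)
      generate_training_stream(n, wc, "watermaze", seed = seed),
      scaled_hierarchy_config("smoke"), seed = 11)
  })
}

## Variable-targets hierarchies (SFA and PCA variants) on the same stream
## configuration.
smoke_world_vt <- function() world_config(resolution = 40, n_objects = 2L)

## The variable-targets stream needs enough frames for the rare identity
## switches (p = 0.002/step) to register as a slow feature, so this
## fixture trains on more frames than the watermaze one.
smoke_hierarchy_vt <- function(variant = "sfa") {
  name <- paste0("smoke_hierarchy_vt_", variant)
  fixture(name, function() {
    wc <- smoke_world_vt()
    sfa_hierarchy(function(n, seed)
      generate_training_stream(n, wc, "variable_targets", seed = seed),
      scaled_hierarchy_config("smoke", n_frames_lower = 8000,
                              n_frames_upper = 8000),
      variant = variant, seed = 12)
  })
}

## Tiny hierarchy trained on a stream whose only slow latent is an
## object's x-position; used by the latent-recovery checks.
single_latent_hierarchy <- function() {
  fixture("single_latent_hierarchy", function() {
    cfg <- hierarchy_config(
      image_side = 24,
      layers = list(
        list(field_side = 8, overlap = 4, spec = node_spec(10, 10)),
        list(field_side = 3, overlap = 1, spec = node_spec(10, 10)),
        list(field_side = 2, overlap = 0, spec = node_spec(12, 12))
      ),
      n_frames_lower = 1500, n_frames_upper = 1500)
    stream_fn <- function(n, seed) {
      s <- make_fixture_stream("single_latent", n, seed = seed)
      ## jitter decorrelates the repeated sweep across layer groups
      jit <- withr_seed_local(seed, matrix(stats::runif(length(s), 0, 1e-3),
                                           nrow(s)))
      structure(s + jit, latents = attr(s, "latents"))
    }
    sfa_hierarchy(stream_fn, cfg, seed = 21)
  })
}

## evaluate expr under a temporary seed, restoring the RNG
withr_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

## Independent brute-force solver of the slowness generalized eigenproblem
## (derivative covariance vs signal covariance) via the non-symmetric
## matrix solve(C) %*% Cdot; used as the oracle for the whitening-based
## implementation.
bruteforce_sfa <- function(x, out_dim) {
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / (nrow(x) - 1)
  d <- diff(x)
  Cd <- crossprod(d) / nrow(d)
  ee <- eigen(solve(C, Cd))
  ord <- order(Re(ee$values))
  list(values = Re(ee$values)[ord][seq_len(out_dim)],
       vectors = Re(ee$vectors)[, ord[seq_len(out_dim)], drop = FALSE])
}

## Largest principal angle (radians) between the column spaces of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}
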