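#' Specification of a single hierarchy node
#'
#' A node processes its input through: additive Gaussian noise (training
#' statistics only) -> linear SFA to \code{sfa1_dim} -> quadratic expansion
#' -> linear SFA to \code{sfa2_dim} -> clipping. Noise and clipping are
#' technical safeguards against singular covariances and diverging
#' quadratic terms on test data.
#'
#' @param sfa1_dim output dimensionality of the first (linear) SFA stage.
#' @param sfa2_dim output dimensionality of the second SFA stage, i.e. of
#'   the node; must not exceed \code{expanded_dim(sfa1_dim)}.
#' @param noise_variance variance of the training-time Gaussian noise.
#' @param clip_bound symmetric output clipping bound, or \code{NULL} to
#'   disable.
#' @return an object of class \code{"node_spec"}.
#' @export
node_spec <- function(sfa1_dim, sfa2_dim, noise_variance = 1e-4,
                      clip_bound = 4) {
  stopifnot(sfa1_dim >= 1, sfa2_dim >= 1, noise_variance >= 0,
            is.null(clip_bound) || clip_bound > 0)
  if (sfa2_dim > expanded_dim(sfa1_dim)) {
    stop("sfa2_dim (", sfa2_dim, ") exceeds expanded dimensionality ",
         expanded_dim(sfa1_dim))
  }
  structure(list(sfa1_dim = sfa1_dim, sfa2_dim = sfa2_dim,
                 noise_variance = noise_variance, clip_bound = clip_bound),
            class = "node_spec")
}

#' @export
print.node_spec <- function(x, ...) {
  cat(sprintf("node spec: sfa1 %d -> expand %d -> sfa2 %d (noise %g, clip %s)\n",
              x$sfa1_dim, expanded_dim(x$sfa1_dim), x$sfa2_dim,
              x$noise_variance,
              if (is.null(x$clip_bound)) "off" else format(x$clip_bound)))
  invisible(x)
}

#' Fit one hierarchy node on a training time series
#'
#' Fits the two SFA stages sequentially on the (noise-augmented)
#' training data. Once fitted, [predict.sfa_node()] is deterministic: noise
#' is applied only while accumulating training statistics, never at apply
#' time, so the closed control loop stays reproducible.
#'
#' @param x numeric matrix, T samples x d channels.
#' @param spec a [node_spec()].
#' @param variant \code{"sfa"} or \code{"pca"} (ranking criterion of both
#'   stages; the pipeline is otherwise identical).
#' @return an object of class \code{"sfa_node"}.
#' @export
sfa_node <- function(x, spec, variant = c("sfa", "pca")) {
  variant <- match.arg(variant)
  x <- as_timeseries(x)
  fit_node_stream(function(t) x[t, , drop = FALSE], nrow(x), ncol(x),
                  spec, variant)
}

## Fit a node from a frame stream: get_block(t) returns the n_loc x d block
## of training samples at time t (one row per grid location). Derivatives
## are taken within each location across consecutive frames. Two passes:
## stage-1 statistics, then stage-2 statistics through the fitted stage 1.
## The same noise realization is replayed in both passes.
fit_node_stream <- function(get_block, n_frames, d, spec,
                            variant = c("sfa", "pca")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "node_spec"))
  if (spec$sfa1_dim > d) {
    stop("sfa1_dim (", spec$sfa1_dim, ") exceeds input dimensionality ", d)
  }
  noise_seed <- sample.int(.Machine$integer.max, 1L)

  st1 <- sfa_stats_init(d)
  withr_seed(noise_seed, {
    for (t in seq_len(n_frames)) {
      b <- add_gaussian_noise(get_block(t), spec$noise_variance)
      st1 <- sfa_stats_update(st1, b, frame = TRUE)
    }
  })
  s1 <- sfa_from_stats(st1, spec$sfa1_dim, variant = variant)

  st2 <- sfa_stats_init(expanded_dim(s1$out_dim))
  withr_seed(noise_seed, {
    for (t in seq_len(n_frames)) {
      b <- add_gaussian_noise(get_block(t), spec$noise_variance)
      st2 <- sfa_stats_update(st2, quadratic_expand(predict(s1, b)),
                              frame = TRUE)
    }
  })
  s2 <- sfa_from_stats(st2, spec$sfa2_dim, variant = variant)

  structure(list(spec = spec, sfa1 = s1, sfa2 = s2, variant = variant,
                 d = d, out_dim = s2$out_dim),
            class = "sfa_node")
}

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Apply a fitted hierarchy node
#'
#' Deterministic pipeline: stage 1 -> quadratic expansion -> stage 2 ->
#' clipping (no noise at apply time).
#'
#' @param object fitted \code{"sfa_node"}.
#' @param newdata numeric matrix (T x d) or length-d vector.
#' @param ... unused.
#' @return numeric matrix, T x out_dim, delta-ordered.
#' @export
predict.sfa_node <- function(object, newdata, ...) {
  y <- predict(object$sfa2, quadratic_expand(predict(object$sfa1, newdata)))
  if (!is.null(object$spec$clip_bound)) {
    y <- clip_signal(y, object$spec$clip_bound)
  }
  y
}

#' @export
print.sfa_node <- function(x, ...) {
  cat(sprintf("%s node: %d -> %d -> (%d) -> %d\n", toupper(x$variant),
              x$d, x$sfa1$out_dim, expanded_dim(x$sfa1$out_dim), x$out_dim))
  invisible(x)
}
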