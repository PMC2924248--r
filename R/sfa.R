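#' Temporal slowness (delta value) of a signal
#'
#' The delta value of a channel is the mean squared temporal derivative,
#' approximated by forward differences: \eqn{\Delta_j = \langle (y_j(t+1) -
#' y_j(t))^2 \rangle_t}. Small delta values indicate slowly varying signals;
#' it is the objective that slow feature analysis minimizes.
#'
#' @param y numeric matrix with one row per time step and one column per
#'   channel (a vector is treated as a single channel).
#' @return numeric vector of per-channel delta values (all >= 0).
#' @examples
#' delta_value(sin(2 * pi * (0:999) / 100))
#' @export
delta_value <- function(y) {
  y <- as_timeseries(y)
  if (nrow(y) < 2L) {
    stop("delta_value() needs at least 2 samples, got ", nrow(y))
  }
  d <- diff(y)
  colMeans(d * d)
}

## Coerce input to a T x d numeric matrix and check finiteness.
as_timeseries <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix (T samples x d channels)")
  }
  if (!all(is.finite(x))) stop("time series contains non-finite values")
  x
}

#' Fit a linear slow feature analysis (or PCA) stage
#'
#' Solves the slowness optimization problem over linear functions of the
#' (centered) input: find projections whose outputs have zero mean, unit
#' variance and zero cross-correlation on the training data, while
#' minimizing the mean squared temporal derivative, in ascending order of
#' delta value. The solution is obtained from the generalized eigenproblem
#' of the forward-difference covariance against the signal covariance
#' (whitening followed by a symmetric eigendecomposition).
#'
#' With \code{variant = "pca"} the same interface instead ranks components
#' by explained variance (descending); outputs are standardized
#' (unit-variance) principal components, so the two variants differ only
#' in their ranking criterion.
#'
#' @param x numeric matrix, T samples x d channels, T > d.
#' @param out_dim number of output components to keep.
#' @param variant \code{"sfa"} (default) or \code{"pca"}.
#' @param reg relative ridge added to the covariance diagonal,
#'   \code{reg * trace/d}, guarding rank deficiency.
#' @return an object of class \code{"sfa"} with fields \code{input_mean},
#'   \code{projection} (d x out_dim), \code{values} (delta values, ascending,
#'   for SFA; explained variances, descending, for PCA) and metadata.
#' @seealso [predict.sfa()], [sfa_node()], [sfa_hierarchy()]
#' @export
sfa <- function(x, out_dim, variant = c("sfa", "pca"), reg = 1e-10) {
  variant <- match.arg(variant)
  x <- as_timeseries(x)
  if (nrow(x) <= ncol(x)) {
    stop("need more samples than channels (T = ", nrow(x),
         ", d = ", ncol(x), ")")
  }
  st <- sfa_stats_init(ncol(x))
  st <- sfa_stats_update(st, x)
  sfa_from_stats(st, out_dim, variant = variant, reg = reg)
}

## Streaming second-order statistics. Samples within one call to
## sfa_stats_update() are treated as consecutive in time per "location":
## the update accepts an n_loc x d block per time step so that weight-shared
## training can difference each location's own time series.
sfa_stats_init <- function(d) {
  list(d = d, n = 0, sum = numeric(d), cross = matrix(0, d, d),
       dn = 0, dcross = matrix(0, d, d), prev = NULL)
}

## x: a T x d matrix for a single location, or a per-frame n_loc x d block
## when called frame-by-frame (frame = TRUE links derivatives across calls).
sfa_stats_update <- function(st, x, frame = FALSE) {
  x <- as_timeseries(x)
  st$n <- st$n + nrow(x)
  st$sum <- st$sum + colSums(x)
  st$cross <- st$cross + crossprod(x)
  if (frame) {
    if (!is.null(st$prev)) {
      d <- x - st$prev
      st$dn <- st$dn + nrow(d)
      st$dcross <- st$dcross + crossprod(d)
    }
    st$prev <- x
  } else if (nrow(x) >= 2L) {
    d <- diff(x)
    st$dn <- st$dn + nrow(d)
    st$dcross <- st$dcross + crossprod(d)
  }
  st
}

sfa_from_stats <- function(st, out_dim, variant = c("sfa", "pca"),
                           reg = 1e-10) {
  variant <- match.arg(variant)
  d <- st$d
  mu <- st$sum / st$n
  C <- (st$cross - st$n * tcrossprod(mu)) / (st$n - 1)
  C <- (C + t(C)) / 2
  eps <- reg * sum(diag(C)) / d
  C <- C + diag(eps, d)

  if (variant == "pca") {
    ec <- eigen(C, symmetric = TRUE)
    rank <- sum(ec$values > max(ec$values) * 1e-12)
    out_dim <- check_out_dim(out_dim, rank)
    vals <- ec$values[seq_len(out_dim)]
    ## standardized (unit-variance) components: keeps the variance RANKING
    ## as the only difference from the SFA stage, and keeps downstream
    ## expansion and clipping on the same scale for both variants
    proj <- ec$vectors[, seq_len(out_dim), drop = FALSE] %*%
      diag(1 / sqrt(vals), out_dim)
  } else {
    if (st$dn < 1) stop("no derivative samples accumulated; need T >= 2")
    Cd <- st$dcross / st$dn
    Cd <- (Cd + t(Cd)) / 2
    ec <- eigen(C, symmetric = TRUE)
    rank <- sum(ec$values > max(ec$values) * 1e-12)
    out_dim <- check_out_dim(out_dim, rank)
    W <- ec$vectors[, seq_len(rank), drop = FALSE] %*%
      diag(1 / sqrt(ec$values[seq_len(rank)]), rank)
    M <- crossprod(W, Cd %*% W)
    M <- (M + t(M)) / 2
    em <- eigen(M, symmetric = TRUE)
    sel <- rev(seq(rank - out_dim + 1L, rank))  # ascending eigenvalues
    proj <- W %*% em$vectors[, sel, drop = FALSE]
    vals <- em$values[sel]
  }
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(proj))) {
    i <- which.max(abs(proj[, j]))
    if (proj[i, j] < 0) proj[, j] <- -proj[, j]
  }
  structure(list(input_mean = mu, projection = proj, values = vals,
                 d = d, out_dim = out_dim, variant = variant, n_train = st$n),
            class = "sfa")
}

check_out_dim <- function(out_dim, rank) {
  if (out_dim < 1) stop("out_dim must be >= 1")
  if (out_dim > rank) {
    warning("requested ", out_dim, " components but rank is ", rank,
            "; reducing")
    out_dim <- rank
  }
  out_dim
}

#' Apply a fitted linear SFA/PCA stage
#'
#' The mapping is instantaneous: \code{y = (x - input_mean) \%*\% projection}.
#' Each output sample depends only on the input sample at the same time
#' step, so a single sample (T = 1) is accepted.
#'
#' @param object fitted \code{"sfa"} object.
#' @param newdata numeric matrix (T x d) or a length-d vector (one sample).
#' @param ... unused.
#' @return numeric matrix, T x out_dim.
#' @export
predict.sfa <- function(object, newdata, ...) {
  if (is.vector(newdata) && is.numeric(newdata)) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  newdata <- as_timeseries(newdata)
  if (ncol(newdata) != object$d) {
    stop("input has ", ncol(newdata), " channels; model expects ", object$d)
  }
  sweep(newdata, 2L, object$input_mean) %*% object$projection
}

#' @export
print.sfa <- function(x, ...) {
  cat(sprintf("Linear %s stage: %d -> %d channels (n_train = %d)\n",
              toupper(x$variant), x$d, x$out_dim, x$n_train))
  lab <- if (x$variant == "sfa") "delta values" else "explained variances"
  cat(lab, ":", format(signif(x$values, 4)), "\n")
  invisible(x)
}

#' @export
summary.sfa <- function(object, ...) {
  out <- list(variant = object$variant, d = object$d,
              out_dim = object$out_dim, values = object$values,
              n_train = object$n_train)
  class(out) <- "summary.sfa"
  out
}

#' @export
print.summary.sfa <- function(x, ...) {
  cat(sprintf("%s stage, input dim %d, output dim %d, trained on %d samples\n",
              toupper(x$variant), x$d, x$out_dim, x$n_train))
  print(data.frame(component = seq_along(x$values), value = x$values),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.sfa <- function(object, ...) object$projection

#' Plot the slowness (or variance) spectrum of a fitted stage
#' @param x fitted \code{"sfa"} object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sfa <- function(x, ...) {
  lab <- if (x$variant == "sfa") expression(Delta ~ value) else "variance"
  graphics::plot(seq_along(x$values), x$values, type = "b",
                 xlab = "component", ylab = lab, ...)
  invisible(x)
}

#' Quadratic (degree-2 polynomial) expansion
#'
#' Augments a d-channel signal with all monomials \eqn{x_i x_j}, i <= j, so
#' that a subsequent linear SFA stage is equivalent to SFA over polynomials
#' of degree up to two. Output order: the d original channels first, then
#' the monomials with (i, j) in row-major order ((1,1), (1,2), ..., (1,d),
#' (2,2), ...). Output dimensionality is d + d(d+1)/2.
#'
#' @param x numeric matrix (T x d) or vector.
#' @return numeric matrix, T x (d + d(d+1)/2).
#' @export
quadratic_expand <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  x <- as_timeseries(x)
  d <- ncol(x)
  ij <- quad_index(d)
  cbind(x, x[, ij$i, drop = FALSE] * x[, ij$j, drop = FALSE])
}

quad_index <- function(d) {
  i <- rep.int(seq_len(d), times = d - seq_len(d) + 1L)
  j <- unlist(lapply(seq_len(d), function(k) k:d), use.names = FALSE)
  list(i = i, j = j)
}

#' Number of channels after quadratic expansion
#' @param d input dimensionality.
#' @export
expanded_dim <- function(d) d + d * (d + 1L) / 2L

#' Add white Gaussian noise to a signal
#'
#' Used while accumulating training statistics to avoid singular
#' covariances in the subsequent SFA step. Variance 0 is the identity.
#' Draws from the global RNG; call \code{set.seed()} for reproducibility.
#'
#' @param x numeric matrix or vector.
#' @param variance noise variance, >= 0.
#' @export
add_gaussian_noise <- function(x, variance) {
  if (!is.numeric(variance) || length(variance) != 1L || variance < 0) {
    stop("variance must be a single non-negative number")
  }
  if (variance == 0) return(x)
  x + stats::rnorm(length(x), sd = sqrt(variance))
}

#' Clip a signal elementwise to a symmetric bound
#'
#' Removes extreme values that the quadratic expansion can produce on test
#' data far from the training distribution.
#'
#' @param x numeric matrix or vector.
#' @param bound positive scalar; values are clamped to \code{[-bound, bound]}.
#' @export
clip_signal <- function(x, bound) {
  if (!is.numeric(bound) || length(bound) != 1L || bound <= 0) {
    stop("bound must be a single positive number")
  }
  pmin(pmax(x, -bound), bound)
}
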