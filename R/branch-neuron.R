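#' Exponential low-pass reward baseline
#'
#' Tracks \eqn{\bar R}, the exponentially filtered reward used as the
#' baseline of the perturbation learning rules; the filtered value is
#' always a convex combination of past rewards (it is initialized to the
#' first reward seen).
#'
#' @param tau filter time constant (steps); the update is
#'   \code{rbar <- rbar + (r - rbar)/tau}.
#' @return an object of class \code{"reward_filter"}.
#' @export
reward_filter <- function(tau = 50) {
  stopifnot(tau >= 1)
  structure(list(tau = tau, rbar = NA_real_), class = "reward_filter")
}

#' Advance the reward filter
#' @param filter a [reward_filter()].
#' @param r observed reward.
#' @return the updated filter (read the baseline from \code{$rbar}).
#' @export
rf_update <- function(filter, r) {
  filter$rbar <- if (is.na(filter$rbar)) r else
    filter$rbar + (r - filter$rbar) / filter$tau
  filter
}

#' Policy neuron with nonlinear dendritic branches
#'
#' The somatic input is a noisy weighted sum of branch signals,
#' \eqn{u = \sum_k q_k b_k + b_0 + \xi}, each branch computing a sigmoidal
#' function of its own weighted synaptic input, \eqn{b_k =
#' \tanh(w_k \cdot x)}. The output is \eqn{y = \sigma(u)} with a tanh soma
#' (angular commands, range (-1,1)) or a logistic soma (speed commands,
#' range (0,1)). The exploratory noise \eqn{\xi} is uniform on
#' \code{[-noise_halfwidth, noise_halfwidth]}, drawn fresh each step.
#' Both the synaptic weights and the branch-soma couplings are plastic.
#'
#' @param n_inputs input dimensionality d.
#' @param n_branches number of dendritic branches K.
#' @param soma \code{"tanh"} or \code{"logistic"}.
#' @param noise_halfwidth half-width of the uniform exploration noise.
#' @param eta_w,eta_q,eta_b learning rates for synaptic weights, branch
#'   couplings and the bias.
#' @param init_sd standard deviation of the random initial parameters
#'   (exactly zero couplings would freeze the synaptic gradient).
#' @return an object of class \code{"branch_neuron"}.
#' @export
branch_neuron <- function(n_inputs, n_branches = 10L,
                          soma = c("tanh", "logistic"),
                          noise_halfwidth = 0.5,
                          eta_w = 0.1, eta_q = 0.1, eta_b = 0.1,
                          init_sd = 0.7) {
  soma <- match.arg(soma)
  stopifnot(n_inputs >= 1, n_branches >= 1, noise_halfwidth >= 0)
  structure(list(
    K = as.integer(n_branches), d = as.integer(n_inputs), soma = soma,
    w = matrix(stats::rnorm(n_branches * n_inputs, sd = init_sd),
               n_branches, n_inputs),
    q = stats::rnorm(n_branches, sd = init_sd),
    bias = 0,
    noise_halfwidth = noise_halfwidth,
    eta_w = eta_w, eta_q = eta_q, eta_b = eta_b), class = "branch_neuron")
}

#' @export
print.branch_neuron <- function(x, ...) {
  cat(sprintf("branch neuron: %d branches on %d inputs, %s soma, noise +/-%.2f\n",
              x$K, x$d, x$soma, x$noise_halfwidth))
  invisible(x)
}

soma_fn <- function(kind) {
  switch(kind, tanh = tanh, logistic = function(u) 1 / (1 + exp(-u)))
}

#' Forward pass of a branch neuron
#'
#' @param neuron a [branch_neuron()].
#' @param x length-d input vector.
#' @param xi exploration noise; omit to draw uniformly from
#'   \code{[-noise_halfwidth, noise_halfwidth]}.
#' @return a list with the output \code{y}, branch activations \code{b},
#'   somatic input \code{u} and the drawn \code{xi} (the internals needed
#'   by [pg_update()]).
#' @export
branch_forward <- function(neuron, x, xi = NULL) {
  if (length(x) != neuron$d) {
    stop("input has length ", length(x), "; neuron expects ", neuron$d)
  }
  if (is.null(xi)) {
    hw <- neuron$noise_halfwidth
    xi <- if (hw > 0) stats::runif(1, -hw, hw) else 0
  }
  a <- drop(neuron$w %*% x)       # branch pre-activations
  b <- tanh(a)
  u <- sum(neuron$q * b) + neuron$bias + xi
  list(y = soma_fn(neuron$soma)(u), b = b, a = a, u = u, xi = xi)
}

#' Perturbation policy-gradient update of a branch neuron
#'
#' Node-perturbation gradient ascent on the reward: the injected somatic
#' noise is correlated with the deviation of the reward from its low-pass
#' baseline, and credited to each parameter through its influence on the
#' somatic input:
#' \deqn{\Delta w_{kj} = \eta_w (R - \bar R)\, \xi\, q_k\, (1 - b_k^2)\, x_j,
#'   \quad \Delta q_k = \eta_q (R - \bar R)\, \xi\, b_k, \quad
#'   \Delta b_0 = \eta_b (R - \bar R)\, \xi.}
#' No eligibility traces are used. The expected update direction matches
#' the gradient of the expected reward (the package's tests verify this
#' against finite differences).
#'
#' @param neuron a [branch_neuron()].
#' @param fwd internals from [branch_forward()] of the same step.
#' @param x the input of that forward pass.
#' @param reward scalar reward R for the step.
#' @param rbar baseline (from a [reward_filter()]).
#' @return a list of parameter deltas \code{dw} (K x d), \code{dq}
#'   (length K) and \code{dbias}; apply with [apply_deltas()].
#' @export
pg_update <- function(neuron, fwd, x, reward, rbar) {
  if (is.null(fwd$xi) || is.null(fwd$b)) {
    stop("pg_update() needs the internals returned by branch_forward()")
  }
  m <- (reward - rbar) * fwd$xi
  list(dw = neuron$eta_w * m * (neuron$q * (1 - fwd$b^2)) %o% x,
       dq = neuron$eta_q * m * fwd$b,
       dbias = neuron$eta_b * m)
}

#' Apply parameter deltas to a neuron or network
#' @param object a [branch_neuron()] or [simple_network()].
#' @param deltas deltas from [pg_update()] / [simple_update()] (or an
#'   average of several).
#' @return the updated object.
#' @export
apply_deltas <- function(object, deltas) UseMethod("apply_deltas")

#' @export
apply_deltas.branch_neuron <- function(object, deltas) {
  object$w <- object$w + deltas$dw
  object$q <- object$q + deltas$dq
  object$bias <- object$bias + deltas$dbias
  object
}

## elementwise mean of a list of delta lists (any nesting of numerics)
average_deltas <- function(deltas) {
  n <- length(deltas)
  out <- deltas[[1L]]
  rec <- function(field) Reduce(`+`, lapply(deltas, `[[`, field)) / n
  for (f in names(out)) out[[f]] <- if (is.list(out[[f]]))
    average_deltas(lapply(deltas, `[[`, f)) else rec(f)
  out
}

#' Two-layer network of simple point neurons
#'
#' The baseline controller: pseudo-linear rate neurons, each applying a
#' sigmoid to a noisy weighted input sum, arranged as a hidden layer of
#' \code{n_hidden} tanh neurons feeding one output neuron. Every neuron
#' carries its own exploration noise and optimizes the reward
#' independently with the same perturbation rule (greedy per-neuron
#' gradient ascent).
#'
#' @param n_inputs input dimensionality.
#' @param n_hidden hidden-layer size.
#' @param soma output nonlinearity, \code{"tanh"} or \code{"logistic"}.
#' @param noise_halfwidth per-neuron uniform noise half-width.
#' @param eta learning rate (all neurons).
#' @param init_sd initial weight scale.
#' @return an object of class \code{"simple_network"}.
#' @export
simple_network <- function(n_inputs, n_hidden = 50L,
                           soma = c("tanh", "logistic"),
                           noise_halfwidth = 0.5, eta = 0.02,
                           init_sd = 0.1) {
  soma <- match.arg(soma)
  structure(list(
    d = as.integer(n_inputs), H = as.integer(n_hidden), soma = soma,
    W1 = matrix(stats::rnorm(n_hidden * n_inputs, sd = init_sd),
                n_hidden, n_inputs),
    b1 = numeric(n_hidden),
    w2 = stats::rnorm(n_hidden, sd = init_sd),
    b2 = 0,
    noise_halfwidth = noise_halfwidth, eta = eta),
    class = "simple_network")
}

#' @export
print.simple_network <- function(x, ...) {
  cat(sprintf("simple network: %d -> %d -> 1 (%s output)\n",
              x$d, x$H, x$soma))
  invisible(x)
}

#' Forward pass of the simple-neuron network
#' @param net a [simple_network()].
#' @param x input vector.
#' @param xi optional length \code{n_hidden + 1} noise vector (hidden
#'   neurons then output neuron); drawn uniformly when omitted.
#' @return list with output \code{y}, hidden activations \code{h}, and the
#'   noise draws.
#' @export
simple_forward <- function(net, x, xi = NULL) {
  if (length(x) != net$d) {
    stop("input has length ", length(x), "; network expects ", net$d)
  }
  if (is.null(xi)) {
    hw <- net$noise_halfwidth
    xi <- if (hw > 0) stats::runif(net$H + 1L, -hw, hw) else numeric(net$H + 1L)
  }
  h <- tanh(drop(net$W1 %*% x) + net$b1 + xi[seq_len(net$H)])
  u <- sum(net$w2 * h) + net$b2 + xi[net$H + 1L]
  list(y = soma_fn(net$soma)(u), h = h, u = u, xi = xi)
}

#' Perturbation update of the simple-neuron network
#'
#' Each neuron correlates its own injected noise with the baseline-
#' subtracted reward: \eqn{\Delta w = \eta (R - \bar R) \xi_i x} for the
#' neuron's own inputs (hidden neurons see the network input, the output
#' neuron sees the hidden activations).
#'
#' @param net a [simple_network()].
#' @param fwd internals from [simple_forward()].
#' @param x the input of that pass.
#' @param reward scalar reward.
#' @param rbar low-pass baseline.
#' @return a list of deltas; apply with [apply_deltas()].
#' @export
simple_update <- function(net, fwd, x, reward, rbar) {
  m <- net$eta * (reward - rbar)
  xih <- fwd$xi[seq_len(net$H)]
  list(dW1 = m * xih %o% x,
       db1 = m * xih,
       dw2 = m * fwd$xi[net$H + 1L] * fwd$h,
       db2 = m * fwd$xi[net$H + 1L])
}

#' @export
apply_deltas.simple_network <- function(object, deltas) {
  object$W1 <- object$W1 + deltas$dW1
  object$b1 <- object$b1 + deltas$db1
  object$w2 <- object$w2 + deltas$dw2
  object$b2 <- object$b2 + deltas$db2
  object
}
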