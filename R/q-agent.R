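#' Population-coded linear Q-learning ensemble
#'
#' The Q-function over movement directions is represented by \code{M}
#' linear neurons, one per preferred direction (uniformly spaced on
#' [0, 2pi)): \eqn{Q_a = w_a \cdot y} for the feature vector y. The greedy
#' action is the angle of the population vector \eqn{\sum_a Q_a
#' (\cos\phi_a, \sin\phi_a)}. Learning is a local synaptic rule gated by
#' the TD error, with a Gaussian activity profile around the chosen action
#' as the postsynaptic factor of the eligibility trace.
#'
#' @param n_features input (feature) dimensionality.
#' @param n_actions number of neurons / preferred directions M.
#' @param gamma discount factor.
#' @param epsilon exploration probability (random direction).
#' @param lambda eligibility-trace decay (0 disables traces).
#' @param eta0,eta_tau learning-rate schedule \eqn{\eta_t = \eta_0 / (1 +
#'   t/\tau)}.
#' @param sigma_profile width (radians) of the Gaussian activity profile.
#' @return an object of class \code{"q_population"}.
#' @export
q_population <- function(n_features, n_actions = 36L, gamma = 0.95,
                         epsilon = 0.1, lambda = 0.9,
                         eta0 = 0.3, eta_tau = 1200,
                         sigma_profile = 1.5 * 2 * pi / n_actions) {
  stopifnot(n_features >= 1, n_actions >= 2, gamma >= 0, gamma < 1,
            epsilon >= 0, epsilon <= 1, lambda >= 0, lambda <= 1,
            eta0 > 0, sigma_profile > 0)
  structure(list(
    M = as.integer(n_actions), d = as.integer(n_features),
    weights = matrix(0, n_actions, n_features),
    dirs = 2 * pi * (seq_len(n_actions) - 1L) / n_actions,
    eligibility = matrix(0, n_actions, n_features),
    gamma = gamma, epsilon = epsilon, lambda = lambda,
    eta0 = eta0, eta_tau = eta_tau, sigma_profile = sigma_profile,
    t = 0L, last = NULL), class = "q_population")
}

#' @export
print.q_population <- function(x, ...) {
  cat(sprintf("Q population: %d neurons on %d features (gamma %.2f, eps %.2f, lambda %.2f, t = %d)\n",
              x$M, x$d, x$gamma, x$epsilon, x$lambda, x$t))
  invisible(x)
}

#' Q-values of the neuron population
#'
#' Linear, bias-free readout: \code{Q = weights \%*\% features}.
#'
#' @param pop a [q_population()].
#' @param features length-d feature vector.
#' @return length-M numeric vector of Q-values.
#' @export
q_forward <- function(pop, features) {
  if (length(features) != pop$d) {
    stop("feature vector has length ", length(features),
         "; population expects ", pop$d)
  }
  drop(pop$weights %*% features)
}

#' Greedy direction from a population vector
#'
#' The angle of \eqn{\sum_a Q_a (\cos\phi_a, \sin\phi_a)}. When the
#' resultant magnitude is below 1e-12 (e.g. uniform Q over a symmetric
#' ring) the direction is undefined and drawn uniformly at random.
#'
#' @param q length-M Q-vector.
#' @param dirs length-M preferred directions (radians).
#' @return an angle in [-pi, pi).
#' @export
population_direction <- function(q, dirs) {
  stopifnot(length(q) == length(dirs), length(q) >= 2)
  vx <- sum(q * cos(dirs))
  vy <- sum(q * sin(dirs))
  if (sqrt(vx^2 + vy^2) < 1e-12) {
    return(stats::runif(1, -pi, pi))
  }
  atan2(vy, vx)
}

#' Epsilon-greedy action selection over directions
#'
#' @param greedy_angle the population-vector direction.
#' @param epsilon exploration probability.
#' @return the greedy angle with probability 1 - epsilon, otherwise a
#'   uniform random angle.
#' @export
select_action <- function(greedy_angle, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    stats::runif(1, 0, 2 * pi)
  } else {
    greedy_angle
  }
}

#' Gaussian activity profile around a chosen action
#'
#' \eqn{a_k = \exp(-\delta(\phi_k, \theta)^2 / 2\sigma^2)} with the
#' circular angle difference \eqn{\delta}; maximal (= 1 when a preferred
#' direction coincides with the action) at the nearest neuron.
#'
#' @param chosen_angle chosen action angle.
#' @param dirs preferred directions.
#' @param sigma profile width (radians), > 0.
#' @return length-M activity vector in (0, 1].
#' @export
gaussian_activity <- function(chosen_angle, dirs, sigma) {
  stopifnot(sigma > 0)
  d <- wrap_angle(dirs - chosen_angle)
  exp(-d^2 / (2 * sigma^2))
}

## normalized-profile readout of Q at an arbitrary angle
profile_q <- function(q, profile) sum(profile * q) / sum(profile)

#' Choose an action and update the eligibility trace
#'
#' One acting half of the Q-learning step: compute the Q-values, take the
#' population-vector direction, epsilon-greedy over it, enforce the
#' Gaussian profile around the chosen action, and update the eligibility
#' trace \code{e <- gamma * lambda * e + profile (x) features} with the
#' normalized profile as the postsynaptic factor. On exploratory (random)
#' actions the trace is first reset, the Watkins convention that keeps the
#' off-policy max-bootstrap update stable. The value estimate never
#' depends on epsilon; exploration only affects the executed action.
#'
#' @param pop a [q_population()].
#' @param features current feature vector.
#' @return a list with the updated \code{pop} and the chosen \code{action}
#'   (radians); the profile-interpolated \code{Q(s, a)} is stored inside
#'   \code{pop} for the learning half.
#' @seealso [q_learn()]
#' @export
q_act <- function(pop, features) {
  q <- q_forward(pop, features)
  greedy <- population_direction(q, pop$dirs)
  action <- select_action(greedy, pop$epsilon)
  profile <- gaussian_activity(action, pop$dirs, pop$sigma_profile)
  pn <- profile / sum(profile)
  if (action != greedy) pop$eligibility[] <- 0  # Watkins trace cut
  pop$eligibility <- pop$gamma * pop$lambda * pop$eligibility +
    tcrossprod(pn, features)
  pop$last <- list(q_sa = profile_q(q, profile))
  list(pop = pop, action = action, q = q, greedy = greedy)
}

#' Apply the TD update after the environment step
#'
#' The learning half: \eqn{\delta = R + \gamma Q(s', a^*) - Q(s,
#' a_{chosen})}, where \eqn{Q(s', a^*)} is the value the population
#' itself assigns to acting greedily in the next state — the
#' normalized-profile readout at the next population-vector direction.
#' Bootstrapping from this readout rather than the raw per-neuron maximum
#' uses the same value definition for acting and learning; with global
#' (non-localized) feature bases the raw maximum over all neurons is
#' upward-biased and destabilizes the update loop. The bootstrap term is
#' dropped on terminal steps. Weights then change by
#' \code{eta_t * delta * eligibility} with the decaying learning rate
#' \eqn{\eta_t = \eta_0/(1 + t/\tau)}.
#'
#' @param pop the population returned by [q_act()].
#' @param reward scalar reward received.
#' @param features_next next-state feature vector.
#' @param done terminal flag (drops the bootstrap term).
#' @return the updated \code{"q_population"}.
#' @export
q_learn <- function(pop, reward, features_next, done = FALSE) {
  if (is.null(pop$last)) stop("q_learn() called before q_act()")
  q_next <- if (done) 0 else {
    q2 <- q_forward(pop, features_next)
    greedy2 <- population_direction(q2, pop$dirs)
    profile_q(q2, gaussian_activity(greedy2, pop$dirs, pop$sigma_profile))
  }
  delta <- reward + pop$gamma * q_next - pop$last$q_sa
  eta <- pop$eta0 / (1 + pop$t / pop$eta_tau)
  pop$weights <- pop$weights + eta * delta * pop$eligibility
  pop$t <- pop$t + 1L
  pop$last <- NULL
  pop
}

## reset the per-episode trace
q_reset_trace <- function(pop) {
  pop$eligibility[] <- 0
  pop$last <- NULL
  pop
}
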