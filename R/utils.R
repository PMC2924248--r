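#' Derive independent child seeds from one root seed
#'
#' All randomness in a run flows from one root seed, fanned out to
#' subsystems (stream generation, training noise, per-seed agents) so that
#' parallel arms are independent but reproducible.
#'
#' @param seed root integer seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## wrap an angle to [-pi, pi)
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
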