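# Sampling of the two stochastic ingredients of the bout process: bout
# durations (exponential, rate omega) and per-bout accelerations (zero mean,
# variance nu_a2, one of three families).

#' Sample bout durations
#'
#' Bout durations are the waiting times between successive environmental
#' cues, assumed to arrive as a Poisson process with rate \eqn{\omega}, so
#' durations are i.i.d. exponential with density
#' \eqn{\psi(t) = \omega e^{-\omega t}} and mean \eqn{1/\omega}.
#'
#' @param omega cue rate (> 0).
#' @param n number of durations (>= 0; `n = 0` gives an empty vector).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of `n` non-negative durations.
#' @examples
#' mean(sample_bout_durations(2, 1e4, seed = 1)) # about 0.5
#' @export
sample_bout_durations <- function(omega, n, seed = NULL) {
  stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0,
            is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  rexp(n, rate = omega)
}

# internal: family string -> integer code shared with the C++ simulator
.accel_family_code <- function(family) {
  match(match.arg(family, c("gaussian", "uniform", "two_point")),
        c("gaussian", "uniform", "two_point")) - 1L
}

#' Sample per-bout accelerations
#'
#' Draws i.i.d. accelerations from one of three zero-mean families with
#' variance `nu_a2`: `"gaussian"` (normal with sd \eqn{\nu_a}), `"uniform"`
#' (on \eqn{[-\sqrt3\nu_a, \sqrt3\nu_a]}) or `"two_point"`
#' (\eqn{\pm\nu_a} equiprobable). The exact MSD of the movement process is
#' the same for all three (it depends on the forcing only through its mean
#' and variance); the families are provided to make that invariance testable
#' over bounded and unbounded supports.
#'
#' @param n number of draws.
#' @param nu_a2 acceleration variance (> 0).
#' @param family distribution family.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` accelerations.
#' @export
sample_accelerations <- function(n, nu_a2,
                                 family = c("gaussian", "uniform", "two_point"),
                                 seed = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(n), n >= 0, is.numeric(nu_a2), nu_a2 > 0)
  if (!is.null(seed)) set.seed(seed)
  nu_a <- sqrt(nu_a2)
  switch(family,
         gaussian = rnorm(n, 0, nu_a),
         uniform = runif(n, -sqrt(3) * nu_a, sqrt(3) * nu_a),
         two_point = nu_a * (2L * (runif(n) < 0.5) - 1L))
}
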