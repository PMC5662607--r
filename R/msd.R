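# Closed-form mean squared displacement of the bout process and its limits.
#
# The exact MSD of the process started at rest is, in dimensionless
# variables (tau = omega t, zeta = gamma/omega, eta = sigma/omega^2):
#
#   <x^2>(zeta, tau) = (2 eta^2 / zeta) { tau/zeta
#                       - [1 + 2(1+zeta)^2] / [2 zeta^2 (1+zeta)]
#                       + 1/(zeta-1) [ e^{-2 zeta tau}/(2 zeta^2)
#                            + e^{-zeta tau}((zeta-2)/zeta^2 - e^{-tau}/(1+zeta))
#                            + e^{-tau} ] }
#
# The formula is exact for all zeta > 0 (the 1/(zeta-1) factor is a removable
# singularity) but is numerically treacherous: at small tau the terms cancel
# to O(tau^4), at small zeta to O(zeta), and near zeta = 1 the bracket itself
# vanishes. Evaluation is therefore split into validated regions:
#   (A) tau <= 0.5 and zeta*tau <= 0.5 (or zeta >= 32 and zeta*tau <= 1):
#       exact power series in tau (orders 4..18, coefficients polynomial in
#       zeta), see .msd_tau_series;
#   (B) zeta <= 0.5 and zeta*tau <= 0.5 with tau > 0.5: exact power series in
#       zeta (orders 0..10), used only when its truncation error estimate
#       beats the direct formula's cancellation estimate;
#   (C) otherwise the direct formula, with a 5-term Taylor expansion of the
#       bracket about zeta = 1 when |zeta - 1| < 1e-3.
# Against a 120-digit reference the hybrid is accurate to ~1e-13 relative in
# routine use and no worse than ~3e-10 in extreme high-drag corners
# (zeta >= 1e3 with zeta*tau near 1).

# polynomial evaluation, coefficients lowest order first
.polyval_lo <- function(coef, x) {
  s <- 0
  for (c_ in rev(coef)) s <- s * x + c_
  s
}

# coefficients highest order first (Horner order)
.polyval_hi <- function(coef, x) {
  s <- 0
  for (c_ in coef) s <- s * x + c_
  s
}

# region A: small-time series, scalar zeta/tau
.msd_exact_tau_series <- function(zeta, tau) {
  s <- 0
  for (k in length(.msd_tau_series):1)
    s <- s * tau + .polyval_lo(.msd_tau_series[[k]], zeta)
  s * tau^4
}

# region B: low-drag series, scalar
.msd_exact_zeta_series <- function(zeta, tau) {
  u <- exp(-tau)
  s <- 0
  for (k in length(.msd_zeta_series_a):1) {
    mk <- .polyval_hi(.msd_zeta_series_a[[k]], tau) +
      u * .polyval_hi(.msd_zeta_series_b[[k]], tau)
    s <- s * zeta + mk
  }
  s
}

# constant (tau-free) term of the exact MSD bracket
.msd_const_term <- function(zeta) {
  (1 + 2 * (1 + zeta)^2) / (2 * zeta^2 * (1 + zeta))
}

# bracket/(zeta-1) by Taylor expansion about zeta = 1 (the bracket has a
# simple zero there); derivatives generated symbolically and frozen
.msd_g_near_one <- function(zeta, tau) {
  d <- zeta - 1
  e1 <- exp(-tau)
  e2 <- exp(-2 * tau)
  b1 <- .polyval_hi(c(1, 3), tau) * e1 +
    .polyval_hi(c(-1/2, -3/4), tau) * e2
  b2 <- .polyval_hi(c(-1, -6, -10), tau) * e1 +
    .polyval_hi(c(3/2, 7/2, 11/4), tau) * e2
  b3 <- .polyval_hi(c(1, 9, 30, 42), tau) * e1 +
    .polyval_hi(c(-7/2, -45/4, -69/4, -93/8), tau) * e2
  b4 <- .polyval_hi(c(-1, -12, -60, -168, -216), tau) * e1 +
    .polyval_hi(c(15/2, 31, 141/2, 189/2, 237/4), tau) * e2
  b5 <- .polyval_hi(c(1, 15, 100, 420, 1080, 1320), tau) * e1 +
    .polyval_hi(c(-31/2, -315/4, -475/2, -1905/4, -2385/4, -2865/8), tau) * e2
  b1 + d * (b2 / 2 + d * (b3 / 6 + d * (b4 / 24 + d * b5 / 120)))
}

# direct evaluation (region C), scalar
.msd_exact_direct <- function(zeta, tau) {
  if (abs(zeta - 1) < 1e-3) {
    g <- .msd_g_near_one(zeta, tau)
  } else {
    g <- (exp(-2 * zeta * tau) / (2 * zeta^2) +
            exp(-zeta * tau) * ((zeta - 2) / zeta^2 - exp(-tau) / (1 + zeta)) +
            exp(-tau)) / (zeta - 1)
  }
  (2 / zeta) * (tau / zeta - .msd_const_term(zeta) + g)
}

.msd_exact_scalar <- function(zeta, tau) {
  if (tau == 0) return(0)
  zt <- zeta * tau
  if ((tau <= 0.5 && zt <= 0.5) || (zeta >= 32 && zt <= 1 && tau <= 0.5))
    return(.msd_exact_tau_series(zeta, tau))
  if (zeta <= 0.5 && zt <= 0.5) {
    v <- .msd_exact_zeta_series(zeta, tau)
    # prefer the direct formula when its cancellation error is smaller than
    # the series truncation (large tau, moderate zeta)
    err_direct <- 1e-16 * (2 / zeta) * .msd_const_term(zeta) / abs(v)
    err_series <- 1e-6 * zt^11
    if (err_direct < err_series) return(.msd_exact_direct(zeta, tau))
    return(v)
  }
  .msd_exact_direct(zeta, tau)
}

#' Exact mean squared displacement of the bout process
#'
#' Evaluates the closed-form MSD of the random-acceleration bout process
#' started at rest, in dimensionless variables (see Details in
#' [boutmotion-package]). The expression holds for every acceleration
#' distribution with zero mean and finite variance; the distribution enters
#' only through \eqn{\eta}. It is valid for all \eqn{\zeta > 0}, including
#' \eqn{\zeta = 1} where the apparent \eqn{1/(\zeta-1)} singularity is
#' removable (handled by a series expansion; results for \eqn{\zeta < 1}
#' extend the original derivation, which assumed \eqn{\zeta > 1}, and are
#' confirmed by simulation).
#'
#' @param zeta dimensionless drag \eqn{\gamma/\omega} (> 0). For
#'   \eqn{\zeta = 0} use [msd_zero_drag]; the zero-drag process has a
#'   different asymptotic character and is deliberately not substituted
#'   silently.
#' @param tau dimensionless time \eqn{\omega t} (>= 0).
#' @param eta dimensionless length scale \eqn{\sigma/\omega^2} (> 0);
#'   the MSD scales as \eqn{\eta^2}.
#' @return MSD in units of length^2 (of \eqn{\eta^2} when `eta = 1`).
#'   Vectorised over `zeta` and `tau` (recycled to a common length).
#' @seealso [msd_zero_drag], [msd_small_time], [diffusive_asymptote],
#'   [msd_low_drag], [msd_high_drag], [msd_curve].
#' @examples
#' msd_exact(zeta = 1, tau = c(0.1, 1, 10))
#' @export
msd_exact <- function(zeta, tau, eta = 1) {
  stopifnot(is.numeric(zeta), is.numeric(tau), is.numeric(eta),
            length(eta) == 1L, eta > 0, all(is.finite(zeta)), all(tau >= 0))
  if (any(zeta <= 0))
    stop("'zeta' must be > 0; for the drag-free process use msd_zero_drag()")
  n <- max(length(zeta), length(tau))
  zeta <- rep_len(zeta, n)
  tau <- rep_len(tau, n)
  out <- vapply(seq_len(n),
                function(i) .msd_exact_scalar(zeta[i], tau[i]),
                numeric(1))
  eta^2 * out
}

# exact small-tau series of the zero-drag bracket, coefficients
# 6 (-1)^n (n-1)/n! for n >= 4
.zero_drag_series_coefs <- local({
  n <- 4:18
  6 * (-1)^n * (n - 1) / factorial(n)
})

#' Zero-drag limit of the MSD
#'
#' The \eqn{\zeta \to 0} limit of the exact MSD:
#' \deqn{\langle z^2(\tau)\rangle = \frac{\eta^2}{3}\left[\tau^2(2\tau - 3)
#'   + 6 - 6(1+\tau)e^{-\tau}\right].}
#' It grows as \eqn{\eta^2\tau^4/4} for \eqn{\tau \ll 1} and as
#' \eqn{(2\eta^2/3)\tau^3} for \eqn{\tau \gg 1}, and bounds the exact MSD
#' from above for every \eqn{\zeta > 0}: drag can only slow the spread.
#'
#' @inheritParams msd_exact
#' @return MSD values, vectorised over `tau`.
#' @export
msd_zero_drag <- function(tau, eta = 1) {
  stopifnot(is.numeric(tau), all(tau >= 0), is.numeric(eta), eta > 0)
  small <- tau < 0.5
  out <- numeric(length(tau))
  if (any(small)) {
    ts <- tau[small]
    s <- 0
    for (c_ in rev(.zero_drag_series_coefs)) s <- s * ts + c_
    out[small] <- s * ts^4 / 3
  }
  if (any(!small)) {
    tl <- tau[!small]
    out[!small] <- (tl^2 * (2 * tl - 3) + 6 - 6 * (1 + tl) * exp(-tl)) / 3
  }
  eta^2 * out
}

#' Small-time (superballistic) asymptote of the MSD
#'
#' For \eqn{\tau \ll 1} the MSD of the process started at rest grows as
#' \deqn{\langle x^2(\tau)\rangle \sim \frac{\eta^2}{4}\tau^4,}
#' independently of \eqn{\zeta}: the spread is superballistic
#' (\eqn{t^\alpha} with \eqn{\alpha = 4 > 2}) at the start of movement.
#'
#' @inheritParams msd_exact
#' @export
msd_small_time <- function(tau, eta = 1) {
  stopifnot(is.numeric(tau), all(tau >= 0), is.numeric(eta), eta > 0)
  eta^2 * tau^4 / 4
}

#' Large-time diffusive asymptote of the MSD
#'
#' Dropping all exponentials from the exact MSD gives the linear-in-time
#' asymptote
#' \deqn{\Delta_d^2(\zeta,\tau) = \frac{2\eta^2}{\zeta^2}\tau
#'   - \eta^2\frac{1 + 2(1+\zeta)^2}{\zeta^3(1+\zeta)},}
#' an ordinary diffusion with coefficient \eqn{D = \eta^2/\zeta^2}
#' (in rescaled units; see [diffusion_coefficient] for physical units).
#' The asymptote is only meaningful at large \eqn{\tau}; for small \eqn{\tau}
#' it is negative and is returned as-is.
#'
#' @inheritParams msd_exact
#' @return Values of \eqn{\Delta_d^2}, possibly negative at small `tau`.
#' @export
diffusive_asymptote <- function(zeta, tau, eta = 1) {
  stopifnot(is.numeric(zeta), all(zeta > 0), is.numeric(tau),
            is.numeric(eta), eta > 0)
  eta^2 * (2 * tau / zeta^2 - (1 + 2 * (1 + zeta)^2) / (zeta^3 * (1 + zeta)))
}

#' Gaussian large-time dispersal kernel
#'
#' At large times the dispersal kernel (probability density of displacement
#' `x`) converges to a centred normal with variance
#' \eqn{\Delta_d^2(\zeta,\tau)}:
#' \deqn{\rho(x,\zeta,\tau) \simeq
#'   \frac{1}{\sqrt{2\pi\Delta_d^2}} e^{-x^2/(2\Delta_d^2)}.}
#' At early times the true kernel has exponential tails and this
#' approximation does not apply; the function refuses times at which the
#' asymptotic variance is not yet positive.
#'
#' @param x displacement(s) at which to evaluate the density.
#' @inheritParams msd_exact
#' @return Probability density values.
#' @seealso [ensemble_pdf] for the simulated kernel.
#' @export
gaussian_kernel <- function(x, zeta, tau, eta = 1) {
  v <- diffusive_asymptote(zeta, tau, eta)
  if (any(v <= 0))
    stop("diffusive asymptote not yet valid: Delta_d^2(zeta, tau) <= 0 at ",
         "this tau; the Gaussian kernel only applies at large times")
  dnorm(x, mean = 0, sd = sqrt(v))
}

# g + exp(-g) - 1, stable at small g
.f2 <- function(g) {
  out <- g + expm1(-g)
  small <- g < 1e-4
  if (any(small)) {
    gs <- g[small]
    out[small] <- gs^2 * (0.5 - gs * (1/6 - gs * (1/24 - gs/120)))
  }
  out
}

#' Low-drag (Wiener-limit) approximation of the MSD
#'
#' For \eqn{\zeta \ll 1} there is a stage with \eqn{\tau \gg 1} but
#' \eqn{\zeta\tau} not necessarily large, where the MSD reduces to
#' \deqn{\frac{2\sigma^2}{\gamma^3\omega}\left[\gamma t - (1 - e^{-\gamma t})
#'   - \tfrac12 (1 - e^{-\gamma t})^2\right],}
#' the MSD of the standard Langevin equation driven by a Wiener process of
#' variance \eqn{q^2 = 2\sigma^2/\omega} started at rest. Its small-time
#' behaviour is \eqn{(2\sigma^2/3\omega)\,t^3} — the intermediate
#' superdiffusive stage of the low-drag regime.
#'
#' @param gamma per-mass drag (> 0).
#' @param sigma root acceleration variance \eqn{\sigma = \nu_a} (> 0).
#' @param omega cue rate (> 0).
#' @param t physical time (>= 0).
#' @export
msd_low_drag <- function(gamma, sigma, omega, t) {
  stopifnot(gamma > 0, sigma > 0, omega > 0, all(t >= 0))
  g <- gamma * t
  em1 <- -expm1(-g)
  (2 * sigma^2 / (gamma^3 * omega)) * (.f2(g) - em1^2 / 2)
}

#' High-drag (velocity-jump) approximation of the MSD
#'
#' For \eqn{\zeta \gg 1} there is a stage with \eqn{\zeta\tau \gg 1} but
#' \eqn{\tau} not necessarily large, where the MSD reduces to
#' \deqn{\frac{2\sigma^2}{\gamma^2\omega^2}\left(\omega t - 1 +
#'   e^{-\omega t}\right),}
#' the MSD of a velocity jump process: velocity relaxes to the within-bout
#' terminal value \eqn{a/\gamma} much faster than cues arrive, so velocity
#' effectively jumps at each cue. Small-time behaviour is
#' \eqn{(\sigma^2/\gamma^2)t^2} — ballistic.
#'
#' @inheritParams msd_low_drag
#' @export
msd_high_drag <- function(gamma, sigma, omega, t) {
  stopifnot(gamma > 0, sigma > 0, omega > 0, all(t >= 0))
  (2 * sigma^2 / (gamma^2 * omega^2)) * .f2(omega * t)
}

#' Tabulate an MSD formula on a time grid
#'
#' Convenience constructor for a tidy table of one of the MSD formulas on a
#' (typically log-spaced) grid of dimensionless times, e.g. for plotting or
#' for [loglog_slope] on tabulated curves.
#'
#' @param zeta dimensionless drag (scalar; ignored by the formulas that do
#'   not depend on it).
#' @param tau numeric vector of dimensionless times.
#' @param eta dimensionless length scale.
#' @param formula which expression to tabulate.
#' @return A `data.frame` of class `"msd_curve"` with columns `formula`,
#'   `zeta`, `tau`, `msd`.
#' @examples
#' msd_curve(zeta = 1, tau = 10^seq(-2, 2, length.out = 5))
#' @export
msd_curve <- function(zeta, tau, eta = 1,
                      formula = c("exact", "zero_drag", "small_time",
                                  "diffusive_asymptote", "low_drag",
                                  "high_drag")) {
  formula <- match.arg(formula)
  stopifnot(length(zeta) == 1L)
  vals <- switch(formula,
    exact = msd_exact(zeta, tau, eta),
    zero_drag = msd_zero_drag(tau, eta),
    small_time = msd_small_time(tau, eta),
    diffusive_asymptote = diffusive_asymptote(zeta, tau, eta),
    # low/high drag forms are stated in physical variables; with omega = 1
    # they coincide with the rescaled ones (sigma = eta, t = tau)
    low_drag = msd_low_drag(gamma = zeta, sigma = eta, omega = 1, t = tau),
    high_drag = msd_high_drag(gamma = zeta, sigma = eta, omega = 1, t = tau))
  structure(data.frame(formula = formula, zeta = zeta, tau = tau, msd = vals),
            class = c("msd_curve", "data.frame"))
}
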