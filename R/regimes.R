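# Transition-time analysis: how long the movement stays superdiffusive and
# when it becomes effectively diffusive, plus regime classification and a
# local log-log slope estimator.

#' Principal branch of the Lambert W function
#'
#' Solves \eqn{w e^w = x} for \eqn{x \ge 0} by Halley iteration, run until
#' the iterate stops changing (machine precision). The achievable residual
#' \eqn{|w e^w - x|} is then of order \eqn{(1+w)\,x\,\epsilon}: below
#' \eqn{10^{-12}} in absolute terms for arguments up to a few hundred, and
#' always below \eqn{10^{-12}\,\max(1,x)} in relative terms.
#'
#' @param x argument (>= 0); vectorised.
#' @return \eqn{W_0(x)}.
#' @examples
#' w <- lambert_w0(4.4626)
#' w * exp(w) # 4.4626
#' @export
lambert_w0 <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x >= 0))
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    w <- if (xi > exp(1)) {
      l <- log(xi)
      l - log(l)
    } else {
      log1p(xi) * 0.665 * (1 + 0.0195 * log1p(xi))  # cheap seed, refined below
    }
    for (i in 1:80) {
      ew <- exp(w)
      f <- w * ew - xi
      w1 <- w + 1
      dw <- f / (ew * w1 - (w + 2) * f / (2 * w1))  # Halley step
      w <- w - dw
      if (abs(dw) <= 2 * .Machine$double.eps * abs(w)) break
    }
    w
  }, numeric(1))
}

#' Duration of the superdiffusive stage (exact)
#'
#' The superdiffusive stage lasts while the exact MSD still tracks its
#' zero-drag (drag-free) envelope. Its duration \eqn{\tau_{sd}} is defined
#' implicitly by the proximity ratio
#' \deqn{\langle x^2(\zeta, \tau_{sd})\rangle / \langle z^2(\tau_{sd})\rangle
#'   = \varepsilon_{sd},}
#' where \eqn{\varepsilon_{sd} \in (0,1)} is a confidence level (closer to 1
#' means a stricter notion of "still superdiffusive"). The ratio starts at 1
#' and decreases; the first crossing is located by geometric bracket
#' expansion followed by bisection to 1e-12 relative width.
#'
#' @param zeta dimensionless drag (> 0).
#' @param epsilon_sd confidence level in (0, 1), exclusive.
#' @return The crossing time \eqn{\tau_{sd}} (dimensionless).
#' @seealso [tau_sd_approx] for the small-\eqn{\zeta} closed form.
#' @export
tau_sd_exact <- function(zeta, epsilon_sd) {
  stopifnot(is.numeric(zeta), length(zeta) == 1L, zeta > 0,
            is.numeric(epsilon_sd), length(epsilon_sd) == 1L)
  if (epsilon_sd <= 0 || epsilon_sd >= 1)
    stop("'epsilon_sd' must lie strictly inside (0, 1)")
  ratio <- function(tau) msd_exact(zeta, tau) / msd_zero_drag(tau)
  lo <- 1e-6
  while (ratio(lo) <= epsilon_sd && lo > 1e-14) lo <- lo / 10
  hi <- lo
  limit <- 1e6 / zeta
  while (ratio(hi) > epsilon_sd) {
    hi <- hi * 2
    if (hi > limit)
      stop("proximity ratio never falls to epsilon_sd = ", epsilon_sd,
           " within tau <= 1e6/zeta")
  }
  .bisect_decreasing(ratio, epsilon_sd, max(lo, hi / 2), hi)
}

# bisection for f decreasing through the level `target` on [lo, hi]
.bisect_decreasing <- function(f, target, lo, hi) {
  if (f(lo) < target) lo <- lo * 1e-6  # safety; should not trigger
  while ((hi - lo) > 1e-12 * hi) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Duration of the superdiffusive stage (small-drag closed form)
#'
#' Leading-order expansion of the defining relation of [tau_sd_exact] for
#' small \eqn{\zeta} and \eqn{\tau}:
#' \deqn{\tau_{sd}(\zeta, \varepsilon_{sd}) \approx
#'   \frac{3(1 - \varepsilon_{sd})}{2\zeta}.}
#' The duration of superdiffusive movement is inversely proportional to the
#' drag: in low-friction environments (air, water at small Reynolds number)
#' the superdiffusive transient can dominate any realistic observation
#' window.
#'
#' @inheritParams tau_sd_exact
#' @return Approximate \eqn{\tau_{sd}}; `Inf` for `zeta = 0` (the drag-free
#'   process never leaves the superdiffusive stage).
#' @export
tau_sd_approx <- function(zeta, epsilon_sd) {
  stopifnot(is.numeric(zeta), all(zeta >= 0),
            all(epsilon_sd > 0), all(epsilon_sd < 1))
  ifelse(zeta == 0, Inf, 3 * (1 - epsilon_sd) / (2 * zeta))
}

#' Convergence time to the diffusive regime (exact)
#'
#' The movement is considered effectively diffusive once the exact MSD stays
#' within confidence \eqn{\varepsilon_d} of the linear asymptote
#' \eqn{\Delta_d^2}. Numerically the exact MSD approaches the asymptote from
#' above (the dropped exponential terms are positive at small and moderate
#' \eqn{\zeta}), so the proximity condition is applied to the magnitude of
#' the relative deviation:
#' \deqn{\left|\frac{\langle x^2(\zeta,\tau_d)\rangle}
#'   {\Delta_d^2(\zeta,\tau_d)} - 1\right| = 1 - \varepsilon_d,}
#' which is the same condition the Lambert W closed form [tau_d_approx]
#' solves at leading order in \eqn{\zeta}. The deviation blows up as
#' \eqn{\tau} approaches the zero of \eqn{\Delta_d^2} and decays to 0 at
#' large \eqn{\tau}; the first crossing is located by geometric bracket
#' expansion plus bisection to 1e-12 relative width, and the deviation is
#' verified to stay within the band on a diagnostic grid up to
#' \eqn{10\tau_d}.
#'
#' @param zeta dimensionless drag (> 0).
#' @param epsilon_d confidence level in (0, 1), exclusive.
#' @return The convergence time \eqn{\tau_d} (dimensionless).
#' @seealso [tau_d_approx] for the Lambert W closed form.
#' @export
tau_d_exact <- function(zeta, epsilon_d) {
  stopifnot(is.numeric(zeta), length(zeta) == 1L, zeta > 0,
            is.numeric(epsilon_d), length(epsilon_d) == 1L)
  if (epsilon_d <= 0 || epsilon_d >= 1)
    stop("'epsilon_d' must lie strictly inside (0, 1)")
  dev <- function(tau)
    abs(msd_exact(zeta, tau) / diffusive_asymptote(zeta, tau) - 1)
  band <- 1 - epsilon_d
  # smallest tau with a positive asymptote; deviation diverges there
  tau_pos <- (1 + 2 * (1 + zeta)^2) / (2 * zeta * (1 + zeta))
  tau_limit <- 1e9 * max(1, 1 / zeta)
  lo <- tau_pos * 1.0001
  if (dev(lo) <= band)
    return(lo)  # already within the band as soon as the asymptote is valid
  hi <- lo
  while (dev(hi) > band) {
    hi <- hi * 1.5
    if (hi > tau_limit)
      stop("deviation from the diffusive asymptote does not reach 1 - ",
           "epsilon_d within tau <= ", tau_limit,
           "; bracket expansion failed")
  }
  lo <- hi / 1.5
  while ((hi - lo) > 1e-12 * hi) {
    mid <- 0.5 * (lo + hi)
    if (dev(mid) > band) lo <- mid else hi <- mid
  }
  root <- 0.5 * (lo + hi)
  chk <- root * c(1.5, 2, 3, 5, 10)
  if (any(vapply(chk, dev, numeric(1)) > band))
    warning("deviation re-enters the band beyond tau_d; reported the first ",
            "crossing")
  root
}

#' Convergence time to the diffusive regime (Lambert W closed form)
#'
#' Small-\eqn{\zeta} leading-order solution of the defining relation of
#' [tau_d_exact]:
#' \deqn{\tau_d(\zeta,\varepsilon_d) \approx \frac{1}{\zeta}\left\{\frac32
#'   + W\!\left[\frac{2}{e^{3/2}(1-\varepsilon_d)}\right]\right\},}
#' with \eqn{W} the principal Lambert branch (see [lambert_w0]). Like
#' \eqn{\tau_{sd}}, the convergence time scales as \eqn{1/\zeta =
#' \omega/\gamma}: slower-dissipating environments keep the animal
#' superdiffusive for longer.
#'
#' @inheritParams tau_d_exact
#' @return Approximate \eqn{\tau_d}; `Inf` for `epsilon_d` at 1 is rejected
#'   (the relation is defined on the open interval).
#' @export
tau_d_approx <- function(zeta, epsilon_d) {
  stopifnot(is.numeric(zeta), all(zeta > 0),
            all(epsilon_d > 0), all(epsilon_d < 1))
  (1 / zeta) * (1.5 + lambert_w0(2 / (exp(1.5) * (1 - epsilon_d))))
}

#' Classify the effective small-time MSD exponent by drag intensity
#'
#' The effective small-time growth of the MSD depends on the relative drag
#' \eqn{\zeta = \gamma/\omega}: in the low-drag limit the dominant early
#' stage is \eqn{t^3} (Wiener-limit superdiffusion), at intermediate drag
#' the \eqn{t^4} superballistic stage dominates, and in the high-drag limit
#' the movement is effectively ballistic, \eqn{t^2} (velocity jump process).
#' The decade thresholds (0.1 and 10) are a reporting convention; for
#' quantitative work use [tau_sd_exact]/[tau_d_exact].
#'
#' @param zeta dimensionless drag (>= 0); vectorised.
#' @return Character vector with levels `"t^3 (low drag)"`,
#'   `"t^4 (intermediate)"`, `"t^2 (high drag)"`.
#' @export
classify_drag_regime <- function(zeta) {
  stopifnot(is.numeric(zeta), all(zeta >= 0))
  ifelse(zeta < 0.1, "t^3 (low drag)",
         ifelse(zeta <= 10, "t^4 (intermediate)", "t^2 (high drag)"))
}

#' Local log-log slope of an MSD curve
#'
#' Estimates the local exponent \eqn{\alpha(\tau) = d\ln \mathrm{MSD} /
#' d\ln\tau} — the quantity behind statements like "the spread grows as
#' \eqn{t^4}". For a callable, a centred finite difference with
#' multiplicative step \eqn{(1 \pm rel\_step)} is used; for a tabulated
#' curve (an [msd_curve] data frame, or anything with `tau` and `msd`
#' columns), a cubic spline through \eqn{(\ln\tau, \ln \mathrm{MSD})} is
#' differentiated.
#'
#' @param curve a function of `tau`, or a data frame with columns `tau`
#'   and `msd`.
#' @param tau dimensionless time(s) (> 0) at which to estimate the slope.
#' @param rel_step relative half-width of the finite-difference stencil.
#' @return Slope estimate(s).
#' @examples
#' loglog_slope(function(tau) msd_small_time(tau), tau = 0.01) # 4
#' @export
loglog_slope <- function(curve, tau, rel_step = 1e-3) {
  stopifnot(is.numeric(tau), all(tau > 0), rel_step > 0, rel_step < 1)
  if (is.function(curve)) {
    m_lo <- curve(tau * (1 - rel_step))
    m_hi <- curve(tau * (1 + rel_step))
    if (any(!is.finite(m_lo)) || any(!is.finite(m_hi)) ||
        any(m_lo <= 0) || any(m_hi <= 0))
      stop("undefined slope: curve is not positive on the stencil around tau")
    (log(m_hi) - log(m_lo)) / (log1p(rel_step) - log1p(-rel_step))
  } else if (is.data.frame(curve) && all(c("tau", "msd") %in% names(curve))) {
    ok <- curve$tau > 0 & curve$msd > 0
    if (sum(ok) < 4)
      stop("tabulated curve needs at least 4 positive (tau, msd) points")
    sf <- splinefun(log(curve$tau[ok]), log(curve$msd[ok]), method = "natural")
    sf(log(tau), deriv = 1)
  } else {
    stop("'curve' must be a function of tau or a data frame with columns ",
         "'tau' and 'msd'")
  }
}

#' Regime report for one drag setting
#'
#' Summarises the movement regimes at dimensionless drag `zeta`: the
#' effective small-time exponent, the superdiffusive-stage duration
#' \eqn{\tau_{sd}} (exact and closed form), the diffusive convergence time
#' \eqn{\tau_d} (exact and closed form), and the rescaled diffusion
#' coefficient \eqn{\eta^2/\zeta^2}.
#'
#' @param zeta dimensionless drag (> 0).
#' @param epsilon_sd confidence level for superdiffusive proximity.
#' @param epsilon_d confidence level for diffusive proximity.
#' @param eta dimensionless length scale.
#' @return An object of class `"regime_report"`: list with fields `zeta`,
#'   `epsilon_sd`, `epsilon_d`, `tau_sd_exact`, `tau_sd_approx`,
#'   `tau_d_exact`, `tau_d_approx`, `small_time_regime`,
#'   `diffusion_coefficient`.
#' @examples
#' regime_report(zeta = 0.01, epsilon_sd = 0.9, epsilon_d = 0.9)
#' @export
regime_report <- function(zeta, epsilon_sd = 0.99, epsilon_d = 0.99, eta = 1) {
  structure(list(
    zeta = zeta,
    epsilon_sd = epsilon_sd,
    epsilon_d = epsilon_d,
    tau_sd_exact = tau_sd_exact(zeta, epsilon_sd),
    tau_sd_approx = tau_sd_approx(zeta, epsilon_sd),
    tau_d_exact = tau_d_exact(zeta, epsilon_d),
    tau_d_approx = tau_d_approx(zeta, epsilon_d),
    small_time_regime = classify_drag_regime(zeta),
    diffusion_coefficient = eta^2 / zeta^2
  ), class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("Movement regime report (zeta = %g)\n", x$zeta))
  cat(sprintf("  small-time regime:        %s\n", x$small_time_regime))
  cat(sprintf("  tau_sd (eps = %g):  exact %.6g, approx %.6g\n",
              x$epsilon_sd, x$tau_sd_exact, x$tau_sd_approx))
  cat(sprintf("  tau_d  (eps = %g):  exact %.6g, approx %.6g\n",
              x$epsilon_d, x$tau_d_exact, x$tau_d_approx))
  cat(sprintf("  diffusion coefficient (rescaled): %g\n",
              x$diffusion_coefficient))
  invisible(x)
}
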