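# Monte Carlo ensemble estimators built on the exact-in-bout trajectory
# engine (compiled): MSD with standard errors, dispersal-kernel histograms,
# and the time-average autocovariance of the forcing.

#' Monte Carlo estimate of the MSD
#'
#' Simulates `n` independent trajectories started at rest and estimates the
#' MSD at each sample time as the ensemble mean of \eqn{x^2}, with the
#' standard error of that mean. Because the within-bout solution is exact,
#' the only error is statistical. With the cue rate and acceleration
#' variance of `params`, sample times are physical times; divide by
#' \eqn{\omega} to convert a grid of dimensionless \eqn{\tau} values.
#'
#' @param params a [model_params] object.
#' @param sample_times non-decreasing, non-negative times.
#' @param n number of trajectories (>= 2).
#' @param seed optional integer seed (defaults to `params$seed`). The whole
#'   ensemble is drawn from one seeded stream, so a given
#'   `(seed, sample_times, n)` triple is bit-reproducible.
#' @return An object of class `"ensemble_msd"`: a data frame with columns
#'   `tau` (the sample times rescaled by \eqn{\omega}), `t`, `msd_hat`,
#'   `se`, `n`.
#' @examples
#' p <- model_params(nu_a2 = 1, omega = 1, gamma = 1)
#' em <- ensemble_msd(p, sample_times = c(0.1, 1, 10), n = 2000, seed = 1)
#' cbind(em$tau, em$msd_hat, msd_exact(1, em$tau))
#' @export
ensemble_msd <- function(params, sample_times, n, seed = NULL) {
  params <- .validate_params(params)
  stopifnot(is.numeric(sample_times), all(sample_times >= 0),
            !is.unsorted(sample_times), is.numeric(n), n >= 2)
  n <- as.integer(n)
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  sums <- .sim_msd_sums(n, as.numeric(sample_times), params$gamma,
                        params$omega, sqrt(params$nu_a2),
                        .accel_family_code(params$accel_dist))
  msd_hat <- sums$sum_x2 / n
  # sd of x^2 across trajectories -> standard error of the mean
  var_x2 <- pmax(0, (sums$sum_x4 - n * msd_hat^2) / (n - 1))
  structure(data.frame(tau = params$omega * sample_times,
                       t = sample_times,
                       msd_hat = msd_hat,
                       se = sqrt(var_x2 / n),
                       n = n),
            class = c("ensemble_msd", "data.frame"))
}

#' Positions of an ensemble of trajectories
#'
#' Raw positions of `n` independent trajectories at the given sample times,
#' as an `n x length(sample_times)` matrix. This is the workhorse behind
#' [ensemble_pdf] and is exported for custom ensemble statistics (e.g.
#' building 2D displacements from two independent coordinates).
#'
#' @inheritParams ensemble_msd
#' @return Numeric matrix, one row per trajectory.
#' @export
ensemble_positions <- function(params, sample_times, n, seed = NULL) {
  params <- .validate_params(params)
  stopifnot(is.numeric(sample_times), all(sample_times >= 0),
            !is.unsorted(sample_times), is.numeric(n), n >= 1)
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  .sim_positions_matrix(as.integer(n), as.numeric(sample_times),
                        params$gamma, params$omega, sqrt(params$nu_a2),
                        .accel_family_code(params$accel_dist))
}

#' Monte Carlo dispersal kernel (renormalized histogram)
#'
#' Estimates the dispersal kernel \eqn{\rho(x, \tau)} — the probability
#' density of displacement after dimensionless time \eqn{\tau} — from `n`
#' trajectories, on a fixed symmetric grid of bins centred at 0, and also
#' returns the renormalized form \eqn{\tilde\rho(x) = \rho(x)/\rho(0)}
#' commonly used to compare kernel shapes across times. At early times the
#' kernel has exponential tails; at large times it converges to the Gaussian
#' of [gaussian_kernel].
#'
#' @param params a [model_params] object.
#' @param tau dimensionless time at which to sample displacements.
#' @param n number of trajectories (>= 1000).
#' @param n_bins number of bins (forced odd so one bin is centred at 0).
#' @param seed optional integer seed.
#' @param half_width half-extent of the binned range; default
#'   \eqn{6\sqrt{\Delta_d^2}} when the large-time variance is positive, else
#'   6 sample standard deviations.
#' @return An object of class `"renormalized_pdf"`: list with `tau`,
#'   `bin_centers`, `density`, `density_renorm`, `counts`, `n`, and the
#'   untouched `positions` vector.
#' @export
ensemble_pdf <- function(params, tau, n, n_bins = 101, seed = NULL,
                         half_width = NULL) {
  params <- .validate_params(params)
  stopifnot(length(tau) == 1L, tau > 0, n >= 1000, n_bins >= 5)
  n_bins <- as.integer(n_bins)
  if (n_bins %% 2L == 0L) n_bins <- n_bins + 1L
  x <- drop(ensemble_positions(params, tau / params$omega, n, seed))
  if (is.null(half_width)) {
    rp <- rescale_parameters(params)
    v <- if (rp$zeta > 0) diffusive_asymptote(rp$zeta, tau, rp$eta) else -1
    half_width <- 6 * sqrt(if (v > 0) v else stats::var(x))
  }
  breaks <- seq(-half_width, half_width, length.out = n_bins + 1L)
  xc <- pmin(pmax(x, -half_width), half_width)  # clamp rare outliers
  counts <- tabulate(findInterval(xc, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  width <- diff(breaks[1:2])
  density <- counts / (n * width)
  central <- (n_bins + 1L) %/% 2L
  if (counts[central] < 10)
    warning("fewer than 10 samples in the central bin; ",
            "renormalized density is unreliable")
  structure(list(tau = tau,
                 bin_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = density,
                 density_renorm = density / density[central],
                 counts = counts,
                 n = n,
                 positions = x),
            class = "renormalized_pdf")
}

#' @export
print.renormalized_pdf <- function(x, ...) {
  cat(sprintf("Dispersal kernel estimate at tau = %g (n = %d, %d bins)\n",
              x$tau, x$n, length(x$bin_centers)))
  cat(sprintf("  sample sd: %.4g; density integrates to %.4f\n",
              sd(x$positions), sum(x$density) * diff(x$bin_centers[1:2])))
  invisible(x)
}

#' Empirical autocovariance of the bout forcing
#'
#' Estimates \eqn{\langle a(t)a(t+\Delta)\rangle} by time-averaging one long
#' realization of the piecewise-constant forcing, for comparison with the
#' theoretical \eqn{\nu_a^2 e^{-\omega \Delta}} of
#' [acceleration_autocovariance]. Standard errors come from averaging over
#' contiguous blocks much longer than the correlation time \eqn{1/\omega}.
#'
#' @param params a [model_params] object.
#' @param lags non-negative lags (physical time units).
#' @param total_time length of the realization; must be much larger than
#'   `max(lags)` (at least 100 correlation times are recommended).
#' @param seed optional integer seed.
#' @param dt sampling interval of the realization; default `0.1/omega`.
#' @param n_blocks number of blocks for the standard error.
#' @return Data frame with columns `lag`, `autocov`, `se`, `theory`.
#' @export
empirical_acc_autocov <- function(params, lags, total_time, seed = NULL,
                                  dt = 0.1 / params$omega, n_blocks = 100) {
  params <- .validate_params(params)
  stopifnot(is.numeric(lags), all(lags >= 0), total_time > 0,
            total_time > 20 * max(lags, 1 / params$omega))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)

  # bout change-points covering [0, total_time]
  n_guess <- ceiling(total_time * params$omega * 1.2 + 50)
  durs <- rexp(n_guess, params$omega)
  while (sum(durs) < total_time) durs <- c(durs, rexp(n_guess, params$omega))
  ends <- cumsum(durs)
  k <- which(ends >= total_time)[1]
  durs <- durs[seq_len(k)]
  accs <- sample_accelerations(k, params$nu_a2, params$accel_dist)

  tgrid <- seq(0, total_time, by = dt)
  a_t <- accs[findInterval(tgrid, c(0, cumsum(durs)), left.open = TRUE,
                           rightmost.closed = TRUE)]
  N <- length(a_t)
  out <- lapply(lags, function(L) {
    l <- as.integer(round(L / dt))
    if (l >= N) stop("lag exceeds the realization length")
    prod <- a_t[seq_len(N - l)] * a_t[seq_len(N - l) + l]
    blocks <- split(prod, cut(seq_along(prod), n_blocks, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    data.frame(lag = l * dt, autocov = mean(prod),
               se = sd(bm) / sqrt(length(bm)))
  })
  res <- do.call(rbind, out)
  res$theory <- acceleration_autocovariance(params, res$lag)
  res
}
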