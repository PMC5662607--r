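# Exact-in-bout simulation of a single trajectory. Within a bout the
# acceleration is constant, so velocity and position obey closed forms and
# the simulator carries no time-discretisation error: the only randomness is
# in the bout durations and the per-bout accelerations.

#' Create a motion state
#'
#' The state of the focal animal inside the bout process: elapsed time,
#' position, velocity, the acceleration of the active bout and the absolute
#' time at which that bout ends. The canonical initial condition is at rest
#' (`y = v = 0`).
#'
#' @param t elapsed time (>= 0).
#' @param y position.
#' @param v velocity.
#' @param a_current acceleration of the active bout.
#' @param bout_end absolute end time of the active bout (>= `t`).
#' @param bout_index number of completed bouts.
#' @return An object of class `"motion_state"`.
#' @export
motion_state <- function(t = 0, y = 0, v = 0, a_current = 0,
                         bout_end = Inf, bout_index = 0L) {
  stopifnot(t >= 0, bout_end >= t, bout_index >= 0)
  structure(list(t = t, y = y, v = v, a_current = a_current,
                 bout_end = bout_end, bout_index = as.integer(bout_index)),
            class = "motion_state")
}

# closed-form within-bout update of (y, v) under constant acceleration a and
# drag gamma over a step dt; gamma = 0 handled by the drag-free limit
.advance_yv <- function(y, v, a, gamma, dt) {
  if (dt == 0) return(c(y = y, v = v))
  if (gamma < 1e-12) {
    return(c(y = y + v * dt + 0.5 * a * dt^2, v = v + a * dt))
  }
  g <- gamma * dt
  em1 <- -expm1(-g)                       # 1 - e^{-gamma dt}
  c(y = y + (v / gamma) * em1 + (a / gamma^2) * .f2(g),
    v = v * (1 - em1) + (a / gamma) * em1)
}

#' Advance the state within the active bout
#'
#' Moves the state forward by `dt` using the exact within-bout solution of
#' \eqn{\ddot y = -\gamma\dot y + a}:
#' \deqn{v(t+dt) = v e^{-\gamma dt} + \frac{a}{\gamma}(1 - e^{-\gamma dt}),}
#' \deqn{y(t+dt) = y + \frac{v}{\gamma}(1 - e^{-\gamma dt})
#'   + \frac{a}{\gamma^2}(\gamma dt + e^{-\gamma dt} - 1).}
#' The update is an exact flow map, so advancing by `dt1` then `dt2` equals
#' advancing by `dt1 + dt2` (to round-off). For \eqn{\gamma = 0} the
#' drag-free forms \eqn{v + a\,dt}, \eqn{y + v\,dt + a\,dt^2/2} are used.
#' The terms \eqn{1 - e^{-\gamma dt}} and \eqn{\gamma dt + e^{-\gamma dt}-1}
#' are evaluated via `expm1`/series to avoid cancellation at small
#' \eqn{\gamma dt}.
#'
#' @param state a [motion_state].
#' @param dt step length; must not overrun the active bout
#'   (`state$t + dt <= state$bout_end`).
#' @param gamma per-mass drag (>= 0).
#' @return The advanced [motion_state] (same bout; `bout_index` unchanged).
#' @export
advance_within_bout <- function(state, dt, gamma) {
  stopifnot(inherits(state, "motion_state"), is.numeric(dt), dt >= 0,
            is.numeric(gamma), gamma >= 0)
  if (state$t + dt > state$bout_end * (1 + 1e-12))
    stop("step overruns the active bout: t + dt = ", state$t + dt,
         " > bout_end = ", state$bout_end)
  yv <- .advance_yv(state$y, state$v, state$a_current, gamma, dt)
  motion_state(t = state$t + dt, y = yv[["y"]], v = yv[["v"]],
               a_current = state$a_current, bout_end = state$bout_end,
               bout_index = state$bout_index)
}

#' Simulate one trajectory of the bout process
#'
#' Simulates a single animal started at rest and returns its positions at
#' the requested times. Bout durations are exponential with rate
#' \eqn{\omega}; the acceleration of each bout is an independent draw from
#' the configured family. Within each bout the exact closed-form solution is
#' used, so there is no time-stepping error. A sample time falling inside a
#' bout does not terminate the bout: the observation merely reads the state,
#' and the bout continues with its residual duration.
#'
#' @param params a [model_params] object.
#' @param sample_times non-decreasing, non-negative times at which to record
#'   the position.
#' @param seed optional integer seed (defaults to `params$seed`).
#' @param keep_bouts if `TRUE`, attach the realised per-bout accelerations
#'   and (untruncated) durations of every bout started, as attributes
#'   `"bout_accelerations"` and `"bout_durations"`, so the trajectory can be
#'   re-derived independently with [positions_closed_form].
#' @return Numeric vector of positions at `sample_times`.
#' @export
simulate_positions <- function(params, sample_times, seed = NULL,
                               keep_bouts = FALSE) {
  params <- .validate_params(params)
  stopifnot(is.numeric(sample_times), all(sample_times >= 0),
            !is.unsorted(sample_times))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  if (length(sample_times) == 0) return(numeric(0))

  gamma <- params$gamma
  t <- 0; y <- 0; v <- 0
  a <- sample_accelerations(1, params$nu_a2, params$accel_dist)
  dur <- rexp(1, params$omega)
  bout_end <- dur
  accs <- a; durs <- dur
  out <- numeric(length(sample_times))

  for (j in seq_along(sample_times)) {
    s <- sample_times[j]
    while (bout_end < s) {
      yv <- .advance_yv(y, v, a, gamma, bout_end - t)
      y <- yv[["y"]]; v <- yv[["v"]]
      t <- bout_end
      a <- sample_accelerations(1, params$nu_a2, params$accel_dist)
      dur <- rexp(1, params$omega)
      bout_end <- bout_end + dur
      if (keep_bouts) { accs <- c(accs, a); durs <- c(durs, dur) }
    }
    yv <- .advance_yv(y, v, a, gamma, s - t)
    y <- yv[["y"]]; v <- yv[["v"]]; t <- s
    out[j] <- y
  }
  if (keep_bouts) {
    attr(out, "bout_accelerations") <- accs
    attr(out, "bout_durations") <- durs
  }
  out
}

#' Positions from a predetermined bout sequence (closed-form sum)
#'
#' Evaluates the explicit solution of the within-bout recurrence for a
#' *given* sequence of bout accelerations and durations:
#' \deqn{y_k = \sum_{n=1}^{k} \frac{a_n}{\gamma^2}\left[\gamma t_n +
#'   (e^{-\gamma t_n} - 1)\, e^{-\gamma \sum_{j>n} t_j}\right],}
#' where the active (last) bout is truncated at the query time, i.e.
#' \eqn{t_k = t - \sum_{n<k} t_n}. This is the independent closed-form route
#' to the same positions that the sequential simulator produces, and the
#' deterministic backbone for test fixtures.
#'
#' @param accelerations per-bout accelerations \eqn{a_1, \dots, a_k}.
#' @param durations per-bout durations \eqn{t_1, \dots, t_k} (> 0); the
#'   sequence must cover each query time.
#' @param gamma per-mass drag (>= 0).
#' @param t_query times at which to evaluate the position.
#' @return Positions at `t_query`.
#' @seealso [simulate_positions]
#' @export
positions_closed_form <- function(accelerations, durations, gamma, t_query) {
  stopifnot(length(accelerations) == length(durations), all(durations > 0),
            gamma >= 0, all(t_query >= 0))
  ends <- cumsum(durations)
  if (length(t_query) == 0) return(numeric(0))
  if (max(t_query) > ends[length(ends)] * (1 + 1e-12))
    stop("bout sequence too short for the largest query time")
  vapply(t_query, function(tq) {
    if (tq == 0) return(0)
    k <- findInterval(tq, ends, left.open = TRUE) + 1L  # active bout index
    k <- min(k, length(durations))
    tn <- durations[seq_len(k)]
    tn[k] <- tq - if (k > 1) ends[k - 1] else 0          # truncate last bout
    an <- accelerations[seq_len(k)]
    if (gamma < 1e-12) return(.positions_dragfree(an, tn))
    # durations elapsing *after* each bout (zero for the active one)
    suffix <- rev(cumsum(rev(c(tn[-1], 0))))
    sum((an / gamma^2) *
          (gamma * tn + expm1(-gamma * tn) * exp(-gamma * suffix)))
  }, numeric(1))
}

# drag-free closed form: repeated integration of constant accelerations
.positions_dragfree <- function(an, tn) {
  y <- 0; v <- 0
  for (i in seq_along(an)) {
    y <- y + v * tn[i] + 0.5 * an[i] * tn[i]^2
    v <- v + an[i] * tn[i]
  }
  y
}
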