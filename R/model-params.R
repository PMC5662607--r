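#' Physical and stochastic parameters of the bout movement process
#'
#' Bundles the parameters of the random-acceleration movement model: the
#' variance \eqn{\nu_a^2} of the per-bout acceleration (force per unit mass),
#' the cue rate \eqn{\omega} (bout durations are exponential with mean
#' \eqn{1/\omega}), and the per-mass drag \eqn{\gamma}. The drag may instead
#' be given through body mass \eqn{m} and whole-body drag coefficient
#' \eqn{c}, in which case \eqn{\gamma = c/m}.
#'
#' @param nu_a2 acceleration variance \eqn{\nu_a^2} (length^2 time^-4); > 0.
#' @param omega cue rate \eqn{\omega} (time^-1); > 0.
#' @param gamma per-mass drag \eqn{\gamma} (time^-1); >= 0. May be omitted
#'   when `mass` and `drag_coeff` are both supplied.
#' @param accel_dist acceleration distribution family, one of `"gaussian"`,
#'   `"uniform"` (on \eqn{[-\sqrt3\nu_a, \sqrt3\nu_a]}) or `"two_point"`
#'   (\eqn{\pm\nu_a} with equal probability). All three have mean zero and
#'   variance `nu_a2`; the MSD of the process depends on the family only
#'   through `nu_a2`.
#' @param mass optional body mass \eqn{m} (mass units); > 0.
#' @param drag_coeff optional whole-body drag coefficient \eqn{c}
#'   (mass time^-1); >= 0.
#' @param seed optional integer seed carried with the parameter set and used
#'   as the default by the stochastic operations.
#'
#' @return An object of class `"model_params"`: a list with elements
#'   `nu_a2`, `omega`, `gamma`, `accel_dist`, `mass`, `drag_coeff`, `seed`.
#'
#' @examples
#' p <- model_params(nu_a2 = 1, omega = 1, gamma = 1)
#' rescale_parameters(p, t = 1)
#' diffusion_coefficient(p)
#'
#' # gamma derived from mass and drag coefficient
#' model_params(nu_a2 = 0.5, omega = 2, mass = 0.01, drag_coeff = 0.002)
#' @export
model_params <- function(nu_a2, omega, gamma = NULL,
                         accel_dist = c("gaussian", "uniform", "two_point"),
                         mass = NULL, drag_coeff = NULL, seed = NULL) {
  accel_dist <- match.arg(accel_dist)
  stopifnot(is.numeric(nu_a2), length(nu_a2) == 1L, is.finite(nu_a2),
            is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (nu_a2 <= 0) stop("'nu_a2' must be > 0 (zero-mean, finite positive variance forcing)")
  if (omega <= 0) stop("'omega' must be > 0 (cue rate of the bout process)")
  has_mc <- !is.null(mass) && !is.null(drag_coeff)
  if (has_mc) {
    stopifnot(is.numeric(mass), mass > 0, is.numeric(drag_coeff), drag_coeff >= 0)
    gamma_mc <- drag_coeff / mass
    if (is.null(gamma)) {
      gamma <- gamma_mc
    } else if (abs(gamma - gamma_mc) > 1e-12 * max(abs(gamma), abs(gamma_mc), 1e-300)) {
      stop("inconsistent drag: 'gamma' must equal drag_coeff/mass ",
           "(got ", gamma, " vs ", gamma_mc, ")")
    }
  }
  if (is.null(gamma)) stop("supply 'gamma', or both 'mass' and 'drag_coeff'")
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma < 0) stop("'gamma' must be >= 0 (drag opposes the motion)")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
  }
  structure(list(nu_a2 = nu_a2, omega = omega, gamma = gamma,
                 accel_dist = accel_dist,
                 mass = if (is.null(mass)) NULL else as.numeric(mass),
                 drag_coeff = if (is.null(drag_coeff)) NULL else as.numeric(drag_coeff),
                 seed = seed),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bout movement model parameters\n")
  cat(sprintf("  nu_a2 (acceleration variance): %g\n", x$nu_a2))
  cat(sprintf("  omega (cue rate):              %g\n", x$omega))
  cat(sprintf("  gamma (per-mass drag):         %g\n", x$gamma))
  cat(sprintf("  acceleration distribution:     %s\n", x$accel_dist))
  if (!is.null(x$mass))
    cat(sprintf("  mass: %g, drag_coeff: %g (gamma = drag_coeff/mass)\n",
                x$mass, x$drag_coeff))
  rp <- rescale_parameters(x)
  cat(sprintf("  dimensionless: eta = %g, zeta = %g (%s)\n",
              rp$eta, rp$zeta, classify_drag_regime(rp$zeta)))
  invisible(x)
}

.validate_params <- function(params) {
  if (!inherits(params, "model_params"))
    stop("'params' must be a 'model_params' object; see ?model_params")
  params
}

#' Dimensionless rescaling of the model parameters
#'
#' Reduces the parameter space to the dimensionless drag ratio
#' \eqn{\zeta = \gamma/\omega}, the length scale \eqn{\eta = \sigma/\omega^2}
#' (with \eqn{\sigma = \sqrt{\nu_a^2}} for any distribution family), and the
#' rescaled time \eqn{\tau = \omega t}. All analytic MSD functions in this
#' package are expressed in these variables.
#'
#' @param params a [model_params] object.
#' @param t physical time (>= 0) to rescale; default 0.
#' @return An object of class `"rescaled_params"`: list with `eta`, `zeta`,
#'   `tau` and the originating `omega` (kept so the scaling can be undone).
#' @seealso [unrescale_parameters] for the inverse map.
#' @examples
#' rescale_parameters(model_params(4, omega = 2, gamma = 1), t = 3)
#' @export
rescale_parameters <- function(params, t = 0) {
  params <- .validate_params(params)
  stopifnot(is.numeric(t), all(t >= 0))
  sigma <- sqrt(params$nu_a2)
  structure(list(eta = sigma / params$omega^2,
                 zeta = params$gamma / params$omega,
                 tau = params$omega * t,
                 omega = params$omega),
            class = "rescaled_params")
}

#' Undo the dimensionless rescaling
#'
#' Recovers the physical parameters \eqn{(\sigma, \omega, \gamma)} and time
#' `t` from `(eta, zeta, tau)` given the cue rate `omega`.
#'
#' @param rescaled a `"rescaled_params"` object, or a list with `eta`,
#'   `zeta`, `tau`.
#' @param omega cue rate; defaults to the one stored in `rescaled`.
#' @return list with `sigma`, `nu_a2`, `omega`, `gamma`, `t`.
#' @export
unrescale_parameters <- function(rescaled, omega = rescaled$omega) {
  stopifnot(is.numeric(omega), omega > 0,
            rescaled$eta > 0, rescaled$zeta >= 0, rescaled$tau >= 0)
  sigma <- rescaled$eta * omega^2
  list(sigma = sigma, nu_a2 = sigma^2, omega = omega,
       gamma = rescaled$zeta * omega, t = rescaled$tau / omega)
}

#' @export
print.rescaled_params <- function(x, ...) {
  cat(sprintf("Dimensionless parameters: eta = %g, zeta = %g, tau = %g\n",
              x$eta, x$zeta, x$tau))
  invisible(x)
}

#' Asymptotic diffusion coefficient
#'
#' In the large-time limit the process becomes an ordinary diffusion with
#' \deqn{D = \nu_a^2 / (\gamma^2 \omega),}
#' equivalently \eqn{D = m^2 \nu_a^2/(c^2\omega)} when the drag is expressed
#' through body mass and drag coefficient. A drag-free process
#' (\eqn{\gamma = 0}) never becomes diffusive and is rejected.
#'
#' @param params a [model_params] object with `gamma > 0`.
#' @return The diffusion coefficient (length^2 time^-1).
#' @examples
#' diffusion_coefficient(model_params(4, omega = 1, gamma = 2)) # = 1
#' @export
diffusion_coefficient <- function(params) {
  params <- .validate_params(params)
  if (params$gamma <= 0)
    stop("no asymptotic diffusion: the zero-drag process stays superdiffusive ",
         "(MSD ~ t^3) and never converges to a linear-in-time MSD")
  params$nu_a2 / (params$gamma^2 * params$omega)
}

#' Theoretical autocovariance of the bout forcing
#'
#' The piecewise-constant forcing of the bout process is exponentially
#' correlated: \eqn{\langle a(t)a(t+\Delta)\rangle = \nu_a^2 e^{-\omega\Delta}}.
#' This is what makes the process a Langevin equation with non-Wiener
#' (coloured, discontinuous) forcing.
#'
#' @param params a [model_params] object.
#' @param lag non-negative time lag(s). The process is stationary; pass
#'   `abs(lag)` for negative lags.
#' @return \eqn{\nu_a^2 \exp(-\omega\,lag)}, vectorised over `lag`.
#' @seealso [empirical_acc_autocov] for the simulation-based estimate.
#' @export
acceleration_autocovariance <- function(params, lag) {
  params <- .validate_params(params)
  stopifnot(is.numeric(lag))
  if (any(lag < 0))
    stop("'lag' must be >= 0: the forcing is stationary, pass abs(lag)")
  params$nu_a2 * exp(-params$omega * lag)
}

#' Matched Wiener-forcing variance of the low-drag limit
#'
#' In the low-drag limit (\eqn{\zeta \ll 1}) the process reduces to the
#' standard Langevin equation driven by a Wiener process whose forcing
#' variance is \eqn{q^2 = 2\sigma^2/\omega} (with
#' \eqn{\sigma^2 = \nu_a^2}).
#'
#' @param params a [model_params] object.
#' @return The matched forcing variance \eqn{q^2}.
#' @export
wiener_limit_variance <- function(params) {
  params <- .validate_params(params)
  2 * params$nu_a2 / params$omega
}

# ---- JSON serialisation ----

.params_json_keys <- c("nu_a2", "omega", "gamma", "accel_dist", "mass",
                       "drag_coeff", "seed")

#' Serialise model parameters to and from JSON
#'
#' The JSON object uses exactly the keys `nu_a2`, `omega`, `gamma`,
#' `accel_dist`, `mass`, `drag_coeff`, `seed`; unknown keys are rejected so
#' that typos in configuration files fail loudly.
#'
#' @param params a [model_params] object.
#' @param json a JSON string, file path, or a list already parsed from JSON.
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a [model_params] object.
#' @examples
#' s <- params_to_json(model_params(1, 1, 1))
#' params_from_json(s)
#' @export
params_to_json <- function(params) {
  params <- .validate_params(params)
  x <- params[!vapply(params, is.null, logical(1))]
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  x <- if (is.list(json)) json else jsonlite::fromJSON(json)
  unknown <- setdiff(names(x), .params_json_keys)
  if (length(unknown))
    stop("unknown model parameter key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.params_json_keys, collapse = ", "), ")")
  if (is.null(x$nu_a2) || is.null(x$omega))
    stop("model parameter JSON must provide at least 'nu_a2' and 'omega'")
  model_params(nu_a2 = x$nu_a2, omega = x$omega, gamma = x$gamma,
               accel_dist = if (is.null(x$accel_dist)) "gaussian" else x$accel_dist,
               mass = x$mass, drag_coeff = x$drag_coeff, seed = x$seed)
}
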