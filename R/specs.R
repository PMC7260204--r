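#' Bead specification
#'
#' Describes a superparamagnetic microbead: its radius, effective
#' susceptibility, mass density and dry-friction coefficient.  The
#' susceptibility is an effective scaling constant relating the bead's
#' dipole moment to the applied field, `m = chi * H_ext * (4/3) pi r^3`;
#' it absorbs the bead volume convention (see [bead_moment()]).
#'
#' @param radius bead radius \eqn{r_{mb}} in metres (> 0).
#' @param chi effective dimensionless susceptibility (>= 0).
#' @param density bead density in kg/m^3; defaults to 1050 (polystyrene).
#' @param friction dimensionless dry-friction coefficient \eqn{F_c}
#'   (>= 0); friction acts only at ground contact.
#' @return an object of class `bead_spec`.
#' @examples
#' bead_spec(radius = 4e-6, chi = 0.0256, friction = 0.03)
#' @export
bead_spec <- function(radius, chi, density = 1050, friction = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1, is.finite(radius))
  if (radius <= 0) stop("bead 'radius' must be > 0")
  if (chi < 0) stop("bead 'chi' must be >= 0")
  if (density <= 0) stop("bead 'density' must be > 0")
  if (friction < 0) stop("bead 'friction' must be >= 0")
  structure(list(r_mb = radius, chi = chi, rho_mb = density, Fc = friction),
            class = "bead_spec")
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf("<bead_spec> r = %.3g um, chi = %g, rho = %g kg/m^3, Fc = %g\n",
              x$r_mb * 1e6, x$chi, x$rho_mb, x$Fc))
  invisible(x)
}

# bead volume [m^3]
bead_volume <- function(bead) (4 / 3) * pi * bead$r_mb^3

#' Fluid environment specification
#'
#' Water temperature, viscosity (computed from temperature via
#' [viscosity_water()] unless overridden), water density and gravitational
#' acceleration.
#'
#' @param temperature water temperature in degrees Celsius (0-100).
#' @param eta dynamic viscosity in Pa s; when `NULL` (default) it is
#'   computed from `temperature`.
#' @param rho_water water density in kg/m^3.
#' @param g gravitational acceleration in m/s^2.
#' @return an object of class `environment_spec`.
#' @examples
#' environment_spec(temperature = 22)
#' @export
environment_spec <- function(temperature = 22, eta = NULL, rho_water = 997.8,
                             g = 9.81) {
  if (is.null(eta)) {
    eta <- viscosity_water(temperature)
  } else {
    stopifnot(is.numeric(eta), length(eta) == 1)
    if (eta <= 0) stop("'eta' must be > 0")
  }
  structure(list(temperature = temperature, eta = eta,
                 rho_water = rho_water, g = g),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf("<environment_spec> T = %g C, eta = %.4g Pa s, rho = %g kg/m^3\n",
              x$temperature, x$eta, x$rho_water))
  invisible(x)
}

#' External magnetic field sequence
#'
#' A periodic external field \eqn{H_{ext}(t)}, either a rotating in-plane
#' field of constant amplitude or a discrete switching sequence of field
#' states.  Amplitudes are given as flux densities \eqn{\mu_0 H} in tesla and
#' stored both as tesla and A/m.  The sampled states carry the times at which
#' the potential landscape is evaluated before Fourier fitting.
#'
#' For rotating mode, state `j` (of `n_states`) is at angle
#' `start_angle + sense * 360 * (j-1) / n_states` degrees (0 deg along +x,
#' `sense = +1` counterclockwise, `-1` clockwise) and time `(j-1) / (n_states * f)`.
#' For switching mode the given states occupy equal fractions of the period
#' in order.
#'
#' @param mode `"rotating"` or `"switching"`.
#' @param amplitude field amplitude \eqn{\mu_0 H} in tesla (rotating mode).
#' @param frequency field frequency in Hz (> 0).
#' @param n_states number of sampled field states per period (rotating mode).
#' @param start_angle starting field angle in degrees (rotating mode).
#' @param sense rotation sense, `+1` counterclockwise, `-1` clockwise.
#' @param states list of per-state \eqn{\mu_0 H} 3-vectors in tesla
#'   (switching mode).
#' @return an object of class `field_sequence` with elements `mode`,
#'   `frequency`, `omega`, `times`, `B` (list of tesla 3-vectors),
#'   `H` (list of A/m 3-vectors) and, for rotating mode, `angles` (degrees).
#' @examples
#' field_sequence("rotating", amplitude = 20e-3, frequency = 0.9, n_states = 72)
#' field_sequence("switching", frequency = 3,
#'                states = list(c(0, 0, -2.5e-3), c(0, 5e-3, -2.5e-3),
#'                              c(0, 5e-3, 2.5e-3), c(0, 0, 2.5e-3)))
#' @export
field_sequence <- function(mode = c("rotating", "switching"), amplitude = NULL,
                           frequency, n_states = 72, start_angle = 0,
                           sense = 1, states = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(frequency), length(frequency) == 1)
  if (frequency <= 0) stop("'frequency' must be > 0")
  period <- 1 / frequency
  if (mode == "rotating") {
    if (is.null(amplitude) || amplitude <= 0)
      stop("rotating mode needs a positive 'amplitude' (tesla)")
    if (!sense %in% c(-1, 1)) stop("'sense' must be +1 or -1")
    if (n_states < 1) stop("'n_states' must be >= 1")
    j <- seq_len(n_states) - 1
    angles <- start_angle + sense * 360 * j / n_states
    B <- lapply(angles * pi / 180,
                function(a) amplitude * c(cos(a), sin(a), 0))
    times <- j * period / n_states
  } else {
    if (is.null(states) || length(states) < 1)
      stop("switching mode needs at least one field state")
    ok <- vapply(states, function(b) is.numeric(b) && length(b) == 3,
                 logical(1))
    if (!all(ok)) stop("each switching state must be a numeric 3-vector (tesla)")
    B <- lapply(states, as.numeric)
    n_states <- length(B)
    angles <- NULL
    times <- (seq_len(n_states) - 1) * period / n_states
  }
  H <- lapply(B, function(b) b / MU0)
  structure(list(mode = mode, frequency = frequency, omega = 2 * pi * frequency,
                 amplitude = amplitude, n_states = n_states, angles = angles,
                 start_angle = start_angle, sense = sense,
                 times = times, B = B, H = H),
            class = "field_sequence")
}

#' @export
print.field_sequence <- function(x, ...) {
  cat(sprintf("<field_sequence> %s, f = %g Hz, %d state(s)\n",
              x$mode, x$frequency, x$n_states))
  invisible(x)
}

#' Field angle of a rotating sequence at time t
#'
#' @param field a rotating-mode [field_sequence()].
#' @param t time(s) in seconds.
#' @return field angle(s) in degrees (unwrapped).
#' @export
field_angle <- function(field, t) {
  if (field$mode != "rotating") stop("field_angle() needs a rotating-mode field")
  field$start_angle + field$sense * 360 * field$frequency * t
}
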