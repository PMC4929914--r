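#' Flight configuration
#'
#' Bundle of the scalar flight and physics parameters that drive every stage
#' of the pipeline: freestream speed, air density, Reynolds number (or
#' kinematic viscosity), body mass, wingbeat frequency, stroke-plane angle,
#' stroke amplitude, wing length, reference single-wing area, body angle and
#' simulation time step.
#'
#' Exactly one of `Re` or `nu` must be supplied; the other is derived through
#' the chord-based Reynolds number \eqn{Re = U \bar{c} / \nu} with mean chord
#' \eqn{\bar{c} = S_{ref} / R}.
#'
#' The coordinate frame used throughout the package is bird-fixed:
#' +X downstream (the freestream blows in +X), +Z vertically up, +Y to the
#' bird's left, origin at the shoulder midpoint.  Thrust is the -X force.
#'
#' @param U flight (freestream) speed, m/s.
#' @param rho air density, kg/m^3.
#' @param M body mass, kg.
#' @param g gravitational acceleration, m/s^2.
#' @param f_beat wingbeat frequency, Hz.
#' @param beta stroke-plane angle from horizontal, degrees (0..90).
#' @param Phi stroke amplitude, degrees (0..180, exclusive).
#' @param R wing length (shoulder to tip), m.
#' @param S_ref reference single-wing area, m^2.
#' @param chi_b body angle from horizontal, degrees.
#' @param dt simulation time step, s.
#' @param Re Reynolds number based on mean chord (supply this or `nu`).
#' @param nu kinematic viscosity, m^2/s (supply this or `Re`).
#'
#' @return An object of class `flight_config`: a named list with the fields
#'   above plus the derived mean chord `c_bar` and whichever of `Re`/`nu` was
#'   not supplied.
#' @seealso [default_calliope_config()]
#' @export
flight_config <- function(U, rho, M, g = 9.81, f_beat, beta, Phi, R, S_ref,
                          chi_b, dt, Re = NULL, nu = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("flight_config: `", nm, "` must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  U <- num1(U, "U"); rho <- num1(rho, "rho"); M <- num1(M, "M")
  g <- num1(g, "g"); f_beat <- num1(f_beat, "f_beat"); beta <- num1(beta, "beta")
  Phi <- num1(Phi, "Phi"); R <- num1(R, "R"); S_ref <- num1(S_ref, "S_ref")
  chi_b <- num1(chi_b, "chi_b"); dt <- num1(dt, "dt")

  for (nm in c("U", "rho", "M", "f_beat", "R", "S_ref", "dt"))
    if (get(nm) <= 0) stop("flight_config: `", nm, "` must be strictly positive", call. = FALSE)
  if (beta < 0 || beta > 90) stop("flight_config: `beta` must lie in [0, 90] degrees", call. = FALSE)
  if (Phi <= 0 || Phi >= 180) stop("flight_config: `Phi` must lie in (0, 180) degrees", call. = FALSE)

  if (is.null(Re) == is.null(nu))
    stop("flight_config: supply exactly one of `Re` or `nu`", call. = FALSE)
  c_bar <- S_ref / R
  if (is.null(nu)) {
    Re <- num1(Re, "Re")
    if (Re <= 0) stop("flight_config: `Re` must be strictly positive", call. = FALSE)
    nu <- U * c_bar / Re
  } else {
    nu <- num1(nu, "nu")
    if (nu <= 0) stop("flight_config: `nu` must be strictly positive", call. = FALSE)
    Re <- U * c_bar / nu
  }

  structure(
    list(U = U, rho = rho, M = M, g = g, f_beat = f_beat, beta = beta,
         Phi = Phi, R = R, S_ref = S_ref, chi_b = chi_b, dt = dt,
         Re = Re, nu = nu, c_bar = c_bar),
    class = "flight_config")
}

#' Default calliope hummingbird configuration
#'
#' Flight parameters of a female calliope hummingbird (*Selasphorus
#' calliope*) in sustained fast forward flight at 8.3 m/s in a wind tunnel:
#' mass 2.8 g, wingbeat frequency 45.5 Hz, stroke-plane angle 67.9 deg,
#' stroke amplitude 102.5 deg, wing length 4.51 cm, mean single-wing area
#' 5.18 cm^2, body angle 12 deg, chord Reynolds number 3000, time step 5 us.
#' Air density is fixed at 1.2 kg/m^3 and g at 9.81 m/s^2.
#'
#' @return A [flight_config()] object.
#' @examples
#' cfg <- default_calliope_config()
#' cfg$c_bar          # mean chord, m
#' cfg$nu             # derived kinematic viscosity
#' @export
default_calliope_config <- function() {
  flight_config(U = 8.3, rho = 1.2, M = 2.8e-3, g = 9.81,
                f_beat = 45.5, beta = 67.9, Phi = 102.5,
                R = 4.51e-2, S_ref = 5.18e-4, chi_b = 12,
                dt = 5e-6, Re = 3000)
}

#' @export
print.flight_config <- function(x, ...) {
  cat("<flight_config>\n")
  cat(sprintf("  U = %.3g m/s, rho = %.3g kg/m^3, M = %.3g kg\n", x$U, x$rho, x$M))
  cat(sprintf("  f = %.3g Hz, beta = %.4g deg, Phi = %.4g deg\n", x$f_beat, x$beta, x$Phi))
  cat(sprintf("  R = %.3g m, S_ref = %.3g m^2 (c_bar = %.4g m), chi_b = %.3g deg\n",
              x$R, x$S_ref, x$c_bar, x$chi_b))
  cat(sprintf("  Re = %.4g (nu = %.4g m^2/s), dt = %.3g s\n", x$Re, x$nu, x$dt))
  invisible(x)
}

#' Simulation steps per wingbeat cycle
#'
#' Number of solver time steps in one wingbeat period, `1 / (f_beat * dt)`.
#' For the default calliope configuration (45.5 Hz, 5 us step) this is
#' approximately 4400.
#'
#' @param config a [flight_config()].
#' @return Steps per cycle (numeric; not rounded).
#' @export
steps_per_cycle <- function(config) {
  stopifnot(inherits(config, "flight_config"))
  1 / (config$f_beat * config$dt)
}
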