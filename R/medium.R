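#' Viscous medium model
#'
#' Describes the suspension medium and probe: a linear temperature model
#' of viscosity `eta(T) = eta0 - mu_abs * (T - T0_visc)` anchored at
#' `T0_visc`, plus the particle radius. Defaults describe glycerol
#' (eta0 = 0.301 Pa s at 35 degC, |slope| = 0.0208 Pa s/degC) and the
#' 25 nm nominal nanodiamond radius. Viscosity decreases with
#' temperature, as for all simple liquids; the slope magnitude and
#' anchor are exposed because published glycerol constants vary between
#' sources.
#'
#' @param eta0 viscosity at the anchor temperature, Pa s.
#' @param mu_abs magnitude of the viscosity slope, Pa s / degC.
#' @param T0_visc anchor temperature, degC.
#' @param particle_radius probe hydrodynamic radius, nm.
#' @param temperature default operating temperature, degC.
#'
#' @return A list of class `nd_medium`.
#' @export
medium_model <- function(eta0 = 0.301, mu_abs = 0.0208, T0_visc = 35,
                         particle_radius = 25, temperature = 35) {
  check_number(eta0, "eta0", lower = .Machine$double.eps)
  check_number(mu_abs, "mu_abs", lower = 0)
  check_number(particle_radius, "particle_radius",
               lower = .Machine$double.eps)
  m <- structure(list(eta0 = eta0, mu_abs = mu_abs, T0_visc = T0_visc,
                      particle_radius = particle_radius,
                      temperature = temperature),
                 class = "nd_medium")
  if (glycerol_viscosity(40, m, warn = FALSE) <= 0) {
    abort("Medium model gives non-positive viscosity inside 21-40 degC.")
  }
  m
}

#' Temperature-dependent viscosity
#'
#' Evaluates the linear viscosity model of an [medium_model()]:
#' `eta(T) = eta0 - mu_abs * (T - T0_visc)`, strictly decreasing in
#' temperature. Temperatures outside the supported 21-40 degC range are
#' extrapolated with a warning.
#'
#' @param T_C temperature(s) in degC.
#' @param medium an [medium_model()].
#' @param warn warn when extrapolating outside 21-40 degC.
#'
#' @return Viscosity in Pa s (vectorized over `T_C`).
#' @examples
#' glycerol_viscosity(35)  # 0.301 Pa s at the anchor temperature
#' @export
glycerol_viscosity <- function(T_C, medium = medium_model(), warn = TRUE) {
  if (!is.numeric(T_C) || !all(is.finite(T_C))) {
    abort("`T_C` must be finite numeric.")
  }
  if (warn && any(T_C < 21 | T_C > 40)) {
    warn("Temperature outside the supported 21-40 degC range; viscosity is extrapolated.")
  }
  medium$eta0 - medium$mu_abs * (T_C - medium$T0_visc)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T_abs / (6 pi eta(T) r)` for a particle of the medium's
#' radius at temperature `T_C`, in nm^2/s. Used by the generators and
#' the pipeline presets to set simulation conditions.
#'
#' @param T_C temperature(s) in degC.
#' @param medium an [medium_model()].
#' @return Diffusion coefficient(s) in nm^2/s.
#' @export
stokes_einstein_D <- function(T_C, medium = medium_model()) {
  eta <- glycerol_viscosity(T_C, medium, warn = FALSE)
  r_m <- medium$particle_radius * 1e-9
  .kB * (T_C + 273.15) / (6 * pi * eta * r_m) * 1e18
}
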