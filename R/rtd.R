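#' RTD calibration
#'
#' The on-chip resistive temperature detector (a gold track) has a
#' linear resistance-temperature relation
#' `R(T) = R0 * (1 + eta_rtd * (T - T0))`, inverted for read-out as
#' `T = T0 + (R/R0 - 1) / eta_rtd`. The default fractional slope is the
#' experimentally determined 2.44e-3 per degC.
#'
#' @param R0 reference resistance in Ohm (> 0).
#' @param T0_rtd reference temperature in degC at which `R0` was
#'   measured.
#' @param eta_rtd fractional resistance slope, 1/degC (> 0).
#'
#' @return A list of class `nd_rtd_cal`.
#' @export
rtd_calibration <- function(R0 = 100, T0_rtd = 21, eta_rtd = 2.44e-3) {
  check_number(R0, "R0", lower = .Machine$double.eps)
  check_number(eta_rtd, "eta_rtd", lower = .Machine$double.eps)
  structure(list(R0 = R0, T0_rtd = T0_rtd, eta_rtd = eta_rtd),
            class = "nd_rtd_cal")
}

#' Generate a synthetic RTD resistance trace
#'
#' @param T_profile a function of time (s) returning temperature in
#'   degC, or a numeric vector of temperatures (one per sample).
#' @param cal an [rtd_calibration()].
#' @param times sample times in seconds (required when `T_profile` is a
#'   function; defaults to the vector indices at 1 s spacing otherwise).
#' @param noise_sd Gaussian read-out noise sd in Ohm.
#' @param seed RNG seed.
#'
#' @return A tibble with columns `t_s`, `R_ohm`.
#' @export
generate_rtd_trace <- function(T_profile, cal = rtd_calibration(),
                               times = NULL, noise_sd = 0, seed = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.function(T_profile)) {
    if (is.null(times)) abort("`times` is required when `T_profile` is a function.")
    T_C <- T_profile(times)
  } else {
    T_C <- as.numeric(T_profile)
    times <- times %||% (seq_along(T_C) - 1)
  }
  R <- cal$R0 * (1 + cal$eta_rtd * (T_C - cal$T0_rtd))
  if (noise_sd > 0) {
    R <- R + with_seed(seed, rnorm(length(R), sd = noise_sd))
  }
  tibble(t_s = times, R_ohm = R)
}

#' Convert RTD resistance to temperature
#'
#' Inverts the linear RTD relation: `T = T0 + (R/R0 - 1) / eta_rtd`.
#'
#' @param R resistance(s) in Ohm (> 0).
#' @param cal an [rtd_calibration()].
#'
#' @return Temperature(s) in degC.
#' @examples
#' cal <- rtd_calibration(R0 = 100, T0_rtd = 21)
#' rtd_to_temperature(100 * (1 + 2.44e-3), cal)  # 22 degC
#' @export
rtd_to_temperature <- function(R, cal = rtd_calibration()) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0)) {
    abort("`R` must be positive and finite.")
  }
  cal$T0_rtd + (R / cal$R0 - 1) / cal$eta_rtd
}
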