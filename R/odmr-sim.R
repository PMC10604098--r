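#' ODMR spectrum model
#'
#' Parameterizes the photoluminescence dip profile of an ensemble-NV
#' ODMR spectrum: by default two Lorentzian dips split symmetrically
#' about the zero-field center (strain-split ensemble), configurable to
#' a single broad dip. The profile is the multiplicative attenuation of
#' the photon rate: 1 off resonance, `1 - contrast/n_dips` at each dip
#' center (for well-separated dips).
#'
#' @param center_frequency zero-field dip center, MHz.
#' @param contrast total fractional PL contrast, in (0, 1).
#' @param linewidth Lorentzian FWHM per dip, MHz.
#' @param n_dips 1 or 2.
#' @param splitting dip separation for `n_dips = 2`, MHz.
#' @param baseline_rate off-resonance photon rate, counts/s (both
#'   detectors combined; 1 Mcps gives the nominal 5 counts per APD per
#'   10 us gate).
#'
#' @return A list of class `nd_spectrum_model`.
#' @export
spectrum_model <- function(center_frequency = 2870, contrast = 0.2,
                           linewidth = 6, n_dips = 2, splitting = 8,
                           baseline_rate = 1e6) {
  check_number(contrast, "contrast", lower = 0, upper = 1)
  if (contrast == 0 || contrast == 1) {
    abort("`contrast` must lie strictly inside (0, 1).")
  }
  check_number(linewidth, "linewidth", lower = .Machine$double.eps)
  if (!n_dips %in% c(1, 2)) abort("`n_dips` must be 1 or 2.")
  check_number(baseline_rate, "baseline_rate",
               lower = .Machine$double.eps)
  structure(list(center_frequency = center_frequency, contrast = contrast,
                 linewidth = linewidth, n_dips = n_dips,
                 splitting = splitting, baseline_rate = baseline_rate),
            class = "nd_spectrum_model")
}

#' Analytic ODMR dip profile
#'
#' @param f_mhz frequencies in MHz.
#' @param model an [spectrum_model()].
#' @param center_frequency optional center override (MHz), e.g. the
#'   temperature-shifted center.
#'
#' @return Attenuation factors in (0, 1].
#' @export
odmr_profile <- function(f_mhz, model, center_frequency = NULL) {
  c0 <- center_frequency %||% model$center_frequency
  lor <- function(x) 1 / (1 + (2 * x / model$linewidth)^2)
  if (model$n_dips == 1L) {
    1 - model$contrast * lor(f_mhz - c0)
  } else {
    1 - (model$contrast / 2) * (lor(f_mhz - c0 - model$splitting / 2) +
                                  lor(f_mhz - c0 + model$splitting / 2))
  }
}

#' Generate a stream of ODMR spectra
#'
#' Emulates the continuous-wave ODMR acquisition: 200-point frequency
#' sweeps completed in 2 ms, 80 scans accumulated per 160 ms window
#' inside a 200 ms duty cycle (no counts during the 40 ms off period).
#' The dip center tracks temperature through the thermal shift
#' coefficient `kappa` (kHz/degC). Counts are Poisson with per-gate mean
#' `baseline_rate * gate_time * profile`, and are stored aggregated per
#' window (summed over the 80 scans per frequency point), matching the
#' instrument's own intermediate storage.
#'
#' @param temperature_profile a function of time (s) returning the
#'   temperature offset from reference in degC, or a single number.
#' @param model an [spectrum_model()].
#' @param kappa thermal shift coefficient in kHz/degC (default -60);
#'   `kappa = 0` gives a temperature-insensitive control.
#' @param duration total wall-clock duration in seconds (at least one
#'   200 ms duty cycle).
#' @param seed RNG seed.
#' @param f_span frequency span of the 200-point sweep, MHz.
#' @param n_points points per sweep (default 200).
#' @param noise `"poisson"` for shot noise, `"none"` for the infinite
#'   photon-budget limit (counts equal their expectation).
#'
#' @return A tibble of class `nd_odmr` with columns `window_index`,
#'   `freq_MHz`, `counts` (window-aggregated) and timing metadata in
#'   attributes (`scan_time = 2e-3`, `scans_per_window = 80`,
#'   `window_time = 0.16`, `duty_cycle_period = 0.2`,
#'   `gate_time = 1e-5`, `n_detectors = 2`).
#' @export
generate_odmr_series <- function(temperature_profile, model = spectrum_model(),
                                 kappa = -60, duration = 10, seed = NULL,
                                 f_span = 60, n_points = 200L,
                                 noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  timing <- list(scan_time = 2e-3, scans_per_window = 80L,
                 window_time = 0.16, duty_cycle_period = 0.2,
                 gate_time = 1e-5, n_detectors = 2L)
  stopifnot(timing$scans_per_window * timing$scan_time == timing$window_time)
  if (duration < timing$duty_cycle_period) {
    abort("`duration` must cover at least one 200 ms duty cycle.")
  }
  if (is.numeric(temperature_profile)) {
    dT0 <- temperature_profile[1]
    temperature_profile <- function(t) rep(dT0, length(t))
  }
  n_win <- floor(duration / timing$duty_cycle_period)
  fgrid <- seq(model$center_frequency - f_span / 2,
               model$center_frequency + f_span / 2,
               length.out = n_points)
  ## window start times; temperature evaluated at the window midpoint
  t_win <- (seq_len(n_win) - 1L) * timing$duty_cycle_period
  dT <- temperature_profile(t_win + timing$window_time / 2)
  centers <- model$center_frequency + kappa * 1e-3 * dT  # kHz -> MHz
  per_gate <- model$baseline_rate * timing$gate_time
  lam <- vapply(centers, function(c0) {
    timing$scans_per_window * per_gate * odmr_profile(fgrid, model, c0)
  }, numeric(n_points))                 # n_points x n_win
  counts <- if (noise == "poisson") {
    with_seed(seed, matrix(rpois(length(lam), lam), nrow = n_points))
  } else {
    lam
  }
  out <- tibble(window_index = rep(seq_len(n_win), each = n_points),
                freq_MHz = rep(fgrid, times = n_win),
                counts = as.vector(counts))
  structure(out,
            class = c("nd_odmr", class(out)),
            timing = timing,
            model = model,
            kappa = kappa,
            frequency_grid = fgrid,
            window_times = t_win,
            seed = seed,
            noise = noise)
}

#' @export
print.nd_odmr <- function(x, ...) {
  tm <- attr(x, "timing")
  cat(sprintf(
    "<nd_odmr> %d windows of %d scans (%g ms scan, %g ms duty cycle)\n",
    max(x$window_index), tm$scans_per_window, tm$scan_time * 1e3,
    tm$duty_cycle_period * 1e3))
  NextMethod()
}
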