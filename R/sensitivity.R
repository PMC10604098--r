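#' Overlapping Allan deviation
#'
#' Two-sample (Allan) deviation of a uniformly sampled series over
#' half-octave-spaced averaging times, using the overlapping estimator:
#' `sigma_A^2(m t0) = mean[(ybar_{i+m} - ybar_i)^2] / 2` with
#' `ybar_i` the running mean of `m` samples.
#'
#' @param x numeric series.
#' @param sample_period sample period `t0`, seconds.
#' @param m averaging factors (default half-octave up to N/3).
#'
#' @return A tibble with `tau_s`, `adev`, `m`, `n_terms`.
#' @export
allan_deviation <- function(x, sample_period, m = NULL) {
  N <- length(x)
  if (N < 10L) abort("Need at least 10 samples for an Allan deviation.")
  if (is.null(m)) {
    m <- unique(floor(2^(seq(0, log2(N / 3), by = 0.5))))
  }
  m <- m[m >= 1 & 2 * m < N]
  cm <- cumsum(c(0, x))
  res <- vapply(m, function(mi) {
    yb <- (cm[(mi + 1):(N + 1)] - cm[1:(N - mi + 1)]) / mi
    d <- yb[(mi + 1):(N - mi + 1)] - yb[1:(N - 2 * mi + 1)]
    c(sqrt(mean(d^2) / 2), length(d))
  }, numeric(2))
  tibble(tau_s = m * sample_period, adev = res[1, ], m = m,
         n_terms = as.integer(res[2, ]))
}

#' Allan-deviation temperature sensitivity
#'
#' Characterizes the temperature precision of a thermometry trace as a
#' function of accumulation time via the overlapping Allan deviation,
#' identifies the white-noise region (where
#' `sigma_A(tau) ~ tau^(-1/2)`) by sliding log-log fits accepting local
#' slopes of `-0.5 +/- 0.1`, and reports the sensitivity
#' `eta = sigma_A(tau) * sqrt(tau)` averaged over that region. If no
#' white-noise region is found the report is flagged and no sensitivity
#' is extrapolated.
#'
#' @param temperature_trace an `nd_temperature` tibble (from
#'   [shift_to_temperature()]) or a numeric vector of temperatures.
#' @param sample_period sample period in seconds (taken from the trace
#'   attributes when available).
#' @param slope_tol acceptance half-width around the ideal -0.5 slope.
#' @param fit_width number of consecutive Allan points per sliding fit.
#'
#' @return An object of class `nd_sensitivity`: `allan` (tibble with a
#'   `white_noise` logical column), `sensitivity_K_rtHz`,
#'   `white_noise_found`, `sample_period`. Has [tidy()]/[glance()]
#'   methods.
#' @export
allan_sensitivity <- function(temperature_trace, sample_period = NULL,
                              slope_tol = 0.1, fit_width = 4L) {
  if (is.data.frame(temperature_trace)) {
    sample_period <- sample_period %||% attr(temperature_trace, "sample_period")
    x <- temperature_trace$dT_C
  } else {
    x <- as.numeric(temperature_trace)
  }
  if (is.null(sample_period)) abort("`sample_period` is required.")
  ad <- allan_deviation(x, sample_period)
  k <- nrow(ad)
  accepted <- rep(FALSE, k)
  if (all(ad$adev == 0)) {
    out <- list(allan = mutate(ad, white_noise = FALSE),
                sensitivity_K_rtHz = 0,
                white_noise_found = FALSE,
                sample_period = sample_period)
    return(structure(out, class = "nd_sensitivity"))
  }
  pos <- ad$adev > 0
  for (i in seq_len(max(0L, k - fit_width + 1L))) {
    j <- i:(i + fit_width - 1L)
    if (!all(pos[j])) next
    sl <- coef(lm(log(ad$adev[j]) ~ log(ad$tau_s[j])))[2]
    if (abs(sl + 0.5) <= slope_tol) accepted[j] <- TRUE
  }
  sens <- if (any(accepted)) {
    mean(ad$adev[accepted] * sqrt(ad$tau_s[accepted]))
  } else {
    NA_real_
  }
  structure(list(allan = mutate(ad, white_noise = accepted),
                 sensitivity_K_rtHz = sens,
                 white_noise_found = any(accepted),
                 sample_period = sample_period),
            class = "nd_sensitivity")
}

#' @export
print.nd_sensitivity <- function(x, ...) {
  cat(sprintf("<nd_sensitivity> %s; sensitivity %.4g K/sqrt(Hz)%s\n",
              if (x$white_noise_found) "white-noise region found"
              else "no white-noise region",
              x$sensitivity_K_rtHz,
              if (!is.null(x$crb_K_rtHz))
                sprintf(" (CRB %.4g, excess %.1f%%)", x$crb_K_rtHz,
                        100 * x$relative_excess) else ""))
  invisible(x)
}

#' Shot-noise Cramer-Rao bound on temperature sensitivity
#'
#' Computes the Fisher information for the dip centre frequency from
#' Poisson photon counts, `I = sum_i (d lambda_i / d f0)^2 / lambda_i`
#' per 2 ms scan (`lambda_i` = expected counts at frequency point `i`),
#' and converts the resulting frequency imprecision into a temperature
#' sensitivity: with 80 scans per 200 ms duty cycle (the 160/200 duty
#' factor), `sigma(f0)` after `t` seconds is
#' `1 / sqrt(I * scans_per_second * t)`, so the sensitivity is
#' `1e3 / (sqrt(I * scans_per_second) * |kappa|)` in K/sqrt(Hz).
#'
#' @param model an [spectrum_model()].
#' @param cal an [thermometry_calibration()] (supplies `kappa`).
#' @param f_span,n_points sweep span (MHz) and number of points,
#'   matching the generated series.
#' @param timing timing list (defaults to the standard
#'   2 ms / 80-scan / 200 ms cycle).
#'
#' @return Sensitivity in K/sqrt(Hz). A zero-contrast model returns
#'   `Inf` with a message.
#' @export
cramer_rao_sensitivity <- function(model, cal = thermometry_calibration(),
                                   f_span = 60, n_points = 200L,
                                   timing = NULL) {
  timing <- timing %||% list(scan_time = 2e-3, scans_per_window = 80L,
                             duty_cycle_period = 0.2, gate_time = 1e-5)
  fgrid <- seq(model$center_frequency - f_span / 2,
               model$center_frequency + f_span / 2,
               length.out = n_points)
  per_gate <- model$baseline_rate * timing$gate_time
  lam <- per_gate * odmr_profile(fgrid, model)
  h <- 1e-5  # MHz step for the centre-frequency derivative
  dlam <- per_gate *
    (odmr_profile(fgrid, model, model$center_frequency + h) -
       odmr_profile(fgrid, model, model$center_frequency - h)) / (2 * h)
  I_scan <- sum(dlam^2 / lam)           # 1/MHz^2 per scan
  if (I_scan <= 0) {
    inform("Zero-contrast model: the bound is infinite.")
    return(Inf)
  }
  scans_per_s <- timing$scans_per_window / timing$duty_cycle_period
  sigma_f_rtHz <- 1 / sqrt(I_scan * scans_per_s)   # MHz / sqrt(Hz)
  sigma_f_rtHz * 1e3 / abs(cal$kappa)              # K / sqrt(Hz)
}

#' Compare an Allan sensitivity with the Cramer-Rao bound
#'
#' @param sensitivity an [allan_sensitivity()] result.
#' @param crb_K_rtHz the [cramer_rao_sensitivity()] value.
#'
#' @return The `nd_sensitivity` object with `crb_K_rtHz` and
#'   `relative_excess` (= sensitivity / crb - 1) filled in.
#' @export
benchmark_sensitivity <- function(sensitivity, crb_K_rtHz) {
  stopifnot(inherits(sensitivity, "nd_sensitivity"))
  sensitivity$crb_K_rtHz <- crb_K_rtHz
  sensitivity$relative_excess <- sensitivity$sensitivity_K_rtHz / crb_K_rtHz - 1
  sensitivity
}

#' @export
tidy.nd_sensitivity <- function(x, ...) {
  x$allan
}

#' @export
glance.nd_sensitivity <- function(x, ...) {
  tibble(sensitivity_K_rtHz = x$sensitivity_K_rtHz,
         crb_K_rtHz = x$crb_K_rtHz %||% NA_real_,
         relative_excess = x$relative_excess %||% NA_real_,
         white_noise_found = x$white_noise_found)
}
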