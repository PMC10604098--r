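#' Thermometry calibration
#'
#' The NV zero-field splitting shifts linearly with temperature; the
#' thermal shift coefficient `kappa` (default -60.0 kHz/degC) converts
#' fitted ODMR frequency shifts into temperature changes,
#' `dT = df / kappa`.
#'
#' @param kappa thermal shift coefficient, kHz/degC (non-zero).
#' @param reference_frequency dip centre at the reference temperature,
#'   MHz.
#' @param reference_temperature reference temperature, degC.
#'
#' @return A list of class `nd_thermo_cal`.
#' @export
thermometry_calibration <- function(kappa = -60, reference_frequency = 2870,
                                    reference_temperature = 33) {
  check_number(kappa, "kappa")
  if (kappa == 0) abort("`kappa` must be non-zero for temperature conversion.")
  structure(list(kappa = kappa, reference_frequency = reference_frequency,
                 reference_temperature = reference_temperature),
            class = "nd_thermo_cal")
}

#' Build the interpolation template from an ODMR series
#'
#' The template is the mean spectrum over all scans in the series,
#' normalized to unit mean, defined between the 200 grid points by
#' piece-wise linear interpolation. Fitting frequency shifts against
#' this self-derived template avoids committing to a parametric line
#' shape.
#'
#' @param series an [generate_odmr_series()] tibble (at least one full
#'   window).
#'
#' @return A list of class `nd_template` with `frequency_grid` (MHz)
#'   and `values` (unit-mean normalized counts).
#' @export
build_template <- function(series) {
  stopifnot(inherits(series, "nd_odmr"))
  tot <- series |>
    group_by(.data$freq_MHz) |>
    summarise(counts = mean(.data$counts), .groups = "drop") |>
    arrange(.data$freq_MHz)
  if (all(tot$counts == 0)) abort("All-zero counts: cannot build a template.")
  structure(list(frequency_grid = tot$freq_MHz,
                 values = tot$counts / mean(tot$counts)),
            class = "nd_template")
}

#' Evaluate an interpolation template
#'
#' Piece-wise linear interpolation between the grid points; constant
#' extrapolation at the edges.
#'
#' @param template an [build_template()] result.
#' @param f_mhz frequencies at which to evaluate.
#' @return Template values.
#' @export
template_eval <- function(template, f_mhz) {
  approx(template$frequency_grid, template$values, xout = f_mhz,
         rule = 2)$y
}

## Core shift search shared by fit_frequency_shift and fit_shift_series.
## Y: n_points x n_bins matrix of bin spectra. Minimizes, per bin,
## ||y - a * t(f - delta) - c||^2 over (a, c) in closed form (QR
## projection) and over delta by coarse grid search at the grid spacing,
## fine search at spacing/10 around the coarse optimum, and a
## three-point parabola through the minimum.
shift_search <- function(Y, template, max_shift, spacing) {
  fgrid <- template$frequency_grid
  n <- length(fgrid)
  sse_for <- function(deltas) {
    S <- matrix(0, length(deltas), ncol(Y))
    y2 <- colSums(Y^2)
    for (k in seq_along(deltas)) {
      tt <- template_eval(template, fgrid - deltas[k])
      Q <- qr.Q(qr(cbind(tt, 1)))
      P <- crossprod(Q, Y)
      S[k, ] <- y2 - colSums(P^2)
    }
    S
  }
  coarse <- seq(-max_shift, max_shift, by = spacing)
  S1 <- sse_for(coarse)
  i1 <- apply(S1, 2, which.min)
  fine_step <- spacing / 10
  d_hat <- se_hat <- numeric(ncol(Y))
  flag <- rep("ok", ncol(Y))
  for (b in seq_len(ncol(Y))) {
    c0 <- coarse[i1[b]]
    fine <- seq(c0 - 2 * spacing, c0 + 2 * spacing, by = fine_step)
    ## evaluate fine grid for this bin only
    yb <- Y[, b, drop = FALSE]
    y2 <- sum(yb^2)
    sse <- vapply(fine, function(d) {
      tt <- template_eval(template, fgrid - d)
      Q <- qr.Q(qr(cbind(tt, 1)))
      y2 - sum(crossprod(Q, yb)^2)
    }, numeric(1))
    i <- which.min(sse)
    if (i == 1L || i == length(fine)) {
      d_hat[b] <- fine[i]
      se_hat[b] <- NA_real_
      flag[b] <- "edge"
    } else {
      s1 <- sse[i - 1L]; s2m <- sse[i]; s3 <- sse[i + 1L]
      curv <- s1 - 2 * s2m + s3
      d_hat[b] <- fine[i] +
        if (curv > 0) 0.5 * fine_step * (s1 - s3) / curv else 0
      ## local-quadratic standard error: Var(d) = 2 sigma^2 / SSE''
      sigma2 <- s2m / (n - 3L)
      se_hat[b] <- if (curv > 0) sqrt(2 * sigma2 * fine_step^2 / curv) else NA_real_
    }
    if (abs(d_hat[b]) > max_shift) flag[b] <- "out_of_range"
  }
  list(shift = d_hat, se = se_hat, flag = flag)
}

#' Fit the frequency shift of one data bin against the template
#'
#' Finds the shift `df` minimizing the sum of squared residuals between
#' the bin's mean spectrum and the template evaluated at `f - df`, with
#' a free multiplicative amplitude and additive offset absorbing slow
#' photoluminescence drifts. Search: coarse grid at the frequency-grid
#' spacing over `+/- span/4`, fine grid at spacing/10, three-point
#' parabolic refinement (resolution well below 1 kHz for the default
#' 0.3 MHz spacing). Shifts beyond a quarter of the grid span are
#' flagged `"out_of_range"`.
#'
#' @param bin_counts numeric vector of per-frequency-point counts for
#'   the bin (length = grid length), or an `nd_odmr` tibble containing
#'   exactly the bin's windows.
#' @param template an [build_template()] result.
#'
#' @return A tibble with `df_khz`, `se_khz`, `flag`.
#' @export
fit_frequency_shift <- function(bin_counts, template) {
  if (inherits(bin_counts, "nd_odmr")) {
    bin_counts <- bin_counts |>
      group_by(.data$freq_MHz) |>
      summarise(counts = sum(.data$counts), .groups = "drop") |>
      arrange(.data$freq_MHz) |>
      (\(d) d$counts)()
  }
  n <- length(template$frequency_grid)
  if (length(bin_counts) != n) {
    abort("`bin_counts` must match the template grid length.")
  }
  span <- diff(range(template$frequency_grid))
  spacing <- span / (n - 1L)
  res <- shift_search(matrix(bin_counts, ncol = 1), template,
                      max_shift = span / 4, spacing = spacing)
  tibble(df_khz = res$shift * 1e3, se_khz = res$se * 1e3, flag = res$flag)
}

#' Fit frequency shifts for every bin of an ODMR series
#'
#' Splits the series into independent bins of `bin_s` seconds of data
#' (default 400 ms = 2 duty cycles) and fits each bin's mean spectrum
#' against the template (see [fit_frequency_shift()]); bins are fitted
#' jointly with a vectorized coarse search for speed.
#'
#' @param series an [generate_odmr_series()] tibble.
#' @param template an [build_template()] result (default: built from
#'   `series` itself).
#' @param bin_s bin length in seconds (a multiple of the 200 ms duty
#'   cycle).
#'
#' @return A tibble of class `nd_shifts` with `bin_index`, `t_s` (bin
#'   left edge), `df_khz`, `se_khz`, `flag`.
#' @export
fit_shift_series <- function(series, template = NULL, bin_s = 0.4) {
  stopifnot(inherits(series, "nd_odmr"))
  timing <- attr(series, "timing")
  wpb <- round(bin_s / timing$duty_cycle_period)
  if (wpb < 1L || abs(wpb * timing$duty_cycle_period - bin_s) > 1e-9) {
    abort("`bin_s` must be a positive multiple of the 200 ms duty cycle.")
  }
  fgrid <- attr(series, "frequency_grid")
  n <- length(fgrid)
  n_win <- max(series$window_index)
  n_bin <- floor(n_win / wpb)
  if (n_bin < 1L) abort("Series shorter than one bin.")
  C <- matrix(series$counts, nrow = n)    # n_points x n_win (window-major)
  grp <- rep(seq_len(n_bin), each = wpb)
  Y <- C[, seq_len(n_bin * wpb), drop = FALSE]
  Y <- t(rowsum(t(Y), grp))               # n_points x n_bin
  span <- diff(range(fgrid))
  spacing <- span / (n - 1L)
  res <- shift_search(Y, structure(list(frequency_grid = fgrid,
                                        values = template_eval(
                                          template %||% build_template(series),
                                          fgrid)),
                                   class = "nd_template"),
                      max_shift = span / 4, spacing = spacing)
  out <- tibble(bin_index = seq_len(n_bin),
                t_s = (seq_len(n_bin) - 1L) * wpb * timing$duty_cycle_period,
                df_khz = res$shift * 1e3,
                se_khz = res$se * 1e3,
                flag = res$flag)
  structure(out, class = c("nd_shifts", class(out)),
            bin_s = bin_s, n_f = 1L)
}

#' Average consecutive frequency shifts
#'
#' Replaces non-overlapping blocks of `n_f` consecutive shifts by their
#' mean, with the standard error of the `n_f` shifts as the error
#' estimate. A trailing partial block is dropped with a warning.
#'
#' @param shifts an [fit_shift_series()] tibble.
#' @param n_f block size (>= 2; default 25, i.e. 10 s of 400 ms bins).
#'
#' @return A tibble of class `nd_shifts` with `t_s` (block left edge),
#'   `df_khz`, `se_khz`, `n_f`.
#' @export
average_shifts <- function(shifts, n_f = 25L) {
  stopifnot(inherits(shifts, "nd_shifts"))
  check_number(n_f, "n_f", lower = 2)
  n_f <- as.integer(n_f)
  n <- nrow(shifts)
  n_blk <- floor(n / n_f)
  if (n_blk < 1L) abort("Fewer shifts than one block of `n_f`.")
  if (n %% n_f != 0L) {
    warn(sprintf("Dropping trailing partial block of %d shifts.", n %% n_f))
  }
  idx <- seq_len(n_blk * n_f)
  blk <- rep(seq_len(n_blk), each = n_f)
  out <- tibble(df = shifts$df_khz[idx], t = shifts$t_s[idx], blk = blk) |>
    group_by(.data$blk) |>
    summarise(t_s = min(.data$t), df_khz = mean(.data$df),
              se_khz = sd(.data$df) / sqrt(n_f), .groups = "drop") |>
    mutate(n_f = n_f) |>
    select("t_s", "df_khz", "se_khz", "n_f")
  structure(out, class = c("nd_shifts", class(out)),
            bin_s = attr(shifts, "bin_s"), n_f = n_f)
}

#' Convert frequency shifts to temperature changes
#'
#' `dT = df / kappa`; standard errors propagate linearly.
#'
#' @param shifts an `nd_shifts` tibble, or a numeric vector of shifts
#'   in kHz.
#' @param cal an [thermometry_calibration()].
#'
#' @return For a tibble input, a tibble with `t_s`, `dT_C`, `se_C`; for
#'   numeric input, a numeric vector of temperature changes in degC.
#' @examples
#' shift_to_temperature(-240, thermometry_calibration(kappa = -60))  # +4 degC
#' @export
shift_to_temperature <- function(shifts, cal = thermometry_calibration()) {
  if (is.numeric(shifts)) {
    return(shifts / cal$kappa)
  }
  stopifnot(inherits(shifts, "nd_shifts"))
  out <- tibble(t_s = shifts$t_s,
                dT_C = shifts$df_khz / cal$kappa,
                se_C = abs(shifts$se_khz / cal$kappa))
  structure(out, class = c("nd_temperature", class(out)),
            kappa = cal$kappa,
            sample_period = attr(shifts, "bin_s") *
              max(1L, attr(shifts, "n_f") %||% 1L))
}
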