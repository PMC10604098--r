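#' Welch power spectral density of a trajectory
#'
#' One-sided PSD of the position fluctuations per transverse axis,
#' estimated by Welch's method: the trajectory is split into
#' mean-detrended, Hann-windowed segments of `window` seconds with 50%
#' overlap, periodograms are averaged and normalized as a density
#' (`sum(psd) * df ~ signal variance`). The total PSD is the sum of the
#' two transverse axes. The value at the read-out frequency (default
#' 40 Hz) is taken from the nearest frequency bin.
#'
#' @param traj an [new_trajectory()].
#' @param window segment length in seconds (default 28.8).
#' @param readout_hz read-out frequency for the summary value.
#'
#' @return A tibble of class `nd_psd` with columns `f_hz`,
#'   `psd_x_um2_hz`, `psd_y_um2_hz`, `psd_total_um2_hz`; attributes
#'   `readout_hz`, `readout_um2_hz` (total PSD at the nearest bin),
#'   `window_s`, `n_segments`.
#' @export
welch_psd <- function(traj, window = 28.8, readout_hz = 40) {
  stopifnot(inherits(traj, "nd_trajectory"))
  dt <- attr(traj, "sampling_period")
  nseg <- floor(window / dt)
  N <- nrow(traj)
  if (nseg < 8L) abort("`window` too short for the sampling period.")
  if (nseg > N) abort("`window` is longer than the trajectory.")
  fs <- 1 / dt
  sx <- welch_one(traj$x_nm * 1e-3, nseg, fs)
  sy <- welch_one(traj$y_nm * 1e-3, nseg, fs)
  total <- sx$psd + sy$psd
  i40 <- which.min(abs(sx$f - readout_hz))
  out <- tibble(f_hz = sx$f, psd_x_um2_hz = sx$psd, psd_y_um2_hz = sy$psd,
                psd_total_um2_hz = total)
  structure(out,
            class = c("nd_psd", class(out)),
            readout_hz = readout_hz,
            readout_bin_hz = sx$f[i40],
            readout_um2_hz = total[i40],
            window_s = nseg * dt,
            n_segments = sx$n_segments)
}

## Welch estimator for one real series: Hann window, 50% overlap,
## constant detrend per segment, one-sided density normalization
## 2 |X|^2 / (fs * sum(w^2)). DC bin dropped.
welch_one <- function(x, nseg, fs) {
  N <- length(x)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, N - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  U <- sum(w^2)
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- (2 / (fs * U)) * Mod(X[2:(nf + 1L)])^2
    if (nseg %% 2L == 0L) p[nf] <- p[nf] / 2   # Nyquist bin is not doubled
    acc <- acc + p
  }
  list(f = (1:nf) * fs / nseg, psd = acc / length(starts),
       n_segments = length(starts))
}

#' Decompose a position PSD into thermal and active force contributions
#'
#' In a linear medium the position PSD obeys Hooke's law,
#' `|K(omega)|^2 <x^2(omega)> = <xi^2(omega)> + <F_ext^2(omega)>`, with
#' the complex spring constant `K(omega) = 6 pi r G*(omega)`. The
#' thermal position PSD is the fluctuation-dissipation form (one-sided,
#' per Hz) `S_th(f) = (2 kB T / (pi f)) * K''(omega) / |K(omega)|^2`
#' per axis -- doubled here to match the two-axis transverse PSD --
#' which reduces to the Brownian `D / (pi^2 f^2)` per axis in a purely
#' viscous medium. The active force PSD is
#' `<F_ext^2> = |K|^2 * (S_meas - S_th)`, clipped at zero (clipped
#' points are flagged).
#'
#' The modulus is interpolated onto the PSD frequency grid over their
#' overlapping support (log-log linear interpolation); points where
#' `|K| = 0` are excluded.
#'
#' @param psd an [welch_psd()] result (total transverse PSD is used).
#' @param modulus an [mason_modulus()] result.
#' @param T_K absolute temperature, K.
#' @param radius_nm probe radius, nm.
#'
#' @return A tibble of class `nd_forces` with columns `f_hz`,
#'   `psd_um2_hz`, `thermal_um2_hz`, `K_abs_N_m`, `F_ext2_N2_hz`,
#'   `clipped`.
#' @export
decompose_forces <- function(psd, modulus, T_K, radius_nm) {
  stopifnot(inherits(psd, "nd_psd"), inherits(modulus, "nd_modulus"))
  check_number(T_K, "T_K", lower = .Machine$double.eps)
  r_m <- radius_nm * 1e-9
  fmin <- max(min(psd$f_hz), min(modulus$f_hz))
  fmax <- min(max(psd$f_hz), max(modulus$f_hz))
  sel <- psd$f_hz >= fmin & psd$f_hz <= fmax
  if (!any(sel)) abort("PSD and modulus have no overlapping frequency support.")
  f <- psd$f_hz[sel]
  gp <- exp(approx(log(modulus$f_hz), log(pmax(modulus$G_prime_Pa, 1e-300)),
                   xout = log(f), rule = 2)$y)
  gpp <- exp(approx(log(modulus$f_hz), log(pmax(modulus$G_double_prime_Pa, 1e-300)),
                    xout = log(f), rule = 2)$y)
  K1 <- 6 * pi * r_m * gp
  K2 <- 6 * pi * r_m * gpp
  Kabs2 <- K1^2 + K2^2
  keep <- Kabs2 > 0
  f <- f[keep]
  S_meas <- psd$psd_total_um2_hz[sel][keep] * 1e-12    # um^2/Hz -> m^2/Hz
  ## per-axis FDT bound, doubled for the two transverse axes summed in
  ## the measured PSD
  S_th <- 2 * (2 * .kB * T_K / (pi * f)) * K2[keep] / Kabs2[keep]
  Fx2 <- Kabs2[keep] * (S_meas - S_th)
  clipped <- Fx2 < 0
  Fx2[clipped] <- 0
  out <- tibble(f_hz = f,
                psd_um2_hz = S_meas * 1e12,
                thermal_um2_hz = S_th * 1e12,
                K_abs_N_m = sqrt(Kabs2[keep]),
                F_ext2_N2_hz = Fx2,
                clipped = clipped)
  structure(out, class = c("nd_forces", class(out)),
            temperature_K = T_K, radius_nm = radius_nm)
}
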