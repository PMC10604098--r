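#' Complex modulus by the Mason generalized Stokes-Einstein method
#'
#' Converts a transverse (two-axis) MSD curve into the medium's complex
#' shear modulus using the local power-law approximation: at each
#' angular frequency `omega = 1/tau` (`f = omega / 2pi`),
#' `|G*| = 2 kB T / (3 pi r MSD(tau) Gamma(1 + alpha(tau)))` and the
#' loss tangent `delta = pi alpha / 2`, where `alpha(tau)` is the local
#' log-log slope of the MSD (quadratic fit over a +/- 3 point window in
#' `ln tau`). `G' = |G*| cos delta`, `G'' = |G*| sin delta`. The
#' normalization is fixed by the viscous limit: a transverse MSD of
#' `4 D tau` with `D = kB T / (6 pi eta r)` returns
#' `G''(f) = 2 pi f eta` exactly.
#'
#' Errors on `|G*|` are propagated from the MSD error (relative errors
#' are equal), treating the error on alpha as negligible. Local
#' exponents outside `[0, 2]` are clipped with a warning; lags whose MSD
#' sits at the noise floor are excluded.
#'
#' @param msd an [compute_msd()] result over two transverse axes.
#' @param T_K absolute temperature, K.
#' @param radius_nm probe hydrodynamic radius, nm.
#' @param half_window half-width (in grid points) of the local log-log
#'   slope fit window.
#'
#' @return A tibble of class `nd_modulus` with columns `f_hz`,
#'   `G_prime_Pa`, `G_double_prime_Pa`, `G_abs_Pa`, `G_abs_se_Pa`,
#'   `delta_rad`, `alpha_local`, `tau_s`.
#' @export
mason_modulus <- function(msd, T_K, radius_nm, half_window = 3L) {
  stopifnot(inherits(msd, "nd_msd"))
  check_number(T_K, "T_K", lower = .Machine$double.eps)
  check_number(radius_nm, "radius_nm", lower = .Machine$double.eps)
  use <- msd$msd_um2 > 0 & msd$flag != "noise_floor"
  m <- msd[use, ]
  if (nrow(m) < 2L * half_window + 1L) {
    abort("Too few usable lags above the noise floor for the modulus.")
  }
  lt <- log(m$tau_s)
  lm_ <- log(m$msd_um2)
  k <- nrow(m)
  alpha <- numeric(k)
  for (i in seq_len(k)) {
    j <- max(1L, i - half_window):min(k, i + half_window)
    ## local quadratic in ln tau; slope evaluated at the centre point
    if (length(j) >= 3L) {
      fit <- lm(lm_[j] ~ poly(lt[j], 2, raw = TRUE))
      alpha[i] <- coef(fit)[2] + 2 * coef(fit)[3] * lt[i]
    } else {
      alpha[i] <- (lm_[max(j)] - lm_[min(j)]) / (lt[max(j)] - lt[min(j)])
    }
  }
  if (any(alpha < 0 | alpha > 2)) {
    warn(sprintf("Local exponent clipped to [0, 2] at %d of %d lags.",
                 sum(alpha < 0 | alpha > 2), k))
    alpha <- pmin(pmax(alpha, 0), 2)
  }
  msd_m2 <- m$msd_um2 * 1e-12
  r_m <- radius_nm * 1e-9
  G_abs <- 2 * .kB * T_K / (3 * pi * r_m * msd_m2 * gamma(1 + alpha))
  rel_err <- m$error_um2 / m$msd_um2
  delta <- pi * alpha / 2
  omega <- 1 / m$tau_s
  out <- tibble(f_hz = omega / (2 * pi),
                G_prime_Pa = G_abs * cos(delta),
                G_double_prime_Pa = G_abs * sin(delta),
                G_abs_Pa = G_abs,
                G_abs_se_Pa = G_abs * rel_err,
                delta_rad = delta,
                alpha_local = alpha,
                tau_s = m$tau_s) |>
    arrange(.data$f_hz)
  structure(out,
            class = c("nd_modulus", class(out)),
            temperature_K = T_K,
            radius_nm = radius_nm,
            axes = attr(msd, "axes"))
}
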