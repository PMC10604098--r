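#' Time-averaged mean square displacement
#'
#' Computes the time-averaged MSD over the selected axes,
#' `MSD(tau) = (1/K) * sum_i |r(i + tau) - r(i)|^2` with `K = N - tau`
#' pairs per lag, for lags up to `N/4` samples (longer lags have too few
#' independent pairs for the variance estimator's regime). For
#' trajectories longer than 200 usable lags a log-spaced lag grid is
#' used; pass `lags` to control it explicitly.
#'
#' Each lag carries the analytic variance of the time-averaged MSD (see
#' [msd_variance()]) and a combined error that is floored at the system
#' noise floor: the error is set to the noise floor whenever the
#' statistical error or the MSD itself falls below it.
#'
#' @param traj an [new_trajectory()].
#' @param axes subset of `c("x", "y", "z")`; default transverse plane.
#' @param lags integer sample lags to evaluate (default: all lags up to
#'   `N/4` when few, log-spaced otherwise).
#' @param variance compute the per-lag variance estimate (default TRUE;
#'   turn off for speed on very long trajectories).
#'
#' @return A tibble of class `nd_msd` with columns `lag` (samples),
#'   `tau_s`, `msd_um2`, `var_um4`, `error_um2`, `n_pairs`, `flag`
#'   (`"ok"`, `"regime"` when the variance estimator is outside its
#'   tau << K validity window, `"noise_floor"`).
#' @export
compute_msd <- function(traj, axes = c("x", "y"), lags = NULL,
                        variance = TRUE) {
  stopifnot(inherits(traj, "nd_trajectory"))
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  if (length(axes) == 0L) abort("`axes` must not be empty.")
  N <- nrow(traj)
  dt <- attr(traj, "sampling_period")
  max_lag <- max(1L, floor(N / 4))
  if (is.null(lags)) {
    lags <- if (max_lag <= 200L) seq_len(max_lag) else log_lags(1L, max_lag, 150L)
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L | lags > N - 1L)) {
    abort("`lags` must lie in [1, N - 1].")
  }
  pos <- as.matrix(traj[, paste0(axes, "_nm")]) * 1e-3   # nm -> um
  msd <- numeric(length(lags))
  vv <- rep(NA_real_, length(lags))
  for (k in seq_along(lags)) {
    n <- lags[k]
    d2 <- rowSums((pos[(1L + n):N, , drop = FALSE] -
                     pos[1:(N - n), , drop = FALSE])^2)
    msd[k] <- mean(d2)
    if (variance) {
      vv[k] <- kim_variance_sq(pos, n)
    }
  }
  K <- N - lags
  floor_um2 <- attr(traj, "noise_floor_um2") %||% 1e-4
  ## the autocovariance-sum estimator can go slightly negative in noisy
  ## regimes; a variance is non-negative, so truncate
  vv[!is.na(vv) & vv < 0] <- 0
  err <- sqrt(vv)
  flag <- rep("ok", length(lags))
  flag[lags > K / 10 | K < 100] <- "regime"
  ## combined-error rule: the error is floored at the noise floor when
  ## either the statistical error or the MSD itself falls below it; the
  ## "noise_floor" flag marks lags whose MSD value is at/below the floor.
  err[(!is.na(err) & err < floor_um2) | msd < floor_um2] <- floor_um2
  flag[msd <= floor_um2] <- "noise_floor"
  out <- tibble(lag = lags, tau_s = lags * dt, msd_um2 = msd,
                var_um4 = vv, error_um2 = err, n_pairs = K, flag = flag)
  structure(out,
            class = c("nd_msd", class(out)),
            axes = axes,
            sampling_period = dt,
            n_samples = N,
            noise_floor_um2 = floor_um2)
}

## Variance of the time-averaged MSD at lag n from the squared pairwise
## differences, summed over axes (independent axes add). `pos` is the
## N x d position matrix in um.
kim_variance_sq <- function(pos, n) {
  N <- nrow(pos)
  K <- N - n
  if (K < 2L) return(NA_real_)
  total <- 0
  for (a in seq_len(ncol(pos))) {
    xi2 <- (pos[(1L + n):N, a] - pos[1:(N - n), a])^2
    total <- total + overlap_variance(xi2, n, K)
  }
  total
}

## Variance of the mean of the correlated series s (= xi^2) whose
## correlation extends over |i - j| < n: (1/K) * [C(0) +
## 2 * sum_{m<n} (1 - m/K) * C(m)] with C the empirical autocovariance.
overlap_variance <- function(s, n, K) {
  sb <- mean(s)
  mmax <- min(n - 1L, K - 1L)
  cm <- vapply(0:mmax, function(m) {
    mean((s[1:(K - m)] - sb) * (s[(1L + m):K] - sb))
  }, numeric(1))
  if (mmax >= 1L) {
    (cm[1] + 2 * sum((1 - (1:mmax) / K) * cm[-1])) / K
  } else {
    cm[1] / K
  }
}

#' Variance of the time-averaged MSD at one lag
#'
#' Estimates the inherent stochastic variance of the time-averaged MSD
#' from a single trajectory, accounting for the correlation between
#' overlapping displacement pairs at `|i - j| < tau`: per axis,
#' `Var[MSD_x(tau)] = (1/K) * [C(0) + 2 * sum_{m=1}^{tau-1} (1 - m/K) * C(m)]`
#' where `C(m)` is the empirical autocovariance of the squared pairwise
#' differences and `K = N - tau`. The three spatial directions are
#' uncorrelated, so the multi-axis variance is the sum of the per-axis
#' variances. The estimator is valid in the `tau << K`, `K >> 1` regime
#' (enforced as `tau <= K/10`, `K >= 100`); outside it the value is
#' returned flagged.
#'
#' @param traj an [new_trajectory()].
#' @param lag sample lag (integer, in samples).
#' @param axes axes to include (summed).
#'
#' @return Variance in um^4, with attribute `flag` (`"ok"` or
#'   `"regime"`).
#' @export
msd_variance <- function(traj, lag, axes = c("x", "y")) {
  stopifnot(inherits(traj, "nd_trajectory"))
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  N <- nrow(traj)
  lag <- as.integer(lag)
  check_number(lag, "lag", lower = 1, upper = N - 1)
  K <- N - lag
  pos <- as.matrix(traj[, paste0(axes, "_nm")]) * 1e-3
  v <- kim_variance_sq(pos, lag)
  flag <- if (lag <= K / 10 && K >= 100) "ok" else "regime"
  structure(v, flag = flag)
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Either reads the MSD at a single lag (`D = MSD(lag) / (2 d lag)`,
#' `d` = number of axes; the nearest available grid point is used), or
#' fits a weighted straight line through the origin over all lags up to
#' `lag` (weights `1/tau^2`, matching the MSD's multiplicative error
#' growth).
#'
#' @param msd an [compute_msd()] result.
#' @param method `"msd_at_lag"` or `"linear_fit"`.
#' @param lag lag time in seconds (default 1 s).
#'
#' @return A tibble of class `nd_diffusion` with columns `D_nm2_s`,
#'   `se_nm2_s`, `method`, `lag_used_s`, `n_axes`, `flag`.
#' @export
estimate_diffusion <- function(msd, method = c("msd_at_lag", "linear_fit"),
                               lag = 1) {
  stopifnot(inherits(msd, "nd_msd"))
  method <- match.arg(method)
  d <- length(attr(msd, "axes"))
  floor_um2 <- attr(msd, "noise_floor_um2")
  i <- which.min(abs(msd$tau_s - lag))
  lag_used <- msd$tau_s[i]
  if (abs(lag_used - lag) > 0.5 * lag) {
    inform(sprintf("Nearest available lag %.4g s used for requested %.4g s.",
                   lag_used, lag))
  }
  if (method == "msd_at_lag") {
    D <- msd$msd_um2[i] * 1e6 / (2 * d * lag_used)
    se <- msd$error_um2[i] * 1e6 / (2 * d * lag_used)
    flag <- if (msd$msd_um2[i] <= floor_um2) "noise_floor" else "ok"
  } else {
    sel <- msd$tau_s <= lag_used + 1e-12
    tau <- msd$tau_s[sel]
    y <- msd$msd_um2[sel] * 1e6
    w <- 1 / tau^2
    slope <- sum(w * tau * y) / sum(w * tau^2)
    res <- y - slope * tau
    k <- length(tau)
    se_slope <- if (k > 1) {
      sqrt(sum(w * res^2) / (k - 1) / sum(w * tau^2))
    } else NA_real_
    D <- slope / (2 * d)
    se <- se_slope / (2 * d)
    flag <- if (all(msd$msd_um2[sel] <= floor_um2)) "noise_floor" else "ok"
  }
  if (D < 0) D <- 0
  tibble(D_nm2_s = D, se_nm2_s = se, method = method,
         lag_used_s = lag_used, n_axes = d, flag = flag)
}

#' Fit the anomalous diffusion exponent
#'
#' Ordinary least squares of `ln MSD` against `ln tau` over the
#' requested lag range; the slope is the anomalous exponent alpha
#' (`MSD ~ tau^alpha`), with its regression standard error.
#'
#' @param msd an [compute_msd()] result.
#' @param lag_range length-2 numeric, lag-time range in seconds
#'   (default: the full curve).
#'
#' @return A tibble of class `nd_alpha_fit` with `alpha`, `alpha_se`,
#'   `amplitude_um2` (MSD at tau = 1 s from the fit), `n_lags`, `flag`
#'   (`"noise_floor"` when the range is dominated by the noise floor).
#' @export
fit_alpha <- function(msd, lag_range = NULL) {
  stopifnot(inherits(msd, "nd_msd"))
  sel <- msd$msd_um2 > 0
  if (!is.null(lag_range)) {
    sel <- sel & msd$tau_s >= lag_range[1] & msd$tau_s <= lag_range[2]
  }
  if (sum(sel) < 4L) abort("Need at least 4 lags in range to fit alpha.")
  floor_um2 <- attr(msd, "noise_floor_um2")
  flag <- if (mean(msd$msd_um2[sel] <= floor_um2) > 0.5) "noise_floor" else "ok"
  fit <- lm(log(msd_um2) ~ log(tau_s), data = msd[sel, ])
  cf <- summary(fit)$coefficients
  tibble(alpha = unname(cf[2, 1]), alpha_se = unname(cf[2, 2]),
         amplitude_um2 = exp(unname(cf[1, 1])),
         n_lags = sum(sel), flag = flag)
}
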