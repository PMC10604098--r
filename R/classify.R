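#' Directionality ratio of a trajectory window
#'
#' `gamma = d / l` over the transverse plane, where `d` is the net
#' displacement between the window's endpoints and `l` the summed path
#' length. Near 1 for directed transport, small for random motion.
#' A stationary window (zero path length) returns 0 with a warning.
#'
#' @param traj an [new_trajectory()].
#' @param start,end sample indices of the window (half-open
#'   `[start, end)`, at least 2 steps).
#'
#' @return The directionality ratio in `[0, 1]`.
#' @export
directionality_ratio <- function(traj, start = 1L, end = nrow(traj)) {
  stopifnot(inherits(traj, "nd_trajectory"))
  start <- as.integer(start); end <- as.integer(end)
  if (end - start < 2L) abort("Window must span at least 2 steps.")
  if (start < 1L || end > nrow(traj)) abort("Window out of range.")
  xy <- as.matrix(traj[start:end, c("x_nm", "y_nm")])
  gamma_xy(xy)
}

## gamma for an (n x 2) transverse window
gamma_xy <- function(xy) {
  steps <- diff(xy)
  l <- sum(sqrt(rowSums(steps^2)))
  if (l == 0) {
    warn("Stationary window: path length is zero, gamma set to 0.")
    return(0)
  }
  d <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  d / l
}

#' Null threshold for the directionality ratio
#'
#' Monte-Carlo quantile of gamma over Brownian windows matched in
#' diffusion coefficient, window length and sampling period. Windows
#' whose observed gamma exceeds this threshold show statistically
#' significant directional persistence at the chosen level.
#'
#' @param D diffusion coefficient of the null, nm^2/s.
#' @param window window length in steps.
#' @param dt sampling period, s.
#' @param quantile null quantile in (0, 1) (default 0.99).
#' @param n_sim number of simulated windows (>= 100; default 1e4).
#' @param seed RNG seed.
#'
#' @return The threshold `gamma*`.
#' @export
gamma_null_threshold <- function(D, window = 50L, dt = 9.6e-3,
                                 quantile = 0.99, n_sim = 1e4, seed = NULL) {
  check_number(D, "D", lower = 0)
  check_number(window, "window", lower = 3)
  check_number(quantile, "quantile", lower = 0, upper = 1)
  if (quantile <= 0 || quantile >= 1) abort("`quantile` must be in (0, 1).")
  if (n_sim < 100) abort("`n_sim` must be at least 100.")
  window <- as.integer(window); n_sim <- as.integer(n_sim)
  sdstep <- sqrt(2 * D * dt)
  g <- with_seed(seed, {
    dx <- matrix(rnorm(window * n_sim, sd = sdstep), nrow = window)
    dy <- matrix(rnorm(window * n_sim, sd = sdstep), nrow = window)
    l <- colSums(sqrt(dx^2 + dy^2))
    d <- sqrt(colSums(dx)^2 + colSums(dy)^2)
    d / l
  })
  unname(quantile(g, quantile, type = 7))
}

#' Segment a trajectory into directed and nondirected motion
#'
#' Computes the directionality ratio in a sliding window (stride 1) and
#' flags windows above the null threshold `gamma*`. Runs of flagged
#' windows lasting at least `min_run` windows are merged into directed
#' segments (adjacent runs separated by fewer than `merge_gap` windows
#' are joined); everything else is labelled nondirected. Each segment
#' carries its own gamma and, when long enough, a fitted anomalous
#' exponent over lags from 2 samples to a quarter of the segment
#' length.
#'
#' @param traj an [new_trajectory()].
#' @param window sliding-window length in steps (default 50, about
#'   0.48 s at the 9.6 ms update period).
#' @param gamma_star threshold from [gamma_null_threshold()].
#' @param min_run minimum directed run length, in windows (default 10).
#' @param merge_gap directed runs closer than this many windows are
#'   merged (default 3).
#' @param fit_alpha_segments fit per-segment exponents (default TRUE).
#'
#' @return A tibble of class `nd_segments` with `start_index`,
#'   `end_index` (half-open), `start_s`, `end_s`, `label`, `gamma`,
#'   `alpha`, `alpha_se`.
#' @export
segment_trajectory <- function(traj, window = 50L, gamma_star,
                               min_run = 10L, merge_gap = 3L,
                               fit_alpha_segments = TRUE) {
  stopifnot(inherits(traj, "nd_trajectory"))
  check_number(window, "window", lower = 3)
  check_number(gamma_star, "gamma_star", lower = 0, upper = 1)
  window <- as.integer(window)
  N <- nrow(traj)
  dt <- attr(traj, "sampling_period")
  if (N < window + 1L) {
    return(segments_from_intervals(traj, tibble(start = 1L, end = N,
                                                label = "nondirected"),
                                   fit_alpha_segments))
  }
  xy <- as.matrix(traj[, c("x_nm", "y_nm")])
  steps <- sqrt(rowSums(diff(xy)^2))
  cl <- cumsum(c(0, steps))
  n_win <- N - window
  i0 <- seq_len(n_win)
  l <- cl[i0 + window] - cl[i0]
  d <- sqrt((xy[i0 + window, 1] - xy[i0, 1])^2 +
              (xy[i0 + window, 2] - xy[i0, 2])^2)
  g <- ifelse(l > 0, d / l, 0)
  flagged <- g > gamma_star
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dir_runs <- tibble(start = starts[runs$values],
                     end = ends[runs$values])   # window indices, inclusive
  if (nrow(dir_runs) > 1L) {
    keep <- list(dir_runs[1, ])
    for (i in 2:nrow(dir_runs)) {
      lastk <- keep[[length(keep)]]
      if (dir_runs$start[i] - lastk$end <= merge_gap) {
        keep[[length(keep)]]$end <- dir_runs$end[i]
      } else {
        keep[[length(keep) + 1L]] <- dir_runs[i, ]
      }
    }
    dir_runs <- bind_rows(keep)
  }
  dir_runs <- filter(dir_runs, .data$end - .data$start + 1L >= min_run)
  ## window run [ws, we] covers samples [ws, we + window]; the
  ## extension can make neighbouring runs overlap in sample space, so
  ## merge again after extending
  if (nrow(dir_runs) > 0L) {
    dir_runs <- mutate(dir_runs, end = pmin(N, .data$end + window))
    merged <- list(dir_runs[1, ])
    if (nrow(dir_runs) > 1L) {
      for (i in 2:nrow(dir_runs)) {
        lastk <- merged[[length(merged)]]
        if (dir_runs$start[i] <= lastk$end + 1L) {
          merged[[length(merged)]]$end <- max(lastk$end, dir_runs$end[i])
        } else {
          merged[[length(merged) + 1L]] <- dir_runs[i, ]
        }
      }
    }
    dir_runs <- bind_rows(merged)
  }
  intervals <- tibble(start = integer(), end = integer(), label = character())
  cursor <- 1L
  if (nrow(dir_runs) > 0L) {
    for (i in seq_len(nrow(dir_runs))) {
      s <- dir_runs$start[i]
      e <- dir_runs$end[i]
      if (s > cursor) {
        intervals <- bind_rows(intervals,
                               tibble(start = cursor, end = s - 1L,
                                      label = "nondirected"))
      }
      intervals <- bind_rows(intervals,
                             tibble(start = s, end = e, label = "directed"))
      cursor <- e + 1L
    }
  }
  if (cursor <= N) {
    intervals <- bind_rows(intervals,
                           tibble(start = cursor, end = N,
                                  label = "nondirected"))
  }
  segments_from_intervals(traj, intervals, fit_alpha_segments)
}

segments_from_intervals <- function(traj, intervals, fit_alpha_segments) {
  dt <- attr(traj, "sampling_period")
  xy <- as.matrix(traj[, c("x_nm", "y_nm")])
  rows <- purrr::pmap(intervals, function(start, end, label) {
    len <- end - start + 1L
    g <- if (len >= 3L) suppressWarnings(gamma_xy(xy[start:end, , drop = FALSE])) else NA_real_
    a <- a_se <- NA_real_
    if (fit_alpha_segments && len >= 17L) {
      sub <- new_trajectory(traj$t_s[start:end], traj$x_nm[start:end],
                            traj$y_nm[start:end], traj$z_nm[start:end],
                            sampling_period = dt,
                            noise_floor_um2 = attr(traj, "noise_floor_um2"))
      msd <- compute_msd(sub, lags = log_lags(2L, max(4L, floor(len / 4)), 40L),
                         variance = FALSE)
      fa <- tryCatch(fit_alpha(msd), error = function(e) NULL)
      if (!is.null(fa)) { a <- fa$alpha; a_se <- fa$alpha_se }
    }
    tibble(start_index = start, end_index = end + 1L,
           start_s = traj$t_s[start], end_s = traj$t_s[end] + dt,
           label = label, gamma = g, alpha = a, alpha_se = a_se)
  })
  out <- list_rbind(rows)
  structure(out, class = c("nd_segments", class(out)),
            sampling_period = dt)
}

#' Summarize a set of anomalous exponents
#'
#' Maximum-likelihood normal fit to a sample of fitted exponents, plus
#' class fractions for subdiffusive (`alpha < 0.9`), diffusive
#' (`alpha` within `1 +/- 0.1`) and superdiffusive (`alpha > 1.1`)
#' motion. The diffusive band is a reporting convenience; the
#' boundary classification at `alpha = 1` is recovered by summing the
#' band into either side.
#'
#' @param alphas numeric vector of exponents (>= 3 values).
#' @param diffusive_band half-width of the diffusive band around 1.
#'
#' @return An object of class `nd_alpha_dist` with `fitted_mean`,
#'   `fitted_sd` (ML, i.e. denominator `n`), `class_fractions`,
#'   `alphas`. Has [tidy()]/[glance()] methods.
#' @export
summarize_alphas <- function(alphas, diffusive_band = 0.1) {
  alphas <- alphas[is.finite(alphas)]
  if (length(alphas) < 3L) abort("Need at least 3 finite exponents.")
  m <- mean(alphas)
  s <- sqrt(mean((alphas - m)^2))
  fr <- c(sub = mean(alphas < 1 - diffusive_band),
          diffusive = mean(abs(alphas - 1) <= diffusive_band),
          super = mean(alphas > 1 + diffusive_band))
  structure(list(fitted_mean = m, fitted_sd = s, class_fractions = fr,
                 alphas = alphas, diffusive_band = diffusive_band),
            class = "nd_alpha_dist")
}

#' @export
print.nd_alpha_dist <- function(x, ...) {
  cat(sprintf("<nd_alpha_dist> n = %d, alpha = %.3f +/- %.3f (sub %.0f%% / diff %.0f%% / super %.0f%%)\n",
              length(x$alphas), x$fitted_mean, x$fitted_sd,
              100 * x$class_fractions["sub"],
              100 * x$class_fractions["diffusive"],
              100 * x$class_fractions["super"]))
  invisible(x)
}

#' @export
tidy.nd_alpha_dist <- function(x, ...) {
  tibble(term = c("mean", "sd"), estimate = c(x$fitted_mean, x$fitted_sd))
}

#' @export
glance.nd_alpha_dist <- function(x, ...) {
  tibble(fitted_mean = x$fitted_mean, fitted_sd = x$fitted_sd,
         n = length(x$alphas),
         frac_sub = unname(x$class_fractions["sub"]),
         frac_diffusive = unname(x$class_fractions["diffusive"]),
         frac_super = unname(x$class_fractions["super"]))
}
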