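#' Trajectory containers
#'
#' A trajectory is a tibble with columns `t_s` (time, seconds), `x_nm`,
#' `y_nm`, `z_nm` (positions, nanometres) sampled on a uniform grid --
#' by default the 9.6 ms update period of the orbital tracker. Sampling
#' metadata travel as attributes: `sampling_period` (s),
#' `localization_sigma` (nm, per-axis localization noise),
#' `noise_floor_um2` (static MSD plateau, micrometre^2), `generator`
#' (parameter list) and `seed`.
#'
#' @param t_s numeric vector of times in seconds, strictly increasing with
#'   constant step.
#' @param x_nm,y_nm,z_nm numeric position vectors in nm.
#' @param sampling_period sampling step in seconds.
#' @param localization_sigma per-axis localization noise sd in nm.
#' @param noise_floor_um2 static MSD noise floor in micrometre^2.
#' @param generator named list describing how the data were generated.
#' @param seed the RNG seed used, or `NULL`.
#'
#' @return A tibble of class `nd_trajectory`.
#' @export
new_trajectory <- function(t_s, x_nm, y_nm, z_nm,
                           sampling_period = NULL,
                           localization_sigma = 0,
                           noise_floor_um2 = 1e-4,
                           generator = list(),
                           seed = NULL) {
  n <- length(t_s)
  if (n < 2L) abort("A trajectory needs at least 2 samples.")
  if (length(x_nm) != n || length(y_nm) != n || length(z_nm) != n) {
    abort("`t_s`, `x_nm`, `y_nm`, `z_nm` must have equal length.")
  }
  dt <- diff(t_s)
  if (any(dt <= 0)) abort("`t_s` must be strictly increasing.")
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    abort("`t_s` must be uniformly spaced.")
  }
  if (!all(is.finite(c(x_nm, y_nm, z_nm)))) {
    abort("Positions must be finite.")
  }
  out <- tibble(t_s = as.numeric(t_s), x_nm = as.numeric(x_nm),
                y_nm = as.numeric(y_nm), z_nm = as.numeric(z_nm))
  structure(out,
            class = c("nd_trajectory", class(out)),
            sampling_period = sampling_period %||% mean(dt),
            localization_sigma = localization_sigma,
            noise_floor_um2 = noise_floor_um2,
            generator = generator,
            seed = seed)
}

#' @export
print.nd_trajectory <- function(x, ...) {
  gen <- attr(x, "generator")
  cat(sprintf("<nd_trajectory> %d samples, dt = %g s%s\n",
              nrow(x), attr(x, "sampling_period"),
              if (length(gen)) paste0(", generator: ", gen$kind %||% "?") else ""))
  NextMethod()
}

## Shared position builder: cumulative Gaussian increments, then drift,
## then localization noise. The RNG draw order (increments first, noise
## second) is identical for all generators so that e.g. simulate_directed
## with v = 0 reproduces simulate_brownian bit-for-bit under the same seed.
brownian_positions <- function(D, n_steps, dt, localization_sigma,
                               drift_nm_s = c(0, 0, 0)) {
  inc_sd <- sqrt(2 * D * dt)
  pos <- vapply(1:3, function(a) {
    cumsum(c(0, rnorm(n_steps - 1L, sd = inc_sd)))
  }, numeric(n_steps))
  t_s <- (seq_len(n_steps) - 1L) * dt
  pos <- pos + outer(t_s, drift_nm_s)
  if (localization_sigma > 0) {
    pos <- pos + matrix(rnorm(3L * n_steps, sd = localization_sigma),
                        ncol = 3L)
  }
  list(t_s = t_s, pos = pos)
}

#' Simulate a free Brownian trajectory
#'
#' Generates a 3D random walk with independent Gaussian increments of
#' per-axis variance `2 * D * dt`, plus additive isotropic localization
#' noise. The default localization sd of 5 nm puts the static transverse
#' MSD plateau (`4 * sigma^2`) at the 1e-4 micrometre^2 system noise
#' floor.
#'
#' @param D diffusion coefficient in nm^2/s (`D >= 0`).
#' @param n_steps number of samples (>= 2).
#' @param dt sampling period in seconds (default 9.6e-3, the orbital
#'   tracking update period).
#' @param seed RNG seed (or `NULL` to use the current RNG state).
#' @param localization_sigma per-axis localization noise sd in nm.
#'
#' @return An [new_trajectory()] tibble.
#' @examples
#' traj <- simulate_brownian(D = 2e3, n_steps = 1000, seed = 1)
#' @export
simulate_brownian <- function(D, n_steps, dt = 9.6e-3, seed = NULL,
                              localization_sigma = 5) {
  check_number(D, "D", lower = 0)
  check_number(n_steps, "n_steps", lower = 2)
  check_number(dt, "dt", lower = .Machine$double.eps)
  check_number(localization_sigma, "localization_sigma", lower = 0)
  n_steps <- as.integer(n_steps)
  sim <- with_seed(seed, brownian_positions(D, n_steps, dt,
                                            localization_sigma))
  new_trajectory(sim$t_s, sim$pos[, 1], sim$pos[, 2], sim$pos[, 3],
                 sampling_period = dt,
                 localization_sigma = localization_sigma,
                 generator = list(kind = "brownian", D = D, dt = dt),
                 seed = seed)
}

## Exact fractional Gaussian noise by circulant embedding (Davies-Harte).
## Returns n standard-fGn samples with Hurst index H; the circulant
## eigenvalues of the fGn autocovariance are non-negative for 0 < H < 1,
## tiny negative round-off is clipped.
fgn_davies_harte <- function(n, H) {
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(gam, rev(gam[2:n]))
  lam <- Re(fft(row))
  lam[lam < 0] <- 0
  m <- 2L * n
  xi <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(lam) * xi))[1:n] / sqrt(m)
}

#' Simulate a fractional Brownian trajectory
#'
#' Per-axis fractional Gaussian increments with Hurst index `alpha / 2`,
#' scaled so that the per-axis ensemble MSD is `2 * scale * tau^alpha`
#' (transverse-plane MSD `4 * scale * tau^alpha`). `alpha = 1` with
#' `scale = D` reduces to Brownian motion.
#'
#' @param alpha anomalous exponent, in (0, 2).
#' @param scale generalized diffusion coefficient in nm^2/s^alpha.
#' @param n_steps,dt,seed,localization_sigma see [simulate_brownian()].
#'
#' @return An [new_trajectory()] tibble.
#' @export
simulate_fbm <- function(alpha, scale, n_steps, dt = 9.6e-3, seed = NULL,
                         localization_sigma = 0) {
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 2) {
    abort("`alpha` must lie strictly inside (0, 2).")
  }
  check_number(scale, "scale", lower = 0)
  check_number(n_steps, "n_steps", lower = 2)
  n_steps <- as.integer(n_steps)
  H <- alpha / 2
  amp <- sqrt(2 * scale) * dt^H
  sim <- with_seed(seed, {
    pos <- vapply(1:3, function(a) {
      cumsum(c(0, amp * fgn_davies_harte(n_steps - 1L, H)))
    }, numeric(n_steps))
    if (localization_sigma > 0) {
      pos <- pos + matrix(rnorm(3L * n_steps, sd = localization_sigma),
                          ncol = 3L)
    }
    pos
  })
  t_s <- (seq_len(n_steps) - 1L) * dt
  new_trajectory(t_s, sim[, 1], sim[, 2], sim[, 3],
                 sampling_period = dt,
                 localization_sigma = localization_sigma,
                 generator = list(kind = "fbm", alpha = alpha,
                                  scale = scale, dt = dt),
                 seed = seed)
}

#' Simulate directed motion (drift plus diffusion)
#'
#' Ballistic drift `v * t * direction` superimposed on a Brownian
#' component, emulating motor-driven transport. The analytic transverse
#' MSD is `4 * D * tau + (v_t * tau)^2` where `v_t` is the transverse
#' drift speed, so the apparent exponent crosses from 1 to 2.
#'
#' @param v drift speed in nm/s (`v >= 0`).
#' @param D diffusion coefficient in nm^2/s.
#' @param direction length-3 direction vector; normalized internally,
#'   the zero vector is rejected.
#' @param n_steps,dt,seed,localization_sigma see [simulate_brownian()].
#'
#' @return An [new_trajectory()] tibble.
#' @export
simulate_directed <- function(v, D, direction = c(1, 0, 0), n_steps,
                              dt = 9.6e-3, seed = NULL,
                              localization_sigma = 5) {
  check_number(v, "v", lower = 0)
  check_number(D, "D", lower = 0)
  if (length(direction) != 3L || !all(is.finite(direction))) {
    abort("`direction` must be a finite length-3 vector.")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must not be the zero vector.")
  direction <- direction / nrm
  n_steps <- as.integer(n_steps)
  sim <- with_seed(seed, brownian_positions(D, n_steps, dt,
                                            localization_sigma,
                                            drift_nm_s = v * direction))
  new_trajectory(sim$t_s, sim$pos[, 1], sim$pos[, 2], sim$pos[, 3],
                 sampling_period = dt,
                 localization_sigma = localization_sigma,
                 generator = list(kind = "directed", v = v, D = D,
                                  direction = direction, dt = dt),
                 seed = seed)
}
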