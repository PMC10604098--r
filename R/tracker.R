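#' Orbital tracker configuration
#'
#' Parameters of the double-plane orbital tracking feedback loop: the
#' excitation beam orbits the last inferred particle position at 50 nm
#' radius while two detection arms collect from planes axially offset by
#' 100 nm; transverse corrections come from the first Fourier harmonic
#' of the counts around the orbit and the axial correction from the
#' top/bottom plane count imbalance.
#'
#' @param orbit_radius orbit radius, nm.
#' @param plane_separation axial separation of the two detection planes,
#'   nm.
#' @param orbit_period time per orbit (= position update period), s.
#' @param psf_radius transverse 1/e^2 radius of the Gaussian PSF, nm.
#' @param psf_radius_z axial 1/e^2 radius (default `2 * psf_radius`,
#'   the typical confocal axial elongation).
#' @param emitter_rate total detected photon rate, counts/s.
#' @param points_per_orbit count samples per orbit per plane.
#' @param gain_xy,gain_z proportional feedback gains, in (0, 2].
#'
#' @return A list of class `nd_tracker_config`.
#' @export
tracker_config <- function(orbit_radius = 50, plane_separation = 100,
                           orbit_period = 9.6e-3, psf_radius = 250,
                           psf_radius_z = 2 * psf_radius,
                           emitter_rate = 1e6, points_per_orbit = 64L,
                           gain_xy = 0.7, gain_z = 0.7) {
  for (nm in c("orbit_radius", "plane_separation", "orbit_period",
               "psf_radius", "psf_radius_z", "emitter_rate")) {
    check_number(get(nm), nm, lower = .Machine$double.eps)
  }
  check_number(points_per_orbit, "points_per_orbit", lower = 4)
  check_number(gain_xy, "gain_xy", lower = 0, upper = 2, allow_zero = FALSE)
  check_number(gain_z, "gain_z", lower = 0, upper = 2, allow_zero = FALSE)
  structure(list(orbit_radius = orbit_radius,
                 plane_separation = plane_separation,
                 orbit_period = orbit_period, psf_radius = psf_radius,
                 psf_radius_z = psf_radius_z, emitter_rate = emitter_rate,
                 points_per_orbit = as.integer(points_per_orbit),
                 gain_xy = gain_xy, gain_z = gain_z),
            class = "nd_tracker_config")
}

#' Simulate the double-plane orbital tracking feedback loop
#'
#' For each orbit, Poisson counts are drawn along the orbit in both
#' detection planes from a 3D Gaussian PSF centred on the true particle
#' position; the transverse offset estimate is the first Fourier
#' harmonic of the summed counts (small-offset linearization
#' `delta = a1 * w0^2 / (4 R)`), the axial estimate the log plane-count
#' ratio `delta_z = wz^2 * log(N_top/N_bot) / (4 s)`. The tracker centre
#' moves by `gain * estimate` each orbit. If the tracking error exceeds
#' `3 * psf_radius` the particle is flagged as lost (the run continues,
#' with the affected updates marked).
#'
#' @param true_trajectory an [new_trajectory()] sampled at (a multiple
#'   of) the orbit period.
#' @param config an [tracker_config()].
#' @param seed RNG seed.
#' @param noise `"poisson"` or `"none"` (expected-count limit).
#' @param start_offset length-3 initial offset (nm) of the tracker
#'   centre from the particle's first position (default: locked on).
#'
#' @return A list of class `nd_tracker_run`: `reported` (trajectory
#'   tibble of tracker positions), `errors` (tibble `t_s`, `err_nm`,
#'   per-axis errors, `lost` flag), and `lost` (TRUE if any update was
#'   flagged).
#' @export
simulate_tracker <- function(true_trajectory, config = tracker_config(),
                             seed = NULL, noise = c("poisson", "none"),
                             start_offset = c(0, 0, 0)) {
  noise <- match.arg(noise)
  stopifnot(inherits(true_trajectory, "nd_trajectory"))
  dt <- attr(true_trajectory, "sampling_period")
  if (dt > config$orbit_period * (1 + 1e-9)) {
    abort("True trajectory must be sampled at least as finely as the orbit period.")
  }
  stride <- max(1L, round(config$orbit_period / dt))
  idx <- seq(1L, nrow(true_trajectory), by = stride)
  truth <- as.matrix(true_trajectory[idx, c("x_nm", "y_nm", "z_nm")])
  n_orb <- nrow(truth)
  R <- config$orbit_radius
  w0 <- config$psf_radius
  wz <- config$psf_radius_z
  sep <- config$plane_separation
  npts <- config$points_per_orbit
  theta <- 2 * pi * (seq_len(npts) - 1L) / npts
  ct <- cos(theta); st <- sin(theta)
  dwell <- config$orbit_period / npts
  rate_arm <- config$emitter_rate / 2

  with_seed(seed, {
    center <- truth[1, ] + start_offset
    rep_pos <- matrix(0, n_orb, 3L)
    errs <- matrix(0, n_orb, 3L)
    lost <- logical(n_orb)
    for (i in seq_len(n_orb)) {
      bx <- center[1] + R * ct
      by <- center[2] + R * st
      r2 <- (bx - truth[i, 1])^2 + (by - truth[i, 2])^2
      lam_t <- rate_arm * dwell *
        exp(-2 * r2 / w0^2 - 2 * (center[3] + sep / 2 - truth[i, 3])^2 / wz^2)
      lam_b <- rate_arm * dwell *
        exp(-2 * r2 / w0^2 - 2 * (center[3] - sep / 2 - truth[i, 3])^2 / wz^2)
      if (noise == "poisson") {
        c_t <- rpois(npts, lam_t); c_b <- rpois(npts, lam_b)
      } else {
        c_t <- lam_t; c_b <- lam_b
      }
      cc <- c_t + c_b
      tot <- sum(cc)
      if (tot > 0) {
        a1 <- 2 * sum(cc * ct) / tot
        b1 <- 2 * sum(cc * st) / tot
        dx <- a1 * w0^2 / (4 * R)
        dy <- b1 * w0^2 / (4 * R)
        nt <- sum(c_t); nb <- sum(c_b)
        dz <- if (nt > 0 && nb > 0) wz^2 * log(nt / nb) / (4 * sep) else 0
        center <- center + c(config$gain_xy * dx, config$gain_xy * dy,
                             config$gain_z * dz)
      }
      rep_pos[i, ] <- center
      errs[i, ] <- center - truth[i, ]
      lost[i] <- sqrt(sum(errs[i, ]^2)) > 3 * w0
    }
    t_s <- true_trajectory$t_s[idx]
    if (any(lost)) {
      warn(sprintf("Particle lost (error > 3 x psf_radius) at %d of %d updates.",
                   sum(lost), n_orb))
    }
    reported <- new_trajectory(t_s, rep_pos[, 1], rep_pos[, 2], rep_pos[, 3],
                               sampling_period = config$orbit_period,
                               generator = list(kind = "tracker"),
                               seed = seed)
    structure(list(reported = reported,
                   errors = tibble(t_s = t_s,
                                   err_x_nm = errs[, 1],
                                   err_y_nm = errs[, 2],
                                   err_z_nm = errs[, 3],
                                   err_nm = sqrt(rowSums(errs^2)),
                                   lost = lost),
                   lost = any(lost),
                   config = config),
              class = "nd_tracker_run")
  })
}
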