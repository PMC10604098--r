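#' Configure an end-to-end dual-modality run
#'
#' Bundles the generator and analysis parameters for [run_pipeline()].
#' Presets emulate the benchmark experiments:
#' \describe{
#'   \item{`glycerol`}{Brownian motion in glycerol with the temperature
#'     stepped by 3.5 degC every 5 min; diffusion follows
#'     Stokes-Einstein through the glycerol viscosity model, so the
#'     temperature and viscosity channels are anti-correlated.}
#'   \item{`gcx_like`}{viscoelastic (subdiffusive fBm, alpha = 0.6)
#'     medium cycled between 28.7 and 39.3 degC every 3 min; the MSD
#'     amplitude is larger in the hot phase, so `|G*|` is lower.}
#'   \item{`cell_like`}{Brownian intracellular motion with an inserted
#'     directed-transport interval and 2.5 degC temperature steps.}
#'   \item{`nocodazole_like`}{subdiffusive fBm (alpha = 0.3), no
#'     directed motion, constant temperature.}
#' }
#'
#' @param preset one of `"glycerol"`, `"gcx_like"`, `"cell_like"`,
#'   `"nocodazole_like"`.
#' @param duration total duration in seconds (default 600).
#' @param seed master seed; per-stage seeds are derived as small fixed
#'   offsets and recorded in the output.
#' @param medium an [medium_model()].
#' @param spectrum an [spectrum_model()].
#' @param cal an [thermometry_calibration()].
#' @param n_f thermometry averaging count (see [average_shifts()]).
#' @param rheology_bin_s averaging interval of the rheology channel
#'   (default 30 s).
#' @param ... preset parameter overrides stored into the config.
#'
#' @return A list of class `nd_run_config`.
#' @export
run_config <- function(preset = c("glycerol", "gcx_like", "cell_like",
                                  "nocodazole_like"),
                       duration = 600, seed = 1,
                       medium = medium_model(),
                       spectrum = spectrum_model(),
                       cal = thermometry_calibration(),
                       n_f = 25L, rheology_bin_s = 30, ...) {
  preset <- match.arg(preset)
  check_number(duration, "duration", lower = 60)
  structure(list(preset = preset, duration = duration, seed = seed,
                 medium = medium, spectrum = spectrum, cal = cal,
                 n_f = as.integer(n_f), rheology_bin_s = rheology_bin_s,
                 overrides = list(...)),
            class = "nd_run_config")
}

## Piecewise-constant temperature profiles per preset, degC offsets
## from the reference temperature.
preset_temperature_profile <- function(config) {
  dur <- config$duration
  switch(config$preset,
    glycerol = function(t) 3.5 * (floor(t / 300) %% 2),
    gcx_like = function(t) ifelse(floor(t / 180) %% 2 == 0, 0, 10.6),
    cell_like = function(t) 2.5 * (floor(t / 300) %% 2),
    nocodazole_like = function(t) rep(0, length(t))
  )
}

## Base temperatures (degC) at profile offset zero.
preset_base_temperature <- function(config) {
  switch(config$preset,
         glycerol = 28, gcx_like = 28.7, cell_like = 33,
         nocodazole_like = 33)
}

#' Run the dual-modality pipeline end to end
#'
#' Generates the two raw data streams on a shared clock from the preset
#' temperature profile -- an ODMR spectrum stream and a particle
#' trajectory -- then runs the thermometry chain (template build, shift
#' fitting, n_f averaging, temperature conversion, Allan sensitivity)
#' and the rheometry chain (MSD, diffusion / modulus / PSD in
#' `rheology_bin_s` bins, plus motion segmentation for the cell-like
#' presets). The two channels share no state other than the clock and
#' the programmed profile. Deterministic given the config seed.
#'
#' @param config an [run_config()].
#'
#' @return A list of class `nd_report`: `temperature` (tibble `t_s`,
#'   `dT_C`, `se_C`), `rheology` (tibble `t_s` plus a preset-dependent
#'   value column), `trajectory`, `odmr`, `shifts`, `sensitivity`,
#'   `segments` (cell presets), `alignment`, `stages` (timings), and
#'   the echoed `preset`/`seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nd_run_config"))
  t_start <- Sys.time()
  profile <- preset_temperature_profile(config)
  base_T <- preset_base_temperature(config)
  dt <- 9.6e-3
  n_steps <- floor(config$duration / dt)
  stages <- list()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  ## --- stage 1: synthetic streams -------------------------------------
  t0 <- tic()
  seed_traj <- config$seed * 13L + 1L
  seed_odmr <- config$seed * 13L + 2L
  traj <- switch(config$preset,
    glycerol = {
      sim_brownian_profile(function(t) stokes_einstein_D(base_T + profile(t),
                                                         config$medium),
                           n_steps, dt, seed_traj)
    },
    gcx_like = {
      ## hotter phase -> larger MSD amplitude (softer network)
      sim_fbm_profile(alpha = 0.6,
                      scale_fun = function(t) 2e3 * ifelse(profile(t) > 5,
                                                           1.6, 1.0),
                      n_steps, dt, seed_traj)
    },
    cell_like = {
      base <- simulate_brownian(D = 2e3, n_steps = n_steps, dt = dt,
                                seed = seed_traj)
      insert_directed_interval(base, v = 250,
                               from_s = config$duration * 0.4,
                               to_s = config$duration * 0.4 + 60)
    },
    nocodazole_like = simulate_fbm(alpha = 0.3, scale = 1e3,
                                   n_steps = n_steps, dt = dt,
                                   seed = seed_traj,
                                   localization_sigma = 5)
  )
  odmr <- generate_odmr_series(profile, model = config$spectrum,
                               kappa = config$cal$kappa,
                               duration = config$duration,
                               seed = seed_odmr)
  stages$simulate_s <- toc(t0)

  ## --- stage 2: thermometry -------------------------------------------
  t0 <- tic()
  shifts <- fit_shift_series(odmr)
  averaged <- average_shifts(shifts, n_f = config$n_f)
  temperature <- shift_to_temperature(averaged, config$cal)
  sens <- tryCatch(allan_sensitivity(shift_to_temperature(shifts, config$cal)),
                   error = function(e) NULL)
  if (!is.null(sens)) {
    sens <- benchmark_sensitivity(sens,
                                  cramer_rao_sensitivity(config$spectrum,
                                                         config$cal))
  }
  stages$thermometry_s <- toc(t0)

  ## --- stage 3: rheology in time bins ---------------------------------
  t0 <- tic()
  bins <- seq(0, config$duration - config$rheology_bin_s,
              by = config$rheology_bin_s)
  rheology <- purrr::map(bins, function(b0) {
    sel <- traj$t_s >= b0 & traj$t_s < b0 + config$rheology_bin_s
    if (sum(sel) < 32L) return(NULL)
    sub <- new_trajectory(traj$t_s[sel], traj$x_nm[sel], traj$y_nm[sel],
                          traj$z_nm[sel], sampling_period = dt,
                          noise_floor_um2 = attr(traj, "noise_floor_um2"))
    msd <- compute_msd(sub, variance = FALSE)
    row <- tibble(t_s = b0)
    if (config$preset == "glycerol") {
      row$D_nm2_s <- estimate_diffusion(msd, "linear_fit", lag = 1)$D_nm2_s
      row$eta_Pa_s <- .kB * (base_T + 273.15) /
        (6 * pi * config$medium$particle_radius * 1e-9 *
           row$D_nm2_s * 1e-18)
    } else if (config$preset %in% c("gcx_like", "nocodazole_like")) {
      mod <- tryCatch(mason_modulus(msd, T_K = base_T + 273.15,
                                    radius_nm = config$medium$particle_radius),
                      error = function(e) NULL)
      row$G_abs_Pa <- if (is.null(mod)) NA_real_ else {
        i <- which.min(abs(mod$f_hz - 2.7))
        mod$G_abs_Pa[i]
      }
    } else {
      psd <- tryCatch(welch_psd(sub, window = min(28.8,
                                                  config$rheology_bin_s * 0.9)),
                      error = function(e) NULL)
      row$psd40_um2_hz <- if (is.null(psd)) NA_real_ else
        attr(psd, "readout_um2_hz")
    }
    row
  }) |> list_rbind()
  stages$rheology_s <- toc(t0)

  ## --- stage 4: classification (cell presets) -------------------------
  segments <- NULL
  if (config$preset %in% c("cell_like", "nocodazole_like")) {
    t0 <- tic()
    gstar <- gamma_null_threshold(D = 2e3, window = 50L, dt = dt,
                                  quantile = 0.99, n_sim = 2000L,
                                  seed = config$seed * 13L + 3L)
    segments <- segment_trajectory(traj, window = 50L, gamma_star = gstar)
    stages$classify_s <- toc(t0)
  }

  stages$total_s <- toc(t_start)
  structure(list(preset = config$preset,
                 seed = config$seed,
                 seeds = list(trajectory = seed_traj, odmr = seed_odmr),
                 temperature = temperature,
                 rheology = rheology,
                 trajectory = traj,
                 odmr = odmr,
                 shifts = shifts,
                 sensitivity = sens,
                 segments = segments,
                 alignment = list(
                   temperature_bin_s = attr(temperature, "sample_period"),
                   rheology_bin_s = config$rheology_bin_s,
                   interval_s = c(0, config$duration),
                   bin_convention = "left-closed right-open, labelled by left edge"),
                 stages = stages,
                 config = config),
            class = "nd_report")
}

#' @export
print.nd_report <- function(x, ...) {
  cat(sprintf("<nd_report> preset '%s', seed %d: %d temperature bins, %d rheology bins\n",
              x$preset, x$seed, nrow(x$temperature), nrow(x$rheology)))
  invisible(x)
}

## Brownian motion whose diffusion coefficient follows a temperature
## program: per-step increment sd sqrt(2 D(t) dt).
sim_brownian_profile <- function(D_fun, n_steps, dt, seed,
                                 localization_sigma = 5) {
  t_s <- (seq_len(n_steps) - 1L) * dt
  sdstep <- sqrt(2 * D_fun(t_s[-n_steps]) * dt)
  with_seed(seed, {
    pos <- vapply(1:3, function(a) cumsum(c(0, rnorm(n_steps - 1L) * sdstep)),
                  numeric(n_steps))
    pos <- pos + matrix(rnorm(3L * n_steps, sd = localization_sigma),
                        ncol = 3L)
    new_trajectory(t_s, pos[, 1], pos[, 2], pos[, 3],
                   sampling_period = dt,
                   localization_sigma = localization_sigma,
                   generator = list(kind = "brownian_profile", dt = dt),
                   seed = seed)
  })
}

## fBm whose amplitude is rescaled piecewise by a temperature program:
## generates unit-scale fGn once, then scales increments by
## sqrt(scale(t)).
sim_fbm_profile <- function(alpha, scale_fun, n_steps, dt, seed,
                            localization_sigma = 5) {
  H <- alpha / 2
  t_s <- (seq_len(n_steps) - 1L) * dt
  amp <- sqrt(2 * scale_fun(t_s[-n_steps])) * dt^H
  with_seed(seed, {
    pos <- vapply(1:3, function(a) {
      cumsum(c(0, amp * fgn_davies_harte(n_steps - 1L, H)))
    }, numeric(n_steps))
    pos <- pos + matrix(rnorm(3L * n_steps, sd = localization_sigma),
                        ncol = 3L)
    new_trajectory(t_s, pos[, 1], pos[, 2], pos[, 3],
                   sampling_period = dt,
                   localization_sigma = localization_sigma,
                   generator = list(kind = "fbm_profile", alpha = alpha,
                                    dt = dt),
                   seed = seed)
  })
}

#' Insert a directed-transport interval into a trajectory
#'
#' Adds a constant-velocity drift over `[from_s, to_s)` in the
#' transverse plane (direction `c(1, 1, 0)/sqrt(2)`), emulating a
#' transient active-transport event on top of the existing motion.
#'
#' @param traj an [new_trajectory()].
#' @param v drift speed, nm/s.
#' @param from_s,to_s interval in seconds.
#' @return The modified trajectory.
#' @export
insert_directed_interval <- function(traj, v, from_s, to_s) {
  stopifnot(inherits(traj, "nd_trajectory"))
  dirv <- c(1, 1, 0) / sqrt(2)
  tt <- pmin(pmax(traj$t_s, from_s), to_s) - from_s
  gen <- attr(traj, "generator")
  out <- new_trajectory(traj$t_s,
                        traj$x_nm + v * tt * dirv[1],
                        traj$y_nm + v * tt * dirv[2],
                        traj$z_nm + v * tt * dirv[3],
                        sampling_period = attr(traj, "sampling_period"),
                        localization_sigma = attr(traj, "localization_sigma"),
                        noise_floor_um2 = attr(traj, "noise_floor_um2"),
                        generator = c(gen, list(directed_interval =
                                                  c(from_s, to_s), v = v)),
                        seed = attr(traj, "seed"))
  out
}
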