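#' Read and write trajectory files
#'
#' Trajectories are stored as CSV with header `t_s,x_nm,y_nm,z_nm`, one
#' row per tracker update, values formatted to 12 significant digits
#' (lossless to better than 1e-9 relative). Sampling metadata travel in
#' a JSON sidecar `<path>.meta.json` (sampling period, seed, generator
#' parameters, localization sigma, noise floor).
#'
#' @param traj an [new_trajectory()].
#' @param path CSV file path.
#'
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `nd_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "nd_trajectory"))
  lines <- c("t_s,x_nm,y_nm,z_nm",
             sprintf("%.12g,%.12g,%.12g,%.12g",
                     traj$t_s, traj$x_nm, traj$y_nm, traj$z_nm))
  writeLines(lines, path)
  meta <- list(sampling_period = attr(traj, "sampling_period"),
               localization_sigma = attr(traj, "localization_sigma"),
               noise_floor_um2 = attr(traj, "noise_floor_um2"),
               generator = attr(traj, "generator"),
               seed = attr(traj, "seed"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, "t_s,x_nm,y_nm,z_nm")) {
    abort(sprintf("Malformed trajectory header: got '%s'.", header))
  }
  d <- read.csv(path)
  bad <- which(!complete.cases(d) |
                 !apply(as.matrix(d), 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    abort(sprintf("Non-finite values at data row %d.", bad[1]))
  }
  nonmono <- which(diff(d$t_s) <= 0)
  if (length(nonmono)) {
    abort(sprintf("Non-monotonic time at data row %d.", nonmono[1] + 1L))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_trajectory(d$t_s, d$x_nm, d$y_nm, d$z_nm,
                 sampling_period = meta$sampling_period,
                 localization_sigma = meta$localization_sigma %||% 0,
                 noise_floor_um2 = meta$noise_floor_um2 %||% 1e-4,
                 generator = as.list(meta$generator %||% list()),
                 seed = meta$seed)
}

#' Read and write ODMR series files
#'
#' ODMR streams are stored as CSV with header
#' `window_index,scan_index,freq_MHz,counts`. The package stores counts
#' aggregated per window (summed over the scans of each 160 ms window),
#' written with `scan_index = 0`; the timing constants (scan time,
#' scans per window, duty cycle, gate time) travel in the
#' `<path>.meta.json` sidecar. On reading, every window must carry the
#' full frequency grid; a missing scan line is reported with its
#' window.
#'
#' @param series an [generate_odmr_series()] tibble.
#' @param path CSV file path.
#'
#' @return `write_odmr()` returns `path` invisibly; `read_odmr()`
#'   returns an `nd_odmr`.
#' @export
write_odmr <- function(series, path) {
  stopifnot(inherits(series, "nd_odmr"))
  lines <- c("window_index,scan_index,freq_MHz,counts",
             sprintf("%d,0,%.12g,%.12g",
                     series$window_index, series$freq_MHz, series$counts))
  writeLines(lines, path)
  timing <- attr(series, "timing")
  model <- attr(series, "model")
  meta <- list(timing = timing,
               model = unclass(model),
               kappa = attr(series, "kappa"),
               seed = attr(series, "seed"),
               noise = attr(series, "noise"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_odmr
#' @export
read_odmr <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, "window_index,scan_index,freq_MHz,counts")) {
    abort(sprintf("Malformed ODMR header: got '%s'.", header))
  }
  d <- read.csv(path)
  if (any(d$counts < 0)) {
    abort(sprintf("Negative counts at data row %d.", which(d$counts < 0)[1]))
  }
  npts <- length(unique(d$freq_MHz))
  per_win <- table(d$window_index)
  short <- names(per_win)[per_win != npts]
  if (length(short)) {
    abort(sprintf("Window %s is missing scan data (%d of %d points).",
                  short[1], per_win[short[1]], npts))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  model <- if (!is.null(meta$model)) {
    do.call(spectrum_model, meta$model)
  } else {
    NULL
  }
  fgrid <- sort(unique(d$freq_MHz))
  out <- tibble(window_index = d$window_index, freq_MHz = d$freq_MHz,
                counts = d$counts)
  structure(out,
            class = c("nd_odmr", class(out)),
            timing = as.list(meta$timing %||%
                               list(scan_time = 2e-3, scans_per_window = 80L,
                                    window_time = 0.16,
                                    duty_cycle_period = 0.2,
                                    gate_time = 1e-5, n_detectors = 2L)),
            model = model,
            kappa = meta$kappa,
            frequency_grid = fgrid,
            window_times = (sort(unique(d$window_index)) - 1) *
              (meta$timing$duty_cycle_period %||% 0.2),
            seed = meta$seed,
            noise = meta$noise)
}

#' Write a dual-modality report to JSON
#'
#' @param report an [run_pipeline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nd_report"))
  payload <- list(
    schema = "diamondsense/dual-modality-report/v1",
    preset = report$preset,
    seed = report$seed,
    alignment = report$alignment,
    temperature = as.list(report$temperature),
    rheology = as.list(report$rheology),
    sensitivity = if (!is.null(report$sensitivity)) {
      as.list(glance(report$sensitivity))
    },
    stages = report$stages
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
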