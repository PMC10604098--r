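#' Hydrodynamic radius from the temperature dependence of diffusion
#'
#' Fits the Stokes-Einstein relation
#' `D(T) = kB T_abs / (6 pi eta(T) r)` to diffusion coefficients
#' measured at several temperatures, with the particle radius `r` as
#' the only free parameter. Writing `D = A(T) / r` with
#' `A(T) = kB T_abs / (6 pi eta(T))`, the model is linear in `u = 1/r`,
#' so the weighted least-squares solution and its standard error are
#' closed-form; positivity of `r` follows from positive `D`. A single
#' temperature point reduces to direct inversion.
#'
#' @param D_by_T a data frame with columns `temperature_C` and
#'   `D_nm2_s` (optionally `se_nm2_s`, used as weights `1/se^2`).
#' @param medium an [medium_model()] supplying `eta(T)`.
#'
#' @return An object of class `nd_stokes_fit` with elements
#'   `radius_nm`, `se_nm`, `data` (augmented with fitted values), and
#'   `medium`. Has [tidy()] and [glance()] methods.
#' @export
stokes_einstein_radius <- function(D_by_T, medium = medium_model()) {
  stopifnot(is.data.frame(D_by_T),
            all(c("temperature_C", "D_nm2_s") %in% names(D_by_T)))
  d <- as_tibble(D_by_T)
  if (nrow(d) < 1L) abort("Need at least one temperature point.")
  if (any(d$D_nm2_s <= 0)) abort("Diffusion coefficients must be positive.")
  eta <- glycerol_viscosity(d$temperature_C, medium, warn = FALSE)
  A <- .kB * (d$temperature_C + 273.15) / (6 * pi * eta) * 1e18 * 1e9
  ## A has units nm^2/s * nm so that D = A / r_nm
  w <- if ("se_nm2_s" %in% names(d) && all(d$se_nm2_s > 0)) {
    1 / d$se_nm2_s^2
  } else {
    rep(1, nrow(d))
  }
  u <- sum(w * A * d$D_nm2_s) / sum(w * A^2)
  if (u <= 0) abort("Fit produced a non-positive 1/r; check inputs.")
  r <- 1 / u
  fitted <- A * u
  n <- nrow(d)
  se_r <- if (n > 1L) {
    s2 <- sum(w * (d$D_nm2_s - fitted)^2) / (n - 1L)
    se_u <- sqrt(s2 / sum(w * A^2))
    se_u / u^2
  } else {
    NA_real_
  }
  structure(list(radius_nm = r, se_nm = se_r,
                 data = mutate(d, fitted_D_nm2_s = fitted),
                 medium = medium),
            class = "nd_stokes_fit")
}

#' @export
print.nd_stokes_fit <- function(x, ...) {
  cat(sprintf("<nd_stokes_fit> hydrodynamic radius %.2f nm (se %.2f) from %d temperature points\n",
              x$radius_nm, x$se_nm, nrow(x$data)))
  invisible(x)
}

#' Tidy a Stokes-Einstein radius fit
#' @param x an `nd_stokes_fit`.
#' @param ... unused.
#' @return One row per parameter with estimate and standard error.
#' @export
tidy.nd_stokes_fit <- function(x, ...) {
  tibble(term = "radius_nm", estimate = x$radius_nm, std.error = x$se_nm)
}

#' Glance at a Stokes-Einstein radius fit
#' @param x an `nd_stokes_fit`.
#' @param ... unused.
#' @export
glance.nd_stokes_fit <- function(x, ...) {
  tibble(radius_nm = x$radius_nm, se_nm = x$se_nm, n_temps = nrow(x$data),
         rmse_nm2_s = sqrt(mean((x$data$D_nm2_s - x$data$fitted_D_nm2_s)^2)))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
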