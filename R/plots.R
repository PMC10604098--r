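#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplot2 figures for every major
#' result type: trajectories (transverse-plane path), MSD curves
#' (log-log with error ribbons), complex moduli (G' and G'' against
#' frequency), PSDs, Allan-deviation sensitivity (with the white-noise
#' region and the Cramer-Rao bound when benchmarked), motion segments
#' (path coloured by label) and exponent distributions (histogram with
#' the fitted normal).
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name diamondsense-plots
NULL

#' @rdname diamondsense-plots
#' @export
autoplot.nd_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$x_nm, y = .data$y_nm, colour = .data$t_s)) +
    geom_path() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", colour = "t (s)")
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_msd <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$tau_s, y = .data$msd_um2)) +
    geom_point(aes(shape = .data$flag)) +
    geom_line(alpha = 0.4) +
    scale_x_log10() + scale_y_log10() +
    labs(x = expression(tau ~ "(s)"), y = expression(MSD ~ (mu * m^2)),
         shape = NULL)
  if (any(is.finite(object$error_um2))) {
    p <- p + geom_ribbon(aes(ymin = pmax(.data$msd_um2 - .data$error_um2,
                                         .Machine$double.xmin),
                             ymax = .data$msd_um2 + .data$error_um2),
                         alpha = 0.2)
  }
  p
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_modulus <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[, c("f_hz", "G_prime_Pa", "G_double_prime_Pa")],
    cols = c("G_prime_Pa", "G_double_prime_Pa"),
    names_to = "component", values_to = "G_Pa")
  ggplot(d, aes(x = .data$f_hz, y = .data$G_Pa, colour = .data$component)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() + scale_y_log10() +
    scale_colour_manual(values = c(G_prime_Pa = "#00b3b3",
                                   G_double_prime_Pa = "#3366cc"),
                        labels = c(G_prime_Pa = "G' (elastic)",
                                   G_double_prime_Pa = "G'' (viscous)")) +
    labs(x = "f (Hz)", y = "G (Pa)", colour = NULL)
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_psd <- function(object, ...) {
  ggplot(object, aes(x = .data$f_hz, y = .data$psd_total_um2_hz)) +
    geom_line() +
    geom_vline(xintercept = attr(object, "readout_hz"), linetype = 3) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "f (Hz)", y = expression(PSD ~ (mu * m^2 / Hz)))
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_sensitivity <- function(object, ...) {
  d <- object$allan
  p <- ggplot(d, aes(x = .data$tau_s, y = .data$adev)) +
    geom_line() +
    geom_point(aes(colour = .data$white_noise)) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "accumulation time (s)", y = expression(sigma[A] ~ (K)),
         colour = "white-noise region")
  if (!is.null(object$crb_K_rtHz) && is.finite(object$crb_K_rtHz)) {
    p <- p + geom_line(aes(y = object$crb_K_rtHz / sqrt(.data$tau_s)),
                       linetype = 2)
  }
  p
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_segments <- function(object, ...) {
  ggplot(object,
         aes(xmin = .data$start_s, xmax = .data$end_s,
             ymin = 0, ymax = 1, fill = .data$label)) +
    geom_rect(alpha = 0.7) +
    labs(x = "t (s)", y = NULL, fill = NULL) +
    theme(axis.text.y = element_blank(), axis.ticks.y = element_blank())
}

#' @rdname diamondsense-plots
#' @export
autoplot.nd_alpha_dist <- function(object, ...) {
  d <- tibble(alpha = object$alphas)
  grid <- tibble(alpha = seq(min(d$alpha) - 0.2, max(d$alpha) + 0.2,
                             length.out = 200))
  grid$density <- dnorm(grid$alpha, object$fitted_mean, object$fitted_sd)
  ggplot(d, aes(x = .data$alpha)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 20,
                   fill = "grey80", colour = "grey40") +
    geom_line(data = grid, aes(y = .data$density)) +
    geom_vline(xintercept = 1, linetype = 3) +
    labs(x = expression(alpha), y = "density")
}

#' Temperature-trace plot
#'
#' @param trace an `nd_temperature` tibble from [shift_to_temperature()].
#' @return A ggplot.
#' @export
plot_temperature <- function(trace) {
  stopifnot(inherits(trace, "nd_temperature"))
  ggplot(trace, aes(x = .data$t_s, y = .data$dT_C)) +
    geom_ribbon(aes(ymin = .data$dT_C - .data$se_C,
                    ymax = .data$dT_C + .data$se_C), alpha = 0.25) +
    geom_line() +
    labs(x = "t (s)", y = expression(Delta * T ~ (degree * C)))
}
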