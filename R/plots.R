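#' Plot an SNR-versus-depth profile
#'
#' Depth on the x axis, SNR on a log y axis, with the detection limit as a
#' horizontal dotted line.
#'
#' @param object A `depth_profile`.
#' @param snr_threshold Detection limit to draw.
#' @param ... Ignored.
#' @export
autoplot.depth_profile <- function(object, snr_threshold = 3, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$depth_um, y = .data$snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = snr_threshold, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "imaging depth (µm)", y = "SNR",
                  title = attr(object, "channel")) +
    ggplot2::theme_minimal()
}

#' Plot a power-law fit on log-log axes
#'
#' @param object A `power_law_fit`.
#' @param ... Ignored.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(energy_nj = exp(seq(log(min(dat$energy_nj)),
                                     log(max(dat$energy_nj)),
                                     length.out = 100)))
  grid$s <- object$a * grid$energy_nj^object$n
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$energy_nj, y = .data$s)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$s - .data$s_err,
                   ymax = .data$s + .data$s_err), width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pulse energy E (nJ)", y = "normalized emission S",
                  subtitle = sprintf("S = A·E^n, n = %.2f ± %.2f",
                                     object$n, object$n_se)) +
    ggplot2::theme_minimal()
}

#' Plot an attenuation fit
#'
#' Normalized signal versus depth on a log y axis with the fitted single
#' exponential.
#'
#' @param object An `attenuation_fit`.
#' @param ... Ignored.
#' @export
autoplot.attenuation_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(depth_um = seq(min(dat$depth_um), max(dat$depth_um),
                                length.out = 100))
  grid$s_norm <- object$a * exp(-grid$depth_um / object$l_e_um)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$depth_um, y = .data$s_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "black") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "imaging depth z (µm)", y = "normalized signal S",
                  subtitle = sprintf("l_e = %.0f ± %.0f µm",
                                     object$l_e_um, object$l_e_se)) +
    ggplot2::theme_minimal()
}

#' Plot per-frame response fractions
#'
#' @param object An `area_response`.
#' @param exposure_window Optional frame range to shade.
#' @param ... Ignored.
#' @export
autoplot.area_response <- function(object, exposure_window = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$frame, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "responding area fraction") +
    ggplot2::theme_minimal()
  if (!is.null(exposure_window)) {
    p <- p + ggplot2::annotate("rect", xmin = min(exposure_window),
                               xmax = max(exposure_window),
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}
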