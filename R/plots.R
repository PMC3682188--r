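## ggplot2 presentation methods for the result types.

#' @export
autoplot.order_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = atan2(.data$y, .data$x),
                                       colour = .data$s)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_gradient(low = "red", high = "blue", limits = c(0, 1),
                                   name = "local order") +
    ggplot2::labs(x = "axial position (nm)", y = "azimuth (rad)",
                  title = sprintf("Local orientational order (global mean %.3f)",
                                  attr(object, "global")))
}

#' @export
autoplot.order_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$global_order)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "step", y = "global mean local order",
                  subtitle = if (attr(object, "converged")) "converged" else "not converged")
}

#' @export
autoplot.spectrum_pair <- function(object, ...) {
  df <- tidyr::pivot_longer(object$spectra, c("full_labeled", "spin_diluted"),
                            names_to = "labeling", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$field, y = .data$amplitude,
                                   colour = .data$labeling)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "field (G)", y = "dA/dB (a.u.)")
}

#' Plot an accessibility profile with its fitted periodicity
#'
#' @param profile Tibble `residue`, `phi`.
#' @param fit Optional [fit_periodicity()] result to overlay.
#' @return A ggplot object.
#' @export
plot_accessibility <- function(profile, fit = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue, y = .data$phi)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "residue", y = expression(Phi))
  if (!is.null(fit)) {
    xs <- seq(min(profile$residue), max(profile$residue), length.out = 200)
    ys <- fit$amplitude * cos(2 * pi * xs / fit$period + fit$phase) + fit$offset
    p <- p + ggplot2::geom_line(data = tibble(residue = xs, phi = ys),
                                colour = "magenta")
  }
  p
}

#' Plot a helicity sweep of the interfacial partitioning free energy
#'
#' @param sweep Tibble from [helicity_sweep()].
#' @return A ggplot object.
#' @export
plot_helicity_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$helicity, y = .data$dg_total)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "helicity", y = expression(Delta * G ~ "(kcal/mol)"))
}

#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = attr(object, "mean_depth"), colour = "red") +
    ggplot2::labs(x = "insertion depth below headgroup shell (nm)", y = "count")
}
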