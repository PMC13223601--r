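#' Plot a simulated HomMTM spectrum
#'
#' Peaks as vertical segments coloured by provenance (sound peaks of each
#' isoform, shared sound peaks, noise).
#'
#' @param object A [simulate_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_spectrum <- function(object, ...) {
  pk <- object$peaks
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$mass, xend = .data$mass,
                                   y = 0, yend = .data$intensity,
                                   colour = .data$label)) +
    ggplot2::geom_segment(linewidth = 0.6) +
    ggplot2::labs(x = "prefix mass (Da)", y = "intensity", colour = NULL,
                  title = sprintf("Simulated HomMTM spectrum (%g:%g)",
                                  object$a1, object$a2)) +
    ggplot2::theme_minimal()
}

#' Plot benchmark accuracy against abundance ratio
#'
#' Three series per ratio: identification accuracy (both ground-truth
#' isoforms recovered), fraction of spectra with two isoforms called, and
#' fraction with one.
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hommtm_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("accuracy", "frac_two", "frac_one"),
                              names_to = "series", values_to = "fraction")
  long$series <- factor(long$series, c("accuracy", "frac_two", "frac_one"),
                        c("both ground-truth isoforms", "two isoforms called",
                          "one isoform called"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a1, y = .data$fraction,
                                     colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "minor-isoform abundance (a1 of a1:100-a1)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an identification against its spectrum
#'
#' Observed peaks (grey) with the fitted theoretical intensities of the
#' identified isoform(s) overlaid at their matched, corrected positions.
#'
#' @param object An `isoform_quant` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isoform_quant <- function(object, ...) {
  if (object$status != "ok") stop("nothing to plot: no isoform identified")
  al <- object$alignments
  scale <- al$P1$scale
  obs <- tibble::tibble(mass = al$P1$smg_peaks$mass / scale,
                        intensity = al$P1$smg_peaks$intensity)
  fit <- dplyr::bind_rows(
    tibble::tibble(mass = al$P1$nodes$corrected / scale, q = object$q1,
                   isoform = object$isoforms$isoform[1]),
    tibble::tibble(mass = al$P2$nodes$corrected / scale, q = object$q2,
                   isoform = object$isoforms$isoform[min(2, nrow(object$isoforms))])
  )
  fit <- fit[fit$mass > 0, , drop = FALSE]
  fit <- dplyr::summarise(dplyr::group_by(fit, .data$mass, .data$isoform),
                          q = sum(unique(.data$q)), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = obs[obs$mass > 0, ],
                          ggplot2::aes(x = .data$mass, xend = .data$mass,
                                       y = 0, yend = .data$intensity),
                          colour = "grey55", linewidth = 0.7) +
    ggplot2::geom_point(data = fit,
                        ggplot2::aes(x = .data$mass, y = .data$q,
                                     colour = .data$isoform), shape = 95, size = 6) +
    ggplot2::labs(x = "prefix mass (Da)", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
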