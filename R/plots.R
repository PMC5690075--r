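#' Plot a depth-dose curve or profile
#'
#' @param object A `pristine_curve`, `dose_profile`, `sobp_plan` or `dvh`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot pristine_curve
#' @export
autoplot.pristine_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth, y = .data$dose)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "depth in water [mm]", y = "relative dose",
                  title = sprintf("Pristine Bragg curve, %.5g MeV",
                                  attr(object, "energy"))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot sobp_plan
#' @export
autoplot.sobp_plan <- function(object, ...) {
  layers <- purrr::imap_dfr(object$curves, function(cv, i) {
    tibble::tibble(depth = cv$depth,
                   dose = cv$dose / max(cv$dose) * object$layers$weight[i],
                   layer = factor(i))
  })
  ggplot2::ggplot(layers,
                  ggplot2::aes(x = .data$depth, y = .data$dose,
                               group = .data$layer)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$layer),
                       show.legend = FALSE, alpha = 0.6) +
    ggplot2::geom_line(data = object$sobp, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::labs(x = "depth in water [mm]", y = "relative dose",
                  title = "Spread-out Bragg peak and constituent layers") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot dose_profile
#' @export
autoplot.dose_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$coordinate, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s [mm]", attr(object, "axis")),
                  y = "relative dose") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot dvh
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold,
                               y = .data$volume_fraction,
                               colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative dose threshold", y = "volume fraction [%]",
                  title = "Cumulative dose-volume histogram") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the transverse FWHM along the beamline
#'
#' Compares the moment-transport prediction with the measured benchmark
#' values at the published planes.
#'
#' @param energy One of the benchmark energies.
#' @return A ggplot object.
#' @export
plot_fwhm_validation <- function(energy = 81.56) {
  src <- cnao_source(energy)
  lay <- build_standard_layout(energy)
  meas <- dplyr::filter(cnao_fwhm_table(), .data$energy == !!energy)
  planes <- seq(-1093.6, 500, by = 25)
  pred <- tibble::tibble(position = planes,
                         fwhm = fwhm_at(lay, src, planes))
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$position, y = .data$fwhm)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(data = meas, colour = "#b2182b", size = 2) +
    ggplot2::labs(x = "beamline position [mm]", y = "FWHM [mm]",
                  title = sprintf("Transverse beam size, %.5g MeV", energy),
                  subtitle = "line: moment transport; points: measured") +
    ggplot2::theme_minimal()
}
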