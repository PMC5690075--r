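#' Published beamline calibration tables
#'
#' The benchmark measurements for the synchrotron proton line that every
#' calibration in this package starts from: `cnao_range_table()` gives the
#' measured and Monte-Carlo proton ranges in water at the four reference
#' energies; `cnao_fwhm_table()` gives the measured transverse FWHM at five
#' planes along the transport line (positions in mm, isocenter at 0, upstream
#' negative) for the same energies.
#'
#' @return A tibble.
#' @export
cnao_range_table <- function() {
  tibble::tribble(
    ~energy, ~range_measured, ~range_mc,
    81.56,   50.00,           49.65,
    100.51,  74.00,           73.60,
    119.05,  101.00,          100.65,
    148.80,  151.00,          150.65
  )
}

#' @rdname cnao_range_table
#' @export
cnao_fwhm_table <- function() {
  tidyr::expand_grid(
    position = c(-1093.6, -654.6, -350.0, 0.0, 500.0),
    energy = c(81.56, 100.51, 119.05, 148.80)
  ) |>
    dplyr::mutate(fwhm = c(
      5.48, 5.60, 5.50, 4.05,
      8.35, 7.24, 6.60, 5.65,
      12.52, 10.46, 9.13, 7.44,
      16.39, 13.63, 11.25, 9.80,
      24.52, 20.64, 17.70, 14.15
    ))
}

#' Fit a power-law range-energy model
#'
#' Protons of kinetic energy E (MeV) have a range in water well described by
#' the Bragg-Kleeman rule `R = alpha * E^p` over therapeutic energies. The
#' fit is an ordinary least-squares line in log-log space.
#'
#' @param points A data frame (or tibble) with columns `energy` (MeV) and
#'   `range` (mm), or a two-column matrix in that order.
#' @return An object of class `range_energy_model` with elements `alpha`
#'   (mm / MeV^p), `p`, and `calibration` (the input points with fitted
#'   values). Supports [tidy()] and [glance()].
#' @examples
#' m <- fit_range_energy(data.frame(energy = c(81.56, 119.05, 148.8),
#'                                  range = c(50, 101, 151)))
#' range_in_water(m, 100.51)
#' @export
fit_range_energy <- function(points) {
  if (is.matrix(points)) {
    points <- tibble::tibble(energy = points[, 1], range = points[, 2])
  }
  if (is.data.frame(points) && !all(c("energy", "range") %in% names(points)) &&
      ncol(points) >= 2) {
    names(points)[1:2] <- c("energy", "range")
  }
  points <- tibble::as_tibble(points)
  if (nrow(points) < 2) {
    stop("need at least 2 calibration points", call. = FALSE)
  }
  if (any(points$energy <= 0) || any(points$range <= 0)) {
    stop("energies and ranges must be positive", call. = FALSE)
  }
  if (anyDuplicated(points$energy)) {
    stop("calibration energies must be distinct", call. = FALSE)
  }
  fit <- stats::lm(log(range) ~ log(energy), data = points)
  alpha <- exp(stats::coef(fit)[[1]])
  p <- stats::coef(fit)[[2]]
  calibration <- dplyr::mutate(
    points,
    fitted = alpha * .data$energy^p,
    rel_error = (.data$fitted - .data$range) / .data$range
  )
  structure(
    list(alpha = alpha, p = p, calibration = calibration),
    class = "range_energy_model"
  )
}

#' The range-energy model calibrated on the published range table
#'
#' Convenience wrapper: [fit_range_energy()] on the measured column of
#' [cnao_range_table()]. Cached for the session.
#'
#' @return A `range_energy_model`.
#' @export
cnao_range_model <- function() {
  if (is.null(.oculardose_cache$cnao_model)) {
    tab <- cnao_range_table()
    .oculardose_cache$cnao_model <- fit_range_energy(
      tibble::tibble(energy = tab$energy, range = tab$range_measured)
    )
  }
  .oculardose_cache$cnao_model
}

.oculardose_cache <- new.env(parent = emptyenv())

#' Evaluate or invert the range-energy law
#'
#' `range_in_water()` returns `alpha * E^p`; `energy_for_range()` inverts it.
#' Energies far outside the calibration interval (beyond 0.5x-1.5x its
#' bounds) trigger an extrapolation warning.
#'
#' @param model A `range_energy_model`.
#' @param energy Kinetic energy, MeV.
#' @param range Range in water, mm.
#' @return Range in mm (or energy in MeV).
#' @export
range_in_water <- function(model, energy) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(energy <= 0)) stop("energy must be positive", call. = FALSE)
  lo <- 0.5 * min(model$calibration$energy)
  hi <- 1.5 * max(model$calibration$energy)
  if (any(energy < lo | energy > hi)) {
    warning("energy outside [0.5x, 1.5x] the calibration interval; ",
            "extrapolating the power law", call. = FALSE)
  }
  model$alpha * energy^model$p
}

#' @rdname range_in_water
#' @export
energy_for_range <- function(model, range) {
  stopifnot(inherits(model, "range_energy_model"))
  if (any(range <= 0)) stop("range must be positive", call. = FALSE)
  (range / model$alpha)^(1 / model$p)
}

#' @export
print.range_energy_model <- function(x, ...) {
  cat(sprintf("<range_energy_model> R = %.5g * E^%.4f (R in mm, E in MeV)\n",
              x$alpha, x$p))
  cat(sprintf("  %d calibration points, max |rel error| %.3g%%\n",
              nrow(x$calibration), 100 * max(abs(x$calibration$rel_error))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted range-energy model
#'
#' @param x A `range_energy_model`.
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter (`alpha`, `p`);
#'   `glance()` returns a one-row summary with the calibration size and the
#'   worst relative calibration error.
#' @method tidy range_energy_model
#' @export
tidy.range_energy_model <- function(x, ...) {
  tibble::tibble(term = c("alpha", "p"), estimate = c(x$alpha, x$p))
}

#' @rdname tidy.range_energy_model
#' @method glance range_energy_model
#' @export
glance.range_energy_model <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$calibration),
    max_abs_rel_error = max(abs(x$calibration$rel_error)),
    energy_min = min(x$calibration$energy),
    energy_max = max(x$calibration$energy)
  )
}
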