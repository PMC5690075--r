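## Gauss-Legendre nodes/weights on [0, 1], cached per order.
.gauss_legendre_01 <- function(n) {
  key <- paste0("gl", n)
  got <- .oculardose_cache[[key]]
  if (!is.null(got)) return(got)
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(j, j + 1)] <- b
  A[cbind(j + 1, j)] <- b
  e <- eigen(A, symmetric = TRUE)
  out <- list(x = (rev(e$values) + 1) / 2,
              w = rev(2 * e$vectors[1, ]^2) / 2)
  .oculardose_cache[[key]] <- out
  out
}

## Range-straggling sigma (mm) of a beam whose total water-equivalent range
## is R mm: the usual sigma ~ 0.012 * R[cm]^0.935 parameterisation.
straggling_sigma <- function(range_mm) {
  10 * 0.012 * (range_mm / 10)^0.935
}

## Depth-dose shape: a proton with residual range R deposits
## s(R - z) = (R - z)^(1/p - 1) per unit depth (the rising stopping power of
## the Bragg-Kleeman rule); range straggling smears R with a Gaussian.
## The substitution u = (R' - z)^(1/p) removes the integrable singularity, so
## a modest Gauss-Legendre rule converges fast:
##   D(z) = p * int_0^Umax phi(z + u^p; R0, sigma) du .
.bragg_dose <- function(z, range_mm, sigma, p, n_quad = 48) {
  gq <- .gauss_legendre_01(n_quad)
  umax <- pmax(range_mm + 5 * sigma - z, 0)^(1 / p)
  nz <- length(z)
  ## outer-product evaluation: rows = depths, cols = quadrature nodes
  u <- outer(umax, gq$x)
  val <- stats::dnorm(z + u^p, mean = range_mm, sd = sigma)
  p * umax * drop(val %*% gq$w)
}

#' Analytic pristine Bragg curve
#'
#' Builds the depth-dose curve of a single energy in water from the power-law
#' range-energy rule plus Gaussian range straggling. The straggling width
#' combines, in quadrature: intrinsic straggling of the full water-equivalent
#' path (`0.012 * R_cm^0.935` cm, with R the *total* range including any
#' upstream degrader), the range spread induced by the relative energy spread
#' of the source (`dR/dE * sigmaE`), and `extra_straggle`.
#'
#' The quoted `range_water` is the depth of the distal 80% dose point, which
#' for this engine coincides with `alpha * E^p` to well under 0.5%.
#'
#' @param energy Beam kinetic energy, MeV (energy *entering the water*, i.e.
#'   the residual energy after any degrader).
#' @param sigmaE_rel Relative energy spread of the source (default 5e-4).
#' @param extra_straggle Additional range-straggling sigma in mm, added in
#'   quadrature (e.g. from an upstream degrader when `total_range` is not
#'   given).
#' @param grid Depth samples in mm (monotone increasing). Defaults to a
#'   0.05 mm grid reaching past the range.
#' @param model Range-energy model (default [cnao_range_model()]).
#' @param total_range Total water-equivalent range in mm used for the
#'   intrinsic straggling term; defaults to the beam's own range. Pass
#'   degrader WET + residual range when the beam has been degraded upstream.
#' @return A `pristine_curve`: a tibble with columns `depth` (mm) and `dose`
#'   (relative, peak-normalised), with attributes `energy`, `range_water`,
#'   `sigma_straggle`.
#' @export
pristine_depth_dose <- function(energy, sigmaE_rel = 5e-4, extra_straggle = 0,
                                grid = NULL, model = cnao_range_model(),
                                total_range = NULL) {
  if (!is.numeric(energy) || length(energy) != 1 || energy <= 0) {
    stop("energy must be a positive number", call. = FALSE)
  }
  if (extra_straggle < 0) stop("extra_straggle must be >= 0", call. = FALSE)
  r0 <- range_in_water(model, energy)
  if (is.null(total_range)) total_range <- r0
  sig_e <- model$p * r0 / energy * (sigmaE_rel * energy)
  sigma <- sqrt(straggling_sigma(total_range)^2 + sig_e^2 + extra_straggle^2)
  if (is.null(grid)) grid <- seq(0, r0 + 6 * sigma + 1, by = 0.05)
  if (length(grid) == 0) stop("depth grid is empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("depth grid must be strictly increasing", call. = FALSE)
  }
  dose <- .bragg_dose(grid, r0, sigma, model$p)
  dose <- dose / max(dose)
  out <- tibble::tibble(depth = grid, dose = dose)
  structure(out,
            class = c("pristine_curve", class(out)),
            energy = energy, range_water = r0, sigma_straggle = sigma)
}

#' Interpolate a depth-dose curve
#'
#' Linear interpolation of a [pristine_depth_dose()] curve (or any
#' depth/dose tibble); zero outside the sampled grid.
#'
#' @param curve A `pristine_curve` (or tibble with `depth`, `dose`).
#' @param depth Depths (mm) at which to evaluate.
#' @return Numeric vector of relative dose.
#' @export
curve_dose_at <- function(curve, depth) {
  stats::approx(curve$depth, curve$dose, xout = depth, rule = 2,
                yleft = 0, yright = 0)$y
}

#' Measured depth of the distal 80% dose point
#'
#' Finds the deepest crossing of 80% of the curve maximum by linear
#' interpolation; the operational "range" of a Bragg curve.
#'
#' @param curve A depth/dose tibble.
#' @param level Fraction of the maximum (default 0.8).
#' @return Depth in mm.
#' @export
distal_depth <- function(curve, level = 0.8) {
  d <- curve$dose
  thr <- level * max(d)
  i <- max(which(d >= thr))
  if (i >= length(d)) return(curve$depth[i])
  stats::approx(d[c(i, i + 1)], curve$depth[c(i, i + 1)], xout = thr)$y
}

#' Export a depth-dose curve as a two-column CSV
#'
#' @param curve A depth/dose tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(depth_mm = curve$depth, dose = curve$dose),
    path, row.names = FALSE
  )
  invisible(path)
}
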