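#' Dose profiles
#'
#' A profile is a tibble with strictly increasing `coordinate` (mm) and
#' non-negative `value` columns plus an `axis` attribute (`"depth"`, `"y"`
#' or `"z"`).
#'
#' @param coordinate Sample positions, mm.
#' @param value Relative dose values.
#' @param axis One of `"depth"`, `"y"`, `"z"`.
#' @return A `dose_profile` tibble.
#' @export
dose_profile <- function(coordinate, value, axis = c("depth", "y", "z")) {
  axis <- match.arg(axis)
  if (is.unsorted(coordinate, strictly = TRUE)) {
    stop("coordinates must be strictly increasing", call. = FALSE)
  }
  if (any(value < 0)) stop("profile values must be >= 0", call. = FALSE)
  out <- tibble::tibble(coordinate = coordinate, value = value)
  structure(out, class = c("dose_profile", class(out)), axis = axis)
}

## First/last crossing of a level, by linear interpolation. side = "left"
## scans from the low-coordinate end, "right" from the high end.
.crossing <- function(coordinate, value, level, side) {
  above <- which(value >= level)
  if (length(above) == 0 || length(above) == length(value)) return(NA_real_)
  if (side == "left") {
    i <- min(above)
    if (i == 1) return(NA_real_)
    idx <- c(i - 1, i)
  } else {
    i <- max(above)
    if (i == length(value)) return(NA_real_)
    idx <- c(i, i + 1)
  }
  v <- value[idx]
  if (diff(v) == 0) return(mean(coordinate[idx]))
  coordinate[idx[1]] + (level - v[1]) / (v[2] - v[1]) * diff(coordinate[idx])
}

#' Full width at half maximum of a profile
#'
#' Linear-interpolated distance between the outermost half-maximum
#' crossings.
#'
#' @param profile A [dose_profile()] (or tibble with `coordinate`, `value`).
#' @return Width in mm.
#' @export
fwhm <- function(profile) {
  half <- max(profile$value) / 2
  l <- .crossing(profile$coordinate, profile$value, half, "left")
  r <- .crossing(profile$coordinate, profile$value, half, "right")
  if (is.na(l) || is.na(r)) {
    stop("profile never crosses half maximum on both sides", call. = FALSE)
  }
  r - l
}

#' 80-20% lateral penumbra of a field edge
#'
#' Distance between the 80% and 20% crossings of the central plateau value
#' on one side of the field.
#'
#' @param profile A [dose_profile()].
#' @param side `"left"` or `"right"`.
#' @param central Reference value; defaults to the value at the coordinate
#'   closest to 0 (the field centre).
#' @return Penumbra width in mm.
#' @export
penumbra_80_20 <- function(profile, side = c("right", "left"),
                           central = NULL) {
  side <- match.arg(side)
  if (is.null(central)) {
    central <- profile$value[which.min(abs(profile$coordinate))]
  }
  c80 <- .crossing(profile$coordinate, profile$value, 0.8 * central, side)
  c20 <- .crossing(profile$coordinate, profile$value, 0.2 * central, side)
  if (is.na(c80) || is.na(c20)) {
    stop("profile does not cross both the 80% and 20% levels on that side",
         call. = FALSE)
  }
  abs(c20 - c80)
}

#' Plateau uniformity of a scanned-field profile
#'
#' Spread of the dose values inside the central region where the dose
#' exceeds 80% of the central value, expressed in percent. The default
#' estimator is the robust Gaussian-equivalent spread
#' `100 * 1.4826 * MAD / median`: the plateau values of a scanned field are
#' distributed like a Gaussian around the plateau level, and a robust scale
#' keeps the figure representative of that Gaussian when the tail of the
#' penumbra shoulder enters the >= 80% window (see the methods vignette).
#' `method = "sd"` gives `100 * sd/mean`, `method = "range"` gives
#' `100 * (max - min)/(max + min)`.
#'
#' @param profile A [dose_profile()].
#' @param method `"mad"` (default), `"sd"` or `"range"`.
#' @return Uniformity in percent.
#' @export
transverse_uniformity <- function(profile, method = c("mad", "sd", "range")) {
  method <- match.arg(method)
  central <- profile$value[which.min(abs(profile$coordinate))]
  v <- profile$value[profile$value >= 0.8 * central]
  if (length(v) < 3) stop("plateau region is empty", call. = FALSE)
  switch(method,
    mad = 100 * 1.4826 * stats::mad(v, constant = 1) / stats::median(v),
    sd = 100 * stats::sd(v) / mean(v),
    range = 100 * (max(v) - min(v)) / (max(v) + min(v))
  )
}

#' Spread-out Bragg peak metrics
#'
#' Width, distal falloff, entrance ratio and flatness of a depth-dose
#' profile containing an SOBP. The plateau is the span between the
#' shallowest and the deepest constituent peak if the plan is supplied, or
#' between the outermost crossings of 95% of the profile maximum otherwise.
#' Metrics:
#' \describe{
#'   \item{width}{distance between the proximal and distal crossings of
#'     `width_level` x plateau mean (default 98%).}
#'   \item{distal_falloff_80_20}{distal distance from 80% to 20% of the
#'     plateau mean.}
#'   \item{entrance_plateau_ratio}{100 x dose at the first sample /
#'     plateau mean.}
#'   \item{flatness}{100 x (max - min)/(max + min) over the plateau span.}
#' }
#'
#' @param depth_profile A depth [dose_profile()] (or tibble `coordinate`,
#'   `value`; a `pristine_curve`'s `depth`/`dose` columns are accepted too).
#' @param width_level Fraction of the plateau mean defining the width
#'   crossings (default 0.98; see the methods vignette for why not 0.95).
#' @param plateau_span Optional `c(lo, hi)` depth span of the plateau, mm.
#' @return A one-row tibble of class `sobp_metrics`.
#' @export
sobp_metrics <- function(depth_profile, width_level = 0.98,
                         plateau_span = NULL) {
  if (all(c("depth", "dose") %in% names(depth_profile))) {
    depth_profile <- tibble::tibble(coordinate = depth_profile$depth,
                                    value = depth_profile$dose)
  }
  x <- depth_profile$coordinate
  v <- depth_profile$value
  if (is.null(plateau_span)) {
    lev95 <- 0.95 * max(v)
    plateau_span <- c(.crossing(x, v, lev95, "left"),
                      .crossing(x, v, lev95, "right"))
    if (anyNA(plateau_span)) {
      stop("cannot locate a plateau in the profile", call. = FALSE)
    }
  }
  sel <- x >= plateau_span[1] & x <= plateau_span[2]
  if (!any(sel)) stop("plateau span contains no samples", call. = FALSE)
  plateau <- mean(v[sel])
  wl <- .crossing(x, v, width_level * plateau, "left")
  wr <- .crossing(x, v, width_level * plateau, "right")
  f80 <- .crossing(x, v, 0.80 * plateau, "right")
  f20 <- .crossing(x, v, 0.20 * plateau, "right")
  if (anyNA(c(wl, wr, f80, f20))) {
    stop("profile does not cross the required levels", call. = FALSE)
  }
  out <- tibble::tibble(
    width = wr - wl,
    distal_falloff_80_20 = f20 - f80,
    entrance_plateau_ratio = 100 * v[1] / plateau,
    flatness = 100 * (max(v[sel]) - min(v[sel])) / (max(v[sel]) + min(v[sel])),
    proximal_edge = wl,
    distal_edge = wr,
    plateau_mean = plateau
  )
  class(out) <- c("sobp_metrics", class(out))
  out
}

#' Cumulative dose-volume histograms per structure
#'
#' For every labelled structure, the fraction of its volume receiving at
#' least each dose threshold. Thresholds span 0 to the grid maximum.
#'
#' @param dose A `dose_grid` (see [simulate_dose()]).
#' @param labels A `labeled_grid` sharing the dose grid's geometry; defaults
#'   to the labels stored in `dose`.
#' @param n_thresholds Number of threshold levels (default 201).
#' @param relative Normalise thresholds to the maximum dose (default TRUE).
#' @return A tibble of class `dvh` with columns `structure`, `threshold`,
#'   `volume_fraction` (percent).
#' @export
dvh <- function(dose, labels = NULL, n_thresholds = 201, relative = TRUE) {
  stopifnot(inherits(dose, "dose_grid"))
  if (is.null(labels)) labels <- dose$labels_grid
  if (is.null(labels)) stop("no labels available for the DVH", call. = FALSE)
  if (!identical(dim(dose$dose), dim(labels$labels))) {
    stop("dose and label grids have different geometry", call. = FALSE)
  }
  dmax <- max(dose$dose)
  thr <- seq(0, dmax, length.out = n_thresholds)
  lab <- as.integer(labels$labels)
  structs <- labels$structures
  res <- purrr::map_dfr(seq_along(structs), function(i) {
    sel <- lab == i
    n <- sum(sel)
    if (n == 0) return(NULL)
    dv <- dose$dose[sel]
    frac <- 100 * vapply(thr, function(t) mean(dv >= t), 0)
    tibble::tibble(structure = structs[i],
                   threshold = if (relative && dmax > 0) thr / dmax else thr,
                   volume_fraction = frac)
  })
  class(res) <- c("dvh", class(res))
  res
}

#' Volume fraction of a structure above a threshold
#'
#' @param dvh_tbl A [dvh()] result.
#' @param structure Structure name.
#' @param threshold Threshold (same scale as the DVH abscissa).
#' @return Percent of the structure volume at or above `threshold`.
#' @export
dvh_fraction_at <- function(dvh_tbl, structure, threshold) {
  d <- dvh_tbl[dvh_tbl$structure == structure, ]
  if (nrow(d) == 0) stop("structure not present in the DVH", call. = FALSE)
  stats::approx(d$threshold, d$volume_fraction, xout = threshold,
                rule = 2)$y
}
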