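#' High-level irradiation runs
#'
#' Convenience wrappers assembling the published study setups: beamline,
#' SOBP plan, scan pattern and scoring grid.
#'
#' `irradiate_water()` delivers a plan to a water box centred on the
#' isocenter (the SOBP benchmark). `irradiate_eye()` delivers the ocular
#' field (gaze-rotated eye phantom, range shifter, elliptical collimator,
#' scanned spots) with the phantom aligned in depth so the tumor sits in
#' the SOBP plateau, the range fine-tuning a planner performs via the
#' shifter. `irradiate_dicom()` fires a point-like beam into a (synthetic)
#' CT-derived grid with physical skin-referenced depth (offset 0).
#'
#' @param plan An `sobp_plan` (defaults to the published 10-layer plan for
#'   water, its 6 deepest layers for the eye).
#' @param rs_thickness Range-shifter thickness, mm.
#' @param collimator A [collimator_spec()] or `NULL`.
#' @param scan A [scan_pattern()].
#' @param target Optional pre-built `labeled_grid`.
#' @param mode `"analytic"` or `"mc"`.
#' @param n_primaries Histories for mc mode.
#' @param seed RNG seed (mc mode).
#' @param energy Nominal beam energy, MeV.
#' @return A `dose_grid`.
#' @export
irradiate_water <- function(plan = sobp_plan_for(35.5, 18, 2),
                            rs_thickness = 43, collimator = NULL,
                            scan = scan_pattern(),
                            target = water_box_grid(),
                            mode = "analytic", n_primaries = NULL,
                            seed = NULL, energy = 100.51) {
  lay <- build_ocular_layout(energy, rs_thickness, collimator)
  simulate_dose(lay, plan, scan, target, mode = mode,
                n_primaries = n_primaries, seed = seed)
}

#' @rdname irradiate_water
#' @param eye An `eye_model` (default: reference radius, 40 degree gaze).
#' @param voxel_size Voxel edge for the phantom grid, mm.
#' @param align Align the tumor's water-equivalent depth span onto the
#'   centre of the SOBP plateau (default TRUE).
#' @export
irradiate_eye <- function(eye = build_eye(12.25, 40),
                          plan = sobp_plan_for(35.5, 10, 2),
                          rs_thickness = 43,
                          collimator = collimator_spec(),
                          scan = scan_pattern(),
                          voxel_size = 0.4, target = NULL,
                          mode = "mc", n_primaries = 5e5, seed = NULL,
                          align = TRUE, energy = 100.51) {
  if (is.null(target)) target <- voxelize(eye, voxel_size = voxel_size)
  offset <- cnao_depth_offset()
  if (align) {
    offset <- align_depth_offset(target, plan, structure_name = "tumor")
  }
  lay <- build_ocular_layout(energy, rs_thickness, collimator)
  simulate_dose(lay, plan, scan, target, mode = mode,
                n_primaries = n_primaries, seed = seed,
                depth_offset = offset)
}

#' @rdname irradiate_water
#' @export
irradiate_dicom <- function(target, plan = sobp_plan_for(35.5, 0, 2,
                              degrader_wet = water_equivalent_thickness(
                                beamline_materials()$pmma, 46)),
                            rs_thickness = 46, collimator = NULL,
                            scan = single_spot(), mode = "analytic",
                            n_primaries = NULL, seed = NULL,
                            energy = 100.51) {
  lay <- build_ocular_layout(energy, rs_thickness, collimator)
  ## physical bookkeeping: water-equivalent depth starts at zero at the
  ## upstream face of the CT grid (air voxels contribute ~nothing)
  offset <- -(target$origin[1] - target$voxel_size[1] / 2)
  simulate_dose(lay, plan, scan, target, mode = mode,
                n_primaries = n_primaries, seed = seed,
                depth_offset = offset)
}

#' Depth offset aligning a structure with the SOBP plateau
#'
#' Chooses the reference-plane offset that positions the named structure's
#' water-equivalent depths inside the plan's high-dose region: the range
#' fine-tuning a planner performs when positioning the patient. With
#' `method = "coverage"` (default) the offset maximises the minimum SOBP
#' dose over the structure's depth samples; `method = "center"` simply
#' centres the structure's depth span on the plateau.
#'
#' @param target A `labeled_grid` containing the structure.
#' @param plan An `sobp_plan`.
#' @param structure_name Structure to align (default `"tumor"`).
#' @param method `"coverage"` or `"center"`.
#' @return Offset in mm (water-equivalent).
#' @export
align_depth_offset <- function(target, plan, structure_name = "tumor",
                               method = c("coverage", "center")) {
  method <- match.arg(method)
  B <- .depth_boundaries(target, 0)
  Dmid <- (B[-1, , drop = FALSE] + B[-nrow(B), , drop = FALSE]) / 2
  sel <- as.vector(target$labels) == match(structure_name, target$structures)
  if (!any(sel)) stop("structure '", structure_name, "' not on the grid",
                      call. = FALSE)
  depths <- as.vector(Dmid)[sel]
  plateau <- range(plan$layers$peak_depth)
  center_off <- mean(plateau) - mean(range(depths))
  if (method == "center") return(center_off)
  ## scan offsets around the centred position for the best worst-case dose
  cand <- center_off + seq(-4, 4, by = 0.1)
  ## subsample the structure depths for speed; extremes must be kept
  dsub <- unique(c(range(depths),
                   stats::quantile(depths, seq(0, 1, 0.02), names = FALSE)))
  worst <- vapply(cand, function(off) {
    min(stats::approx(plan$sobp$depth, plan$sobp$dose, xout = dsub + off,
                      rule = 2, yleft = 0, yright = 0)$y)
  }, 0)
  cand[which.max(worst)]
}

## 3-point running mean along one array dimension (edge-replicated).
.smooth_dim <- function(arr, dim) {
  n <- base::dim(arr)[dim]
  idx_lo <- c(1L, seq_len(n - 1L))
  idx_hi <- c(seq_len(n - 1L) + 1L, n)
  pick <- function(i) {
    ix <- rep(list(quote(expr = )), 3)
    ix[[dim]] <- i
    do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
  }
  (pick(idx_lo) + arr + pick(idx_hi)) / 3
}

#' Local-mean smoothing of a dose array
#'
#' Separable 3 x 3 x 3 box average, used when reading voxel-level
#' statistics (such as a minimum target dose) off a Monte-Carlo dose grid
#' whose per-voxel counting noise would otherwise dominate the reading.
#'
#' @param arr 3-D dose array.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_dose3 <- function(arr) {
  .smooth_dim(.smooth_dim(.smooth_dim(arr, 1), 2), 3)
}

#' Prescription iso-level and structure coverage of a dose grid
#'
#' The prescription iso-level is the highest relative dose level at which
#' the named target structure is still fully covered (its minimum dose over
#' the structure, relative to the grid maximum). For Monte-Carlo grids the
#' reading is taken from a locally averaged dose ([smooth_dose3()]); the
#' minimum of a raw sampled grid estimates the noise floor, not the
#' delivered dose. Returns the level plus the DVH volume fractions of every
#' structure at that level.
#'
#' @param dose A `dose_grid` with labelled structures.
#' @param target_structure The planning target (default `"tumor"`).
#' @param smooth Apply [smooth_dose3()] before the reading; defaults to
#'   TRUE for mc grids, FALSE for analytic ones.
#' @return A list with `iso_level` (fraction of max dose) and `coverage`
#'   (tibble of `structure`, `volume_fraction` percent at the iso-level).
#' @export
prescription_coverage <- function(dose, target_structure = "tumor",
                                  smooth = NULL) {
  g <- dose$labels_grid
  if (is.null(smooth)) smooth <- identical(dose$mode, "mc")
  sel <- as.vector(g$labels) == match(target_structure, g$structures)
  if (!any(sel)) stop("target structure missing", call. = FALSE)
  arr <- if (smooth) smooth_dose3(dose$dose) else dose$dose
  dmax <- max(arr)
  iso <- min(arr[array(sel, dim(arr))]) / dmax
  lab <- as.integer(g$labels)
  cov <- purrr::map_dfr(seq_along(g$structures), function(i) {
    s <- lab == i
    if (!any(s)) return(NULL)
    tibble::tibble(structure = g$structures[i],
                   volume_fraction = 100 * mean(arr[s] >= iso * dmax))
  })
  list(iso_level = iso, coverage = cov)
}
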