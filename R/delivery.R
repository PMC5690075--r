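#' Published SOBP layer table
#'
#' The ten energy layers used to build the benchmark 18 mm SOBP behind a
#' 43 mm PMMA range shifter: nominal synchrotron energy, residual range in
#' water (depth of the distal 80% point) and the published weight in
#' percent of the deepest layer's height.
#'
#' @return A tibble with columns `nominal_energy`, `residual_range`,
#'   `weight_pct`.
#' @export
cnao_sobp_layers <- function() {
  tibble::tibble(
    nominal_energy = c(100.51, 99.03, 97.54, 96.04, 94.51, 92.97, 91.41,
                       89.82, 88.22, 86.59),
    residual_range = seq(35.5, 17.5, by = -2),
    weight_pct = c(90.00, 32.10, 25.60, 21.00, 18.24, 15.66, 14.00, 13.00,
                   11.00, 10.00)
  )
}

#' Reference-plane depth offset of the published SOBP
#'
#' The published residual ranges (35.5 mm for the deepest layer) and the
#' published SOBP extent about the isocenter (-8.9 to +9.2 mm) imply that
#' ranges are booked from a reference plane 35.5 - 9.2 = 26.3 mm
#' water-equivalent upstream of the isocenter. Dose lookups use this offset
#' so the delivered SOBP lands at the published position.
#'
#' @return Offset in mm (water-equivalent).
#' @export
cnao_depth_offset <- function() 35.5 - 9.2

#' Select SOBP energy layers
#'
#' Layers are placed at residual ranges `distal_range`, `distal_range -
#' spacing`, ... until `sobp_width` is covered; nominal energies are
#' obtained by inverting the range-energy law through the degrader's
#' water-equivalent thickness.
#'
#' @param distal_range Residual range of the deepest layer, mm water.
#' @param sobp_width Width to cover, mm (0 gives a single layer).
#' @param spacing Layer spacing, mm (default 2).
#' @param degrader_wet Water-equivalent thickness of the upstream degrader,
#'   mm (default: the calibrated 43 mm PMMA shifter).
#' @param model Range-energy model.
#' @return Tibble with `nominal_energy`, `residual_range`, ordered deepest
#'   first.
#' @export
select_energy_layers <- function(distal_range, sobp_width, spacing = 2,
                                 degrader_wet = NULL,
                                 model = cnao_range_model()) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (sobp_width < 0) stop("sobp_width must be >= 0", call. = FALSE)
  if (is.null(degrader_wet)) {
    degrader_wet <- water_equivalent_thickness(beamline_materials()$pmma, 43)
  }
  ranges <- seq(distal_range, distal_range - sobp_width, by = -spacing)
  if (any(ranges <= 0)) {
    stop("layer residual ranges must stay positive", call. = FALSE)
  }
  tibble::tibble(
    nominal_energy = energy_for_range(model, ranges + degrader_wet),
    residual_range = ranges
  )
}

#' Solve SOBP plateau weights
#'
#' Distal-to-proximal plateau filling: iterating from the deepest layer, the
#' weight of layer j solves
#' `w_j = (H - sum_k<j w_k h_k(b_j)) / h_j(b_j)` where `b_j` is the depth
#' bin of layer j's Bragg peak and `h_k` the peak-normalised depth-dose of
#' layer k. A bounded non-negative least-squares refinement pass over the
#' whole plateau grid then reduces the inter-peak ripple (to about 2%
#' flatness for 2 mm spacing); `refine = FALSE` keeps the raw recursion.
#'
#' @param curves List of [pristine_depth_dose()] curves, ordered deepest
#'   first, all sampled on the same depth grid.
#' @param H Target plateau height (arbitrary dose units, default 1).
#' @param refine Run the least-squares ripple refinement (default TRUE).
#' @param layers Optional tibble of layer metadata (e.g. from
#'   [select_energy_layers()]) carried into the plan.
#' @return An `sobp_plan`: `layers` (tibble with `weight` and `peak_depth`),
#'   `H`, `sobp` (summed depth-dose tibble), `curves`.
#' @export
compute_sobp_weights <- function(curves, H = 1, refine = TRUE,
                                 layers = NULL) {
  nl <- length(curves)
  if (nl < 1) stop("need at least one curve", call. = FALSE)
  depth <- curves[[1]]$depth
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$depth, depth))) {
      stop("curves must share one depth grid", call. = FALSE)
    }
  }
  ranges <- vapply(curves, function(cv) attr(cv, "range_water"), 0)
  if (is.unsorted(rev(ranges), strictly = TRUE)) {
    stop("curves must be ordered deepest first with distinct ranges",
         call. = FALSE)
  }
  M <- vapply(curves, function(cv) cv$dose / max(cv$dose), numeric(length(depth)))
  pk <- apply(M, 2, which.max)
  w <- numeric(nl)
  for (j in seq_len(nl)) {
    prev <- if (j > 1) sum(w[seq_len(j - 1)] * M[pk[j], seq_len(j - 1)]) else 0
    w[j] <- (H - prev) / M[pk[j], j]
    if (w[j] <= 0) {
      stop("plateau infeasible: solved weight for layer ", j,
           " is not positive", call. = FALSE)
    }
  }
  ## fixed point on the peak bins, then (optionally) least squares on the
  ## full plateau to damp the ripple between peaks
  for (it in 1:25) {
    S <- drop(M %*% w)
    for (j in rev(seq_len(nl))) {
      others <- S[pk[j]] - w[j] * M[pk[j], j]
      w[j] <- max((H - others) / M[pk[j], j], 1e-9)
      S <- drop(M %*% w)
    }
  }
  if (refine && nl > 1) {
    sel <- depth >= depth[min(pk)] & depth <= depth[max(pk)]
    wls <- pracma::lsqnonneg(M[sel, , drop = FALSE], rep(H, sum(sel)))$x
    if (all(wls > 0)) w <- wls
  }
  sobp <- tibble::tibble(depth = depth, dose = drop(M %*% w))
  if (is.null(layers)) {
    layers <- tibble::tibble(residual_range = ranges)
  }
  layers$weight <- w
  layers$peak_depth <- depth[pk]
  structure(
    list(layers = layers, H = H, sobp = sobp, curves = curves),
    class = "sobp_plan"
  )
}

#' Build a full SOBP plan behind a degrader
#'
#' Convenience constructor: selects layers, builds the analytic pristine
#' curves (straggling from the *total* water-equivalent range, degrader
#' included) and solves the plateau weights.
#'
#' @inheritParams select_energy_layers
#' @param H Plateau height.
#' @param grid Depth grid, mm (default 0 to distal + 6 mm at 0.02 mm).
#' @param sigmaE_rel Source relative energy spread.
#' @param refine Passed to [compute_sobp_weights()].
#' @return An `sobp_plan`.
#' @export
sobp_plan_for <- function(distal_range = 35.5, sobp_width = 18, spacing = 2,
                          degrader_wet = NULL, H = 1, grid = NULL,
                          sigmaE_rel = 5e-4, refine = TRUE,
                          model = cnao_range_model()) {
  if (is.null(degrader_wet)) {
    degrader_wet <- water_equivalent_thickness(beamline_materials()$pmma, 43)
  }
  layers <- select_energy_layers(distal_range, sobp_width, spacing,
                                 degrader_wet, model)
  if (is.null(grid)) grid <- seq(0, distal_range + 6, by = 0.02)
  curves <- purrr::map(layers$residual_range, function(r) {
    e_res <- energy_for_range(model, r)
    pristine_depth_dose(e_res, sigmaE_rel = sigmaE_rel, grid = grid,
                        model = model, total_range = r + degrader_wet)
  })
  compute_sobp_weights(curves, H = H, refine = refine, layers = layers)
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf("<sobp_plan> %d layers, plateau height %g\n",
              nrow(x$layers), x$H))
  print(x$layers)
  invisible(x)
}

#' Scanned-spot pattern
#'
#' Discrete spot positions on a square lattice covering the field, the
#' active-scanning delivery pattern. Spots sit at multiples of `step` with
#' `|y|, |z| <= field/2`.
#'
#' @param step Lattice step, mm (default 3).
#' @param field Field size `c(y, z)`, mm (default 40 x 40).
#' @return A `scan_pattern` tibble with columns `y`, `z`.
#' @export
scan_pattern <- function(step = 3, field = c(40, 40)) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  my <- floor(field[1] / 2 / step)
  mz <- floor(field[2] / 2 / step)
  out <- tidyr::expand_grid(y = step * (-my:my), z = step * (-mz:mz))
  structure(out, class = c("scan_pattern", class(out)),
            step = step, field = field)
}

#' Single-spot "pattern"
#'
#' @return A `scan_pattern` with one spot on the axis.
#' @export
single_spot <- function() {
  out <- tibble::tibble(y = 0, z = 0)
  structure(out, class = c("scan_pattern", class(out)),
            step = 0, field = c(0, 0))
}

## Transverse spot model at the scoring plane: Gaussian sigma of one spot at
## the isocenter, and (with a collimator) the sigma at the collimator plane
## plus the drift blur from the post-degrader angular spread.
.spot_model <- function(layout, source) {
  iso <- layout$active_isocenter
  at_iso <- .transport_moments(layout, source, iso)
  out <- list(sigma_iso = at_iso$sigma, divergence = at_iso$divergence,
              energy_iso = at_iso$energy, wet = at_iso$wet)
  if (!is.null(layout$collimator)) {
    cp <- layout$collimator$position
    at_col <- .transport_moments(layout, source, cp)
    out$sigma_col <- at_col$sigma
    ## the mask edge is blurred by the *conditional* angular spread given
    ## the position at the collimator plane: the correlated part of (y, y')
    ## is a deterministic shear that shifts the edge rather than washing it
    ## out. sigma_blur = L * sqrt(C - B^2/A) in Fermi-Eyges moments.
    cond <- at_col$divergence^2 - (at_col$covar / at_col$sigma)^2
    out$blur <- (iso - cp) * sqrt(max(cond, 1e-12))
    out$aperture <- layout$collimator$aperture
  }
  out
}

## Transverse fluence of the scanned field on (y, z) grids, one value per
## (iy, iz) pair. With a collimator, the spot fluence is masked at the
## collimator plane and blurred over the remaining drift (separable
## Gaussian convolution on an internal fine grid).
.transverse_fluence <- function(spot, scan, ycents, zcents) {
  if (is.null(spot$sigma_col)) {
    fy <- vapply(scan$y, function(c0) stats::dnorm(ycents, c0, spot$sigma_iso),
                 numeric(length(ycents)))
    fz <- vapply(scan$z, function(c0) stats::dnorm(zcents, c0, spot$sigma_iso),
                 numeric(length(zcents)))
    ## sum over spots of outer(fy_s, fz_s)
    T <- matrix(0, length(ycents), length(zcents))
    for (s in seq_len(nrow(scan))) T <- T + outer(fy[, s], fz[, s])
    return(T)
  }
  half <- max(abs(c(ycents, zcents))) + 6 * spot$sigma_col
  h <- 0.25
  g <- seq(-half, half, by = h)
  fy <- vapply(unique(scan$y), function(c0) stats::dnorm(g, c0, spot$sigma_col),
               numeric(length(g)))
  fz <- vapply(unique(scan$z), function(c0) stats::dnorm(g, c0, spot$sigma_col),
               numeric(length(g)))
  uy <- match(scan$y, unique(scan$y))
  uz <- match(scan$z, unique(scan$z))
  F <- matrix(0, length(g), length(g))
  for (s in seq_len(nrow(scan))) F <- F + outer(fy[, uy[s]], fz[, uz[s]])
  mask <- outer((g / spot$aperture[1])^2, (g / spot$aperture[2])^2, "+") <= 1
  F[!mask] <- 0
  ## separable blur over the collimator-isocenter drift
  kern <- stats::dnorm(seq(-5 * spot$blur, 5 * spot$blur, by = h), 0,
                       spot$blur)
  kern <- kern / sum(kern)
  F <- apply(F, 2, function(col) {
    stats::filter(col, kern, sides = 2) |> (\(v) ifelse(is.na(v), 0, v))()
  })
  F <- t(apply(F, 1, function(row) {
    stats::filter(row, kern, sides = 2) |> (\(v) ifelse(is.na(v), 0, v))()
  }))
  ## bilinear interpolation onto the requested grids
  iy <- findInterval(ycents, g, all.inside = TRUE)
  iz <- findInterval(zcents, g, all.inside = TRUE)
  wy <- (ycents - g[iy]) / h
  wz <- (zcents - g[iz]) / h
  T <- matrix(0, length(ycents), length(zcents))
  for (jz in seq_along(zcents)) {
    c0 <- F[, iz[jz]] * (1 - wz[jz]) + F[, iz[jz] + 1] * wz[jz]
    T[, jz] <- c0[iy] * (1 - wy) + c0[iy + 1] * wy
  }
  T
}

## Water-equivalent depth at voxel boundaries along x for every (y, z) ray:
## a [nx + 1, nray] matrix. Upstream of the grid the path is booked as water
## from the reference plane (see cnao_depth_offset()).
.depth_boundaries <- function(target, depth_offset) {
  d <- dim(target$labels)
  nx <- d[1]; nray <- d[2] * d[3]
  dx <- target$voxel_size[1]
  wer <- matrix(target$wer, nx, nray)
  front <- target$origin[1] - dx / 2
  entry <- depth_offset + front
  B <- apply(wer * dx, 2, cumsum)
  rbind(rep(entry, nray), entry + B)
}

#' Simulate delivered dose on a voxel grid
#'
#' Delivers a scanned, weighted multi-layer field onto a labelled voxel
#' grid.
#'
#' In `analytic` mode the dose at a voxel is
#' `sum_l w_l h_l(d) * T(y, z)`: the straggling-convolved depth-dose of each
#' layer evaluated at the ray's water-equivalent depth, times the transverse
#' fluence of the scanned spots (masked and blurred by the collimator when
#' present). In `mc` mode the same marginal distributions are sampled per
#' primary: layer by weight, spot uniformly, transverse position from the
#' spot Gaussian (with collimator rejection at the collimator plane), range
#' from the straggling Gaussian, and the Bragg-Kleeman stopping power is
#' integrated exactly across each traversed voxel. The two modes agree
#' within counting statistics.
#'
#' Depth bookkeeping: the water-equivalent depth of a voxel is accumulated
#' voxel-by-voxel along rays parallel to the beam axis, referenced to a
#' plane `depth_offset` mm (water-equivalent) upstream of the isocenter;
#' the path upstream of the grid is booked as water. See
#' [cnao_depth_offset()].
#'
#' @param layout A `beamline_layout` (its collimator, if any, shapes the
#'   field).
#' @param plan An `sobp_plan`.
#' @param scan A [scan_pattern()].
#' @param target A `labeled_grid`.
#' @param mode `"analytic"` or `"mc"`.
#' @param n_primaries Number of sampled histories (mc mode).
#' @param seed Integer RNG seed; mandatory in mc mode.
#' @param depth_offset Reference-plane offset, mm (default
#'   [cnao_depth_offset()]).
#' @param source Beam source; default [cnao_source()] at the layout energy.
#' @return A `dose_grid`: `dose` (array), `labels_grid`, `mode`,
#'   `n_primaries`, `seed`, `spot` (transverse model), `plan`.
#' @export
simulate_dose <- function(layout, plan, scan, target,
                          mode = c("analytic", "mc"), n_primaries = NULL,
                          seed = NULL, depth_offset = cnao_depth_offset(),
                          source = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "sobp_plan"), inherits(target, "labeled_grid"))
  if (mode == "mc") {
    if (is.null(seed)) {
      stop("mc mode requires an integer seed (reproducibility contract)",
           call. = FALSE)
    }
    if (is.null(n_primaries) || n_primaries <= 0) {
      stop("mc mode requires n_primaries > 0", call. = FALSE)
    }
  }
  if (is.null(source)) source <- cnao_source(layout$energy)
  spot <- .spot_model(layout, source)
  dgrid <- dim(target$labels)
  nx <- dgrid[1]; ny <- dgrid[2]; nz <- dgrid[3]
  ycents <- target$origin[2] + (seq_len(ny) - 1) * target$voxel_size[2]
  zcents <- target$origin[3] + (seq_len(nz) - 1) * target$voxel_size[3]
  B <- .depth_boundaries(target, depth_offset)   # [nx+1, nray]
  Dmid <- (B[-1, , drop = FALSE] + B[-nrow(B), , drop = FALSE]) / 2
  w <- plan$layers$weight
  if (max(B) < max(plan$layers$residual_range) - 20 && nx > 4) {
    warning("beam range extends beyond the scored grid", call. = FALSE)
  }
  if (min(B[1, ]) > max(plan$layers$residual_range)) {
    warning("beam stops before reaching the grid (range exhausted)",
            call. = FALSE)
  }
  if (mode == "analytic") {
    T <- .transverse_fluence(spot, scan, ycents, zcents)
    sobp_at <- stats::approx(plan$sobp$depth, plan$sobp$dose,
                             xout = as.vector(Dmid), rule = 2, yleft = 0,
                             yright = 0)$y
    dose <- array(sobp_at, dim = c(nx, ny * nz)) *
      rep(as.vector(T), each = nx)
    dose <- array(dose, dim = dgrid)
  } else {
    dose <- .simulate_dose_mc(plan, scan, spot, target, B, n_primaries,
                              seed, ycents, zcents)
  }
  structure(
    list(dose = dose, labels_grid = target, mode = mode,
         n_primaries = n_primaries, seed = seed, spot = spot, plan = plan,
         depth_offset = depth_offset),
    class = "dose_grid"
  )
}

## Monte-Carlo sampling of the same delivery model. Particles are binned
## onto (y, z) rays; per x-slice the Bragg-Kleeman stopping power is
## integrated exactly over the voxel: dE = p * [(R-d_lo)^(1/p) -
## (R-d_hi)^(1/p)] for the sampled range R, with the singular peak handled
## by the closed-form antiderivative.
.simulate_dose_mc <- function(plan, scan, spot, target, B, n_primaries,
                              seed, ycents, zcents) {
  set.seed(seed)
  model <- cnao_range_model()
  p <- model$p
  dgrid <- dim(target$labels)
  nx <- dgrid[1]; ny <- dgrid[2]; nz <- dgrid[3]
  dy <- target$voxel_size[2]; dz <- target$voxel_size[3]
  nl <- nrow(plan$layers)
  w <- plan$layers$weight
  ## effective per-layer intensities: weight * peak-normalisation already in
  ## the curves; sample layers proportional to their weights
  li <- sample.int(nl, n_primaries, replace = TRUE, prob = w / sum(w))
  si <- sample.int(nrow(scan), n_primaries, replace = TRUE)
  if (is.null(spot$sigma_col)) {
    yp <- stats::rnorm(n_primaries, scan$y[si], spot$sigma_iso)
    zp <- stats::rnorm(n_primaries, scan$z[si], spot$sigma_iso)
  } else {
    yc <- stats::rnorm(n_primaries, scan$y[si], spot$sigma_col)
    zc <- stats::rnorm(n_primaries, scan$z[si], spot$sigma_col)
    keep <- (yc / spot$aperture[1])^2 + (zc / spot$aperture[2])^2 <= 1
    yp <- stats::rnorm(sum(keep), yc[keep], spot$blur)
    zp <- stats::rnorm(sum(keep), zc[keep], spot$blur)
    li <- li[keep]
  }
  sig <- vapply(plan$curves, function(cv) attr(cv, "sigma_straggle"), 0)
  rng <- vapply(plan$curves, function(cv) attr(cv, "range_water"), 0)
  R <- stats::rnorm(length(yp), rng[li], sig[li])
  ## scale: analytic curves are peak-normalised; one sampled proton of layer
  ## l carries the layer's peak-height normalisation 1/max-stopping; fold the
  ## per-layer constant so MC expectation matches the analytic sum
  peak_raw <- vapply(seq_along(plan$curves), function(l) {
    cv <- plan$curves[[l]]
    max(.bragg_dose(cv$depth, rng[l], sig[l], p))
  }, 0)
  ## the trailing factor makes the MC expectation equal the analytic dose
  ## absolutely (spot Gaussians integrate to 1; counts bin into dy*dz cells)
  wt_particle <- (sum(w) / n_primaries) / peak_raw[li] *
    nrow(scan) / (target$voxel_size[2] * target$voxel_size[3])
  iy <- floor((yp - (ycents[1] - dy / 2)) / dy) + 1
  iz <- floor((zp - (zcents[1] - dz / 2)) / dz) + 1
  ok <- iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
  iy <- iy[ok]; iz <- iz[ok]; R <- R[ok]; wt_particle <- wt_particle[ok]
  ray <- (iz - 1L) * ny + iy
  dose <- matrix(0, nx, ny * nz)
  for (ix in seq_len(nx)) {
    dlo <- B[ix, ray]; dhi <- B[ix + 1, ray]
    ulo <- pmax(R - dlo, 0); uhi <- pmax(R - dhi, 0)
    dep <- (ulo^(1 / p) - uhi^(1 / p)) * p / (dhi - dlo)
    nzi <- which(dep > 0)
    if (length(nzi)) {
      acc <- rowsum(dep[nzi] * wt_particle[nzi], ray[nzi])
      dose[ix, as.integer(rownames(acc))] <-
        dose[ix, as.integer(rownames(acc))] + acc[, 1]
    }
  }
  array(dose, dim = dgrid)
}

#' Extract dose profiles from a dose grid
#'
#' `depth_profile()` returns the depth-dose along the beam axis (averaged
#' over a transverse window); `lateral_profile()` returns a transverse
#' profile (averaged over the grid depth and a window on the other axis).
#'
#' @param dose A `dose_grid`.
#' @param half_window Averaging half-window on the transverse axes, mm.
#' @param axis `"y"` or `"z"` for `lateral_profile()`.
#' @return A [dose_profile()].
#' @export
depth_profile <- function(dose, half_window = 2) {
  g <- dose$labels_grid
  d <- dim(dose$dose)
  y <- g$origin[2] + (seq_len(d[2]) - 1) * g$voxel_size[2]
  z <- g$origin[3] + (seq_len(d[3]) - 1) * g$voxel_size[3]
  sel_y <- abs(y) <= half_window
  sel_z <- abs(z) <= half_window
  v <- apply(dose$dose[, sel_y, sel_z, drop = FALSE], 1, mean)
  x <- g$origin[1] + (seq_len(d[1]) - 1) * g$voxel_size[1]
  dose_profile(x, v, axis = "depth")
}

#' @rdname depth_profile
#' @export
lateral_profile <- function(dose, axis = c("y", "z"), half_window = 2.5) {
  axis <- match.arg(axis)
  g <- dose$labels_grid
  d <- dim(dose$dose)
  y <- g$origin[2] + (seq_len(d[2]) - 1) * g$voxel_size[2]
  z <- g$origin[3] + (seq_len(d[3]) - 1) * g$voxel_size[3]
  if (axis == "y") {
    sel <- abs(z) <= half_window
    v <- apply(dose$dose[, , sel, drop = FALSE], 2, mean)
    dose_profile(y, v, axis = "y")
  } else {
    sel <- abs(y) <= half_window
    v <- apply(dose$dose[, sel, , drop = FALSE], 3, mean)
    dose_profile(z, v, axis = "z")
  }
}

#' Treatment session timing
#'
#' Synchrotron spill structure: `ceiling(dose / gy_per_spill)` spills of
#' `spill_s` seconds separated by `pause_s` pauses.
#'
#' @param prescription A [prescription_config()].
#' @return Session time in seconds.
#' @export
session_time <- function(prescription = prescription_config()) {
  with(prescription, {
    if (dose_per_fraction == 0) return(0)
    spills <- ceiling(dose_per_fraction / gy_per_spill)
    spills * spill_s + (spills - 1) * pause_s
  })
}

#' @rdname session_time
#' @param dose_per_fraction Physical dose per fraction, Gy.
#' @param rbe Relative biological effectiveness (dose reporting only).
#' @param gy_per_spill Dose per synchrotron spill, Gy.
#' @param spill_s Spill duration, s.
#' @param pause_s Pause between spills, s.
#' @export
prescription_config <- function(dose_per_fraction = 12, rbe = 1.1,
                                gy_per_spill = 1, spill_s = 1, pause_s = 5) {
  vals <- list(dose_per_fraction = dose_per_fraction, rbe = rbe,
               gy_per_spill = gy_per_spill, spill_s = spill_s,
               pause_s = pause_s)
  if (any(unlist(vals) < 0) || gy_per_spill <= 0 || spill_s <= 0) {
    stop("prescription values must be positive", call. = FALSE)
  }
  structure(vals, class = "prescription_config")
}
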