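#' Beamline elements and layouts
#'
#' The transport line is modelled as a stack of material slabs in air along
#' the beam axis (x, beam travelling towards +x; the standard isocenter is
#' x = 0 and upstream positions are negative). An element's `position` is its
#' *downstream face*; its layers occupy `[position - total thickness,
#' position]`.
#'
#' @param name Element name.
#' @param position Downstream face, mm.
#' @param layers List of `list(material =, thickness =)` entries (thickness
#'   in mm), ordered along the beam.
#' @return A `beamline_element`.
#' @export
beamline_element <- function(name, position, layers) {
  th <- vapply(layers, `[[`, 0, "thickness")
  if (any(th <= 0)) stop("layer thicknesses must be > 0", call. = FALSE)
  structure(list(name = name, position = position, layers = layers),
            class = "beamline_element")
}

#' Brass collimator specification
#'
#' A patient-specific collimator with an elliptical aperture, modelled as a
#' perfect absorber outside the aperture and a perfect transmitter inside
#' (edge scatter off the brass is neglected).
#'
#' @param thickness Collimator thickness, mm.
#' @param aperture Semi-axes of the elliptical aperture `c(y, z)` in mm;
#'   default `c(10, 11)` (a 20 x 22 mm^2 opening).
#' @param material A [material_spec()]; default brass.
#' @return A `collimator_spec`.
#' @export
collimator_spec <- function(thickness = 10, aperture = c(10, 11),
                            material = beamline_materials()$brass) {
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (length(aperture) != 2 || any(aperture <= 0)) {
    stop("aperture must be two positive semi-axes", call. = FALSE)
  }
  structure(list(thickness = thickness, aperture = aperture,
                 material = material),
            class = "collimator_spec")
}

## Monitor-chamber foil stacks. Four anode/cathode foil types:
##   M1 = 12 um Mylar + 1 um Al      (shutter / integral cathode, both boxes)
##   M2 = 25 um Mylar + 2 um Al      (cathode strips, Box 1)
##   A  = 25 um Kapton + 10 um Al    (integral anode both boxes, strip anode)
##   P  = 50 um Kapton + 20 um Cu    (pixel anode, Box 2)
## Box 1 holds M1 + two strip planes (M2/A each) + integral A; Box 2 holds
## M1 + A + P. The chamber fill gas and electrode segmentation are reduced to
## this foil material budget.
.foil <- function(mats, type) {
  switch(type,
    M1 = list(list(material = mats$mylar, thickness = 0.012),
              list(material = mats$al, thickness = 0.001)),
    M2 = list(list(material = mats$mylar, thickness = 0.025),
              list(material = mats$al, thickness = 0.002)),
    A  = list(list(material = mats$kapton, thickness = 0.025),
              list(material = mats$al, thickness = 0.010)),
    P  = list(list(material = mats$kapton, thickness = 0.050),
              list(material = mats$cu, thickness = 0.020))
  )
}

.box_foils <- function(mats) {
  list(
    box1 = c(.foil(mats, "M1"),
             .foil(mats, "M2"), .foil(mats, "A"),
             .foil(mats, "M2"), .foil(mats, "A"),
             .foil(mats, "A")),
    box2 = c(.foil(mats, "M1"), .foil(mats, "A"), .foil(mats, "P"))
  )
}

#' Build the standard transport-line layout
#'
#' Vacuum exit window (carbon fibre) at -1093.6 mm, the two monitor chambers
#' (Box 1 and Box 2) between the window and the nozzle end at -640 mm, air
#' everywhere else, isocenter at 0. Internal foil positions are not published;
#' the two boxes are spread uniformly over the nozzle (isocenter-plane
#' observables change by well under 1% with this choice).
#'
#' @param energy Nominal beam energy, MeV (synchrotron range 63-250).
#' @param materials Material set from [beamline_materials()].
#' @return A `beamline_layout`.
#' @export
build_standard_layout <- function(energy, materials = beamline_materials()) {
  if (energy < 63 || energy > 250) {
    stop("energy outside the synchrotron range [63, 250] MeV", call. = FALSE)
  }
  boxes <- .box_foils(materials)
  n1 <- length(boxes$box1)
  n2 <- length(boxes$box2)
  pos1 <- seq(-1050, -880, length.out = n1)
  pos2 <- seq(-820, -660, length.out = n2)
  elements <- c(
    list(beamline_element("exit window", -1093.4,
                          list(list(material = materials$carbon,
                                    thickness = 0.2)))),
    purrr::map2(seq_len(n1), pos1, function(i, p) {
      beamline_element(paste0("box1 foil ", i), p, boxes$box1[i])
    }),
    purrr::map2(seq_len(n2), pos2, function(i, p) {
      beamline_element(paste0("box2 foil ", i), p, boxes$box2[i])
    })
  )
  structure(
    list(energy = energy, elements = elements, exit_window_pos = -1093.6,
         nozzle_end_pos = -640, active_isocenter = 0, rs_thickness = 0,
         collimator = NULL, materials = materials),
    class = "beamline_layout"
  )
}

#' Build the ocular (optimised) layout
#'
#' The standard line with the isocenter moved upstream to -530 mm (11 cm
#' downstream of the nozzle end), a PMMA range shifter whose downstream face
#' sits 65 mm upstream of the new isocenter, and optionally a brass
#' collimator whose downstream face sits 50 mm upstream of it.
#'
#' @inheritParams build_standard_layout
#' @param rs_thickness Range-shifter thickness, mm (>= 0).
#' @param collimator Optional [collimator_spec()].
#' @param isocenter Active isocenter, mm (default -530).
#' @return A `beamline_layout`.
#' @export
build_ocular_layout <- function(energy, rs_thickness = 43, collimator = NULL,
                                isocenter = -530,
                                materials = beamline_materials()) {
  if (rs_thickness < 0) stop("rs_thickness must be >= 0", call. = FALSE)
  lay <- build_standard_layout(energy, materials)
  lay$active_isocenter <- isocenter
  lay$rs_thickness <- rs_thickness
  if (rs_thickness > 0) {
    wet <- water_equivalent_thickness(materials$pmma, rs_thickness)
    if (wet >= range_in_water(cnao_range_model(), energy)) {
      stop("range shifter exhausts the beam range", call. = FALSE)
    }
    lay$elements <- c(lay$elements, list(
      beamline_element("range shifter", isocenter - 65,
                       list(list(material = materials$pmma,
                                 thickness = rs_thickness)))
    ))
  }
  if (!is.null(collimator)) {
    stopifnot(inherits(collimator, "collimator_spec"))
    collimator$position <- isocenter - 50
    lay$collimator <- collimator
  }
  lay
}

#' @export
print.beamline_layout <- function(x, ...) {
  cat(sprintf(
    "<beamline_layout> %g MeV, isocenter at %g mm, %d elements%s%s\n",
    x$energy, x$active_isocenter, length(x$elements),
    if (x$rs_thickness > 0) sprintf(", RS %g mm", x$rs_thickness) else "",
    if (!is.null(x$collimator)) ", collimator" else ""))
  invisible(x)
}

## Compile a layout into an ordered segment list from `from` to `to`:
## material slabs at their geometric extents, air gaps in between. Used by
## the moment transport and by the ray-sampling oracle in the tests.
.compile_segments <- function(layout, from, to) {
  els <- layout$elements
  pos <- vapply(els, `[[`, 0, "position")
  keep <- order(pos)
  els <- els[keep]; pos <- pos[keep]
  segs <- list()
  cur <- from
  for (i in seq_along(els)) {
    t_tot <- sum(vapply(els[[i]]$layers, `[[`, 0, "thickness"))
    z0 <- pos[i] - t_tot
    if (pos[i] <= from || z0 >= to - 1e-9) next
    if (z0 > cur) segs <- c(segs, list(list(type = "air", length = z0 - cur)))
    zl <- z0
    for (ly in els[[i]]$layers) {
      ## clip a layer straddling the requested plane
      len <- min(ly$thickness, to - zl)
      if (len <= 0) break
      segs <- c(segs, list(list(type = "slab", material = ly$material,
                                length = len)))
      zl <- zl + len
    }
    cur <- min(pos[i], to)
  }
  if (to > cur) segs <- c(segs, list(list(type = "air", length = to - cur)))
  segs
}

## Fermi-Eyges moment transport of one Gaussian beam through the segment
## list: A = <y^2>, B = <y y'>, C = <y'^2>. Drifts of length L update
## A += 2LB + L^2 C, B += LC; thin scattering kicks update C += sigma^2.
## Air gaps and thick slabs are subdivided with the kick applied mid-step.
.transport_moments <- function(layout, source, plane,
                               model = cnao_range_model()) {
  if (plane < source$emission_plane) {
    stop("plane is upstream of the source emission plane", call. = FALSE)
  }
  mats <- layout$materials
  segs <- .compile_segments(layout, source$emission_plane, plane)
  A <- (source$fwhm0 / 2.355)^2
  B <- 0
  C <- source$effective_divergence^2
  E <- source$nominal_energy
  wet <- 0
  drift <- function(L) {
    A <<- A + 2 * L * B + L^2 * C
    B <<- B + L * C
  }
  for (sg in segs) {
    if (sg$type == "air") {
      n <- max(1L, ceiling(sg$length / 50))
      dL <- sg$length / n
      for (k in seq_len(n)) {
        kick <- highland_sigma(mats$air, dL, E, model)$sigma_theta
        drift(dL / 2); C <- C + kick^2; drift(dL / 2)
        wet <- wet + water_equivalent_thickness(mats$air, dL)
        E <- .energy_after_wet(E, water_equivalent_thickness(mats$air, dL),
                               model)
      }
    } else {
      step <- 2
      n <- max(1L, ceiling(sg$length / step))
      dt <- sg$length / n
      x_tot <- sg$length / 10 * sg$material$density /
        sg$material$radiation_length
      log_corr <- 1 + 0.038 * log(x_tot)
      dx <- dt / 10 * sg$material$density / sg$material$radiation_length
      for (k in seq_len(n)) {
        dwet <- water_equivalent_thickness(sg$material, dt)
        if (wet + dwet >= .range_nw(model, source$nominal_energy)) {
          stop("beam stops inside '", sg$material$name, "' before the plane",
               call. = FALSE)
        }
        e_mid <- .energy_after_wet(E, dwet / 2, model)
        kick2 <- (13.6 / proton_beta_pc(e_mid))^2 * dx * log_corr^2
        drift(dt / 2); C <- C + kick2; drift(dt / 2)
        E <- .energy_after_wet(E, dwet, model)
        wet <- wet + dwet
      }
    }
  }
  list(sigma = sqrt(A), covar = B, divergence = sqrt(C), energy = E,
       wet = wet)
}

#' Calibrate a beam source from two measured FWHM planes
#'
#' Sets the source spot size to the FWHM measured at the exit window and
#' solves for the effective (uncorrelated) divergence that reproduces the
#' FWHM measured at the standard isocenter after transport through the full
#' standard layout (foils + air). Intermediate planes then become genuine
#' predictions.
#'
#' @param energy Nominal energy, MeV.
#' @param fwhm_at_window Measured FWHM at the exit window plane, mm.
#' @param fwhm_at_isocenter Measured FWHM at the standard isocenter, mm.
#' @param layout Layout used for the calibration transport; defaults to the
#'   standard layout at `energy`.
#' @return A `beam_source`: `nominal_energy`, `sigmaE_rel`, `fwhm0`,
#'   `effective_divergence` (rad), `emission_plane` (mm).
#' @export
calibrate_source <- function(energy, fwhm_at_window, fwhm_at_isocenter,
                             layout = build_standard_layout(energy)) {
  if (!(fwhm_at_isocenter > fwhm_at_window && fwhm_at_window > 0)) {
    stop("need fwhm_at_isocenter > fwhm_at_window > 0", call. = FALSE)
  }
  target <- fwhm_at_isocenter / 2.355
  mk <- function(div) {
    structure(list(nominal_energy = energy, sigmaE_rel = 5e-4,
                   fwhm0 = fwhm_at_window, effective_divergence = div,
                   emission_plane = -1093.6),
              class = "beam_source")
  }
  f <- function(div) .transport_moments(layout, mk(div), 0)$sigma - target
  if (f(0) > 0) {
    stop("calibration infeasible: zero divergence already exceeds the ",
         "isocenter FWHM", call. = FALSE)
  }
  div <- stats::uniroot(f, c(0, 0.05), tol = 1e-8)$root
  mk(div)
}

#' Calibrated source at a published benchmark energy
#'
#' [calibrate_source()] fed with the exit-window and isocenter rows of
#' [cnao_fwhm_table()] for one of the four benchmark energies.
#'
#' @param energy One of 81.56, 100.51, 119.05, 148.80.
#' @return A `beam_source`.
#' @export
cnao_source <- function(energy) {
  tab <- cnao_fwhm_table()
  row0 <- tab[tab$position == -1093.6 & abs(tab$energy - energy) < 1e-6, ]
  rowi <- tab[tab$position == 0 & abs(tab$energy - energy) < 1e-6, ]
  if (nrow(row0) != 1) {
    stop("energy must be one of the tabulated benchmark energies",
         call. = FALSE)
  }
  calibrate_source(energy, row0$fwhm, rowi$fwhm)
}

#' @export
print.beam_source <- function(x, ...) {
  cat(sprintf(
    "<beam_source> %g MeV, FWHM0 %.3g mm, divergence %.3g mrad\n",
    x$nominal_energy, x$fwhm0, 1000 * x$effective_divergence))
  invisible(x)
}

#' Transverse beam FWHM at a plane
#'
#' Moment-based transport of the source through every element of the layout
#' upstream of `plane`; FWHM = 2.355 sigma of the transported Gaussian.
#'
#' @param layout A `beamline_layout`.
#' @param source A `beam_source`.
#' @param plane Beam-axis coordinate, mm.
#' @return FWHM in mm (vectorised over `plane`).
#' @export
fwhm_at <- function(layout, source, plane) {
  vapply(plane, function(p) {
    2.355 * .transport_moments(layout, source, p)$sigma
  }, 0)
}

#' Beam FWHM as a function of range-shifter thickness
#'
#' Reproduces the range-shifter study: the FWHM of a single pencil beam at
#' either the standard isocenter (0 mm) or the optimised ocular isocenter
#' (-530 mm). The shifter stays at its ocular position (downstream face at
#' -595 mm) in both cases; scoring at the standard isocenter adds the 530 mm
#' air gap that motivated moving the patient upstream.
#'
#' @param energy Nominal energy, MeV.
#' @param thicknesses Range-shifter thicknesses, mm.
#' @param at_standard_isocenter Score at 0 mm (TRUE) or at -530 mm (FALSE).
#' @param source Optional pre-calibrated `beam_source`.
#' @return A tibble with columns `rs_thickness` and `fwhm`.
#' @export
fwhm_vs_rs_thickness <- function(energy, thicknesses,
                                 at_standard_isocenter = FALSE,
                                 source = cnao_source(energy)) {
  if (any(thicknesses < 0)) stop("thicknesses must be >= 0", call. = FALSE)
  plane <- if (at_standard_isocenter) 0 else -530
  fw <- vapply(thicknesses, function(t) {
    lay <- build_ocular_layout(energy, rs_thickness = t, isocenter = -530)
    fwhm_at(lay, source, plane)
  }, 0)
  tibble::tibble(rs_thickness = thicknesses, fwhm = fw)
}
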