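## Chemical formulas of the elementary eye materials, as atom counts.
.eye_formulas <- list(
  water          = c(H = 2, O = 1),
  nacl           = c(Na = 1, Cl = 1),
  proline        = c(H = 9, C = 5, O = 2, N = 1),
  idrossiproline = c(H = 9, C = 5, O = 3, N = 1),
  lipids         = c(H = 48, C = 24, O = 6, P = 1, N = 2),
  lactate        = c(H = 5, C = 3, O = 2),
  sugar          = c(H = 2, C = 1, O = 1),
  naa            = c(H = 9, C = 6, O = 5, N = 1),
  choline        = c(H = 14, C = 5, O = 1, N = 1),
  creatine       = c(H = 9, C = 4, O = 2, N = 3)
)

## Mass fractions of a formula material.
.formula_fractions <- function(counts) {
  rows <- .element_row(names(counts))
  m <- counts * rows$A
  m / sum(m)
}

## Mixture-level recipes: component -> mass fraction. "proteins" is itself an
## elemental mass-fraction recipe (the average amino-acid composition).
.eye_mixtures <- list(
  collagen = c(proline = 0.86, idrossiproline = 0.14)
)
.protein_fractions <- c(H = 0.50, C = 0.28, O = 0.13, N = 0.08, S = 0.01)

## Resolve a recipe written over {formula materials, proteins, collagen}
## into elemental mass fractions.
.resolve_recipe <- function(recipe) {
  out <- numeric(0)
  add <- function(fracs, w) {
    for (el in names(fracs)) {
      out[el] <<- (if (is.na(out[el])) 0 else out[el]) + w * fracs[[el]]
    }
  }
  for (comp in names(recipe)) {
    w <- recipe[[comp]]
    if (comp == "proteins") {
      add(.protein_fractions, w)
    } else if (comp %in% names(.eye_mixtures)) {
      sub <- .resolve_recipe(.eye_mixtures[[comp]])
      add(sub, w)
    } else if (comp %in% names(.eye_formulas)) {
      add(.formula_fractions(.eye_formulas[[comp]]), w)
    } else {
      stop("unknown component '", comp, "' in tissue recipe", call. = FALSE)
    }
  }
  out
}

## Tissue recipes and densities of the six stock eye tissues.
.eye_tissue_recipes <- list(
  aqueous_humor  = list(recipe = c(water = 0.985, nacl = 0.015),
                        density = 1.0080),
  vitreous_humor = list(recipe = c(water = 0.985, proteins = 0.015),
                        density = 1.0050),
  sclera         = list(recipe = c(collagen = 0.50, proteins = 0.25,
                                   sugar = 0.25), density = 1.0710),
  lens           = list(recipe = c(water = 0.60, proteins = 0.40),
                        density = 1.0670),
  retina         = list(recipe = c(water = 0.80, naa = 0.10,
                                   choline = 0.05, creatine = 0.05),
                        density = 1.0174),
  tumor          = list(recipe = c(water = 0.80, naa = 0.03, choline = 0.12,
                                   creatine = 0.03, lipids = 0.01,
                                   lactate = 0.01), density = 1.0174)
)

#' Eye tissue materials
#'
#' The stock tissues of the anatomical eye phantom, built from elementary
#' biochemical mixtures (proline, hydroxyproline, collagen, lipids, lactate,
#' sugar, N-acetylaspartate, choline, creatine, and an average-amino-acid
#' protein recipe) combined into six component tissues with their published
#' densities: aqueous humor (1.0080 g/cm^3), vitreous humor (1.0050),
#' sclera/cornea/ciliary body (1.0710), crystalline lens (1.0670), retina
#' (1.0174), and tumor (1.0174). Elemental mass fractions are resolved
#' recursively; each tissue's water-equivalent ratio follows the
#' relative-stopping approximation of [material_spec()].
#'
#' Cornea and ciliary body share the sclera's collagen-rich recipe; brain is
#' water; air closes the list.
#'
#' @return Named list of [material_spec()] objects with names
#'   `aqueous_humor`, `vitreous_humor`, `sclera`, `cornea`, `ciliary_body`,
#'   `lens`, `retina`, `tumor`, `optic_nerve`, `brain`, `air`.
#' @export
eye_materials <- function() {
  base <- lapply(names(.eye_tissue_recipes), function(nm) {
    rec <- .eye_tissue_recipes[[nm]]
    material_spec(nm, rec$density, .resolve_recipe(rec$recipe))
  })
  names(base) <- names(.eye_tissue_recipes)
  bl <- beamline_materials()
  scl <- base$sclera
  c(base,
    list(
      cornea = material_spec("cornea", scl$density, scl$composition),
      ciliary_body = material_spec("ciliary_body", scl$density,
                                   scl$composition),
      ## the optic nerve is not given its own recipe; use the retina's
      ## neural-tissue composition
      optic_nerve = material_spec("optic_nerve", base$retina$density,
                                  base$retina$composition),
      brain = material_spec("brain", 1.0, bl$water$composition, wer = 1.0),
      air = bl$air
    ))
}

#' Water-equivalent ratio of a tissue
#'
#' Relative stopping power of a resolved material:
#' `density * (Z/A) / (Z/A)_water` (mean-excitation correction ignored).
#' This is the value [material_spec()] stores as `wer` unless overridden.
#'
#' @param tissue A [material_spec()].
#' @return Dimensionless WER.
#' @export
material_wer <- function(tissue) {
  stopifnot(inherits(tissue, "material_spec"))
  tissue$density * tissue$z_over_a / 0.555087
}

#' Build the parameterised eye model
#'
#' Constructive solid geometry of the eye phantom, every linear dimension
#' proportional to the outer sclera radius (default 12.25 mm): a 1 mm sclera
#' shell, a corneal cap, an ellipsoidal crystalline lens, a ciliary-body
#' ring, a 0.5 mm retina lining the posterior inner surface, aqueous and
#' vitreous humours, an optic-nerve cylinder behind the posterior pole, a
#' dome-shaped tumor (half-ellipsoid, 9 mm axial extent, 14 x 16 mm base)
#' rising from the posterior inner wall, and a 48 mm water box for the
#' brain. Exact internal proportions are documented package defaults (the
#' published description fixes only the tumor extent, brain box, rotation
#' and the sclera-radius parameterisation); all of them can be overridden
#' through `proportions`.
#'
#' The model is rotated rigidly by `gaze_angle` about the horizontal
#' transverse axis through the globe centre (positive = eye rotated upward,
#' tumor displaced downward) and then translated so that the tumor centroid
#' lies on the beam axis, with the tumor apex at the isocenter for
#' `gaze_angle = 0`.
#'
#' @param sclera_outer_radius Outer sclera radius, mm (9 to 16).
#' @param gaze_angle Vertical gaze rotation, degrees (|angle| <= 60).
#' @param proportions Optional named list overriding geometry defaults
#'   (in mm at the reference radius 12.25; see `eye_proportions()`).
#' @return An `eye_model`.
#' @export
build_eye <- function(sclera_outer_radius = 12.25, gaze_angle = 0,
                      proportions = list()) {
  if (sclera_outer_radius < 9 || sclera_outer_radius > 16) {
    stop("sclera_outer_radius must lie in [9, 16] mm", call. = FALSE)
  }
  if (abs(gaze_angle) > 60) {
    stop("|gaze_angle| must be <= 60 degrees", call. = FALSE)
  }
  geo <- utils::modifyList(eye_proportions(), proportions)
  structure(
    list(sclera_outer_radius = sclera_outer_radius,
         gaze_angle = gaze_angle,
         scale = sclera_outer_radius / 12.25,
         geo = geo,
         materials = eye_materials()),
    class = "eye_model"
  )
}

#' @rdname build_eye
#' @export
eye_proportions <- function() {
  list(
    sclera_thickness = 1.0,
    retina_thickness = 0.5,
    retina_back_of = -3.0,       # retina lines the region x > this (eye frame)
    cornea_radius = 7.8,
    cornea_thickness = 0.9,
    cornea_center_x = -5.85,
    limbus_x = -10.55,
    lens_center_x = -7.8,
    lens_semi_axial = 2.25,
    lens_semi_equatorial = 4.5,
    ciliary_inner = 4.5,
    ciliary_outer = 6.5,
    ciliary_half_width = 1.2,
    tumor_base_x = 10.75,        # base on the inner posterior wall
    tumor_axial = 9.0,
    tumor_semi_y = 7.0,
    tumor_semi_z = 8.0,
    nerve_radius = 1.5,
    nerve_start_x = 11.8,
    nerve_length = 10.0,
    brain_side = 48.0,
    brain_front_x = -4.0
  )
}

## Tumor centroid along the optical axis (eye frame): a half-ellipsoid's
## centroid sits 3/8 of its axial semi-axis from the base.
.tumor_centroid_x <- function(geo) geo$tumor_base_x - 3 / 8 * geo$tumor_axial
.tumor_apex_x <- function(geo) geo$tumor_base_x - geo$tumor_axial

## Beam-frame pose: rotation angle (radians) and translation such that the
## tumor centroid maps to (x_anchor, 0, 0) with the apex at the isocenter
## when the gaze is straight ahead.
.eye_pose <- function(eye) {
  k <- eye$scale
  geo <- eye$geo
  th <- -eye$gaze_angle * pi / 180   # positive gaze -> tumor moves down (-y)
  cx <- .tumor_centroid_x(geo) * k
  anchor_x <- (.tumor_centroid_x(geo) - .tumor_apex_x(geo)) * k
  T <- c(anchor_x - cx * cos(th), -cx * sin(th), 0)
  list(theta = th, translation = T)
}

## Classify beam-frame points (vectors) into structure labels. Priority is
## innermost-first; the first matching rule wins.
.eye_structures <- c("tumor", "lens", "cornea", "ciliary_body", "retina",
                     "sclera", "optic_nerve", "aqueous_humor",
                     "vitreous_humor", "brain", "air")

.classify_eye_points <- function(eye, x, y, z) {
  k <- eye$scale
  g <- lapply(eye$geo, function(v) v * k)
  pose <- .eye_pose(eye)
  th <- pose$theta; T <- pose$translation
  ## beam -> eye frame
  xb <- x - T[1]; yb <- y - T[2]; zb <- z - T[3]
  xe <- cos(th) * xb + sin(th) * yb
  ye <- -sin(th) * xb + cos(th) * yb
  ze <- zb
  r2 <- xe^2 + ye^2 + ze^2
  rho2 <- ye^2 + ze^2
  rc2 <- (xe - g$cornea_center_x)^2 + rho2
  R_out <- 12.25 * k
  R_in <- R_out - g$sclera_thickness
  R_vit <- R_in - g$retina_thickness
  lab <- integer(length(xe))
  unset <- function() lab == 0L
  set <- function(cond, name) {
    i <- which(unset() & cond)
    lab[i] <<- match(name, .eye_structures)
  }
  ## dome rising from the posterior inner wall: half-ellipsoid anchored at
  ## the wall pole, clipped to the vitreous cavity so the rim hugs the
  ## curved wall instead of poking through it
  set(((xe - g$tumor_base_x) / g$tumor_axial)^2 +
        (ye / g$tumor_semi_y)^2 + (ze / g$tumor_semi_z)^2 <= 1 &
        xe <= g$tumor_base_x &
        r2 <= (R_out - g$sclera_thickness - g$retina_thickness)^2, "tumor")
  set(((xe - g$lens_center_x) / g$lens_semi_axial)^2 +
        (ye / g$lens_semi_equatorial)^2 +
        (ze / g$lens_semi_equatorial)^2 <= 1, "lens")
  set(rc2 <= g$cornea_radius^2 &
        rc2 > (g$cornea_radius - g$cornea_thickness)^2 &
        xe < g$limbus_x, "cornea")
  set(rho2 >= g$ciliary_inner^2 & rho2 <= g$ciliary_outer^2 &
        abs(xe - g$lens_center_x) <= g$ciliary_half_width &
        r2 <= R_in^2, "ciliary_body")
  set(r2 <= R_in^2 & r2 > R_vit^2 & xe > g$retina_back_of, "retina")
  set(r2 <= R_out^2 & r2 > R_vit^2 & xe >= g$limbus_x, "sclera")
  set(rho2 <= g$nerve_radius^2 & xe >= g$nerve_start_x &
        xe <= g$nerve_start_x + g$nerve_length, "optic_nerve")
  set((rc2 <= (g$cornea_radius - g$cornea_thickness)^2 & xe < g$limbus_x) |
        (r2 <= R_vit^2 & xe < g$lens_center_x), "aqueous_humor")
  set(r2 <= R_vit^2, "vitreous_humor")
  set(xe >= g$brain_front_x & xe <= g$brain_front_x + g$brain_side &
        abs(ye) <= g$brain_side / 2 & abs(ze) <= g$brain_side / 2, "brain")
  lab[unset()] <- match("air", .eye_structures)
  lab
}

#' Low-level labelled grid constructor
#'
#' @param labels Integer array of structure indices.
#' @param structures Character vector naming the indices.
#' @param materials Named list of [material_spec()], one per structure.
#' @param voxel_size Voxel edge lengths `c(dx, dy, dz)`, mm.
#' @param origin Coordinates of the first voxel centre, mm (beam frame).
#' @return A `labeled_grid` with per-voxel `density` and `wer` arrays.
#' @export
labeled_grid <- function(labels, structures, materials, voxel_size, origin) {
  dens <- vapply(structures, function(s) materials[[s]]$density, 0)
  wer <- vapply(structures, function(s) materials[[s]]$wer, 0)
  structure(
    list(labels = labels, structures = structures,
         density = array(dens[labels], dim(labels)),
         wer = array(wer[labels], dim(labels)),
         voxel_size = voxel_size, origin = origin),
    class = "labeled_grid"
  )
}

#' Voxelize the eye model
#'
#' Samples the constructive geometry at voxel centres over a cube centred on
#' the isocenter. The default grid reproduces the published scoring
#' geometry: 200 x 200 x 200 voxels of 0.2 mm.
#'
#' @param eye An `eye_model`.
#' @param voxel_size Voxel edge, mm.
#' @param half_extent Half-width of the cubic grid, mm (default 20).
#' @param max_voxels Memory cap; grids larger than this raise an error.
#' @return A `labeled_grid`.
#' @export
voxelize <- function(eye, voxel_size = 0.2, half_extent = 20,
                     max_voxels = 1.6e7) {
  stopifnot(inherits(eye, "eye_model"))
  if (voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  n <- round(2 * half_extent / voxel_size)
  if (n^3 > max_voxels) {
    stop("requested grid has ", n, "^3 voxels, above the cap of ",
         max_voxels, call. = FALSE)
  }
  centers <- -half_extent + (seq_len(n) - 0.5) * voxel_size
  pts <- expand.grid(x = centers, y = centers, z = centers,
                     KEEP.OUT.ATTRS = FALSE)
  lab <- .classify_eye_points(eye, pts$x, pts$y, pts$z)
  labels <- array(lab, dim = c(n, n, n))
  labeled_grid(labels, .eye_structures, eye$materials,
               voxel_size = rep(voxel_size, 3),
               origin = rep(centers[1], 3))
}

#' Uniform water phantom grid
#'
#' A water box (optionally a thin layer) centred on the isocenter, as used
#' for the depth-dose and field-uniformity studies.
#'
#' @param size Box edge lengths `c(x, y, z)` in mm.
#' @param voxel_size Voxel edges `c(dx, dy, dz)` in mm.
#' @param center Box centre in beam coordinates, mm.
#' @return A `labeled_grid` with a single `water` structure.
#' @export
water_box_grid <- function(size = c(25, 25, 25),
                           voxel_size = c(0.05, 1, 1),
                           center = c(0, 0, 0)) {
  n <- pmax(1L, round(size / voxel_size))
  labels <- array(1L, dim = n)
  mats <- list(water = beamline_materials()$water)
  labeled_grid(labels, "water", mats, voxel_size = voxel_size,
               origin = center - size / 2 + voxel_size / 2)
}

#' @export
print.labeled_grid <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_grid> %d x %d x %d voxels of %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  tab <- table(factor(x$structures[x$labels], levels = x$structures))
  for (nm in names(tab)) {
    if (tab[[nm]] > 0) {
      cat(sprintf("  %-15s %8d voxels (%.2f cm^3)\n", nm, tab[[nm]],
                  tab[[nm]] * prod(x$voxel_size) / 1000))
    }
  }
  invisible(x)
}

#' Per-structure volumes of a labelled grid
#'
#' @param grid A `labeled_grid`.
#' @return Tibble with `structure`, `n_voxels`, `volume_mm3`.
#' @export
structure_volumes <- function(grid) {
  tab <- tabulate(grid$labels, nbins = length(grid$structures))
  tibble::tibble(structure = grid$structures, n_voxels = tab,
                 volume_mm3 = tab * prod(grid$voxel_size))
}
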