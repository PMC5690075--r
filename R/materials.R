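## Element lookup used for mixture-level quantities: Z, A (g/mol) and the
## elemental radiation length X0 (g/cm^2), from the usual Tsai tabulation.
.elements <- tibble::tribble(
  ~element, ~Z, ~A,      ~X0,
  "H",       1,  1.008,  63.04,
  "C",       6, 12.011,  42.70,
  "N",       7, 14.007,  37.99,
  "O",       8, 15.999,  34.24,
  "Na",     11, 22.990,  27.74,
  "Al",     13, 26.982,  24.01,
  "P",      15, 30.974,  21.21,
  "S",      16, 32.06,   19.50,
  "Cl",     17, 35.45,   19.28,
  "Cu",     29, 63.546,  12.86,
  "Zn",     30, 65.38,   12.43,
  "Pb",     82, 207.2,    6.37
)

.element_row <- function(el) {
  i <- match(el, .elements$element)
  if (anyNA(i)) {
    stop("unknown element(s): ", paste(el[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  .elements[i, ]
}

#' Define a material for beam transport
#'
#' A material is a named density plus an elemental mass-fraction map. The
#' radiation length and the water-equivalent ratio (WER, mm of water per mm
#' of material) are derived from the composition unless overridden: the
#' radiation length of a mixture combines the elemental Tsai values as
#' `1/X0 = sum(w_i / X0_i)`, and the default WER is the relative-stopping
#' approximation `density * (Z/A)_material / (Z/A)_water` (mean-excitation
#' corrections ignored; see the methods vignette).
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3.
#' @param composition Named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-9; renormalised with a warning otherwise).
#' @param radiation_length Optional override, g/cm^2.
#' @param wer Optional override of the water-equivalent ratio.
#' @return An object of class `material_spec`.
#' @examples
#' material_spec("water", 1.0, c(H = 0.1119, O = 0.8881))
#' @export
material_spec <- function(name, density, composition,
                          radiation_length = NULL, wer = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("density must be a positive number", call. = FALSE)
  }
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mass fractions", call. = FALSE)
  }
  if (any(composition < 0)) stop("mass fractions must be >= 0", call. = FALSE)
  s <- sum(composition)
  if (abs(s - 1) > 1e-9) {
    warning("mass fractions of '", name, "' sum to ", format(s),
            "; renormalising", call. = FALSE)
    composition <- composition / s
  }
  rows <- .element_row(names(composition))
  za <- sum(composition * rows$Z / rows$A)
  x0 <- if (is.null(radiation_length)) {
    1 / sum(composition / rows$X0)
  } else {
    radiation_length
  }
  za_water <- 0.555087 # Z/A of water (from its own mass fractions)
  wer_val <- if (is.null(wer)) density * za / za_water else wer
  if (wer_val <= 0) stop("WER must be positive", call. = FALSE)
  structure(
    list(name = name, density = density, composition = composition,
         radiation_length = x0, z_over_a = za, wer = wer_val),
    class = "material_spec"
  )
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: %.4g g/cm^3, X0 = %.3g g/cm^2, WER = %.4g\n",
              x$name, x$density, x$radiation_length, x$wer))
  comp <- paste(sprintf("%s %.3g", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' Built-in beamline materials
#'
#' The stock materials of the transport line: water, PMMA (the range-shifter
#' plastic), brass (61.5% Cu / 35.2% Zn / 3.3% Pb), Mylar and Kapton foils,
#' aluminium, copper, nitrogen (chamber fill gas), dry air, and carbon fibre
#' (vacuum exit window).
#'
#' The PMMA water-equivalent ratio defaults to the value calibrated from the
#' published range tables (a 43 mm slab removing 38.20 mm of water-equivalent
#' range for a 100.51 MeV beam, WER = 0.8885); set
#' `pmma_wer = "physical"` to use the textbook stopping-power value (~1.16)
#' instead.
#'
#' @param pmma_wer Either `"calibrated"` (default), `"physical"`, or a
#'   number.
#' @return Named list of [material_spec()] objects.
#' @export
beamline_materials <- function(pmma_wer = c("calibrated", "physical")) {
  pw <- if (is.numeric(pmma_wer)) {
    pmma_wer
  } else {
    switch(match.arg(pmma_wer), calibrated = .pmma_wer_calibrated(),
           physical = 1.16)
  }
  list(
    water  = material_spec("water", 1.0, c(H = 0.111894, O = 0.888106),
                           wer = 1.0),
    pmma   = material_spec("pmma", 1.19,
                           c(H = 0.080538, C = 0.599848, O = 0.319614),
                           wer = pw),
    brass  = material_spec("brass", 8.49,
                           c(Cu = 0.615, Zn = 0.352, Pb = 0.033)),
    mylar  = material_spec("mylar", 1.40,
                           c(H = 0.041959, C = 0.625017, O = 0.333024)),
    kapton = material_spec("kapton", 1.42,
                           c(H = 0.026362, C = 0.691133, N = 0.073270,
                             O = 0.209235)),
    al     = material_spec("aluminium", 2.699, c(Al = 1)),
    cu     = material_spec("copper", 8.96, c(Cu = 1)),
    n2     = material_spec("nitrogen", 1.165e-3, c(N = 1)),
    air    = material_spec("air", 1.205e-3, c(N = 0.765, O = 0.235),
                           radiation_length = 36.62),
    carbon = material_spec("carbon fibre", 1.70, c(C = 1))
  )
}

## PMMA WER implied by the published tables: fitted range at 100.51 MeV minus
## the 35.5 mm residual range behind the 43 mm shifter.
.pmma_wer_calibrated <- function() {
  m <- cnao_range_model()
  (range_in_water(m, 100.51) - 35.5) / 43
}

#' Water-equivalent thickness of a slab
#'
#' @param material A [material_spec()].
#' @param thickness Slab thickness in mm.
#' @return Water-equivalent thickness in mm (`thickness * WER`).
#' @export
water_equivalent_thickness <- function(material, thickness) {
  stopifnot(inherits(material, "material_spec"))
  if (any(thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  thickness * material$wer
}

#' Read / write material definitions as YAML
#'
#' Plain-text persistence for material sets: each entry carries the name,
#' density, elemental mass fractions and optional `wer` / `radiation_length`
#' overrides.
#'
#' @param path File path.
#' @param materials Named list of [material_spec()] objects.
#' @return `read_materials()` returns a named list of [material_spec()];
#'   `write_materials()` returns `path` invisibly.
#' @export
read_materials <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(m) {
    material_spec(m$name, m$density, unlist(m$composition),
                  radiation_length = m$radiation_length, wer = m$wer)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  raw <- lapply(materials, function(m) {
    list(name = m$name, density = m$density,
         composition = as.list(m$composition), wer = m$wer,
         radiation_length = m$radiation_length)
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}
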