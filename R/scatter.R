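## Proton kinematics: beta * p * c in MeV for kinetic energy T (MeV).
.proton_mass <- 938.272
proton_beta_pc <- function(T) {
  pc <- sqrt(T^2 + 2 * T * .proton_mass)
  beta <- pc / (T + .proton_mass)
  beta * pc
}

## Internal no-warning range law (the public range_in_water() warns on
## extrapolation; slab bookkeeping legitimately reaches low energies).
.range_nw <- function(model, energy) model$alpha * energy^model$p

## Residual energy after losing `wet` mm of water-equivalent path.
.energy_after_wet <- function(energy, wet, model) {
  r <- .range_nw(model, energy) - wet
  if (any(r <= 0)) stop("beam stops inside the slab", call. = FALSE)
  energy_for_range(model, r)
}

#' Multiple-Coulomb-scattering angle of a slab (Highland formula)
#'
#' Plane-projected RMS scattering angle of a proton crossing a material slab,
#' using the Highland parameterisation
#' `sigma = 13.6 MeV / (beta p c) * sqrt(x/X0) * (1 + 0.038 ln(x/X0))`.
#' Slabs thicker than 2 mm are subdivided and the sub-slab contributions are
#' summed in quadrature, each evaluated at its local mid-slab energy; the
#' logarithmic term uses the full slab thickness once (the usual thin-slab
#' correction would otherwise shrink with the subdivision).
#'
#' @param material A [material_spec()].
#' @param thickness Slab thickness, mm.
#' @param energy_in Kinetic energy entering the slab, MeV.
#' @param model Range-energy model for the energy-loss bookkeeping.
#' @param step Maximum sub-slab thickness, mm.
#' @return An object of class `angular_spread`: `sigma_theta` (rad),
#'   `energy_in`, `energy_out` (MeV), `material`, `path_length` (mm).
#' @export
highland_sigma <- function(material, thickness, energy_in,
                           model = cnao_range_model(), step = 2) {
  stopifnot(inherits(material, "material_spec"))
  if (thickness < 0) stop("thickness must be >= 0", call. = FALSE)
  if (thickness == 0) {
    return(structure(list(sigma_theta = 0, material = material,
                          path_length = 0, energy_in = energy_in,
                          energy_out = energy_in),
                     class = "angular_spread"))
  }
  wet_total <- water_equivalent_thickness(material, thickness)
  if (wet_total >= .range_nw(model, energy_in)) {
    stop("beam stops inside the slab", call. = FALSE)
  }
  x_tot <- thickness / 10 * material$density / material$radiation_length
  log_corr <- 1 + 0.038 * log(x_tot)
  n <- max(1L, ceiling(thickness / step))
  dt <- thickness / n
  dx <- dt / 10 * material$density / material$radiation_length
  e <- energy_in
  s2 <- 0
  for (i in seq_len(n)) {
    e_mid <- .energy_after_wet(e, water_equivalent_thickness(material, dt / 2),
                               model)
    s2 <- s2 + (13.6 / proton_beta_pc(e_mid))^2 * dx * log_corr^2
    e <- .energy_after_wet(e, water_equivalent_thickness(material, dt), model)
  }
  structure(
    list(sigma_theta = sqrt(s2), material = material, path_length = thickness,
         energy_in = energy_in, energy_out = e),
    class = "angular_spread"
  )
}

#' @export
print.angular_spread <- function(x, ...) {
  cat(sprintf(
    "<angular_spread> %.3g mrad over %.3g mm of %s (%.4g -> %.4g MeV)\n",
    1000 * x$sigma_theta, x$path_length, x$material$name, x$energy_in,
    x$energy_out))
  invisible(x)
}
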