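## Shared fixtures, built once per test run (several tests reuse the same
## expensive objects: the 10-layer benchmark plan, the 6-layer ocular plan,
## a coarse voxelized eye, thin-layer scoring grids).
.fix <- new.env()

fix_plan10 <- function() {
  if (is.null(.fix$plan10)) .fix$plan10 <- sobp_plan_for(35.5, 18, 2)
  .fix$plan10
}

fix_plan6 <- function() {
  if (is.null(.fix$plan6)) .fix$plan6 <- sobp_plan_for(35.5, 10, 2)
  .fix$plan6
}

fix_plan_single <- function() {
  if (is.null(.fix$plan1)) .fix$plan1 <- sobp_plan_for(35.5, 0, 2)
  .fix$plan1
}

fix_eye_grid <- function() {
  if (is.null(.fix$eyegrid)) {
    .fix$eyegrid <- voxelize(build_eye(12.25, 40), voxel_size = 0.4)
  }
  .fix$eyegrid
}

fix_thin_layer <- function() {
  if (is.null(.fix$thin)) {
    .fix$thin <- water_box_grid(size = c(1, 70, 70),
                                voxel_size = c(0.5, 0.5, 0.5))
  }
  .fix$thin
}

## Independent ray-sampling oracle for the moment transport: N particles
## with Gaussian position/angle at the source, drifted through the compiled
## segment list with one Gaussian angular kick per material step.
ray_mc_fwhm <- function(layout, source, plane, n = 1e5, seed = 42) {
  set.seed(seed)
  segs <- oculardose:::.compile_segments(layout, source$emission_plane,
                                         plane)
  model <- cnao_range_model()
  y <- rnorm(n, 0, source$fwhm0 / 2.355)
  yp <- rnorm(n, 0, source$effective_divergence)
  E <- source$nominal_energy
  mats <- layout$materials
  for (sg in segs) {
    if (sg$type == "air") {
      nstep <- max(1L, ceiling(sg$length / 50))
      dL <- sg$length / nstep
      for (k in seq_len(nstep)) {
        kick <- highland_sigma(mats$air, dL, E)$sigma_theta
        y <- y + yp * dL / 2
        yp <- yp + rnorm(n, 0, kick)
        y <- y + yp * dL / 2
        E <- E - (E - highland_sigma(mats$air, dL, E)$energy_out)
      }
    } else {
      hs <- highland_sigma(sg$material, sg$length, E)
      nstep <- max(1L, ceiling(sg$length / 2))
      dkick <- hs$sigma_theta / sqrt(nstep)
      dL <- sg$length / nstep
      for (k in seq_len(nstep)) {
        y <- y + yp * dL / 2
        yp <- yp + rnorm(n, 0, dkick)
        y <- y + yp * dL / 2
      }
      E <- hs$energy_out
    }
  }
  2.355 * sd(y)
}
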