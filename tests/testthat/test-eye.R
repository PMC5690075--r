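test_that("tissue materials carry the published densities and resolve to elements", {
  em <- eye_materials()
  expect_equal(em$tumor$density, 1.0174)
  expect_equal(em$retina$density, 1.0174)
  expect_equal(em$lens$density, 1.0670)
  expect_equal(em$sclera$density, 1.0710)
  expect_equal(em$aqueous_humor$density, 1.0080)
  expect_equal(em$vitreous_humor$density, 1.0050)
  for (m in em) expect_equal(sum(m$composition), 1, tolerance = 1e-9)
})

test_that("recursive mass fractions match a hand expansion", {
  em <- eye_materials()
  ## vitreous humor = 98.5% water + 1.5% protein;
  ## H fraction = 0.985 * (2*1.008/18.015) + 0.015 * 0.50
  h_water <- 2 * 1.008 / (2 * 1.008 + 15.999)
  expect_equal(unname(em$vitreous_humor$composition["H"]),
               0.985 * h_water + 0.015 * 0.50, tolerance = 1e-6)
  expect_equal(unname(em$vitreous_humor$composition["S"]),
               0.015 * 0.01, tolerance = 1e-9)
  ## aqueous humor carries the NaCl minority fractions
  expect_equal(unname(em$aqueous_humor$composition["Na"]),
               0.015 * 22.990 / (22.990 + 35.45), tolerance = 1e-6)
})

test_that("tissue WER follows the stopping approximation", {
  em <- eye_materials()
  expect_equal(material_wer(beamline_materials()$water), 1.0,
               tolerance = 1e-5)
  expect_gt(material_wer(em$tumor), 1.00)
  expect_lt(material_wer(em$tumor), 1.05)
  ## WER strictly increases with density at fixed composition
  denser <- material_spec("t2", em$tumor$density * 1.1, em$tumor$composition)
  expect_gt(material_wer(denser), material_wer(em$tumor))
})

test_that("geometry guards reject out-of-range parameters", {
  expect_error(build_eye(8), "sclera_outer_radius")
  expect_error(build_eye(12.25, 70), "gaze_angle")
})

test_that("gaze rotation is rigid: tumor recentred, volumes preserved", {
  g0 <- voxelize(build_eye(12.25, 0), voxel_size = 0.5)
  g40 <- voxelize(build_eye(12.25, 40), voxel_size = 0.5)
  v0 <- structure_volumes(g0)
  v40 <- structure_volumes(g40)
  for (s in c("tumor", "lens", "vitreous_humor")) {
    expect_equal(v40$volume_mm3[v40$structure == s],
                 v0$volume_mm3[v0$structure == s], tolerance = 0.02,
                 label = s)
  }
  ## the thin sclera shell is the worst case for voxelized rotation
  expect_equal(v40$volume_mm3[v40$structure == "sclera"],
               v0$volume_mm3[v0$structure == "sclera"], tolerance = 0.03)
  ## tumor centroid stays on the beam axis after rotation + translation
  idx <- which(g40$labels == match("tumor", g40$structures), arr.ind = TRUE)
  cy <- g40$origin[2] + (mean(idx[, 2]) - 1) * g40$voxel_size[2]
  expect_lt(abs(cy), 0.6)
  ## straight gaze: tumor apex at the isocenter, extent ~9 mm downstream
  idx0 <- which(g0$labels == match("tumor", g0$structures), arr.ind = TRUE)
  x0 <- g0$origin[1] + (idx0[, 1] - 1) * g0$voxel_size[1]
  expect_equal(min(x0), 0, tolerance = 0.5)
  expect_equal(max(x0), 9, tolerance = 0.5)
})

test_that("structure volumes scale as the cube of the sclera radius", {
  g1 <- voxelize(build_eye(12.25, 0), voxel_size = 0.5)
  g2 <- voxelize(build_eye(14.0, 0), voxel_size = 0.5)
  k3 <- (14 / 12.25)^3
  v1 <- structure_volumes(g1)
  v2 <- structure_volumes(g2)
  for (s in c("tumor", "lens", "vitreous_humor")) {
    expect_equal(v2$volume_mm3[v2$structure == s] /
                   v1$volume_mm3[v1$structure == s], k3, tolerance = 0.02,
                 label = s)
  }
})

test_that("voxelization partitions the grid and converges", {
  g <- fix_eye_grid()
  expect_equal(sum(tabulate(g$labels, length(g$structures))),
               length(g$labels))
  ## whole-globe volume against the analytic sphere
  globe <- c("tumor", "lens", "cornea", "ciliary_body", "retina", "sclera",
             "aqueous_humor", "vitreous_humor")
  v <- structure_volumes(g)
  vol_globe <- sum(v$volume_mm3[v$structure %in% globe])
  ## the corneal cap bulges out of the sphere, the limbus trims it: compare
  ## against the sphere with a 2.5% geometric allowance on top of the
  ## voxelization error
  expect_equal(vol_globe, 4 / 3 * pi * 12.25^3, tolerance = 0.04)
  ## halving the voxel changes volumes by < 1%
  g_fine <- voxelize(build_eye(12.25, 40), voxel_size = 0.2)
  vf <- structure_volumes(g_fine)
  for (s in c("tumor", "vitreous_humor")) {
    expect_equal(vf$volume_mm3[vf$structure == s],
                 v$volume_mm3[v$structure == s], tolerance = 0.01, label = s)
  }
  expect_error(voxelize(build_eye(), voxel_size = 0.05), "cap")
})

test_that("the tumor stays inside the globe with ~9 mm axial extent", {
  g <- fix_eye_grid()
  lab_t <- match("tumor", g$structures)
  idx <- which(g$labels == lab_t, arr.ind = TRUE)
  x <- g$origin[1] + (idx[, 1] - 1) * g$voxel_size[1]
  ## rotated dome, rim clipped to the curved wall: axial extent frozen from
  ## the geometry at 0.4 mm voxels
  expect_equal(diff(range(x)), 10.4, tolerance = 0.05)
  ## no tumor voxel outside the outer sclera sphere
  pose <- oculardose:::.eye_pose(build_eye(12.25, 40))
  y <- g$origin[2] + (idx[, 2] - 1) * g$voxel_size[2]
  z <- g$origin[3] + (idx[, 3] - 1) * g$voxel_size[3]
  T <- pose$translation
  r <- sqrt((x - T[1])^2 + (y - T[2])^2 + (z - T[3])^2)
  expect_lt(max(r), 12.25)
})
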