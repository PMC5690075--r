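test_that("standard layout is assembled as documented", {
  lay <- build_standard_layout(100.51)
  ## exit window + 12 Box-1 foils + 6 Box-2 foils
  expect_length(lay$elements, 19)
  pos <- vapply(lay$elements, `[[`, 0, "position")
  expect_true(all(diff(sort(pos)) > 0))
  expect_true(all(pos > -1093.6 & pos <= -640))
  ## total foil water-equivalent budget stays below 1 mm
  wet <- sum(vapply(lay$elements, function(el) {
    sum(vapply(el$layers, function(l) {
      water_equivalent_thickness(l$material, l$thickness)
    }, 0))
  }, 0))
  expect_lt(wet, 1)
  expect_error(build_standard_layout(50), "synchrotron")
})

test_that("ocular layout adds shifter and collimator at the stated gaps", {
  lay <- build_ocular_layout(100.51, 43, collimator_spec())
  expect_equal(lay$active_isocenter, -530)
  rs <- lay$elements[[length(lay$elements)]]
  expect_equal(rs$position, -595)
  expect_equal(lay$collimator$position, -580)
  ## collimator strictly between the shifter face and the isocenter
  expect_true(rs$position < lay$collimator$position)
  expect_true(lay$collimator$position < lay$active_isocenter)
  expect_error(build_ocular_layout(100.51, 100), "exhausts")
  ## zero-thickness shifter leaves the element stack unchanged
  lay0 <- build_ocular_layout(100.51, 0)
  expect_length(lay0$elements, length(build_standard_layout(100.51)$elements))
})

test_that("the published residual ranges follow from WET arithmetic", {
  m <- cnao_range_model()
  mats <- beamline_materials()
  r43 <- range_in_water(m, 100.51) - water_equivalent_thickness(mats$pmma, 43)
  expect_equal(r43, 35.5, tolerance = 1e-9)
  r46 <- range_in_water(m, 100.51) - water_equivalent_thickness(mats$pmma, 46)
  expect_equal(r46, 35.5 - 3 * mats$pmma$wer, tolerance = 1e-9)
})

test_that("source calibration is a fixed point of the transport", {
  src <- cnao_source(81.56)
  lay <- build_standard_layout(81.56)
  expect_equal(fwhm_at(lay, src, 0), 16.39, tolerance = 1e-6)
  expect_equal(fwhm_at(lay, src, -1093.6), 5.48, tolerance = 1e-8)
  expect_gt(src$effective_divergence, 0)
  expect_lt(src$effective_divergence, 0.01)
  expect_error(calibrate_source(81.56, 10, 5), "fwhm_at_isocenter")
})

test_that("intermediate planes are predicted within the 10% benchmark error", {
  tab <- cnao_fwhm_table()
  for (e in c(81.56, 100.51)) {
    src <- cnao_source(e)
    lay <- build_standard_layout(e)
    rows <- tab[tab$energy == e & tab$position %in% c(-654.6, -350, 500), ]
    pred <- fwhm_at(lay, src, rows$position)
    expect_true(all(abs(pred - rows$fwhm) / rows$fwhm < 0.10),
                label = paste("energy", e))
  }
})

test_that("sigma grows monotonically and materials never shrink the beam", {
  src <- cnao_source(100.51)
  lay <- build_ocular_layout(100.51, 43)
  planes <- c(-1000, -800, -640, -600, -560, -530)
  f <- fwhm_at(lay, src, planes)
  expect_true(all(diff(f) > 0))
  ## removing the shifter reduces the downstream width
  lay0 <- build_ocular_layout(100.51, 0)
  expect_lt(fwhm_at(lay0, src, -530), fwhm_at(lay, src, -530))
  expect_error(fwhm_at(lay, src, -1200), "upstream")
})

test_that("pure drift reduces to the quadrature formula", {
  ## a source with no downstream material (plane upstream of the first foil)
  src <- cnao_source(100.51)
  lay <- build_standard_layout(100.51)
  plane <- -1060
  drift <- plane - src$emission_plane
  sig0 <- src$fwhm0 / 2.355
  expected <- 2.355 * sqrt(sig0^2 + (src$effective_divergence * drift)^2)
  ## air adds a whisker of scattering over 30 mm; agreement to 0.5%
  expect_equal(fwhm_at(lay, src, plane), expected, tolerance = 0.005)
})

test_that("moment transport agrees with a ray-sampling oracle", {
  src <- cnao_source(100.51)
  lay <- build_ocular_layout(100.51, 43)
  got <- fwhm_at(lay, src, -530)
  mc <- ray_mc_fwhm(lay, src, -530, n = 1e5, seed = 7)
  expect_equal(got, mc, tolerance = 0.02)
})

test_that("range-shifter study reproduces the published FWHM bands", {
  th <- seq(45, 65, by = 5)
  opt <- fwhm_vs_rs_thickness(100.51, th, at_standard_isocenter = FALSE)
  expect_true(all(opt$fwhm >= 10 & opt$fwhm <= 13))
  std <- fwhm_vs_rs_thickness(100.51, th, at_standard_isocenter = TRUE)
  expect_true(all(std$fwhm >= 40 & std$fwhm <= 70 + 1))
  ## monotone growth with thickness at a fixed plane
  expect_true(all(diff(opt$fwhm) > 0))
  ## zero thickness equals the layout without a shifter
  z <- fwhm_vs_rs_thickness(100.51, 0, at_standard_isocenter = FALSE)
  lay0 <- build_ocular_layout(100.51, 0)
  expect_equal(z$fwhm, fwhm_at(lay0, cnao_source(100.51), -530),
               tolerance = 1e-9)
})
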