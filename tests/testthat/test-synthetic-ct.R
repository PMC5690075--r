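test_that("the synthetic series is deterministic and round-trips exactly", {
  spec <- synthetic_head_spec(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  v1 <- generate_head_ct(spec, d1)$volume
  v2 <- generate_head_ct(spec, d2)$volume
  expect_identical(v1, v2)
  expect_equal(dim(v1), c(512, 512, 10))
  ser <- read_dicom_series(d1)
  expect_identical(ser$hu, v1)
  expect_equal(ser$pixel_spacing, c(0.97, 0.97))
  expect_equal(ser$slice_thickness, 2)
  ## slice positions 2 mm apart
  expect_equal(diff(ser$positions[, 3]), rep(2, 9))
  ## a different seed changes the noise
  v3 <- generate_head_ct(synthetic_head_spec(seed = 8),
                         withr::local_tempdir())$volume
  expect_false(identical(v1, v3))
})

test_that("HU content matches the configured tissue means", {
  spec <- synthetic_head_spec(seed = 3, noise_sigma = 10)
  vol <- generate_head_ct(spec, withr::local_tempdir())$volume
  ## central globe region on the middle slices: mean within 3 sigma of the
  ## configured 15 HU (n pixels makes the tolerance tiny; allow the lens)
  er <- spec$eye_center[1]; ec <- spec$eye_center[2]
  patch <- vol[(er + 2):(er + 8), (ec - 3):(ec + 3), 5:6]
  expect_lt(abs(mean(patch) - 15), 3 * 10 / sqrt(length(patch)) + 1)
  ## background is air
  expect_lt(mean(vol[1:20, 1:20, 1]), -950)
})

test_that("cropping preserves values and the documented geometry", {
  spec <- synthetic_head_spec(seed = 2)
  dir <- withr::local_tempdir()
  vol <- generate_head_ct(spec, dir)$volume
  ser <- read_dicom_series(dir)
  crop <- crop_roi(ser, spec$eye_center)
  expect_equal(dim(crop$hu), c(86, 86, 10))
  expect_equal(crop$voxel_size, c(0.97, 0.97, 2))
  ## crop of a constant array is constant
  const <- crop_roi(array(7L, dim = c(512, 512, 10)), c(256, 256))
  expect_true(all(const$hu == 7))
  ## voxel index 43 (0-based) sits at the isocenter within half a pixel
  x43 <- crop$origin[1] + 43 * crop$voxel_size[1]
  expect_lt(abs(x43), crop$voxel_size[1] / 2 + 1e-9)
  expect_error(crop_roi(ser, c(20, 20)), "bounds")
})

test_that("the HU calibration ramp hits its anchors and is monotone", {
  conv <- hu_to_density_wer(c(-1000, 0, 100))
  expect_equal(conv$density[2], 1.0)
  expect_equal(conv$wer[2], 1.0)
  expect_lt(conv$density[1], 0.01)
  hu <- seq(-1000, 2000, by = 10)
  c2 <- hu_to_density_wer(hu)
  expect_true(all(diff(c2$density) >= 0))
  expect_true(all(diff(c2$wer) >= 0))
  ## two-segment oracle recoded independently: soft tissue slope 1/1000,
  ## bone slope 5e-4 above 100 HU
  oracle <- function(h) {
    if (h <= 100) 1 + h / 1000 else 1.1 + (h - 100) * 5e-4
  }
  mids <- c(-500, 50, 500, 1500)
  expect_equal(hu_to_density_wer(mids)$density,
               vapply(mids, oracle, 0))
  expect_warning(hu_to_density_wer(5000), "clamped")
})

test_that("a degraded point beam stops inside the imaged globe", {
  spec <- synthetic_head_spec(seed = 1)
  dir <- withr::local_tempdir()
  generate_head_ct(spec, dir)
  ser <- read_dicom_series(dir)
  tg <- ct_target_grid(crop_roi(ser, spec$eye_center))
  dg <- irradiate_dicom(tg)
  dp <- depth_profile(dg, half_window = 3)
  peak <- dp$coordinate[which.max(dp$value)]
  expect_gt(peak, -12)
  expect_lt(peak, 12)
})
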