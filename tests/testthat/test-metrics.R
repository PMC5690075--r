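test_that("fwhm matches closed forms", {
  x <- seq(-20, 20, by = 0.1)
  g <- dose_profile(x, exp(-x^2 / (2 * 16)), axis = "y")
  expect_equal(fwhm(g), 2.355 * 4, tolerance = 1e-3)
  rect <- dose_profile(x, as.numeric(abs(x) <= 5), axis = "y")
  expect_equal(fwhm(rect), 10, tolerance = 0.11)
  expect_error(fwhm(dose_profile(x, rep(1, length(x)))), "half maximum")
})

test_that("fwhm of an asymmetric mixture matches a fine-grid search", {
  x <- seq(-25, 25, by = 0.05)
  v <- exp(-(x + 3)^2 / 8) + 0.6 * exp(-(x - 6)^2 / 30)
  p <- dose_profile(x, v, axis = "y")
  ## brute-force oracle on a 1000x finer grid
  xf <- seq(-25, 25, by = 5e-5)
  vf <- exp(-(xf + 3)^2 / 8) + 0.6 * exp(-(xf - 6)^2 / 30)
  half <- max(vf) / 2
  oracle <- diff(range(xf[vf >= half]))
  expect_equal(fwhm(p), oracle, tolerance = 1e-3)
})

test_that("penumbra of an error-function edge is 1.683 sigma", {
  x <- seq(-40, 40, by = 0.02)
  sig <- 3.1
  v <- stats::pnorm((20 - x) / sig) + stats::pnorm((20 + x) / sig) - 1
  p <- dose_profile(x, v, axis = "y")
  expect_equal(penumbra_80_20(p, "right"), 1.6832 * sig, tolerance = 0.01)
  expect_equal(penumbra_80_20(p, "left"), 1.6832 * sig, tolerance = 0.01)
  ## a step falls inside one sample spacing
  step <- dose_profile(x, as.numeric(abs(x) <= 10), axis = "y")
  expect_lt(penumbra_80_20(step, "right"), 0.021)
  ## convolving with a wider kernel strictly widens the penumbra
  v2 <- stats::pnorm((20 - x) / (2 * sig)) +
    stats::pnorm((20 + x) / (2 * sig)) - 1
  expect_gt(penumbra_80_20(dose_profile(x, v2, axis = "y"), "right"),
            penumbra_80_20(p, "right"))
})

test_that("uniformity metrics respond to noise as designed", {
  x <- seq(-20, 20, by = 0.25)
  flat <- dose_profile(x, rep(1, length(x)), axis = "y")
  expect_equal(transverse_uniformity(flat), 0)
  expect_equal(transverse_uniformity(flat, "sd"), 0)
  expect_equal(transverse_uniformity(flat, "range"), 0)
  ## i.i.d. Gaussian noise of relative sd s reads ~100 s on the robust scale
  set.seed(5)
  s <- 0.03
  reads <- replicate(40, {
    p <- dose_profile(x, 1 + stats::rnorm(length(x), 0, s), axis = "y")
    transverse_uniformity(p)
  })
  expect_equal(mean(reads), 100 * s, tolerance = 0.1)
  ## metrics are invariant under uniform rescaling
  p <- dose_profile(x, 5 * (1 + stats::rnorm(length(x), 0, s)), axis = "y")
  p2 <- dose_profile(x, p$value / 5, axis = "y")
  expect_equal(transverse_uniformity(p), transverse_uniformity(p2))
})

test_that("sobp metrics reduce sensibly for a single pristine curve", {
  cv <- pristine_depth_dose(100.51, grid = seq(0, 85, by = 0.02))
  m <- sobp_metrics(cv)
  ## width collapses to the curve's own near-peak width
  lev <- 0.98 * mean(cv$dose[cv$dose >= 0.95 * max(cv$dose)])
  oracle <- diff(range(cv$depth[cv$dose >= lev]))
  expect_equal(m$width, oracle, tolerance = 0.02)
})

test_that("a real sobp is much wider than its distal falloff", {
  m <- sobp_metrics(fix_plan10()$sobp)
  expect_gt(m$width, m$distal_falloff_80_20)
})

test_that("metrics are invariant under dose rescaling", {
  plan <- fix_plan10()
  m1 <- sobp_metrics(plan$sobp)
  scaled <- plan$sobp
  scaled$dose <- scaled$dose * 7.3
  m2 <- sobp_metrics(scaled)
  expect_equal(m1$width, m2$width)
  expect_equal(m1$distal_falloff_80_20, m2$distal_falloff_80_20)
  expect_equal(m1$entrance_plateau_ratio, m2$entrance_plateau_ratio)
})

test_that("dvh matches exhaustive enumeration on a toy grid", {
  labels <- array(c(1L, 2L, 2L), dim = c(3, 1, 1))
  mats <- list(a = beamline_materials()$water,
               b = beamline_materials()$water)
  lg <- labeled_grid(labels, c("a", "b"), mats, voxel_size = c(1, 1, 1),
                     origin = c(0, 0, 0))
  dose <- structure(list(dose = array(c(2, 1, 3), dim = c(3, 1, 1)),
                         labels_grid = lg, mode = "analytic"),
                    class = "dose_grid")
  d <- dvh(dose, n_thresholds = 7, relative = FALSE)
  ## thresholds 0, 0.5, ..., 3; structure b = voxels {1, 3}
  b <- d[d$structure == "b", ]
  expect_equal(b$volume_fraction, c(100, 100, 100, 50, 50, 50, 50))
  a <- d[d$structure == "a", ]
  expect_equal(a$volume_fraction, c(100, 100, 100, 100, 100, 0, 0))
  expect_equal(dvh_fraction_at(d, "b", 2.9), 50)
})

test_that("dvh curves are monotone and start at exactly 100%", {
  dg <- irradiate_water(fix_plan6(),
                        target = water_box_grid(size = c(40, 20, 20),
                                                voxel_size = c(1, 2, 2)))
  d <- dvh(dg, n_thresholds = 51)
  for (s in unique(d$structure)) {
    vf <- d$volume_fraction[d$structure == s]
    expect_true(all(diff(vf) <= 0))
    expect_equal(vf[1], 100)
  }
  ## uniform dose: every structure is a step at the common value
  u <- dg
  u$dose[] <- 4
  du <- dvh(u, n_thresholds = 5, relative = FALSE)
  expect_equal(du$volume_fraction, rep(100, 5))
  expect_error(dvh(dg, labels = fix_eye_grid()), "geometry")
})
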