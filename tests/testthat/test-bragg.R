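test_that("pristine curves peak at the power-law range (distal 80% point)", {
  for (e in c(81.56, 100.51, 148.8)) {
    cv <- pristine_depth_dose(e)
    r <- attr(cv, "range_water")
    expect_equal(distal_depth(cv), r, tolerance = 0.015)
    ## single maximum, non-negative dose
    expect_true(all(cv$dose >= 0))
    expect_equal(sum(diff(sign(diff(cv$dose))) < 0), 1)
    ## negligible dose beyond range + 5 sigma
    tail <- cv$dose[cv$depth > r + 5 * attr(cv, "sigma_straggle")]
    if (length(tail)) expect_lt(max(tail), 0.01)
  }
})

test_that("the 81.56 MeV curve reproduces the printed 50 mm range", {
  cv <- pristine_depth_dose(81.56, sigmaE_rel = 5e-4)
  expect_equal(distal_depth(cv), 50.0, tolerance = 0.015)
})

test_that("straggling obeys the quadrature law", {
  grid <- seq(0, 60, by = 0.02)
  base <- pristine_depth_dose(81.56, grid = grid)
  s0 <- attr(base, "sigma_straggle")
  falloff <- function(cv) {
    distal_depth(cv, 0.2) - distal_depth(cv, 0.8)
  }
  f0 <- falloff(base)
  for (s in c(0.5, 1.0, 2.0)) {
    cv <- pristine_depth_dose(81.56, extra_straggle = s, grid = grid)
    expect_equal(attr(cv, "sigma_straggle"), sqrt(s0^2 + s^2))
    ## measured distal falloff scales with the combined sigma within 2%
    expect_equal(falloff(cv) / f0, sqrt(s0^2 + s^2) / s0, tolerance = 0.02)
    ## adding straggle always widens the falloff
    expect_gt(falloff(cv), f0)
  }
})

test_that("zero energy spread and zero extra straggle give the narrowest falloff", {
  grid <- seq(0, 60, by = 0.02)
  narrow <- pristine_depth_dose(81.56, sigmaE_rel = 0, grid = grid)
  wide <- pristine_depth_dose(81.56, sigmaE_rel = 0.01, grid = grid)
  f <- function(cv) distal_depth(cv, 0.2) - distal_depth(cv, 0.8)
  expect_lt(f(narrow), f(wide))
})

test_that("distal falloff tracks the straggling sigma", {
  ## shape constant of the engine: the 80-20% falloff of a pristine curve is
  ## a fixed multiple (~1.3) of sigma; frozen from a fine-grid measurement
  cv <- pristine_depth_dose(100.51, grid = seq(0, 85, by = 0.01))
  f <- distal_depth(cv, 0.2) - distal_depth(cv, 0.8)
  expect_equal(f / attr(cv, "sigma_straggle"), 1.31, tolerance = 0.02)
})

test_that("curves are grid-converged and guard their inputs", {
  c1 <- pristine_depth_dose(100.51, grid = seq(0, 85, by = 0.05))
  c2 <- pristine_depth_dose(100.51, grid = seq(0, 85, by = 0.025))
  expect_lt(abs(distal_depth(c1) - distal_depth(c2)), 0.1)
  ## finite positive integral
  expect_gt(sum(c1$dose) * 0.05, 0)
  expect_error(pristine_depth_dose(-5), "positive")
  expect_error(pristine_depth_dose(100, grid = numeric(0)), "empty")
  expect_error(pristine_depth_dose(100, grid = c(3, 2, 1)), "increasing")
})
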