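test_that("direct geometric inversion solves the shell-fraction cubic", {
  expect_equal(directShellInversion(1, 1, 954), 477)
  frac <- 1 - (1 - 26 / 954)^3
  expect_equal(directShellInversion(frac * 5e7, 5e7, 954), 13, tolerance = 1e-4)
  # width grows with observed fluorescence per volume at fixed diameter
  ws <- vapply(c(0.1, 0.3, 0.6, 0.9), function(fr)
    directShellInversion(fr, 1, 500), numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_error(directShellInversion(2, 1, 500), "exceed")
  expect_error(directShellInversion(-1, 1, 500), "> 0")
})

test_that("model chain and direct inversion agree on noise-free populations", {
  m <- 5e7; xg <- 954; w <- 89
  d <- makeShellColonies(w, 3000, 2 * w, 1500, seed = 99)
  sf <- suppressWarnings(
    fitFsModel(d, sphereSurface(2 * w), sphereSurface(xg), form = "hyperbolic"))
  dfs <- deltaFs(sf)
  fi <- intensityCorrection(sf, dfs, form = "linear")
  sh <- shellWidthAndRadius(makeFixedFit(2 * w), sf, fi, xg, m = m)
  oracle <- directShellInversion(m * shellFraction(xg, w), m, xg)
  expect_equal(sh@rGamma, oracle, tolerance = 0.05)
  expect_equal(sh@iV, 1 - (1 - sh@iX)^3, tolerance = 1e-12)
  # with no intensity correction the width is exactly half of x_b
  sh0 <- shellWidthAndRadius(makeFixedFit(2 * w), sf, 0, xg, m = m)
  expect_equal(sh0@rGamma, w, tolerance = 1e-6)
  expect_equal(sh0@iX, 2 * w / xg, tolerance = 1e-6)
})

test_that("fully fluorescent colonies give a relative radius of one", {
  d <- makeShellColonies(89, 500, 178, 1500, seed = 12)
  sf <- suppressWarnings(
    fitFsModel(d, sphereSurface(178), sphereSurface(954), form = "shell"))
  sh <- shellWidthAndRadius(makeFixedFit(300), sf, 0, xGamma = 200, m = 5e7)
  expect_equal(sh@iX, 1)
  expect_equal(sh@iV, 1)
  expect_equal(sh@rGamma, 100)
})

test_that("shell widths and x_b must be positive", {
  d <- makeShellColonies(89, 200, 178, 1500, seed = 13)
  sf <- suppressWarnings(
    fitFsModel(d, sphereSurface(178), sphereSurface(954), form = "shell"))
  expect_error(shellWidthAndRadius(makeFixedFit(-40), sf, 0, 954, m = 5e7),
               "x_b")
  expect_error(shellIntensity(structure(list(), class = "x"), 10))
})

test_that("the implied width function is flat for a constant-width truth", {
  m <- 5e7; w <- 89; xg <- 954
  d <- makeShellColonies(w, 2000, 2 * w, 1500, seed = 14)
  sf <- suppressWarnings(
    fitFsModel(d, sphereSurface(2 * w), sphereSurface(xg), form = "shell"))
  sh <- shellWidthAndRadius(makeFixedFit(2 * w), sf, 0, xg, m = m)
  ws <- shellWidth(sh, c(250, 500, 954, 1400))
  expect_equal(ws, rep(w, 4), tolerance = 1e-6)
  expect_equal(shellWidth(sh, 100), 50)  # below x_b: fully fluorescent
})

test_that("volume fraction follows the cubic identity over the unit interval", {
  iX <- seq(0, 1, by = 0.01)
  expect_identical(fluorescentVolumeFraction(iX), 1 - (1 - iX)^3)
  expect_equal(fluorescentVolumeFraction(0.2), 0.488, tolerance = 1e-12)
  expect_equal(fluorescentVolumeFraction(c(0, 1)), c(0, 1))
  expect_error(fluorescentVolumeFraction(1.2), "\\[0, 1\\]")
})

test_that("radial profiles yield the half-maximum shell width", {
  # exact step profile
  pr <- simulateRadialProfile(1000, 120, blurSigma = 0, dr = 0.5)
  expect_equal(estimateShellFromRadialProfile(pr$radius_um, pr$intensity), 120)
  # solid disc: width equals the full radius
  disc <- simulateRadialProfile(400, 200)
  expect_equal(estimateShellFromRadialProfile(disc$radius_um, disc$intensity),
               200)
  # uniform profile
  expect_equal(estimateShellFromRadialProfile(seq(0, 50, 0.5),
                                              rep(2, 101)), 50)
  # Gaussian blur sigma << w moves the edge by less than 2 sigma
  pr2 <- simulateRadialProfile(1795, 63, blurSigma = 2)
  est <- estimateShellFromRadialProfile(pr2$radius_um, pr2$intensity)
  expect_lt(abs(est - 63), 2 * 2)
  expect_error(estimateShellFromRadialProfile(0:10, rep(0, 11)), "all-zero")
})

test_that("summary rows report the fluorescent fraction of the radius", {
  m <- 5e7; w <- 13; xg <- 954
  d <- makeShellColonies(w, 1500, 2 * w, 1500, seed = 15)
  sf <- suppressWarnings(
    fitFsModel(d, sphereSurface(2 * w), sphereSurface(xg), form = "shell"))
  fit <- makeFixedFit(2 * w)
  sh <- shellWidthAndRadius(fit, sf, 0, xg, m = m)
  row <- tableOneReport(fit, sh)
  expect_equal(row$r_gamma_um, 13, tolerance = 1e-6)
  expect_equal(row$ratio_pct, 100 * 13 / 477, tolerance = 1e-6)
  # a shell reaching the centre covers 100% of the radius
  shFull <- shellWidthAndRadius(fit, sf, 0, xGamma = 20, m = m)
  expect_equal(tableOneReport(fit, shFull)$ratio_pct, 100)
})

test_that("both fluorescent-radius conventions are available", {
  expect_equal(fluorescentRadiusPct(13, 954), 100 * 13 / 477, tolerance = 1e-12)
  expect_equal(fluorescentRadiusPct(69, 1025, "diameter"), 100 * 69 / 1025,
               tolerance = 1e-12)
})
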