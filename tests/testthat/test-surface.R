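test_that("linear and hyperbolic FS^-1 forms recover their generating curves", {
  set.seed(5)
  S <- runif(300, 0.01, 7)
  lin <- data.frame(surface_mm2 = S, fs_au_mm2 = 2 * S + 1)
  f <- suppressWarnings(fitFsModel(lin, sB = 0.02, sGamma = 6, form = "linear"))
  expect_equal(unname(f@coef["g"]), 2, tolerance = 1e-6)
  expect_equal(unname(f@coef["i"]), 1, tolerance = 1e-6)
  expect_equal(f@fsB, 2 * 0.02 + 1, tolerance = 1e-6)
  # constant FS^-1 gives zero slope
  flat <- data.frame(surface_mm2 = S, fs_au_mm2 = rep(3, 300))
  expect_equal(unname(suppressWarnings(
    fitFsModel(flat, 0.02, 6, form = "linear"))@coef["g"]), 0,
               tolerance = 1e-9)
  hyp <- data.frame(surface_mm2 = S, fs_au_mm2 = -2 / (S - 0.005) + 9)
  fh <- suppressWarnings(fitFsModel(hyp, 0.02, 6, form = "hyperbolic"))
  expect_equal(unname(fh@coef["g0"]), -2, tolerance = 1e-3)
  expect_equal(unname(fh@coef["l"]), 0.005, tolerance = 1e-3)
  expect_equal(unname(fh@coef["i"]), 9, tolerance = 1e-3)
})

test_that("surface transformation of x_b matches the sphere formula", {
  expect_equal(sphereSurface(288), 0.2605758, tolerance = 1e-5)
  d <- makeShellColonies(89, 500, 178, 1500, seed = 6)
  f <- suppressWarnings(fitFsModel(d, sphereSurface(178), sphereSurface(954)))
  expect_lt(f@fsB, f@fsGamma)  # per-surface intensity grows toward steady state
})

test_that("the shell-volume null zeroes the residual for constant-width data", {
  for (w in c(13, 89)) {
    d <- makeShellColonies(w, 2000, 2 * w, 1500, seed = 20 + w)
    sf <- suppressWarnings(
      fitFsModel(d, sphereSurface(2 * w), sphereSurface(954), form = "shell"))
    span <- sf@fsGamma - sf@fsB
    expect_lt(abs(deltaFs(sf)) / abs(span), 1e-8)
  }
  # empty integration range
  d <- makeShellColonies(13, 200, 30, 1500, seed = 3)
  sf <- suppressWarnings(fitFsModel(d, 0.01, 2, form = "shell"))
  expect_equal(deltaFs(sf, 2, 2), 0)
})

test_that("doubling shell intensity over the range breaks the null", {
  set.seed(8)
  x <- exp(runif(2000, log(178), log(1500)))
  mRamp <- 5e7 * (1 + (x - 178) / (1500 - 178))   # intensity doubles
  f <- mRamp * shellVolume(x, 89)
  d <- data.frame(surface_mm2 = sphereSurface(x), fs_au_mm2 = f / sphereSurface(x))
  sB <- sphereSurface(178); sG <- sphereSurface(954)
  sf <- suppressWarnings(fitFsModel(d, sB, sG, form = "hyperbolic"))
  dn <- data.frame(surface_mm2 = sphereSurface(x),
                   fs_au_mm2 = 5e7 * shellVolume(x, 89) / sphereSurface(x))
  sfn <- suppressWarnings(fitFsModel(dn, sB, sG, form = "hyperbolic"))
  dd <- deltaFs(sf); d0 <- deltaFs(sfn)
  expect_gt(dd, 0)
  # the intensity signal dwarfs the model-family bias of the matched
  # constant-intensity twin
  expect_gt(abs(dd) / abs(sf@fsGamma - sf@fsB),
            3 * abs(d0) / abs(sfn@fsGamma - sfn@fsB))
})

test_that("a growing shell raises the residual above its constant-width twin", {
  # effect size of the glucoamylase case: width 144 -> 157 um over
  # diameters 288 -> 1556 um, 10% fluorescence noise
  slope <- 13 / 1268; w0 <- 144 - slope * 288
  exceed <- 0; positive <- 0
  for (s in 1:10) {
    dg <- makeShellColonies(NA, 1200, 288, 1556, cv = 0.1, seed = 200 + s,
                            widthFun = function(x) w0 + slope * x)
    dc <- makeShellColonies(144, 1200, 288, 1556, cv = 0.1, seed = 200 + s)
    sg <- suppressWarnings(
      fitFsModel(dg, sphereSurface(288), sphereSurface(1556), form = "hyperbolic"))
    sc <- suppressWarnings(
      fitFsModel(dc, sphereSurface(288), sphereSurface(1556), form = "hyperbolic"))
    exceed <- exceed + (deltaFs(sg) > deltaFs(sc))
    positive <- positive + (deltaFs(sg) > 0)
  }
  expect_gte(exceed, 9)
  expect_gte(positive, 9)
})

test_that("the intensity correction integrates the residual ramp exactly", {
  d <- makeShellColonies(89, 800, 178, 1500, seed = 9)
  sB <- sphereSurface(178); sG <- sphereSurface(954)
  sf <- suppressWarnings(fitFsModel(d, sB, sG, form = "hyperbolic"))
  dfs <- deltaFs(sf)
  fi <- intensityCorrection(sf, dfs, form = "linear")
  # closed form of the ramp integral
  expect_equal(fi, dfs * (sG - sB) / 2, tolerance = 1e-8)
  # independent adaptive quadrature oracle
  oracle <- pracma::integral(function(S) dfs * (S - sB) / (sG - sB),
                             sB, sG, reltol = 1e-12)
  expect_equal(fi, oracle, tolerance = 1e-8)
  expect_equal(intensityCorrection(sf, 0), 0)
  expect_equal(intensityCorrection(sf, dfs, sB = sG, sGamma = sG), 0)
})

test_that("the closed-form hyperbolic correction matches an independent quadrature", {
  # decreasing FS^-1 curve with positive hyperbolic scale, fixed parameters
  sf <- new("SurfaceFit", form = "hyperbolic",
            coef = c(g0 = 4, l = -0.5, i = 2), sB = 1, sGamma = 6,
            fsB = NA_real_, fsGamma = NA_real_, sRange = c(0.8, 7),
            loss = 0, n = 100L)
  sf@fsB <- pelletShell:::.fsCurve(sf, 1)
  sf@fsGamma <- pelletShell:::.fsCurve(sf, 6)
  dfs <- 0.3
  fi <- intensityCorrection(sf, dfs)
  fcv <- function(S) 4 / (S + 0.5) + 2
  den <- ((sqrt(4) + 2 + dfs - fcv(6)) / (sqrt(4) - 0.5 - 1)) *
    ((sqrt(4) - 0.5 - 6) / (sqrt(4) + 2 - fcv(1)))
  oracle <- pracma::integral(function(S) {
    ((fcv(S) - fcv(1)) / (S - 1)) * ((S - 6) / (fcv(S) - fcv(6))) / den - fcv(1)
  }, 1, 6, reltol = 1e-12)
  expect_equal(fi, oracle, tolerance = 1e-8)
  # negative scale has no real sqrt: named error
  sf@coef["g0"] <- -4
  expect_error(intensityCorrection(sf, dfs), "sqrt\\(g0\\)")
})
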