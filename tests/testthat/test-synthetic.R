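test_that("clean events pass every gate and debris fail exactly one rule each", {
  cfg <- simulationConfig(nEvents = 1000, debrisFraction = 0.2, seed = 21)
  sim <- simulatePopulation(cfg)
  cs <- gateEvents(sim$events)
  expect_equal(nColonies(cs), 800L)
  expect_equal(unname(sum(rejectedCounts(cs))), 200L)
  # rule cycling makes per-rule counts exactly predictable
  expect_equal(rejectedCounts(cs),
               c(tof = 50L, peak = 50L, width = 50L, integrated = 50L))
  # each debris event violates only its designated rule
  p <- defaultProfiles()$reporter
  deb <- merge(sim$events, sim$truth[!sim$truth$clean, c("event_id", "rule")])
  viol <- cbind(tof = deb$tof < p@tofMin | deb$tof > p@tofMax,
                peak = deb$peak_green < p@peakMin,
                width = deb$width_green < p@widthMin,
                integrated = pmin(deb$int_green, deb$int_red,
                                  deb$int_yellow) < p@intMin)
  expect_true(all(rowSums(viol) == 1))
  expect_equal(colnames(viol)[apply(viol, 1, which)], deb$rule)
})

test_that("noise-free fluorescence matches the closed-form shell fraction", {
  cfg <- simulationConfig(nEvents = 500, noiseCv = 0, debrisFraction = 0,
                          w0Um = 13, seed = 22)
  sim <- simulatePopulation(cfg)
  cs <- gateEvents(sim$events)
  x <- diameters(cs)
  fv <- colonyTable(cs)$fv_au_mm3
  expect_equal(fv, 5e7 * shellFraction(x, 13), tolerance = 1e-9)
})

test_that("uniform expression collapses FV^-1 to the constant m", {
  cfg <- simulationConfig(nEvents = 300, noiseCv = 0, debrisFraction = 0,
                          widthLaw = "none", seed = 23)
  sim <- simulatePopulation(cfg)
  cs <- gateEvents(sim$events)
  expect_equal(colonyTable(cs)$fv_au_mm3, rep(5e7, nColonies(cs)),
               tolerance = 1e-9)
})

test_that("simulation output is byte-identical for a fixed seed", {
  cfg <- simulationConfig(nEvents = 400, seed = 24)
  s1 <- simulatePopulation(cfg)
  s2 <- simulatePopulation(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulatePopulation(simulationConfig(nEvents = 400, seed = 25))
  expect_false(identical(s1$events, s3$events))
})

test_that("diameters respect the truncation range and mixture weights", {
  cfg <- simulationConfig(nEvents = 3000, seed = 26)
  sim <- simulatePopulation(cfg)
  d <- sim$truth$diameter_um[sim$truth$clean]
  expect_true(all(d >= 30 & d <= 1500))
  # the dominant component puts the mode near 950 um
  expect_gt(pelletShell:::.kdeMode(d), 850)
  expect_lt(pelletShell:::.kdeMode(d), 1100)
})

test_that("invalid simulation settings are rejected", {
  expect_error(simulationConfig(nEvents = 0), "nEvents")
  expect_error(simulationConfig(debrisFraction = 1), "debrisFraction")
  expect_error(simulationConfig(diameterMedianUm = c(100, 900),
                                diameterSdlog = 0.3,
                                diameterWeights = c(0.5, 0.5)),
               "equal lengths")
  expect_error(simulateRadialProfile(100, 60), "x/2")
})

test_that("radial profile simulation produces the documented shapes", {
  pr <- simulateRadialProfile(200, 40, blurSigma = 0, dr = 1)
  expect_true(all(pr$intensity %in% c(0, 1)))
  expect_equal(sum(pr$intensity), 41)  # band [60, 100] on a 1 um grid
  solid <- simulateRadialProfile(200, 100)
  expect_true(all(solid$intensity == 1))
  noisy1 <- simulateRadialProfile(200, 40, noiseSd = 0.1, seed = 3)
  noisy2 <- simulateRadialProfile(200, 40, noiseSd = 0.1, seed = 3)
  expect_identical(noisy1, noisy2)
})
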