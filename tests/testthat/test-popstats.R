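test_that("percentile categories follow the stated convention", {
  counts <- categorizeSizes(sample(1:1000))
  expect_equal(as.integer(counts), c(25L, 225L, 500L, 225L, 25L))
  expect_equal(sum(counts), 1000L)
  th <- attr(counts, "thresholds")
  expect_true(all(diff(th) > 0))
  # degenerate sample: all mass collapses into one category, no crash
  same <- suppressWarnings(categorizeSizes(rep(7, 50)))
  expect_equal(max(same), 50L)
  expect_equal(sum(same), 50L)
  expect_warning(categorizeSizes(1:20), "40")
  expect_error(categorizeSizes(c(1, -2, 3)), "> 0")
})

test_that("category proportions converge to 2.5/22.5/50/22.5/2.5 percent", {
  set.seed(11)
  d <- rlnorm(20000, log(800), 0.4)
  props <- as.integer(categorizeSizes(d)) / length(d)
  expect_equal(props, c(0.025, 0.225, 0.5, 0.225, 0.025), tolerance = 0.02)
})

test_that("bootstrap mode is degenerate on constant data and seeded", {
  bm <- bootstrapMode(rep(42, 25), nBoot = 50, seed = 1)
  expect_equal(bm$mode, 42)
  expect_equal(bm$ci, c(42, 42))
  d <- rlnorm(300, log(500), 0.3)
  b1 <- bootstrapMode(d, nBoot = 100, seed = 9)
  b2 <- bootstrapMode(d, nBoot = 100, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci[1] <= b1$mode && b1$mode <= b1$ci[2])
  expect_error(bootstrapMode(1:5), "at least 10")
})

test_that("bootstrap mode lands in the heavier peak of a bimodal mixture", {
  set.seed(10)
  d <- c(rnorm(300, 200, 20), rnorm(700, 800, 40))
  bm <- bootstrapMode(d, nBoot = 200, seed = 6)
  expect_gt(bm$mode, 650)
  expect_lt(bm$mode, 950)
})

test_that("bootstrap mode CI narrows as the sample grows", {
  set.seed(9)
  small <- rlnorm(200, log(800), 0.3)
  large <- rlnorm(5000, log(800), 0.3)
  wSmall <- diff(bootstrapMode(small, nBoot = 200, seed = 4)$ci)
  wLarge <- diff(bootstrapMode(large, nBoot = 200, seed = 4)$ci)
  expect_lt(wLarge, wSmall)
})

test_that("Kolmogorov-Smirnov distances match the ECDF geometry", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ksTwoSample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3,
               tolerance = 1e-12)
  expect_equal(ksTwoSample(1:5, 11:15)$D, 1)
  d <- rlnorm(50, 5, 1)
  out <- ksTwoSample(d, d)
  expect_equal(out$D, 0)
  expect_true(out$D >= 0 && out$D <= 1)
  expect_error(ksTwoSample(numeric(0), 1:3), "empty")
})

test_that("chi-square on category tables matches the Pearson formula", {
  same <- c(10, 40, 100, 40, 10)
  expect_equal(chisqCategories(same, same)$statistic, 0)
  # extreme table with empty middle categories: hand-computed Pearson value
  expect_warning(chisqCategories(c(10, 0, 0, 0, 0), c(0, 0, 0, 0, 10)), "pool")
  out <- suppressWarnings(chisqCategories(c(10, 0, 0, 0, 0), c(0, 0, 0, 0, 10)))
  expect_equal(out$statistic, 20)
  expect_equal(out$df, 4L)
  # independent Pearson-sum oracle on a dense table
  a <- c(12, 50, 101, 47, 9); b <- c(20, 44, 90, 55, 14)
  tab <- rbind(a, b)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisqCategories(a, b)$statistic, sum((tab - e)^2 / e),
               tolerance = 1e-12)
  expect_equal(chisqCategories(a, b)$df, 4L)
})

test_that("Kruskal-Wallis H matches the rank-sum formula and symmetry", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  out <- kruskalWallis(g)
  # H = 12/(N(N+1)) * sum R_j^2/n_j - 3(N+1) with R = (3, 7, 11), N = 6
  expect_equal(out$H, 12 / 42 * (9 / 2 + 49 / 2 + 121 / 2) - 21,
               tolerance = 1e-12)
  expect_equal(out$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kruskalWallis(list(1:4, 1:4, 1:4))$H,
               kruskalWallis(list(1:4, 1:4, 1:4)[c(3, 1, 2)])$H)
  expect_equal(kruskalWallis(list(c(5, 5), c(5, 5)))$H, 0)
  expect_error(kruskalWallis(list(1:3)), "two groups")
})

test_that("size-distribution summaries are internally consistent", {
  set.seed(12)
  d <- rlnorm(500, log(900), 0.3)
  sm <- sizeDistributionSummary(d, nBoot = 100, seed = 2)
  expect_equal(sum(sm@counts), sm@n)
  expect_equal(sum(sm@props), 1, tolerance = 1e-12)
  expect_true(sm@modeCi[1] <= sm@mode && sm@mode <= sm@modeCi[2])
})
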