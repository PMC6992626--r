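# Size-distribution statistics: percentile categories, bootstrap mode,
# and the population comparison tests.

.CATEGORY_NAMES <- c("smallest", "small", "median", "large", "largest")

#' Percentile size categories
#'
#' Assigns each diameter to one of five categories bounded by the sample's
#' 2.5th, 25th, 75th and 97.5th percentiles (linear interpolation between
#' order statistics). Values exactly at a boundary go to the lower category.
#'
#' @param diameters micro-colony diameters (micrometres), > 0.
#' @return named integer vector of counts (smallest, small, median, large,
#'   largest) with the percentile thresholds as attribute `"thresholds"`.
#' @examples
#' categorizeSizes(1:1000)   # 25, 225, 500, 225, 25
#' @export
categorizeSizes <- function(diameters) {
  .checkNumeric(diameters, "diameters", positive = TRUE)
  n <- length(diameters)
  if (n < 40L)
    warning("fewer than 40 diameters: some size categories may be empty",
            call. = FALSE)
  q <- stats::quantile(diameters, c(0.025, 0.25, 0.75, 0.975),
                       names = FALSE, type = 7)
  # boundary values go to the lower category; explicit comparisons also
  # handle degenerate samples where percentiles coincide
  counts <- c(sum(diameters <= q[1L]),
              sum(diameters > q[1L] & diameters <= q[2L]),
              sum(diameters > q[2L] & diameters <= q[3L]),
              sum(diameters > q[3L] & diameters <= q[4L]),
              sum(diameters > q[4L]))
  counts <- as.integer(counts)
  names(counts) <- .CATEGORY_NAMES
  attr(counts, "thresholds") <- stats::setNames(q, c("p2.5", "p25", "p75", "p97.5"))
  counts
}

# mode of a continuous sample: Gaussian KDE (Silverman bandwidth) evaluated
# on a 1 um grid over the data range; argmax, smallest on ties
.kdeMode <- function(x, gridBy = 1) {
  if (diff(range(x)) == 0) return(x[1L])
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  grid <- seq(floor(min(x)), ceiling(max(x)), by = gridBy)
  d <- stats::density(x, bw = bw, from = grid[1L], to = grid[length(grid)],
                      n = length(grid))
  d$x[which.max(d$y)]
}

#' Bootstrap mode of a diameter distribution
#'
#' Resamples the sample with replacement `nBoot` times at full size, records
#' the mode of each resample (kernel density estimate, Gaussian kernel,
#' Silverman bandwidth, argmax on a 1 micrometre grid), and reports the
#' median of the resample modes with their 2.5th/97.5th percentiles as the
#' confidence interval.
#'
#' @param diameters micro-colony diameters (micrometres); at least 10.
#' @param nBoot number of resamples.
#' @param seed RNG seed; results are reproducible per seed.
#' @return list with `mode`, `ci` (length 2) and `modes` (the resample modes).
#' @export
bootstrapMode <- function(diameters, nBoot = 1000L, seed = NULL) {
  .checkNumeric(diameters, "diameters", positive = TRUE)
  n <- length(diameters)
  if (n < 10L) stop("need at least 10 diameters", call. = FALSE)
  modes <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(i)
      .kdeMode(sample(diameters, n, replace = TRUE)), numeric(1))
  })
  est <- stats::median(modes)
  ci <- stats::quantile(modes, c(0.025, 0.975), names = FALSE, type = 7)
  list(mode = est, ci = ci, modes = modes)
}

#' Summarise a size distribution
#'
#' @inheritParams bootstrapMode
#' @return a [SizeDistributionSummary-class].
#' @export
sizeDistributionSummary <- function(diameters, nBoot = 1000L, seed = NULL) {
  counts <- categorizeSizes(diameters)
  bm <- bootstrapMode(diameters, nBoot = nBoot, seed = seed)
  new("SizeDistributionSummary", n = length(diameters), mode = bm$mode,
      modeCi = bm$ci, counts = as.integer(counts) |>
        stats::setNames(.CATEGORY_NAMES),
      props = as.integer(counts) / length(diameters),
      thresholds = attr(counts, "thresholds"), nBoot = as.integer(nBoot))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' asymptotic.
#'
#' @param d1,d2 diameter samples.
#' @return list with `D` and `p.value`.
#' @export
ksTwoSample <- function(d1, d2) {
  if (!length(d1) || !length(d2)) stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(d1, d2, exact = FALSE))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}

#' Chi-square test on size-category proportions
#'
#' Pearson chi-square on the 2 x 5 contingency table of category counts
#' (df = 4, no continuity correction). Cells whose expected count is zero
#' (possible only when a whole category is empty in both samples) contribute
#' zero to the statistic; a warning then advises pooling categories.
#'
#' @param countsA,countsB length-5 category count vectors.
#' @return list with `statistic`, `df` and `p.value`.
#' @export
chisqCategories <- function(countsA, countsB) {
  if (length(countsA) != 5L || length(countsB) != 5L)
    stop("category counts must have length 5", call. = FALSE)
  tab <- rbind(countsA, countsB)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("zero expected count in some categories; consider pooling them",
            call. = FALSE)
    ok <- expected > 0
    stat <- sum((tab[ok] - expected[ok])^2 / expected[ok])
    df <- 4L
    return(list(statistic = stat, df = df,
                p.value = stats::pchisq(stat, df, lower.tail = FALSE)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value)
}

#' Kruskal-Wallis rank test across culture conditions
#'
#' Tie-corrected H with the asymptotic chi-square p-value; used for dry
#' weight comparisons between media.
#'
#' @param groups list of at least two numeric vectors.
#' @return list with `H`, `df` and `p.value`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(!vapply(groups, length, 1L)))
    stop("each group needs at least one observation", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p.value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}
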