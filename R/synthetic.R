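# Seeded generator of synthetic cytometry runs with known shell geometry.

#' Construct synthetic-population settings
#'
#' Defaults emulate a typical post-transfer population: a two-component
#' lognormal mixture of diameters -- a dominant pellet mode (median 1000 um,
#' log-sd 0.25, modal diameter near 940 um, 80\% weight) plus a minority
#' tail of small pellets and fragments (median 250 um, log-sd 0.8, 20\%
#' weight) -- truncated to the instrument range 30-1500 um, a constant 13 um
#' expression shell, fluorescence 5e7 AU per mm^3 of shell (which puts the
#' faintest in-range colonies comfortably above the integrated-density
#' gate), 10\% multiplicative noise and 10\% debris.
#'
#' @param nEvents total events.
#' @param diameterMedianUm,diameterSdlog,diameterWeights lognormal mixture
#'   of diameters (medians um, log-sd, weights).
#' @param diameterRangeUm truncation range (um).
#' @param widthLaw `"constant"`, `"linear"` or `"none"`.
#' @param w0Um shell width (um); intercept of the linear law.
#' @param wSlope width gain per um diameter (linear law only).
#' @param mAuPerMm3 fluorescence per shell volume.
#' @param noiseCv CV of multiplicative fluorescence noise.
#' @param debrisFraction fraction of gate-violating events.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nEvents = 10000L,
                             diameterMedianUm = c(1000, 250),
                             diameterSdlog = c(0.25, 0.8),
                             diameterWeights = c(0.8, 0.2),
                             diameterRangeUm = c(30, 1500),
                             widthLaw = c("constant", "linear", "none"),
                             w0Um = 13, wSlope = 0, mAuPerMm3 = 5e7,
                             noiseCv = 0.1, debrisFraction = 0.1, seed = 1L) {
  widthLaw <- match.arg(widthLaw)
  new("SimulationConfig", nEvents = as.integer(nEvents),
      diameterMedianUm = diameterMedianUm, diameterSdlog = diameterSdlog,
      diameterWeights = diameterWeights / sum(diameterWeights),
      diameterRangeUm = diameterRangeUm, widthLaw = widthLaw, w0Um = w0Um,
      wSlope = wSlope, mAuPerMm3 = mAuPerMm3, noiseCv = noiseCv,
      debrisFraction = debrisFraction, seed = as.integer(seed))
}

.drawDiameters <- function(n, cfg) {
  k <- length(cfg@diameterMedianUm)
  lo <- cfg@diameterRangeUm[1L]; hi <- cfg@diameterRangeUm[2L]
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    comp <- sample.int(k, m, replace = TRUE, prob = cfg@diameterWeights)
    x <- stats::rlnorm(m, meanlog = log(cfg@diameterMedianUm)[comp],
                       sdlog = cfg@diameterSdlog[comp])
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

.widthAt <- function(x, cfg) {
  w <- switch(cfg@widthLaw,
              constant = rep(cfg@w0Um, length(x)),
              linear = cfg@w0Um + cfg@wSlope * x,
              none = x / 2)
  pmin(w, x / 2)
}

# channel values that clear every default reporter gate
.CLEAN_PEAK <- 500
.CLEAN_WIDTH <- 5000
.CLEAN_INT <- 100

#' Simulate a cytometry run over a shell-expressing population
#'
#' Draws colony diameters from the configured truncated lognormal mixture,
#' assigns each a shell width w(x) by the width law, and sets the
#' integrated green fluorescence to
#' \eqn{F = m V_{shell}(x, w(x)) (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, cv)} truncated so F >= 0. TOF is the forward
#' calibration of the diameter; the remaining channels are set safely above
#' the reporter gating thresholds. Debris events are appended, each
#' violating exactly one gating rule (cycling tof, peak, width, integrated)
#' so per-rule rejection counts are exactly predictable, then all rows are
#' shuffled. Output is byte-identical for a given configuration.
#'
#' @param cfg a [SimulationConfig-class].
#' @param cal a [CalibrationCurve-class] used for the forward TOF map.
#' @return list with `events` (the raw event table, one row per particle)
#'   and `truth` (per-event ground truth: diameter, shell width, shell
#'   volume, noise-free and realised fluorescence, clean/debris flag and
#'   violated rule), joined by `event_id`, plus the `config`.
#' @export
simulatePopulation <- function(cfg = simulationConfig(),
                               cal = calibrationCurve()) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  n <- cfg@nEvents
  nClean <- as.integer(round(n * (1 - cfg@debrisFraction)))
  nDebris <- n - nClean

  .withSeed(cfg@seed, {
    x <- .drawDiameters(nClean, cfg)
    w <- .widthAt(x, cfg)
    vs <- shellVolume(x, w)
    f0 <- cfg@mAuPerMm3 * vs
    eps <- if (cfg@noiseCv > 0) stats::rnorm(nClean, 0, cfg@noiseCv) else 0
    f <- f0 * pmax(1 + eps, 0)
    clean <- data.frame(
      tof = diameterToTof(x, cal), peak_green = .CLEAN_PEAK,
      width_green = .CLEAN_WIDTH, int_green = f,
      int_red = .CLEAN_INT, int_yellow = .CLEAN_INT)

    rules <- c("tof", "peak", "width", "integrated")
    debris <- NULL
    if (nDebris > 0L) {
      xd <- .drawDiameters(nDebris, cfg)
      rule <- rules[(seq_len(nDebris) - 1L) %% 4L + 1L]
      debris <- data.frame(
        tof = diameterToTof(xd, cal), peak_green = .CLEAN_PEAK,
        width_green = .CLEAN_WIDTH, int_green = .CLEAN_INT,
        int_red = .CLEAN_INT, int_yellow = .CLEAN_INT)
      low <- rep(c(TRUE, FALSE), length.out = sum(rule == "tof"))
      debris$tof[rule == "tof"] <- ifelse(low, 100, 20000)
      debris$peak_green[rule == "peak"] <- 40
      debris$width_green[rule == "width"] <- 1000
      debris$int_red[rule == "integrated"] <- 10
    }

    events <- rbind(clean, debris)
    events$event_id <- seq_len(n)
    truth <- data.frame(
      event_id = seq_len(n),
      clean = rep(c(TRUE, FALSE), c(nClean, nDebris)),
      rule = c(rep(NA_character_, nClean),
               if (nDebris > 0L) rules[(seq_len(nDebris) - 1L) %% 4L + 1L]),
      diameter_um = c(x, if (nDebris > 0L) xd),
      width_um = c(w, if (nDebris > 0L) rep(NA_real_, nDebris)),
      shell_volume_mm3 = c(vs, if (nDebris > 0L) rep(NA_real_, nDebris)),
      f_noisefree_au = c(f0, if (nDebris > 0L) rep(NA_real_, nDebris)),
      f_au = c(f, if (nDebris > 0L) rep(NA_real_, nDebris)))

    perm <- sample.int(n)
    events <- events[perm, c("event_id", "tof", "peak_green", "width_green",
                             "int_green", "int_red", "int_yellow")]
    truth <- truth[perm, ]
    rownames(events) <- rownames(truth) <- NULL
    list(events = events, truth = truth, config = cfg)
  })
}

#' Simulate a 1-D radial intensity profile
#'
#' Unit intensity on the outer band \[x/2 - w, x/2\], zero inside, optionally
#' smoothed with a Gaussian kernel (reflected at both ends) and perturbed
#' with additive noise. A stand-in for a confocal equatorial cross-section.
#'
#' @param x colony diameter (micrometres).
#' @param w shell width (micrometres), <= x/2.
#' @param blurSigma Gaussian blur scale (micrometres); 0 gives the exact
#'   step profile.
#' @param dr radial sampling step (micrometres).
#' @param noiseSd additive noise sd.
#' @param seed RNG seed for the noise.
#' @return data.frame with `radius_um` and `intensity`.
#' @export
simulateRadialProfile <- function(x, w, blurSigma = 0, dr = 0.5,
                                  noiseSd = 0, seed = NULL) {
  .checkNumeric(x, "x", positive = TRUE)
  .checkNumeric(w, "w", positive = TRUE)
  if (w > x / 2) stop("'w' must not exceed x/2", call. = FALSE)
  r <- seq(0, x / 2, by = dr)
  intensity <- as.numeric(r >= x / 2 - w)
  if (blurSigma > 0) {
    half <- max(1L, ceiling(4 * blurSigma / dr))
    kern <- stats::dnorm(seq(-half, half) * dr, sd = blurSigma)
    kern <- kern / sum(kern)
    padded <- c(rev(intensity[seq_len(half) + 1L]), intensity,
                rev(intensity)[seq_len(half) + 1L])
    intensity <- vapply(seq_along(intensity), function(i)
      sum(padded[i:(i + 2L * half)] * kern), numeric(1))
  }
  if (noiseSd > 0)
    intensity <- pmax(intensity +
                        .withSeed(seed, stats::rnorm(length(r), 0, noiseSd)), 0)
  data.frame(radius_um = r, intensity = intensity)
}
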