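#' @import methods
NULL

#' Quadratic time-of-flight calibration
#'
#' Maps between the large-particle cytometer's time-of-flight (TOF, arbitrary
#' units) and micro-colony diameter (micrometres) through the bead-derived
#' quadratic \eqn{TOF = a x^2 + b x}. The inverse is the positive root of the
#' quadratic.
#'
#' @slot aCal quadratic coefficient (AU per square micrometre), > 0.
#' @slot bCal linear coefficient (AU per micrometre), > 0.
#'
#' @seealso [calibrationCurve()], [tofToDiameter()], [diameterToTof()]
#' @export
setClass("CalibrationCurve",
  representation(aCal = "numeric", bCal = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@aCal) != 1L || !is.finite(object@aCal) || object@aCal <= 0)
      msg <- c(msg, "'aCal' must be a single positive number")
    if (length(object@bCal) != 1L || !is.finite(object@bCal) || object@bCal <= 0)
      msg <- c(msg, "'bCal' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Particle-selection thresholds
#'
#' Thresholds applied to raw cytometer events before analysis. An event is
#' kept when its TOF lies in `[tofMin, tofMax]`, its green fluorescence peak
#' height is at least `peakMin`, its peak width at least `widthMin`, and (for
#' reporter strains) the integrated density of each of the green, red and
#' yellow channels is at least `intMin`. Events exactly at a threshold are
#' kept.
#'
#' @slot tofMin,tofMax TOF acceptance window (AU).
#' @slot peakMin minimum green peak height (AU).
#' @slot widthMin minimum green peak width (AU).
#' @slot intMin minimum integrated density per channel (AU); `NA` when unused.
#' @slot requireIntegrated whether the integrated-density rule is applied.
#'
#' @seealso [gatingProfile()], [defaultProfiles()], [gateEvents()]
#' @export
setClass("GatingProfile",
  representation(tofMin = "numeric", tofMax = "numeric", peakMin = "numeric",
                 widthMin = "numeric", intMin = "numeric",
                 requireIntegrated = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!isTRUE(object@tofMin < object@tofMax))
      msg <- c(msg, "'tofMin' must be < 'tofMax'")
    thr <- c(object@tofMin, object@peakMin, object@widthMin)
    if (any(!is.finite(thr)) || any(thr < 0))
      msg <- c(msg, "thresholds must be finite and >= 0")
    if (object@requireIntegrated &&
        (!is.finite(object@intMin) || object@intMin < 0))
      msg <- c(msg, "'intMin' must be >= 0 when the integrated rule is active")
    if (is.null(msg)) TRUE else msg
  })

#' Gated micro-colony population
#'
#' The result of [gateEvents()]: one row per kept particle with its derived
#' diameter, spherical volume and surface, integrated green fluorescence F,
#' and the per-volume (FV^-1) and per-surface (FS^-1) intensities, together
#' with per-rule rejection counts.
#'
#' @slot colonies data.frame with columns `diameter_um`, `volume_mm3`,
#'   `surface_mm2`, `f_au`, `fv_au_mm3`, `fs_au_mm2`.
#' @slot nInput number of input events.
#' @slot rejected named integer vector of per-rule rejection counts, in the
#'   fixed attribution order tof, peak, width, integrated.
#' @slot profile the [GatingProfile-class] applied.
#' @slot calibration the [CalibrationCurve-class] used.
#'
#' @export
setClass("ColonySet",
  representation(colonies = "data.frame", nInput = "integer",
                 rejected = "integer", profile = "GatingProfile",
                 calibration = "CalibrationCurve"),
  validity = function(object) {
    need <- c("diameter_um", "volume_mm3", "surface_mm2", "f_au",
              "fv_au_mm3", "fs_au_mm2")
    msg <- NULL
    if (!all(need %in% names(object@colonies)))
      msg <- c(msg, paste("missing colony columns:",
                          paste(setdiff(need, names(object@colonies)), collapse = ", ")))
    if (length(object@rejected) != 4L ||
        !identical(names(object@rejected), c("tof", "peak", "width", "integrated")))
      msg <- c(msg, "'rejected' must be named counts for tof, peak, width, integrated")
    else if (nrow(object@colonies) + sum(object@rejected) != object@nInput)
      msg <- c(msg, "kept + rejected must equal the number of input events")
    if (is.null(msg)) TRUE else msg
  })

#' Hyperbolic fluorescence-per-volume fit
#'
#' Median (tau = 0.5) quantile fit of FV^-1 = a/(x - b) + c to gated
#' colonies, with a case-resampling bootstrap ensemble and pointwise 95\%
#' band. `b` is the vertical-asymptote diameter x_b at which fluorescence
#' per volume is maximal; `gamma` is the steady-state fluorescence per
#' volume (by default the fitted intercept `c`); `alpha` is the scale of the
#' companion fit dF/dV = alpha/V + gamma when that fit was requested.
#'
#' @slot a,b,c hyperbola parameters (a >= 0; b in micrometres).
#' @slot alpha,gamma companion-model parameters; `alpha` may be `NA`.
#' @slot gammaSource `"intercept"` or `"dfdv"`.
#' @slot degenerate flag for the horizontal-line special case (a = 0, b
#'   arbitrary), used when a hyperbola does not improve on a flat median.
#' @slot loss attained pinball loss.
#' @slot tau fitted quantile.
#' @slot n number of colonies.
#' @slot xRange observed diameter range (micrometres).
#' @slot boot B x 3 matrix of bootstrap (a, b, c) draws.
#' @slot band data.frame `x`, `lo`, `hi`: pointwise percentile band of the
#'   median curve on a 1 micrometre grid.
#'
#' @export
setClass("HyperbolicFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", gamma = "numeric", gammaSource = "character",
                 degenerate = "logical", loss = "numeric", tau = "numeric",
                 n = "integer", xRange = "numeric", boot = "matrix",
                 band = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!object@degenerate && (!is.finite(object@a) || object@a < 0))
      msg <- c(msg, "'a' must be >= 0")
    if (length(object@xRange) != 2L) msg <- c(msg, "'xRange' must be length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Fluorescence-per-surface model fit
#'
#' Median quantile fit of FS^-1 against spherical surface area S on one of
#' three forms: `"linear"` (g S + i), `"hyperbolic"` (g0/(S - l) + i, with the
#' asymptote l constrained below the data), or `"shell"` (the constant-width
#' spherical-shell law m V_shell(x(S), x_b/2)/S, the generator's null model).
#'
#' @slot form one of `"linear"`, `"hyperbolic"`, `"shell"`.
#' @slot coef named parameter vector (`g`,`i` / `g0`,`l`,`i` / `m`,`xB`).
#' @slot sB,sGamma surface areas (mm^2) corresponding to x_b and x_gamma.
#' @slot fsB,fsGamma fitted FS^-1 at `sB` and `sGamma` (AU per mm^2).
#' @slot sRange observed surface range of the data (mm^2).
#' @slot loss attained pinball loss.
#' @slot n number of colonies used.
#'
#' @export
setClass("SurfaceFit",
  representation(form = "character", coef = "numeric", sB = "numeric",
                 sGamma = "numeric", fsB = "numeric", fsGamma = "numeric",
                 sRange = "numeric", loss = "numeric", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@form %in% c("linear", "hyperbolic", "shell"))
      msg <- c(msg, "'form' must be linear, hyperbolic or shell")
    if (!isTRUE(object@sB < object@sGamma))
      msg <- c(msg, "'sB' must be < 'sGamma'")
    if (is.null(msg)) TRUE else msg
  })

#' Inferred peripheral expression shell
#'
#' Output of [shellWidthAndRadius()]: the spherical-shell geometry implied by
#' the fitted fluorescence models. `rGamma` is the shell radial width at the
#' steady-state diameter `xGamma`; `iX` the fluorescent fraction of the
#' colony radius there; `iV = 1 - (1 - iX)^3` the fluorescent volume
#' fraction.
#'
#' @slot xB,xGamma diameters (micrometres) bounding the transition regime.
#' @slot m fluorescence per unit shell volume (AU per mm^3).
#' @slot deltaFs residual change in FS^-1 not explained by shell-volume
#'   growth (AU per mm^2).
#' @slot fI surface- and volume-independent intensity correction (AU).
#' @slot z shell-radius increment at `xGamma` (micrometres).
#' @slot iX,iV relative fluorescent radius and volume fraction at `xGamma`.
#' @slot rGamma shell width at steady state (micrometres).
#' @slot rGammaCi percentile 95\% CI for `rGamma` (`NA` when no bootstrap
#'   ensemble was supplied).
#' @slot sfit the [SurfaceFit-class] used.
#'
#' @export
setClass("ShellEstimate",
  representation(xB = "numeric", xGamma = "numeric", m = "numeric",
                 deltaFs = "numeric", fI = "numeric", z = "numeric",
                 iX = "numeric", iV = "numeric", rGamma = "numeric",
                 rGammaCi = "numeric", sfit = "SurfaceFit"),
  validity = function(object) {
    msg <- NULL
    if (!(object@iX > 0 && object@iX <= 1)) msg <- c(msg, "'iX' must be in (0, 1]")
    if (object@iV < 0 || object@iV > 1) msg <- c(msg, "'iV' must be in [0, 1]")
    if (object@rGamma > object@xGamma / 2 + 1e-9)
      msg <- c(msg, "'rGamma' cannot exceed half the steady-state diameter")
    if (is.null(msg)) TRUE else msg
  })

#' Size-distribution summary
#'
#' Mode of the diameter distribution with a bootstrap percentile confidence
#' interval, and counts/proportions of the five percentile size categories
#' (smallest, small, median, large, largest).
#'
#' @slot n sample size.
#' @slot mode estimated modal diameter (micrometres).
#' @slot modeCi bootstrap 2.5th/97.5th percentile interval.
#' @slot counts named category counts.
#' @slot props category proportions (sum to 1).
#' @slot thresholds the sample 2.5/25/75/97.5 percentiles used.
#' @slot nBoot number of bootstrap resamples.
#'
#' @export
setClass("SizeDistributionSummary",
  representation(n = "integer", mode = "numeric", modeCi = "numeric",
                 counts = "integer", props = "numeric", thresholds = "numeric",
                 nBoot = "integer"),
  validity = function(object) {
    msg <- NULL
    if (sum(object@counts) != object@n) msg <- c(msg, "counts must sum to n")
    if (abs(sum(object@props) - 1) > 1e-12) msg <- c(msg, "props must sum to 1")
    if (!(object@modeCi[1L] <= object@mode && object@mode <= object@modeCi[2L]))
      msg <- c(msg, "mode must lie inside its confidence interval")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic-population settings
#'
#' Parameters of the seeded generator that emulates a cytometry run on a
#' population of spherical micro-colonies expressing a fluorescent reporter
#' in a peripheral shell. Diameters follow a (mixture of) lognormal
#' distribution(s) truncated to the instrument range; fluorescence is
#' proportional to the shell volume with multiplicative noise; a configurable
#' fraction of debris events each violate exactly one gating rule.
#'
#' @slot nEvents total number of events (clean + debris).
#' @slot diameterMedianUm,diameterSdlog,diameterWeights mixture components of
#'   the diameter law (median in micrometres, log-scale sd, weights summing
#'   to 1).
#' @slot diameterRangeUm truncation range (micrometres).
#' @slot widthLaw `"constant"`, `"linear"` (in diameter) or `"none"`
#'   (uniform expression through the whole colony).
#' @slot w0Um shell width (micrometres); intercept for the linear law.
#' @slot wSlope width increase per micrometre of diameter (linear law).
#' @slot mAuPerMm3 fluorescence per unit shell volume.
#' @slot noiseCv coefficient of variation of multiplicative fluorescence
#'   noise (normal on the CV scale, truncated at zero).
#' @slot debrisFraction fraction of events that violate a gate.
#' @slot seed RNG seed; the output is reproducible per seed.
#'
#' @export
setClass("SimulationConfig",
  representation(nEvents = "integer", diameterMedianUm = "numeric",
                 diameterSdlog = "numeric", diameterWeights = "numeric",
                 diameterRangeUm = "numeric", widthLaw = "character",
                 w0Um = "numeric", wSlope = "numeric", mAuPerMm3 = "numeric",
                 noiseCv = "numeric", debrisFraction = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    k <- length(object@diameterMedianUm)
    if (object@nEvents <= 0L) msg <- c(msg, "'nEvents' must be > 0")
    if (length(object@diameterSdlog) != k || length(object@diameterWeights) != k)
      msg <- c(msg, "diameter mixture components must have equal lengths")
    if (abs(sum(object@diameterWeights) - 1) > 1e-9)
      msg <- c(msg, "'diameterWeights' must sum to 1")
    if (any(object@diameterSdlog <= 0) || any(object@diameterMedianUm <= 0))
      msg <- c(msg, "diameter law parameters must be positive")
    if (!object@widthLaw %in% c("constant", "linear", "none"))
      msg <- c(msg, "'widthLaw' must be constant, linear or none")
    if (object@widthLaw != "none" && object@w0Um <= 0)
      msg <- c(msg, "'w0Um' must be > 0")
    if (object@noiseCv < 0) msg <- c(msg, "'noiseCv' must be >= 0")
    if (object@debrisFraction < 0 || object@debrisFraction >= 1)
      msg <- c(msg, "'debrisFraction' must be in [0, 1)")
    if (object@mAuPerMm3 <= 0) msg <- c(msg, "'mAuPerMm3' must be > 0")
    if (is.null(msg)) TRUE else msg
  })
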