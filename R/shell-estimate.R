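# Spherical-shell geometry inversion: from the fitted fluorescence models to
# the width, relative radius and volume fraction of the peripheral
# expression zone.

# integral of the fitted FS^-1 curve over [lo, hi] by adaptive quadrature
.fsIntegral <- function(sfit, lo, hi) {
  if (lo == hi) return(0)
  int <- stats::integrate(function(S) .fsCurve(sfit, S), lo, hi,
                          abs.tol = 1e-10, subdivisions = 500L)
  if (int$message != "OK")
    stop("integration failure over the FS^-1 curve: ", int$message,
         call. = FALSE)
  int$value
}

# diameter (um) of the colony whose shell of width xB/2 has volume V (mm^3);
# monotone in x over (0, Inf) because the shell fills the whole colony for
# x <= xB
.diameterOfShellVolume <- function(V, xB) {
  if (V <= 0) stop("negative shell volume", call. = FALSE)
  f <- function(x) shellVolume(x, xB / 2) - V
  hi <- xB
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

#' Fluorescence per unit shell volume
#'
#' Estimates m, the proportionality between integrated fluorescence and the
#' volume of a peripheral shell of width x_b/2, as the median over colonies
#' of \eqn{F / V_{shell}(x, x_b/2)}.
#'
#' @param object a [ColonySet-class].
#' @param xB the maximal-expression diameter x_b (micrometres), > 0.
#' @return m in AU per mm^3.
#' @export
shellIntensity <- function(object, xB) {
  stopifnot(is(object, "ColonySet"))
  if (!isTRUE(xB > 0))
    stop("'xB' must be > 0 (negative shell volume)", call. = FALSE)
  x <- object@colonies$diameter_um
  stats::median(object@colonies$f_au / shellVolume(x, xB / 2))
}

#' Infer the peripheral shell's width, relative radius and volume fraction
#'
#' Converts the fitted fluorescence-per-surface curve into shell volumes
#' \eqn{V_{s_b} = \int_{S_b}^{S_\gamma} FS^{-1} dS / m} (uncorrected) and
#' \eqn{V_s = (F_i + \int FS^{-1} dS)/m} (including the intensity
#' correction), maps both to the diameters of colonies whose x_b/2-wide
#' shells hold those volumes, and forms the radius increment
#' \eqn{z = x_b x_{V_s} / (2 x_{V_{s_b}}) - x_{V_{s_b}}/2}, the relative
#' fluorescent radius \eqn{I_x = (x_{V_{s_b}}/2 + z)/(x/2)} evaluated at the
#' steady-state diameter, and the shell width
#' \eqn{r_\gamma = I_x \cdot x_\gamma/2}. Algebraically
#' \eqn{r_\gamma = (x_b/2) \cdot x_{V_s}/x_{V_{s_b}}}: with no intensity
#' correction the shell width at steady state is exactly half the
#' maximal-expression diameter.
#'
#' When the fit carries a bootstrap ensemble and `colonies` are supplied,
#' the chain is re-evaluated per bootstrap draw of (b, c) to give a
#' percentile CI for r_gamma.
#'
#' @param fit a [HyperbolicFit-class] (provides x_b = b).
#' @param sfit a [SurfaceFit-class].
#' @param fI intensity correction from [intensityCorrection()].
#' @param xGamma steady-state diameter from [findXGamma()].
#' @param m fluorescence per shell volume; estimated from `colonies` via
#'   [shellIntensity()] when `NULL`.
#' @param colonies optional [ColonySet-class] for estimating `m` and the
#'   bootstrap CI.
#' @return a [ShellEstimate-class].
#' @export
shellWidthAndRadius <- function(fit, sfit, fI, xGamma, m = NULL,
                                colonies = NULL) {
  stopifnot(is(fit, "HyperbolicFit"), is(sfit, "SurfaceFit"))
  xB <- fit@b
  if (!isTRUE(is.finite(xB) && xB > 0))
    stop("x_b must be positive and finite to define a shell ",
         "(negative shell volume implied by x_b = ", xB, ")", call. = FALSE)
  if (is.null(m)) {
    if (is.null(colonies))
      stop("supply 'm' or 'colonies' to estimate it", call. = FALSE)
    m <- shellIntensity(colonies, xB)
  }
  est <- .shellChain(xB, sfit, fI, xGamma, m)

  ci <- c(NA_real_, NA_real_)
  if (nrow(fit@boot) && !is.null(colonies)) {
    rs <- vapply(seq_len(nrow(fit@boot)), function(k) {
      bk <- fit@boot[k, "b"]
      if (!is.finite(bk) || bk <= 0) return(NA_real_)
      mk <- shellIntensity(colonies, bk)
      tryCatch(.shellChain(bk, sfit, fI, xGamma, mk)$rGamma,
               error = function(e) NA_real_)
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    if (length(rs) >= 20L)
      ci <- stats::quantile(rs, c(0.025, 0.975), names = FALSE, type = 7)
  }

  new("ShellEstimate", xB = xB, xGamma = xGamma, m = m,
      deltaFs = est$dFs, fI = fI, z = est$z, iX = est$iX, iV = est$iV,
      rGamma = est$rGamma, rGammaCi = ci, sfit = sfit)
}

.shellChain <- function(xB, sfit, fI, xGamma, m) {
  sB <- sphereSurface(xB)
  sG <- sphereSurface(xGamma)
  if (xGamma <= xB) {
    # fully fluorescent regime: the shell is the whole colony
    return(list(dFs = 0, z = 0, iX = 1, iV = 1, rGamma = xGamma / 2))
  }
  intF <- .fsIntegral(sfit, sB, sG)
  vSb <- intF / m
  vS <- (fI + intF) / m
  if (vSb <= 0 || vS <= 0) stop("negative shell volume", call. = FALSE)
  xVs <- .diameterOfShellVolume(vS, xB)
  xVsb <- .diameterOfShellVolume(vSb, xB)
  z <- xB * xVs / (2 * xVsb) - 0.5 * xVsb
  iX <- min((0.5 * xVsb + z) / (0.5 * xGamma), 1)
  rGamma <- iX * 0.5 * xGamma
  list(dFs = tryCatch(deltaFs(sfit, sB, sG), error = function(e) NA_real_),
       z = z, iX = iX, iV = 1 - (1 - iX)^3, rGamma = rGamma)
}

#' @describeIn shellWidthAndRadius shell width (micrometres) implied at
#'   arbitrary diameters: the chain is re-evaluated with the running upper
#'   limit S(x), the intensity correction accumulated along the Eq-ramp
#'   \eqn{F_i(S) = F_i ((S - S_b)/(S_\gamma - S_b))^2}.
#' @param object a [ShellEstimate-class].
#' @param x diameters (micrometres).
#' @export
setMethod("shellWidth", "ShellEstimate", function(object, x) {
  vapply(x, function(xi) {
    if (xi <= object@xB) return(xi / 2)
    sB <- sphereSurface(object@xB)
    sG <- sphereSurface(object@xGamma)
    S <- sphereSurface(xi)
    intF <- .fsIntegral(object@sfit, sB, S)
    fIx <- object@fI * ((S - sB) / (sG - sB))^2
    vSb <- intF / object@m
    vS <- (fIx + intF) / object@m
    if (vSb <= 0 || vS <= 0) stop("negative shell volume", call. = FALSE)
    w <- (object@xB / 2) * .diameterOfShellVolume(vS, object@xB) /
      .diameterOfShellVolume(vSb, object@xB)
    min(w, xi / 2)
  }, numeric(1))
})

#' Fluorescent volume fraction from the relative radius
#'
#' \eqn{I_v = 1 - (1 - I_x)^3}: the fraction of a sphere's volume occupied
#' by a peripheral shell reaching a fraction I_x of its radius.
#'
#' @param iX relative fluorescent radius, in \[0, 1\].
#' @return I_v in \[0, 1\].
#' @export
fluorescentVolumeFraction <- function(iX) {
  .checkNumeric(iX, "iX")
  if (any(iX < 0 | iX > 1)) stop("'iX' must be in [0, 1]", call. = FALSE)
  1 - (1 - iX)^3
}

#' Direct geometric inversion of a shell width
#'
#' Independent oracle for the model-based shell estimate: solves
#' \eqn{V_{shell}(x, w) / V(x) = fv / fv_{max}} for the width w by bisection
#' (tolerance 1e-6 micrometres). `fv` is the observed fluorescence per
#' volume at diameter `x` and `fvMax` the fluorescence per volume of a fully
#' fluorescent colony.
#'
#' @param fv fluorescence per volume at `x` (AU per mm^3), > 0.
#' @param fvMax maximal fluorescence per volume (AU per mm^3), >= `fv`.
#' @param x diameter (micrometres), > 0.
#' @return shell width w in (0, x/2\].
#' @examples
#' directShellInversion(1, 1, 954)            # 477: fully fluorescent
#' @export
directShellInversion <- function(fv, fvMax, x) {
  .checkNumeric(fv, "fv", positive = TRUE)
  .checkNumeric(fvMax, "fvMax", positive = TRUE)
  .checkNumeric(x, "x", positive = TRUE)
  if (fv > fvMax) stop("'fv' must not exceed 'fvMax'", call. = FALSE)
  frac <- fv / fvMax
  if (frac >= 1) return(x / 2)
  lo <- 0; hi <- x / 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (shellFraction(x, mid) < frac) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Shell width from a radial intensity profile
#'
#' Measures, on a 1-D radial profile (e.g. a confocal cross-section through
#' a colony's equator), the width of the contiguous outer region whose
#' intensity is at least half the profile maximum.
#'
#' @param radius radial positions (micrometres), increasing from the centre.
#' @param intensity non-negative intensities at `radius`.
#' @return shell width in micrometres.
#' @export
estimateShellFromRadialProfile <- function(radius, intensity) {
  .checkNumeric(radius, "radius", nonNegative = TRUE)
  .checkNumeric(intensity, "intensity", nonNegative = TRUE)
  if (length(radius) != length(intensity))
    stop("'radius' and 'intensity' must have equal length", call. = FALSE)
  if (all(intensity == 0)) stop("all-zero profile", call. = FALSE)
  o <- order(radius)
  radius <- radius[o]; intensity <- intensity[o]
  above <- intensity >= max(intensity) / 2
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- max(which(runs$values))   # run closest to the outer edge
  radius[ends[k]] - radius[starts[k]]
}

#' Fluorescent radius as a percentage of colony size
#'
#' Two conventions are in use for relating a measured fluorescent-shell
#' radius to colony size: relative to the colony radius
#' (`"radius"`: 100 r / (d/2)) or relative to the diameter
#' (`"diameter"`: 100 r / d).
#'
#' @param radius fluorescent shell radius (micrometres).
#' @param diameter colony diameter (micrometres).
#' @param convention `"radius"` or `"diameter"`.
#' @return percentage.
#' @export
fluorescentRadiusPct <- function(radius, diameter,
                                 convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  .checkNumeric(radius, "radius", nonNegative = TRUE)
  .checkNumeric(diameter, "diameter", positive = TRUE)
  if (convention == "radius") 100 * radius / (diameter / 2)
  else 100 * radius / diameter
}

#' Summary row of the fitted shell model
#'
#' Collects x_b, x_gamma, r_gamma and the percentage of the steady-state
#' colony radius that fluoresces, 100 r_gamma / (x_gamma / 2), with
#' bootstrap percentile CIs where an ensemble is available.
#'
#' @param fit a [HyperbolicFit-class].
#' @param shell a [ShellEstimate-class].
#' @return one-row data.frame with unit-suffixed columns.
#' @export
tableOneReport <- function(fit, shell) {
  stopifnot(is(fit, "HyperbolicFit"), is(shell, "ShellEstimate"))
  xbCi <- if (nrow(fit@boot))
    stats::quantile(fit@boot[, "b"], c(0.025, 0.975), names = FALSE, type = 7)
  else c(NA_real_, NA_real_)
  ratio <- 100 * shell@rGamma / (0.5 * shell@xGamma)
  ratioCi <- 100 * shell@rGammaCi / (0.5 * shell@xGamma)
  data.frame(x_b_um = shell@xB, x_b_lo_um = xbCi[1L], x_b_hi_um = xbCi[2L],
             x_gamma_um = shell@xGamma,
             r_gamma_um = shell@rGamma,
             r_gamma_lo_um = shell@rGammaCi[1L],
             r_gamma_hi_um = shell@rGammaCi[2L],
             ratio_pct = ratio,
             ratio_lo_pct = ratioCi[1L], ratio_hi_pct = ratioCi[2L],
             i_v = shell@iV)
}
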