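# Fluorescence per surface area: model fit, the shell-volume-growth null,
# and the intensity correction F_i.

# evaluate a SurfaceFit curve at surface areas S (mm^2)
.fsCurve <- function(sfit, S) {
  cf <- sfit@coef
  switch(sfit@form,
    linear = cf[["g"]] * S + cf[["i"]],
    hyperbolic = cf[["g0"]] / (S - cf[["l"]]) + cf[["i"]],
    shell = {
      x <- .diameterFromSurface(S)
      cf[["m"]] * shellVolume(x, cf[["xB"]] / 2) / S
    })
}

# analytic derivative for the closed forms; central difference for "shell"
.fsDeriv <- function(sfit, S) {
  cf <- sfit@coef
  switch(sfit@form,
    linear = rep(cf[["g"]], length(S)),
    hyperbolic = -cf[["g0"]] / (S - cf[["l"]])^2,
    {
      h <- pmax(abs(S), 1e-6) * 1e-6
      (.fsCurve(sfit, S + h) - .fsCurve(sfit, S - h)) / (2 * h)
    })
}

.extractSFs <- function(object) {
  if (is(object, "ColonySet"))
    return(list(S = object@colonies$surface_mm2, fs = object@colonies$fs_au_mm2))
  if (is.data.frame(object) && all(c("surface_mm2", "fs_au_mm2") %in% names(object)))
    return(list(S = object$surface_mm2, fs = object$fs_au_mm2))
  stop("'object' must be a ColonySet or a data.frame with surface_mm2 and fs_au_mm2",
       call. = FALSE)
}

#' Fit a fluorescence-per-surface model
#'
#' Median quantile regression of FS^-1 against spherical surface area S on
#' one of three forms: `"linear"` \eqn{FS^{-1} = gS + i} (glucoamylase-type
#' behaviour), `"hyperbolic"` \eqn{FS^{-1} = g_0/(S - l) + i} with the
#' asymptote l constrained below the observed surfaces
#' (alpha-glucuronidase / feruloyl esterase type), or `"shell"`: the
#' constant-width spherical-shell null law
#' \eqn{FS^{-1} = m V_{shell}(x(S), x_b/2)/S} with the single free scale m.
#' The fitted curve is evaluated at the surfaces `sB` and `sGamma`
#' corresponding to x_b and x_gamma, giving the minimal and maximal
#' fluorescence intensity per unit surface area.
#'
#' @param object a [ColonySet-class] or data.frame with `surface_mm2` and
#'   `fs_au_mm2`.
#' @param sB,sGamma surface areas (mm^2) of the x_b and x_gamma diameters;
#'   see [sphereSurface()].
#' @param form model form.
#' @param tau fitted quantile.
#' @return a [SurfaceFit-class].
#' @export
fitFsModel <- function(object, sB, sGamma,
                       form = c("hyperbolic", "linear", "shell"), tau = 0.5) {
  form <- match.arg(form)
  d <- .extractSFs(object)
  S <- d$S; fs <- d$fs
  if (!isTRUE(sB < sGamma)) stop("'sB' must be < 'sGamma'", call. = FALSE)
  if (min(S) > sGamma || max(S) < sB)
    stop("colonies do not cover the [sB, sGamma] surface range", call. = FALSE)
  if (min(S) > sB)
    warning("no colonies at sB; FS^-1 at sB is extrapolated", call. = FALSE)

  if (form == "linear") {
    f <- .l1Linear(cbind(S, 1), fs, tau)
    coef <- c(g = unname(f$coefficients[1L]), i = unname(f$coefficients[2L]))
    loss <- f$value
  } else if (form == "hyperbolic") {
    Smin <- min(S)
    obj <- function(p) {
      l <- Smin - exp(p[1L])
      .pinball(fs - (p[3L] / (S - l) + p[2L]), tau)
    }
    best <- NULL
    for (gap in c(1e-4, 1e-3, 1e-2, 0.1, 1) * max(Smin, 1e-4)) {
      inner <- .l1Linear(cbind(1 / (S - (Smin - gap)), 1), fs, tau)
      p0 <- c(log(gap), inner$coefficients[2L], inner$coefficients[1L])
      o <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000L, reltol = 1e-13))
      o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000L, reltol = 1e-13))
      if (is.null(best) || o$value < best$value) best <- o
    }
    l <- Smin - exp(best$par[1L])
    if (l >= min(S) && l <= max(S))
      stop("hyperbolic asymptote l falls inside the data range", call. = FALSE)
    coef <- c(g0 = unname(best$par[3L]), l = unname(l), i = unname(best$par[2L]))
    loss <- best$value
  } else {
    xB <- .diameterFromSurface(sB)
    g <- shellVolume(.diameterFromSurface(S), xB / 2) / S
    f <- .l1Linear(cbind(g), fs, tau)
    coef <- c(m = unname(f$coefficients), xB = xB)
    loss <- f$value
  }

  sf <- new("SurfaceFit", form = form, coef = coef, sB = sB, sGamma = sGamma,
            fsB = NA_real_, fsGamma = NA_real_, sRange = range(S),
            loss = loss, n = length(S))
  sf@fsB <- unname(.fsCurve(sf, sB))
  sf@fsGamma <- unname(.fsCurve(sf, sGamma))
  sf
}

#' Residual FS^-1 change beyond shell-volume growth
#'
#' Integrates the derivative of the fitted FS^-1 curve over surface area
#' from sB to sGamma, and subtracts the same integral with the curve's
#' change constrained to shell-volume growth alone: the null prediction
#' anchors the fitted value at sB and lets it evolve proportionally to
#' \eqn{V_{shell}(x(S), x_b/2)/S}, the volume (per unit surface) of a shell
#' of constant radial width x_b/2. A residual of (approximately) zero means
#' the FS^-1 change is fully explained by growth of the shell volume;
#' otherwise the shell's width or its intensity must change with colony
#' size.
#'
#' Both integrals use adaptive quadrature with absolute tolerance 1e-10.
#'
#' @param sfit a [SurfaceFit-class].
#' @param sB,sGamma integration limits (mm^2); default to the fit's.
#' @return the residual, in AU per mm^2.
#' @export
deltaFs <- function(sfit, sB = sfit@sB, sGamma = sfit@sGamma) {
  stopifnot(is(sfit, "SurfaceFit"))
  if (sB == sGamma) return(0)
  if (!isTRUE(sB < sGamma)) stop("'sB' must be <= 'sGamma'", call. = FALSE)
  xB <- .diameterFromSurface(sB)
  fB <- .fsCurve(sfit, sB)
  vRatio <- function(S) shellVolume(.diameterFromSurface(S), xB / 2) / S
  mB <- fB / vRatio(sB)
  nullDeriv <- function(S) {
    h <- pmax(abs(S), 1e-6) * 1e-6
    mB * (vRatio(S + h) - vRatio(S - h)) / (2 * h)
  }
  int1 <- stats::integrate(function(S) .fsDeriv(sfit, S), sB, sGamma,
                           abs.tol = 1e-10, subdivisions = 500L)
  int2 <- stats::integrate(nullDeriv, sB, sGamma,
                           abs.tol = 1e-10, subdivisions = 500L)
  if (int1$message != "OK" || int2$message != "OK")
    stop("integration failure in deltaFs: ", int1$message, " / ",
         int2$message, call. = FALSE)
  unname(int1$value - int2$value)
}

#' Surface- and volume-independent intensity correction F_i
#'
#' Converts the residual [deltaFs()] into a fluorescence-intensity
#' correction. For the linear form the residual is accumulated as a ramp
#' growing from zero at sB to `dFs` at sGamma,
#' \eqn{F_i = \int_{S_b}^{S_\gamma} \Delta FS^{-1} (S - S_b)/(S_\gamma - S_b)\, dS},
#' which vanishes identically when the residual is zero. For the hyperbolic
#' form the printed closed-form integrand is evaluated literally with
#' left-to-right grouping; it is only defined for g0 > 0 and is gated by the
#' `dFs = 0` short-circuit. The `"shell"` form is the null model itself, so
#' its correction is zero.
#'
#' @param sfit a [SurfaceFit-class].
#' @param dFs residual from [deltaFs()].
#' @param sB,sGamma integration limits (mm^2).
#' @param form override of the correction form; defaults to the fit's.
#' @return F_i in AU.
#' @export
intensityCorrection <- function(sfit, dFs, sB = sfit@sB, sGamma = sfit@sGamma,
                                form = sfit@form) {
  stopifnot(is(sfit, "SurfaceFit"))
  if (sB == sGamma || dFs == 0 || form == "shell") return(0)
  if (form == "linear") {
    int <- stats::integrate(function(S) dFs * (S - sB) / (sGamma - sB),
                            sB, sGamma, abs.tol = 1e-10)
    if (int$message != "OK")
      stop("integration failure in intensityCorrection: ", int$message,
           call. = FALSE)
    return(int$value)
  }
  # hyperbolic form, literal evaluation
  cf <- sfit@coef
  g0 <- cf[["g0"]]; l <- cf[["l"]]; i <- cf[["i"]]
  if (g0 <= 0)
    stop("non-finite sub-expression in the hyperbolic intensity correction: ",
         "sqrt(g0) with g0 <= 0", call. = FALSE)
  sg <- sqrt(g0)
  fB <- .fsCurve(sfit, sB); fG <- .fsCurve(sfit, sGamma)
  den <- ((sg + i + dFs - fG) / (sg + l - sB)) * ((sg + l - sGamma) / (sg + i - fB))
  if (!is.finite(den) || den == 0)
    stop("non-finite sub-expression in the hyperbolic intensity correction: ",
         "denominator ((sqrt(g0)+i+dFs-FSgamma)/(sqrt(g0)+l-Sb)) * ",
         "((sqrt(g0)+l-Sgamma)/(sqrt(g0)+i-FSb))", call. = FALSE)
  integrand <- function(S) {
    f <- .fsCurve(sfit, S)
    num <- ((f - fB) / (S - sB)) * ((S - sGamma) / (f - fG))
    num / den - fB
  }
  int <- stats::integrate(integrand, sB, sGamma, abs.tol = 1e-10,
                          subdivisions = 500L)
  if (int$message != "OK")
    stop("integration failure in intensityCorrection: ", int$message,
         call. = FALSE)
  if (!is.finite(int$value))
    stop("non-finite sub-expression in the hyperbolic intensity correction: ",
         "integrand ((FS-FSb)/(S-Sb))*((S-Sgamma)/(FS-FSgamma))", call. = FALSE)
  int$value
}
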