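# Nonlinear median quantile regression of fluorescence per volume against
# diameter: FV^-1 = a/(x - b) + c, with a >= 0 and b < min(x).
#
# The pinball loss is minimised by multi-start Nelder-Mead over
# (log a, log(min(x) - b), c); for each start the inner (a, c) pair is
# initialised by an L1 linear fit at fixed b. Ties are broken by smallest
# loss, then smallest b.

.fitHyperbolaCore <- function(x, fv, tau = 0.5, gapFracs = c(0.02, 0.1, 0.3, 0.7, 1)) {
  xmin <- min(x)
  obj <- function(p) {
    a <- exp(p[1L]); b <- xmin - exp(p[2L])
    .pinball(fv - (a / (x - b) + p[3L]), tau)
  }
  candidates <- list()
  conv <- integer(0)
  for (gap in gapFracs * xmin) {
    b0 <- xmin - gap
    inner <- .l1Linear(cbind(1 / (x - b0), 1), fv, tau)
    a0 <- max(inner$coefficients[1L], 1e-8 * max(abs(fv)) * gap)
    p0 <- c(log(a0), log(gap), inner$coefficients[2L])
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000L, reltol = 1e-13))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000L, reltol = 1e-13))
    conv <- c(conv, o$convergence)
    candidates[[length(candidates) + 1L]] <- o
  }
  if (all(conv != 0L) && length(conv))
    stop("hyperbolic fit did not converge from any start; losses: ",
         paste(signif(vapply(candidates, `[[`, 1, "value"), 6), collapse = ", "),
         call. = FALSE)
  losses <- vapply(candidates, `[[`, 1, "value")
  bs <- vapply(candidates, function(o) xmin - exp(o$par[2L]), 1)
  near <- which(losses <= min(losses) * (1 + 1e-9))
  best <- candidates[[near[which.min(bs[near])]]]
  list(a = unname(exp(best$par[1L])), b = unname(xmin - exp(best$par[2L])),
       c = unname(best$par[3L]), loss = best$value)
}

.extractXFv <- function(object) {
  if (is(object, "ColonySet"))
    return(list(x = object@colonies$diameter_um, fv = object@colonies$fv_au_mm3,
                V = object@colonies$volume_mm3))
  if (is.data.frame(object) &&
      all(c("diameter_um", "fv_au_mm3") %in% names(object)))
    return(list(x = object$diameter_um, fv = object$fv_au_mm3,
                V = pi / 6 * object$diameter_um^3 * 1e-9))
  stop("'object' must be a ColonySet or a data.frame with diameter_um and fv_au_mm3",
       call. = FALSE)
}

#' Fit the hyperbolic fluorescence-per-volume model
#'
#' Median (tau = 0.5) quantile regression of FV^-1 on diameter x under
#' \eqn{FV^{-1} = a/(x - b) + c}, with a >= 0 and the vertical asymptote b
#' constrained below the smallest observed diameter. A nonparametric
#' case-resampling bootstrap supplies the parameter ensemble and a pointwise
#' 95\% percentile band of the median curve on a 1 micrometre grid. When the
#' hyperbola does not improve on a horizontal line (flat fluorescence per
#' volume, as for glucoamylase induction in complete medium), the fit is
#' flagged degenerate with a = 0 and b arbitrary.
#'
#' @param object a [ColonySet-class], or a data.frame with columns
#'   `diameter_um` and `fv_au_mm3`.
#' @param tau fitted quantile (0.5 = median regression).
#' @param nBoot bootstrap resamples for the confidence band (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param gammaFrom source of the steady-state level gamma: the fitted
#'   intercept `c` (`"intercept"`) or the companion fit [fitDfDv()]
#'   (`"dfdv"`).
#' @return a [HyperbolicFit-class].
#' @export
fitFvHyperbola <- function(object, tau = 0.5, nBoot = 200L, seed = NULL,
                           gammaFrom = c("intercept", "dfdv")) {
  gammaFrom <- match.arg(gammaFrom)
  d <- .extractXFv(object)
  x <- d$x; fv <- d$fv
  if (length(x) < 50L)
    stop("need at least 50 gated colonies", call. = FALSE)
  if (diff(range(x)) <= 0 || max(x) / min(x) < 4)
    stop("colonies must span at least a 4-fold diameter range (observed ",
         signif(min(x), 4), "-", signif(max(x), 4), " um)", call. = FALSE)

  lossFlat <- .pinball(fv - stats::median(fv), tau)
  fit <- .fitHyperbolaCore(x, fv, tau)
  degenerate <- fit$loss >= lossFlat * (1 - 1e-4)

  if (degenerate) {
    a <- 0; b <- NA_real_; cc <- stats::median(fv); loss <- lossFlat
  } else {
    a <- fit$a; b <- fit$b; cc <- fit$c; loss <- fit$loss
  }

  boot <- matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("a", "b", "c")))
  band <- data.frame(x = numeric(0), lo = numeric(0), hi = numeric(0))
  if (nBoot > 0L && !degenerate) {
    n <- length(x)
    start <- c(log(a), log(min(x) - b), cc)
    boot <- .withSeed(seed, {
      t(vapply(seq_len(nBoot), function(k) {
        idx <- sample.int(n, n, replace = TRUE)
        xk <- x[idx]; fvk <- fv[idx]; xmink <- min(xk)
        objK <- function(p) {
          .pinball(fvk - (exp(p[1L]) / (xk - (xmink - exp(p[2L]))) + p[3L]), tau)
        }
        # re-anchor the gap to the resample's own minimum
        st <- c(start[1L], log(max(xmink - b, 1e-6)), start[3L])
        o <- stats::optim(st, objK, method = "Nelder-Mead",
                          control = list(maxit = 2500L, reltol = 1e-11))
        c(exp(o$par[1L]), xmink - exp(o$par[2L]), o$par[3L])
      }, numeric(3)))
    })
    colnames(boot) <- c("a", "b", "c")
    grid <- seq(ceiling(min(x)), floor(max(x)), by = 1)
    curves <- vapply(seq_len(nrow(boot)), function(k)
      boot[k, 1L] / (grid - boot[k, 2L]) + boot[k, 3L], numeric(length(grid)))
    qs <- apply(curves, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    band <- data.frame(x = grid, lo = qs[1L, ], hi = qs[2L, ])
  }

  gamma <- cc; alpha <- NA_real_
  if (gammaFrom == "dfdv") {
    dv <- fitDfDv(object, tau = tau)
    gamma <- dv$gamma; alpha <- dv$alpha
  }
  new("HyperbolicFit", a = a, b = b, c = cc, alpha = alpha, gamma = gamma,
      gammaSource = gammaFrom, degenerate = degenerate, loss = loss,
      tau = tau, n = length(x), xRange = range(x), boot = boot, band = band)
}

#' Fit the fluorescence increment model dF/dV = alpha/V + gamma
#'
#' Median quantile regression of fluorescence per volume on 1/V. `gamma` is
#' the steady-state fluorescence per volume; a bootstrap interval for
#' `alpha` excludes zero when fluorescence is confined to a peripheral shell
#' rather than distributed through the colony volume.
#'
#' @inheritParams fitFvHyperbola
#' @param nBoot resamples for the percentile CI of alpha (0 disables).
#' @return list with `alpha`, `gamma`, `loss` and (when bootstrapped)
#'   `alphaCi`.
#' @export
fitDfDv <- function(object, tau = 0.5, nBoot = 0L, seed = NULL) {
  d <- .extractXFv(object)
  fv <- d$fv; V <- d$V
  if (length(fv) < 50L)
    stop("need at least 50 gated colonies", call. = FALSE)
  if (max(d$x) / min(d$x) < 4)
    stop("colonies must span at least a 4-fold diameter range", call. = FALSE)
  fitOne <- function(fvk, Vk) .l1Linear(cbind(1 / Vk, 1), fvk, tau)
  f <- fitOne(fv, V)
  out <- list(alpha = unname(f$coefficients[1L]),
              gamma = unname(f$coefficients[2L]), loss = f$value)
  if (nBoot > 0L) {
    n <- length(fv)
    alphas <- .withSeed(seed, vapply(seq_len(nBoot), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      unname(fitOne(fv[idx], V[idx])$coefficients[1L])
    }, numeric(1)))
    out$alphaCi <- stats::quantile(alphas, c(0.025, 0.975), names = FALSE)
  }
  out
}

#' Steady-state diameter x_gamma
#'
#' The smallest diameter (on the fit's 1 micrometre grid) at which the lower
#' 95\% confidence limit of the fitted median FV^-1 curve reaches the
#' steady-state level gamma; colonies beyond it have constant fluorescence
#' per volume.
#'
#' @param fit a [HyperbolicFit-class] with a bootstrap band.
#' @param gamma steady-state level; defaults to the fit's gamma.
#' @return diameter in micrometres.
#' @export
findXGamma <- function(fit, gamma = fit@gamma) {
  stopifnot(is(fit, "HyperbolicFit"))
  if (fit@degenerate || !(fit@a > 0))
    stop("x_gamma requires a non-degenerate hyperbolic fit with a > 0",
         call. = FALSE)
  band <- fit@band
  if (!nrow(band))
    stop("fit carries no confidence band; refit with nBoot > 0", call. = FALSE)
  ok <- band$x > fit@b & band$lo <= gamma
  if (!any(ok))
    stop(sprintf(paste0("lower confidence limit does not reach gamma = %s ",
                        "within the observed diameter range [%s, %s] um"),
                 signif(gamma, 6), signif(fit@xRange[1L], 5),
                 signif(fit@xRange[2L], 5)), call. = FALSE)
  band$x[which(ok)[1L]]
}

#' Fitted median curve and band for plotting
#'
#' @param fit a [HyperbolicFit-class].
#' @return data.frame with `x`, the fitted median curve `fit`, and (when a
#'   bootstrap band exists) `lo`/`hi`.
#' @export
fittedCurve <- function(fit) {
  stopifnot(is(fit, "HyperbolicFit"))
  if (nrow(fit@band)) {
    x <- fit@band$x
    data.frame(x = x, fit = .hypCurve(fit, x), lo = fit@band$lo, hi = fit@band$hi)
  } else {
    x <- seq(ceiling(fit@xRange[1L]), floor(fit@xRange[2L]), by = 1)
    data.frame(x = x, fit = .hypCurve(fit, x))
  }
}

.hypCurve <- function(fit, x) {
  if (fit@degenerate) rep(fit@c, length(x)) else fit@a / (x - fit@b) + fit@c
}
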