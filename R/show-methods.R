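setMethod("show", "CalibrationCurve", function(object) {
  cat("TOF calibration: TOF =", object@aCal, "* x^2 +", object@bCal, "* x\n")
})

setMethod("show", "GatingProfile", function(object) {
  cat("Gating profile\n",
      " TOF in [", object@tofMin, ", ", object@tofMax, "] AU\n",
      " peak >= ", object@peakMin, " AU, width >= ", object@widthMin, " AU\n",
      if (object@requireIntegrated)
        paste0("  integrated density >= ", object@intMin, " AU (green/red/yellow)\n")
      else "  integrated density not used\n", sep = "")
})

setMethod("show", "ColonySet", function(object) {
  cat("ColonySet:", nColonies(object), "colonies from", object@nInput,
      "events\n rejected:",
      paste(names(object@rejected), object@rejected, sep = "=", collapse = ", "),
      "\n")
  if (nColonies(object))
    cat(" diameters:", signif(min(diameters(object)), 4), "-",
        signif(max(diameters(object)), 4), "um\n")
})

setMethod("show", "HyperbolicFit", function(object) {
  if (object@degenerate) {
    cat("Degenerate (horizontal-line) FV^-1 fit: gamma =",
        signif(object@c, 6), "AU/mm^3\n")
  } else {
    cat("FV^-1 = a/(x - b) + c  (median quantile fit, n =", object@n, ")\n",
        " a =", signif(object@a, 6), " b (x_b) =", signif(object@b, 6),
        "um  c =", signif(object@c, 6), "\n")
    if (nrow(object@boot))
      cat("  bootstrap ensemble: B =", nrow(object@boot), "\n")
  }
})

setMethod("show", "SurfaceFit", function(object) {
  cat("FS^-1 model (", object@form, "), n = ", object@n, "\n  ",
      paste(names(object@coef), signif(object@coef, 6), sep = " = ",
            collapse = ", "),
      "\n  FS^-1 at S_b = ", signif(object@fsB, 6), ", at S_gamma = ",
      signif(object@fsGamma, 6), " AU/mm^2\n", sep = "")
})

setMethod("show", "ShellEstimate", function(object) {
  cat("Peripheral expression shell\n",
      " x_b =", signif(object@xB, 5), "um; x_gamma =",
      signif(object@xGamma, 5), "um\n",
      " r_gamma =", signif(object@rGamma, 5), "um  (I_x =",
      signif(object@iX, 4), ", I_v =", signif(object@iV, 4), ")\n")
})

setMethod("show", "SizeDistributionSummary", function(object) {
  cat("Size distribution (n =", object@n, ")\n",
      " mode:", signif(object@mode, 5), "um, 95% CI [",
      signif(object@modeCi[1L], 5), ",", signif(object@modeCi[2L], 5), "]\n",
      " categories:",
      paste(names(object@counts), object@counts, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("Synthetic population:", object@nEvents, "events, width law",
      object@widthLaw, "(w0 =", object@w0Um, "um), noise CV",
      object@noiseCv, ", debris", object@debrisFraction, ", seed",
      object@seed, "\n")
})
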