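# TOF <-> diameter calibration and spherical geometry.
#
# Canonical internal units: micrometres for lengths, mm^3 / mm^2 for volume
# and surface (hence the 1e-9 / 1e-6 factors); all unit conversion happens
# in this file.

# bead-derived coefficients printed with decimal commas on the instrument
# report; read here as decimal points
.DEFAULT_A_CAL <- 0.00215762
.DEFAULT_B_CAL <- 5.433189436

#' Construct a TOF calibration curve
#'
#' @param a quadratic coefficient (AU per square micrometre).
#' @param b linear coefficient (AU per micrometre).
#' @return a [CalibrationCurve-class]. The defaults are the bead-derived
#'   BioSorter FOCA 2000 coefficients.
#' @examples
#' cal <- calibrationCurve()
#' tofToDiameter(165, cal)    # ~30 um, the lower instrument limit
#' @export
calibrationCurve <- function(a = .DEFAULT_A_CAL, b = .DEFAULT_B_CAL) {
  new("CalibrationCurve", aCal = a, bCal = b)
}

#' Convert time of flight to micro-colony diameter
#'
#' Inverts the quadratic calibration \eqn{TOF = a x^2 + b x} by its positive
#' root \eqn{x = (-b + \sqrt{b^2 + 4 a \cdot TOF}) / (2a)}.
#'
#' @param tof time of flight in arbitrary units, > 0.
#' @param cal a [CalibrationCurve-class].
#' @return diameter in micrometres.
#' @export
tofToDiameter <- function(tof, cal = calibrationCurve()) {
  .checkNumeric(tof, "tof")
  if (any(tof <= 0)) stop("'tof' must be > 0", call. = FALSE)
  a <- cal@aCal; b <- cal@bCal
  (-b + sqrt(b^2 + 4 * a * tof)) / (2 * a)
}

#' Convert diameter to time of flight
#'
#' Forward quadratic map \eqn{TOF = a x^2 + b x} (zero intercept, as implied
#' by the printed root formula); exact inverse of [tofToDiameter()].
#'
#' @param x diameter in micrometres, >= 0.
#' @inheritParams tofToDiameter
#' @return TOF in arbitrary units.
#' @export
diameterToTof <- function(x, cal = calibrationCurve()) {
  .checkNumeric(x, "x", nonNegative = TRUE)
  cal@aCal * x^2 + cal@bCal * x
}

#' Spherical geometry of a micro-colony
#'
#' Volume \eqn{V = \pi x^3 / 6 \cdot 10^{-9}} (mm^3), surface
#' \eqn{S = \pi x^2 \cdot 10^{-6}} (mm^2), and the volume of a peripheral
#' shell of radial width `w`,
#' \eqn{V_s = \pi (x^3 - \max(x - 2w, 0)^3)/6 \cdot 10^{-9}}: a shell of
#' width `w` spans diameters `x` down to `x - 2w`, so colonies with
#' `x <= 2w` are filled completely.
#'
#' @param x diameter in micrometres, >= 0.
#' @param w shell radial width in micrometres, >= 0.
#' @return volume in mm^3 (surface in mm^2; shell fraction dimensionless).
#' @examples
#' sphereVolume(100)                     # 5.23599e-4 mm^3
#' shellVolume(954, 477) == sphereVolume(954)  # fully fluorescent
#' @export
sphereVolume <- function(x) {
  .checkNumeric(x, "x", nonNegative = TRUE)
  pi / 6 * x^3 * 1e-9
}

#' @rdname sphereVolume
#' @export
sphereSurface <- function(x) {
  .checkNumeric(x, "x", nonNegative = TRUE)
  pi * x^2 * 1e-6
}

#' @rdname sphereVolume
#' @export
shellVolume <- function(x, w) {
  .checkNumeric(x, "x", nonNegative = TRUE)
  .checkNumeric(w, "w", nonNegative = TRUE)
  pi / 6 * (x^3 - pmax(x - 2 * w, 0)^3) * 1e-9
}

#' @rdname sphereVolume
#' @export
shellFraction <- function(x, w) {
  .checkNumeric(x, "x", positive = TRUE)
  .checkNumeric(w, "w", nonNegative = TRUE)
  1 - pmax(1 - 2 * w / x, 0)^3
}

# diameter (um) of the sphere with surface S (mm^2)
.diameterFromSurface <- function(S) sqrt(S / pi) * 1e3
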