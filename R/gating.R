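# Particle-selection (gating) rules applied to raw event tables.

.EVENT_COLUMNS <- c("tof", "peak_green", "width_green",
                    "int_green", "int_red", "int_yellow")

#' Construct a gating profile
#'
#' @param tofMin,tofMax TOF acceptance window (AU).
#' @param peakMin minimum green fluorescence peak height (AU).
#' @param widthMin minimum green peak width (AU).
#' @param intMin minimum integrated density for each of the green, red and
#'   yellow channels (AU); ignored when `requireIntegrated = FALSE`.
#' @param requireIntegrated apply the integrated-density rule?
#' @return a [GatingProfile-class].
#' @export
gatingProfile <- function(tofMin = 165, tofMax = 13005, peakMin = 80,
                          widthMin = 2000, intMin = 25,
                          requireIntegrated = TRUE) {
  new("GatingProfile", tofMin = tofMin, tofMax = tofMax, peakMin = peakMin,
      widthMin = widthMin, intMin = if (requireIntegrated) intMin else NA_real_,
      requireIntegrated = requireIntegrated)
}

#' Default gating profiles
#'
#' `reporter`: the profile for GFP reporter strains (TOF in \[165, 13005\] AU,
#' peak >= 80 AU, peak width >= 2000 AU, integrated density >= 25 AU in
#' green, red and yellow). `wildtype`: the profile for the non-fluorescent
#' control strain (peak >= 100 AU; integrated density not a selection
#' variable). Events exactly at a threshold are kept.
#'
#' @return a named list with elements `reporter` and `wildtype`.
#' @export
defaultProfiles <- function() {
  list(reporter = gatingProfile(),
       wildtype = gatingProfile(peakMin = 100, requireIntegrated = FALSE))
}

#' Gate raw cytometer events
#'
#' Applies the selection rules in the fixed order tof, peak, width,
#' integrated; an event failing several rules is attributed to the first.
#' Kept events are converted to micro-colonies: diameter from TOF through
#' the calibration, spherical volume and surface, fluorescence F taken as
#' the integrated green density, and the derived FV^-1 and FS^-1.
#'
#' @param events data.frame with columns `tof`, `peak_green`, `width_green`,
#'   `int_green`, `int_red`, `int_yellow` (see [readEventTable()]).
#' @param profile a [GatingProfile-class].
#' @param cal a [CalibrationCurve-class].
#' @return a [ColonySet-class].
#' @examples
#' ev <- data.frame(tof = c(164, 5000), peak_green = c(500, 200),
#'                  width_green = c(5000, 5000), int_green = c(100, 100),
#'                  int_red = c(100, 100), int_yellow = c(100, 100))
#' gateEvents(ev)   # first event rejected by the TOF rule
#' @export
gateEvents <- function(events, profile = defaultProfiles()$reporter,
                       cal = calibrationCurve()) {
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("'events' must be a non-empty data.frame", call. = FALSE)
  missing <- setdiff(.EVENT_COLUMNS, names(events))
  if (length(missing))
    stop("missing event column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in .EVENT_COLUMNS) {
    v <- events[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop(sprintf("column '%s' must be numeric without NA", col), call. = FALSE)
    if (any(v < 0))
      stop(sprintf("negative values in channel '%s'", col), call. = FALSE)
  }

  failTof   <- events$tof < profile@tofMin | events$tof > profile@tofMax
  failPeak  <- events$peak_green < profile@peakMin
  failWidth <- events$width_green < profile@widthMin
  failInt   <- if (profile@requireIntegrated)
    pmin(events$int_green, events$int_red, events$int_yellow) < profile@intMin
  else rep(FALSE, nrow(events))

  # attribute each rejected event to the first failing rule
  rejected <- c(
    tof        = sum(failTof),
    peak       = sum(!failTof & failPeak),
    width      = sum(!failTof & !failPeak & failWidth),
    integrated = sum(!failTof & !failPeak & !failWidth & failInt))
  keep <- !(failTof | failPeak | failWidth | failInt)

  kept <- events[keep, , drop = FALSE]
  x <- if (nrow(kept)) tofToDiameter(kept$tof, cal) else numeric(0)
  V <- pi / 6 * x^3 * 1e-9
  S <- pi * x^2 * 1e-6
  f <- kept$int_green
  colonies <- data.frame(diameter_um = x, volume_mm3 = V, surface_mm2 = S,
                         f_au = f, fv_au_mm3 = f / V, fs_au_mm2 = f / S,
                         row.names = NULL)
  new("ColonySet", colonies = colonies, nInput = nrow(events),
      rejected = as.integer(rejected) |> stats::setNames(names(rejected)),
      profile = profile, calibration = cal)
}

#' @describeIn gateEvents summarise gating as a list suitable for JSON export.
#' @param object a [ColonySet-class].
#' @export
gatingReport <- function(object) {
  stopifnot(is(object, "ColonySet"))
  list(n_input = object@nInput,
       n_kept = nColonies(object),
       rejected = as.list(object@rejected),
       thresholds = list(tof_min_au = object@profile@tofMin,
                         tof_max_au = object@profile@tofMax,
                         peak_min_au = object@profile@peakMin,
                         width_min_au = object@profile@widthMin,
                         int_min_au = object@profile@intMin,
                         require_integrated = object@profile@requireIntegrated),
       calibration = list(a = object@calibration@aCal,
                          b = object@calibration@bCal))
}

#' Accessors for gated populations
#'
#' @param object a [ColonySet-class].
#' @return `diameters`: micro-colony diameters (um); `fluorescence`:
#'   integrated green F (AU); `nColonies`: number of kept colonies;
#'   `rejectedCounts`: per-rule rejection counts; `colonyTable`: the full
#'   per-colony data.frame.
#' @name ColonySet-accessors
NULL

#' @rdname ColonySet-accessors
#' @export
setMethod("diameters", "ColonySet", function(object) object@colonies$diameter_um)

#' @rdname ColonySet-accessors
#' @export
setMethod("fluorescence", "ColonySet", function(object) object@colonies$f_au)

#' @rdname ColonySet-accessors
#' @export
setMethod("nColonies", "ColonySet", function(object) nrow(object@colonies))

#' @rdname ColonySet-accessors
#' @export
setMethod("rejectedCounts", "ColonySet", function(object) object@rejected)

#' @rdname ColonySet-accessors
#' @export
setMethod("colonyTable", "ColonySet", function(object) object@colonies)
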