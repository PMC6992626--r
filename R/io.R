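# Event-table and configuration I/O.

#' Read a cytometer event table
#'
#' Reads a CSV/TSV export with a header row naming the six channels (`tof`,
#' `peak_green`, `width_green`, `int_green`, `int_red`, `int_yellow`). File
#' columns with other names can be mapped through `columnMap`; tables
#' written with comma decimals are supported through `decimal = "comma"`.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param columnMap named character vector mapping standard names to file
#'   column names, e.g. `c(tof = "TOF")`.
#' @param decimal `"point"` or `"comma"`.
#' @return data.frame with the six standard channel columns (plus any
#'   extras, e.g. `event_id`).
#' @export
readEventTable <- function(path, columnMap = NULL,
                           decimal = c("point", "comma")) {
  decimal <- match.arg(decimal)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dec <- if (decimal == "comma") "," else "."
  sepTab <- grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = if (sepTab) "\t" else ",",
                          dec = dec, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (std in names(columnMap)) {
      src <- columnMap[[std]]
      if (!src %in% names(df))
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      names(df)[names(df) == src] <- std
    }
  }
  missing <- setdiff(.EVENT_COLUMNS, names(df))
  if (length(missing))
    stop("event table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' @describeIn readEventTable write an event table as dot-decimal CSV.
#' @param events data.frame of events.
#' @export
writeEventTable <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

.CONFIG_SCHEMA <- list(
  calibration = c("a", "b"),
  gating = c("profile", "tof_min", "tof_max", "peak_min", "width_min",
             "int_min", "require_integrated"),
  simulate = c("n_events", "diameter_median_um", "diameter_sdlog",
               "diameter_weights", "diameter_range_um", "width_law", "w0_um",
               "w_slope", "m_au_mm3", "noise_cv", "debris_fraction", "seed"),
  model = c("form", "gamma_from", "n_boot", "tau", "seed"),
  stats = c("n_boot", "seed"),
  io = c("events", "out_dir", "decimal", "column_map")
)

#' Read and validate a run configuration
#'
#' YAML configuration with sections `calibration`, `gating`, `simulate`,
#' `model`, `stats` and `io`; unknown sections or keys are rejected with a
#' message listing them. Omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @describeIn readRunConfig validate an in-memory configuration list.
#' @param cfg configuration list.
#' @export
validateRunConfig <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a list", call. = FALSE)
  badSections <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  offending <- if (length(badSections)) paste0(badSections, " (section)")
  for (sec in intersect(names(cfg), names(.CONFIG_SCHEMA))) {
    bad <- setdiff(names(cfg[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(bad)) offending <- c(offending, paste0(sec, "$", bad))
  }
  if (length(offending))
    stop("unknown configuration key(s): ", paste(offending, collapse = ", "),
         call. = FALSE)
  for (sec in c("model", "stats", "simulate")) {
    s <- cfg[[sec]]$seed
    if (!is.null(s) && (length(s) != 1L || !is.numeric(s) || s != round(s)))
      stop("'", sec, "$seed' must be a single integer", call. = FALSE)
  }
  cfg
}

.configCalibration <- function(cfg) {
  cc <- cfg$calibration
  calibrationCurve(a = cc$a %||% .DEFAULT_A_CAL, b = cc$b %||% .DEFAULT_B_CAL)
}

.configProfile <- function(cfg) {
  g <- cfg$gating
  base <- defaultProfiles()[[g$profile %||% "reporter"]]
  if (is.null(base))
    stop("unknown gating profile '", g$profile, "'", call. = FALSE)
  gatingProfile(
    tofMin = g$tof_min %||% base@tofMin,
    tofMax = g$tof_max %||% base@tofMax,
    peakMin = g$peak_min %||% base@peakMin,
    widthMin = g$width_min %||% base@widthMin,
    intMin = g$int_min %||% base@intMin,
    requireIntegrated = g$require_integrated %||% base@requireIntegrated)
}

.configSimulation <- function(cfg) {
  s <- cfg$simulate
  # YAML emits plain scientific notation (e.g. "5.0e7") as character
  num <- function(v) if (is.null(v)) v else as.numeric(unlist(v))
  for (k in setdiff(names(s), c("width_law", "seed", "n_events")))
    s[[k]] <- num(s[[k]])
  simulationConfig(
    nEvents = s$n_events %||% 10000L,
    diameterMedianUm = s$diameter_median_um %||% c(1000, 250),
    diameterSdlog = s$diameter_sdlog %||% c(0.25, 0.8),
    diameterWeights = s$diameter_weights %||%
      if (is.null(s$diameter_median_um)) c(0.8, 0.2)
      else rep(1, length(s$diameter_median_um)),
    diameterRangeUm = unlist(s$diameter_range_um %||% c(30, 1500)),
    widthLaw = s$width_law %||% "constant",
    w0Um = s$w0_um %||% 13,
    wSlope = s$w_slope %||% 0,
    mAuPerMm3 = s$m_au_mm3 %||% 5e7,
    noiseCv = s$noise_cv %||% 0.1,
    debrisFraction = s$debris_fraction %||% 0.1,
    seed = s$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
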