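# Pipeline stages tying the modules together; each stage reads and writes
# the documented CSV/JSON artifacts under the configured output directory.
# `runReport()` chains gate -> stats -> fit -> shell.

.outDir <- function(cfg) {
  dir <- cfg$io$out_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

.logLine <- function(dir, ...) {
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n"),
      file = file.path(dir, "run_log.txt"), append = TRUE)
}

.startLog <- function(cfg, dir, stage) {
  .logLine(dir, "stage=", stage,
           " package=pelletShell/", as.character(utils::packageVersion("pelletShell")),
           " R=", R.version.string)
  for (sec in c("simulate", "model", "stats"))
    if (!is.null(cfg[[sec]]$seed)) .logLine(dir, sec, " seed=", cfg[[sec]]$seed)
}

#' Run pipeline stages from a configuration
#'
#' `runSimulate` writes `events.csv` and `truth.csv`; `runGate` writes
#' `gated.csv` and `gating_report.json`; `runStats` writes
#' `size_summary.json`; `runFit` writes `fv_fit.json` and `fv_curve.csv`;
#' `runShell` writes `shell_report.json`; `runReport` chains
#' gate-stats-fit-shell and writes `report.json` with the x_b / x_gamma /
#' r_gamma summary. All outputs are deterministic for a fixed configuration;
#' a `run_log.txt` records versions, seeds, thresholds and per-stage counts.
#'
#' @param cfg configuration list (see [readRunConfig()]).
#' @return invisibly, the paths (or objects) produced by the stage.
#' @export
runSimulate <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  .startLog(cfg, dir, "simulate")
  sim <- simulatePopulation(.configSimulation(cfg), .configCalibration(cfg))
  writeEventTable(sim$events, file.path(dir, "events.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  .logLine(dir, "simulated n=", nrow(sim$events))
  invisible(list(events = file.path(dir, "events.csv"),
                 truth = file.path(dir, "truth.csv")))
}

.loadEvents <- function(cfg, dir) {
  path <- cfg$io$events %||% file.path(dir, "events.csv")
  readEventTable(path, columnMap = unlist(cfg$io$column_map),
                 decimal = cfg$io$decimal %||% "point")
}

#' @rdname runSimulate
#' @export
runGate <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  .startLog(cfg, dir, "gate")
  cs <- gateEvents(.loadEvents(cfg, dir), .configProfile(cfg),
                   .configCalibration(cfg))
  utils::write.csv(colonyTable(cs), file.path(dir, "gated.csv"),
                   row.names = FALSE, quote = FALSE)
  .writeJson(gatingReport(cs), file.path(dir, "gating_report.json"))
  .logLine(dir, "gated kept=", nColonies(cs), " of ", cs@nInput,
           " rejected=", paste(names(rejectedCounts(cs)),
                               rejectedCounts(cs), sep = ":", collapse = ","))
  invisible(cs)
}

#' @rdname runSimulate
#' @export
runStats <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  cs <- runGate(cfg)
  sm <- sizeDistributionSummary(diameters(cs),
                                nBoot = cfg$stats$n_boot %||% 1000L,
                                seed = cfg$stats$seed %||% 1L)
  .writeJson(list(n = sm@n, mode_um = sm@mode,
                  mode_ci_um = as.list(stats::setNames(sm@modeCi, c("lo", "hi"))),
                  category_counts = as.list(as.integer(sm@counts) |>
                                              stats::setNames(names(sm@counts))),
                  category_props = as.list(stats::setNames(sm@props, names(sm@counts))),
                  thresholds_um = as.list(sm@thresholds)),
             file.path(dir, "size_summary.json"))
  .logLine(dir, "stats mode=", signif(sm@mode, 6))
  invisible(sm)
}

#' @rdname runSimulate
#' @export
runFit <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  cs <- runGate(cfg)
  fit <- fitFvHyperbola(cs, tau = cfg$model$tau %||% 0.5,
                        nBoot = cfg$model$n_boot %||% 200L,
                        seed = cfg$model$seed %||% 1L,
                        gammaFrom = cfg$model$gamma_from %||% "intercept")
  .writeJson(list(a = fit@a, b_um = fit@b, c_au_mm3 = fit@c,
                  gamma_au_mm3 = fit@gamma, alpha_au = fit@alpha,
                  degenerate = fit@degenerate, loss = fit@loss, n = fit@n),
             file.path(dir, "fv_fit.json"))
  utils::write.csv(fittedCurve(fit), file.path(dir, "fv_curve.csv"),
                   row.names = FALSE, quote = FALSE)
  .logLine(dir, "fit b=", signif(fit@b, 6), " degenerate=", fit@degenerate)
  invisible(list(fit = fit, colonies = cs))
}

#' @rdname runSimulate
#' @export
runShell <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  st <- runFit(cfg)
  fit <- st$fit; cs <- st$colonies
  # a shell estimate needs a positive asymptote and a steady-state crossing;
  # populations without either get an explicit status instead of a crash
  res <- tryCatch({
    xGamma <- findXGamma(fit)
    if (!isTRUE(is.finite(fit@b) && fit@b > 0))
      stop("fitted asymptote x_b = ", signif(fit@b, 5),
           " um is not positive; no peripheral shell can be inferred",
           call. = FALSE)
    sB <- sphereSurface(fit@b); sG <- sphereSurface(xGamma)
    sfit <- fitFsModel(cs, sB, sG, form = cfg$model$form %||% "hyperbolic")
    dFs <- deltaFs(sfit)
    # the hyperbolic closed form of the intensity correction is only defined
    # for decreasing FS^-1 curves (g0 > 0); otherwise accumulate the residual
    # along the generic ramp
    fI <- tryCatch(intensityCorrection(sfit, dFs),
                   error = function(e) intensityCorrection(sfit, dFs,
                                                           form = "linear"))
    shell <- shellWidthAndRadius(fit, sfit, fI, xGamma, colonies = cs)
    list(status = "ok", shell = shell)
  }, error = function(e) list(status = "no_shell_estimate",
                              reason = conditionMessage(e), shell = NULL))
  if (res$status == "ok") {
    shell <- res$shell
    .writeJson(list(status = "ok", x_b_um = shell@xB,
                    x_gamma_um = shell@xGamma, m_au_mm3 = shell@m,
                    delta_fs_au_mm2 = shell@deltaFs, f_i_au = shell@fI,
                    i_x = shell@iX, i_v = shell@iV,
                    r_gamma_um = shell@rGamma),
               file.path(dir, "shell_report.json"))
    .logLine(dir, "shell r_gamma=", signif(shell@rGamma, 6))
  } else {
    .writeJson(list(status = res$status, reason = res$reason,
                    x_b_um = if (isTRUE(fit@b > 0)) fit@b else NA_real_,
                    x_gamma_um = NA_real_, r_gamma_um = NA_real_),
               file.path(dir, "shell_report.json"))
    .logLine(dir, "shell not estimable: ", res$reason)
  }
  invisible(c(res, list(fit = fit, colonies = cs)))
}

#' @rdname runSimulate
#' @export
runReport <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir <- .outDir(cfg)
  sm <- runStats(cfg)
  st <- runShell(cfg)
  out <- list(n_colonies = nColonies(st$colonies), mode_um = sm@mode,
              status = st$status)
  if (st$status == "ok") {
    out <- c(out, as.list(tableOneReport(st$fit, st$shell)))
  } else {
    out$reason <- st$reason
    out <- c(out, list(x_b_um = if (isTRUE(st$fit@b > 0)) st$fit@b else NA_real_,
                       x_gamma_um = NA_real_, r_gamma_um = NA_real_))
  }
  .writeJson(out, file.path(dir, "report.json"))
  .logLine(dir, "report written, status=", st$status)
  invisible(out)
}
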