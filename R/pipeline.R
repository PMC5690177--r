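# Pipeline entry points tying the modules together, plus a small
# command-line dispatcher (see inst/cli/wbrt.R). Every run is
# non-interactive and, for a fixed seed, fully reproducible.

readAnyVolume <- function(path) {
  if (dir.exists(path)) readCTSeries(path) else readVolume(path)
}

resolveBestPlan <- function(ranking) {
  pp <- attr(ranking, "bestPlanPath")
  if (!is.null(pp) && length(pp) == 1L && !is.na(pp) && file.exists(pp))
    return(readPlan(pp))
  pl <- attr(ranking, "bestPlan")
  if (is.null(pl)) stop("best match carries no plan", call. = FALSE)
  pl
}

#' Generate a phantom case on disk
#'
#' Writes the CT (internal volume format, optionally also a slice
#' series) and the ground-truth structure set.
#'
#' @param outDir output directory.
#' @param seed phantom seed.
#' @param spacing isotropic voxel size in mm (grid scales accordingly).
#' @param writeSeries also write the CT as a JSON slice series.
#' @return Invisibly, a list of written paths.
#' @export
runPhantom <- function(outDir, seed = 1L, spacing = 1, writeSeries = FALSE) {
  spec <- phantomSpecAtSpacing(spacing, seed)
  ph <- generatePhantom(spec)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ctStem <- file.path(outDir, "ct")
  writeVolume(ph$ct, ctStem)
  ssPath <- file.path(outDir, "ground_truth.json")
  writeStructureSet(ph$masks, ssPath)
  paths <- list(ct = ctStem, structures = ssPath)
  if (writeSeries) {
    withSeed(seed, writeCTSeries(ph$ct, file.path(outDir, "ct_series")))
    paths$series <- file.path(outDir, "ct_series")
  }
  invisible(paths)
}

# Default phantom spec rescaled to a coarser isotropic spacing.
phantomSpecAtSpacing <- function(spacing, seed = 1L) {
  base <- phantomSpec()
  shape <- as.integer(ceiling(base@gridShape / spacing))
  shape <- shape + (shape %% 2L == 0L)  # odd counts center the grid
  phantomSpec(gridShape = shape, spacing = rep(spacing, 3),
              rngSeed = as.integer(seed))
}

#' Auto-segment a CT from disk
#'
#' @param ctPath CT path: a slice-series directory or an internal-volume
#'   stem.
#' @param outPath output structure-set JSON.
#' @param params a [SegmentationParams-class].
#' @return Invisibly, the [SegmentationResult-class].
#' @export
runSegment <- function(ctPath, outPath, params = segmentationParams()) {
  ct <- readAnyVolume(ctPath)
  seg <- segmentAll(ct, params)
  writeStructureSet(seg, outPath)
  invisible(seg)
}

#' Compare two structure sets from disk
#'
#' @param pathA,pathB structure-set JSON files (A's grid is used).
#' @param outPath output JSON report.
#' @return Invisibly, the metric data.frame.
#' @export
runEvaluate <- function(pathA, pathB, outPath) {
  a <- readStructureSet(pathA)
  b <- readStructureSet(pathB, reference = a[[1]])
  rep <- metricReport(a, b)
  jsonlite::write_json(rep, outPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(rep)
}

#' Build a database manifest from case directories
#'
#' @param casesDir directory of case subdirectories (each with
#'   structures.json + plan.json, see [writeCaseDir()]).
#' @param manifestPath output manifest JSON.
#' @param tiltDeg crop-plane tilt, degrees.
#' @return Invisibly, the index.
#' @export
runBuildDb <- function(casesDir, manifestPath, tiltDeg = 15) {
  idx <- indexFromDirectory(casesDir, tiltDeg = tiltDeg)
  writeDatabaseIndex(idx, manifestPath)
  invisible(idx)
}

#' Match a structure set against a database manifest
#'
#' @param ssPath structure-set JSON of the patient.
#' @param manifestPath database manifest.
#' @param outPath output JSON report (ranked cases).
#' @return Invisibly, the ranking data.frame.
#' @export
runMatch <- function(ssPath, manifestPath, outPath) {
  ss <- readStructureSet(ssPath)
  idx <- readDatabaseIndex(manifestPath)
  rk <- rankDatabase(ss, idx)
  jsonlite::write_json(list(best_case = rk$case_id[1],
                            best_score_mm = rk$score[1],
                            ranking = rk),
                       outPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(rk)
}

#' Run the full autoplanning pipeline
#'
#' Segments the CT, ranks the database, retargets the best-matching plan
#' to the new patient and writes plan, structure set and a JSON match
#' report. Input is only the CT dataset (plus the prior-case database);
#' no user interaction anywhere.
#'
#' @param ctPath CT path (slice-series directory or internal-volume
#'   stem).
#' @param db database manifest path or an in-memory index.
#' @param outDir output directory.
#' @param patientName,patientID identity written into the new plan.
#' @param params a [SegmentationParams-class].
#' @param seed seed controlling UID generation (reproducible runs).
#' @return Invisibly, list with \code{seg}, \code{ranking}, \code{plan}
#'   and output paths.
#' @export
runAutoplan <- function(ctPath, db, outDir, patientName = "AUTO^PATIENT",
                        patientID = "AUTO001",
                        params = segmentationParams(), seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ct <- readAnyVolume(ctPath)
  seg <- segmentAll(ct, params)
  idx <- if (is.character(db)) readDatabaseIndex(db) else db
  rk <- rankDatabase(seg, idx)
  template <- resolveBestPlan(rk)
  plan <- withSeed(seed, retargetPlan(template, patientName, patientID,
                                      c(rk$tx[1], rk$ty[1], rk$tz[1])))
  ssPath <- file.path(outDir, "structures.json")
  planPath <- file.path(outDir, "plan.json")
  reportPath <- file.path(outDir, "match_report.json")
  writeStructureSet(seg, ssPath)
  withSeed(seed + 1L, writePlan(plan, planPath))
  jsonlite::write_json(list(patient_name = patientName,
                            patient_id = patientID,
                            best_case = rk$case_id[1],
                            best_score_mm = rk$score[1],
                            icp_translation_mm = c(rk$tx[1], rk$ty[1],
                                                   rk$tz[1]),
                            ranking = rk),
                       reportPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(seg = seg, ranking = rk, plan = plan,
                 paths = list(structures = ssPath, plan = planPath,
                              report = reportPath)))
}

# ---- command-line interface ----

#' Command-line dispatcher
#'
#' Subcommands: \code{phantom}, \code{segment}, \code{evaluate},
#' \code{build-db}, \code{match}, \code{autoplan}. See
#' \code{inst/cli/wbrt.R} for the Rscript wrapper; run it without
#' arguments for usage.
#'
#' @param args character vector, e.g. \code{commandArgs(TRUE)}.
#' @return 0 invisibly on success; errors propagate to the caller.
#' @export
wbrtCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: wbrt.R <command> [--flag value ...]",
    "  phantom   --out DIR [--seed N] [--spacing MM] [--series]",
    "  segment   --ct PATH --out FILE",
    "  evaluate  --a FILE --b FILE --out FILE",
    "  build-db  --cases DIR --out MANIFEST [--generate N] [--seed N]",
    "  match     --structures FILE --db MANIFEST --out FILE",
    "  autoplan  --ct PATH --db MANIFEST --out DIR [--name N] [--id I]",
    sep = "\n")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- parseFlags(args[-1])
  need <- function(k) {
    if (is.null(opt[[k]]))
      stop("missing required flag --", k, "\n", usage, call. = FALSE)
    opt[[k]]
  }
  num <- function(k, default) if (is.null(opt[[k]])) default
                              else as.numeric(opt[[k]])
  switch(cmd,
    "phantom" = runPhantom(need("out"), seed = as.integer(num("seed", 1)),
                           spacing = num("spacing", 1),
                           writeSeries = isTRUE(opt[["series"]])),
    "segment" = runSegment(need("ct"), need("out")),
    "evaluate" = runEvaluate(need("a"), need("b"), need("out")),
    "build-db" = {
      if (!is.null(opt[["generate"]])) {
        n <- as.integer(opt[["generate"]])
        spec <- phantomSpecAtSpacing(num("spacing", 2),
                                     as.integer(num("seed", 1)))
        db <- generateDatabase(spec, n)
        for (cs in db)
          writeCaseDir(cs, file.path(need("cases"), cs$id))
      }
      runBuildDb(need("cases"), need("out"))
    },
    "match" = runMatch(need("structures"), need("db"), need("out")),
    "autoplan" = runAutoplan(need("ct"), need("db"), need("out"),
                             patientName = if (is.null(opt[["name"]]))
                               "AUTO^PATIENT" else opt[["name"]],
                             patientID = if (is.null(opt[["id"]]))
                               "AUTO001" else opt[["id"]],
                             seed = as.integer(num("seed", 1))),
    stop("unknown command '", cmd, "'\n", usage, call. = FALSE))
  invisible(0L)
}

parseFlags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}
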