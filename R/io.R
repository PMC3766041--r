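## File formats: delimited-text curves and velocity matrices with JSON
## sidecar descriptors, contour files, presence tables, case descriptors.
## All numeric text is written with 9 significant digits so a write/read
## round trip is lossless at that precision; parsing is strict (a decimal
## comma or any non-numeric cell is a parse error, never a silent misread).

fmtNum <- function(x) sprintf("%.9g", x)

parseNumericStrict <- function(s, path, lineNo, what) {
  x <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(x) | !nzchar(trimws(s)))
  if (length(bad))
    stopParse("%s: line %d: non-numeric %s '%s'", path, lineNo[bad[1]],
              what, s[bad[1]])
  x
}

#' Read and write curve files
#'
#' Curve files are two-column delimited text with the exact header
#' `time_ms,value`, one row per phase.  Reading is strict: a malformed
#' header, a wrong field count, a non-numeric cell (including locale
#' decimal commas) or non-increasing times raise a parse error naming the
#' offending line.
#'
#' @param path file path.
#' @param units unit label to attach to the curve read (the label lives in
#'   the case descriptor, not in the curve file).
#' @return `readCurve` returns a [SampledCurve-class]; `writeCurve`
#'   (invisibly) the path.
#' @export
readCurve <- function(path, units = "") {
  lines <- readLines(path)
  if (length(lines) < 3L) stopParse("%s: need a header and at least 2 rows", path)
  if (trimws(lines[1]) != "time_ms,value")
    stopParse("%s: line 1: expected header 'time_ms,value', got '%s'", path, lines[1])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    stopParse("%s: line %d: expected 2 comma-separated fields, got %d (decimal commas are not accepted)",
              path, bad + 1L, nf[bad])
  }
  ln <- seq_along(body) + 1L
  t <- parseNumericStrict(vapply(parts, `[`, "", 1L), path, ln, "time")
  v <- parseNumericStrict(vapply(parts, `[`, "", 2L), path, ln, "value")
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1]
    stopParse("%s: line %d: time %g does not increase past %g",
              path, ln[bad + 1L], t[bad + 1L], t[bad])
  }
  sampledCurve(t, v, units)
}

#' @rdname readCurve
#' @param curve a [SampledCurve-class] to write.
#' @export
writeCurve <- function(curve, path) {
  writeLines(c("time_ms,value",
               paste(fmtNum(curve@times), fmtNum(curve@values), sep = ",")),
             path)
  invisible(path)
}

## ---- velocity-map series ---------------------------------------------------

writeVelocityMatrix <- function(m, path) {
  writeLines(apply(m, 1L, function(r) paste(fmtNum(r), collapse = ",")), path)
  invisible(path)
}

readVelocityMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (length(unique(nf)) != 1L)
    stopParse("%s: ragged matrix (row lengths %s)", path,
              paste(unique(nf), collapse = ", "))
  vals <- parseNumericStrict(unlist(parts), path,
                             rep(seq_along(lines), each = nf[1]), "velocity")
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' Read and write velocity-map series
#'
#' A series is a JSON descriptor (pixel spacing in mm, trigger times in ms,
#' Venc in cm/s, and a list of matrix files) next to one comma-delimited
#' matrix file per phase (rows = grid rows, velocities in cm/s).
#'
#' @param path path of the JSON series descriptor.
#' @return `readVelocitySeries` returns a list of [VelocityFrame-class].
#' @export
readVelocitySeries <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pixel_spacing_mm", "trigger_times_ms", "venc_cm_s", "files")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopParse("%s: missing field(s) %s", path, paste(miss, collapse = ", "))
  dir <- dirname(path)
  if (length(d$files) != length(d$trigger_times_ms))
    stopParse("%s: %d file(s) for %d trigger time(s)", path,
              length(d$files), length(d$trigger_times_ms))
  lapply(seq_along(d$files), function(i) {
    f <- file.path(dir, d$files[[i]])
    if (!file.exists(f)) stopParse("%s: referenced file %s does not exist", path, f)
    velocityFrame(readVelocityMatrix(f), d$pixel_spacing_mm,
                  d$trigger_times_ms[[i]], venc = d$venc_cm_s)
  })
}

#' @rdname readVelocitySeries
#' @param frames list of [VelocityFrame-class] to write.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the matrix files.
#' @return `writeVelocitySeries` returns the descriptor path, invisibly.
#' @export
writeVelocitySeries <- function(frames, dir, prefix = "vel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.txt", prefix, seq_along(frames) - 1L)
  for (i in seq_along(frames))
    writeVelocityMatrix(frames[[i]]@velocities, file.path(dir, files[i]))
  desc <- list(pixel_spacing_mm = frames[[1]]@pixelSpacing,
               trigger_times_ms = vapply(frames, function(f) f@triggerTime, numeric(1)),
               venc_cm_s = frames[[1]]@venc, files = files)
  p <- file.path(dir, paste0(prefix, "_series.json"))
  jsonlite::write_json(desc, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

## ---- ROI and contours ------------------------------------------------------

#' Read and write ROI polygons
#'
#' A JSON array of `[row, col]` vertex pairs (0-based pixel coordinates).
#'
#' @param path file path.
#' @return `readRoi` returns an [RoiPolygon-class].
#' @export
readRoi <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.matrix(v) || ncol(v) != 2L)
    stopParse("%s: expected an array of [row, col] pairs", path)
  roiPolygon(v)
}

#' @rdname readRoi
#' @param roi an [RoiPolygon-class].
#' @export
writeRoi <- function(roi, path) {
  m <- unname(roi@vertices)
  jsonlite::write_json(lapply(seq_len(nrow(m)), function(i) m[i, ]),
                       path, digits = NA)
  invisible(path)
}

writeContourFile <- function(polygon, path) {
  v <- polygon@vertices
  writeLines(paste(fmtNum(v[, 1]), fmtNum(v[, 2]), sep = ","), path)
  invisible(path)
}

readContourFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stopParse("%s: expected 'row,col' rows", path)
  r <- parseNumericStrict(vapply(parts, `[`, "", 1L), path, seq_along(lines), "row")
  c <- parseNumericStrict(vapply(parts, `[`, "", 2L), path, seq_along(lines), "col")
  roiPolygon(cbind(r, c))
}

#' Read and write contour stacks
#'
#' A JSON stack descriptor (pixel spacing, slice thickness and gap in mm,
#' trigger times in ms, basal truncation fractions, and a phase-by-slice
#' file map with `null` for slices without a contour) next to one
#' `row,col` delimited-text file per contour.
#'
#' @param path path of the JSON stack descriptor.
#' @return `readContourStack` returns a [ContourStack-class].
#' @export
readContourStack <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("pixel_spacing_mm", "slice_thickness_mm", "slice_gap_mm",
            "trigger_times_ms", "files")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopParse("%s: missing field(s) %s", path, paste(miss, collapse = ", "))
  dir <- dirname(path)
  contours <- lapply(d$files, function(phase) {
    lapply(phase, function(f) {
      if (is.null(f) || length(f) == 0L || (length(f) == 1L && is.na(f)))
        return(NULL)
      fp <- file.path(dir, f)
      if (!file.exists(fp)) stopParse("%s: referenced file %s does not exist", path, fp)
      readContourFile(fp)
    })
  })
  bt <- if (is.null(d$basal_truncation)) 1 else unlist(d$basal_truncation)
  contourStack(contours, pixelSpacing = unlist(d$pixel_spacing_mm),
               sliceThickness = d$slice_thickness_mm,
               sliceGap = d$slice_gap_mm,
               triggerTimes = unlist(d$trigger_times_ms),
               basalTruncation = bt)
}

#' @rdname readContourStack
#' @param stack a [ContourStack-class].
#' @param dir output directory.
#' @return `writeContourStack` returns the descriptor path, invisibly.
#' @export
writeContourStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(seq_along(stack@contours), function(p) {
    lapply(seq_along(stack@contours[[p]]), function(s) {
      poly <- stack@contours[[p]][[s]]
      if (is.null(poly)) return(NA_character_)  # serialised as JSON null
      f <- sprintf("contour_p%03d_s%02d.txt", p - 1L, s - 1L)
      writeContourFile(poly, file.path(dir, f))
      f
    })
  })
  desc <- list(pixel_spacing_mm = stack@pixelSpacing,
               slice_thickness_mm = stack@sliceThickness,
               slice_gap_mm = stack@sliceGap,
               trigger_times_ms = stack@triggerTimes,
               basal_truncation = stack@basalTruncation,
               files = files)
  p <- file.path(dir, "contour_stack.json")
  jsonlite::write_json(desc, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(p)
}

## ---- jet presence ----------------------------------------------------------

#' Read and write jet-presence tables
#'
#' Delimited text with header `time_ms,present` and one 0/1 row per
#' systolic frame.
#'
#' @param path file path.
#' @return `readPresence` returns a [JetPresence-class].
#' @export
readPresence <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopParse("%s: need a header and at least one row", path)
  if (trimws(lines[1]) != "time_ms,present")
    stopParse("%s: line 1: expected header 'time_ms,present'", path)
  body <- lines[-1]; body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stopParse("%s: expected 2 comma-separated fields per row", path)
  ln <- seq_along(body) + 1L
  t <- parseNumericStrict(vapply(parts, `[`, "", 1L), path, ln, "time")
  p <- vapply(parts, `[`, "", 2L)
  if (!all(p %in% c("0", "1")))
    stopParse("%s: line %d: present must be 0 or 1, got '%s'",
              path, ln[which(!p %in% c("0", "1"))[1]], p[!p %in% c("0", "1")][1])
  jetPresence(p == "1", t)
}

#' @rdname readPresence
#' @param presence a [JetPresence-class].
#' @export
writePresence <- function(presence, path) {
  writeLines(c("time_ms,present",
               paste(fmtNum(presence@frameTimes),
                     as.integer(presence@present), sep = ",")),
             path)
  invisible(path)
}

## ---- case descriptor and the file-based pipeline ---------------------------

descriptorKnownKeys <- c("velocity_series", "phantom_series", "roi",
                         "contour_stack", "presence", "params")
descriptorKnownParams <- c("smoothing_window", "grid_points",
                           "forward_flow_window")

#' Read a case descriptor
#'
#' A JSON file binding the input files of one case: `velocity_series`,
#' `roi` and `contour_stack` (required), `phantom_series` and `presence`
#' (optional), and a `params` block (`smoothing_window`, `grid_points`,
#' `forward_flow_window`).  Unknown keys are rejected; relative paths
#' resolve against the descriptor's directory; referenced files must exist.
#'
#' @param path descriptor path.
#' @return a named list with resolved paths and parameters.
#' @export
readCaseDescriptor <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(d), descriptorKnownKeys)
  if (length(unknown))
    stopConfig("%s: unknown key(s): %s", path, paste(unknown, collapse = ", "))
  need <- c("velocity_series", "roi", "contour_stack")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopConfig("%s: missing required key(s): %s", path, paste(miss, collapse = ", "))
  if (!is.null(d$params)) {
    unknownP <- setdiff(names(d$params), descriptorKnownParams)
    if (length(unknownP))
      stopConfig("%s: unknown params key(s): %s", path, paste(unknownP, collapse = ", "))
  }
  dir <- dirname(path)
  resolve <- function(key) {
    if (is.null(d[[key]])) return(NULL)
    f <- d[[key]]
    if (!grepl("^/", f)) f <- file.path(dir, f)
    if (!file.exists(f)) stopConfig("%s: %s file %s does not exist", path, key, f)
    f
  }
  list(velocity_series = resolve("velocity_series"),
       phantom_series = resolve("phantom_series"),
       roi = resolve("roi"),
       contour_stack = resolve("contour_stack"),
       presence = resolve("presence"),
       params = if (is.null(d$params)) list() else as.list(d$params))
}

profileAsList <- function(res) {
  pr <- res$profile
  list(
    lv_stroke_volume_ml = res$lvStrokeVolume,
    forward_volume_ml = res$forwardVolume,
    regurgitant_volume_ml = pr@regurgitantVolume,
    regurgitant_volume_from_curve_ml = pr@volumeFromCurve,
    severity = pr@severity,
    peak_rates_by_third_ml_s = pr@peakRatesByThird,
    peak_rate_ml_s = pr@peakRate,
    mean_rate_ml_s = pr@meanRate,
    peak_to_average_ratio = if (is.na(pr@peakToAverageRatio)) NULL
                            else pr@peakToAverageRatio,
    jet_pattern = if (is.na(pr@jetPattern)) NULL else pr@jetPattern,
    jet_pattern_extension = pr@jetPatternExtension,
    t_ed_ms = res$timing@tEd, t_es_ms = res$timing@tEs,
    rate_curve = list(time_ms = res$profile@rateCurve@times,
                      rate_ml_s = res$profile@rateCurve@values))
}

#' Run the file-based quantification pipeline
#'
#' Reads every input named by a case descriptor, runs [quantifyCase()],
#' and optionally writes the full result as JSON and a flat one-row CSV
#' for cohort tables.  The JSON payload is deterministic — identical
#' inputs give identical bytes; run metadata (log messages, file paths)
#' stays out of it.  All decisions (missing phantom, clamping, pattern
#' warnings) are collected in the returned `log`.
#'
#' @param descriptor a descriptor path or the list from
#'   [readCaseDescriptor()].
#' @param outJson optional path for the result JSON.
#' @param outCsv optional path for the one-row cohort CSV.
#' @param caseId identifier written to the CSV row (default the descriptor
#'   file name).
#' @return the [quantifyCase()] result list, plus `log` (character).
#' @export
runQuantify <- function(descriptor, outJson = NULL, outCsv = NULL,
                        caseId = NULL) {
  if (is.character(descriptor)) {
    if (is.null(caseId)) caseId <- sub("\\.json$", "", basename(descriptor))
    descriptor <- readCaseDescriptor(descriptor)
  }
  if (is.null(caseId)) caseId <- "case"
  log <- character(0)
  frames <- readVelocitySeries(descriptor$velocity_series)
  phantom <- NULL
  if (!is.null(descriptor$phantom_series))
    phantom <- phantomSeries(readVelocitySeries(descriptor$phantom_series))
  roi <- readRoi(descriptor$roi)
  stack <- readContourStack(descriptor$contour_stack)
  presence <- if (is.null(descriptor$presence)) NULL
              else readPresence(descriptor$presence)
  p <- descriptor$params
  res <- withCallingHandlers(
    quantifyCase(frames = frames, roi = roi, stack = stack,
                 phantom = phantom, presence = presence,
                 smoothWindow = p$smoothing_window,
                 nGrid = if (is.null(p$grid_points)) 64L else as.integer(p$grid_points),
                 forwardWindow = if (is.null(p$forward_flow_window)) "cycle"
                                 else p$forward_flow_window),
    mrflow_warning = function(w) {
      log <<- c(log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  log <- c(log,
           sprintf("%d phase-contrast frame(s), %d cine phase(s), grid %d points",
                   length(frames), nPhases(stack),
                   if (is.null(p$grid_points)) 64L else as.integer(p$grid_points)))
  res$log <- log
  if (!is.null(outJson))
    jsonlite::write_json(profileAsList(res), outJson, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(outCsv)) {
    pr <- res$profile
    row <- data.frame(
      case = caseId,
      lv_stroke_volume_ml = res$lvStrokeVolume,
      forward_volume_ml = res$forwardVolume,
      regurgitant_volume_ml = pr@regurgitantVolume,
      severity = pr@severity,
      peak_rate_early_ml_s = pr@peakRatesByThird[1],
      peak_rate_mid_ml_s = pr@peakRatesByThird[2],
      peak_rate_late_ml_s = pr@peakRatesByThird[3],
      peak_rate_ml_s = pr@peakRate,
      mean_rate_ml_s = pr@meanRate,
      peak_to_average_ratio = pr@peakToAverageRatio,
      jet_pattern = ifelse(is.na(pr@jetPattern), "", pr@jetPattern),
      stringsAsFactors = FALSE)
    utils::write.csv(row, outCsv, row.names = FALSE)
  }
  res
}

#' Aggregate per-case result JSONs into a cohort table
#'
#' @param dir directory containing `*.json` results from [runQuantify()].
#' @param outCsv optional output CSV path.
#' @return a data.frame, one row per case.
#' @export
reportCohort <- function(dir, outCsv = NULL) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stopMissing("no result JSON files in %s", dir)
  rows <- lapply(files, function(f) {
    d <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(case = sub("\\.json$", "", basename(f)),
               lv_stroke_volume_ml = d$lv_stroke_volume_ml,
               forward_volume_ml = d$forward_volume_ml,
               regurgitant_volume_ml = d$regurgitant_volume_ml,
               severity = d$severity,
               peak_rate_early_ml_s = d$peak_rates_by_third_ml_s[1],
               peak_rate_mid_ml_s = d$peak_rates_by_third_ml_s[2],
               peak_rate_late_ml_s = d$peak_rates_by_third_ml_s[3],
               peak_rate_ml_s = d$peak_rate_ml_s,
               mean_rate_ml_s = d$mean_rate_ml_s,
               peak_to_average_ratio = if (is.null(d$peak_to_average_ratio))
                 NA_real_ else d$peak_to_average_ratio,
               jet_pattern = if (is.null(d$jet_pattern)) "" else d$jet_pattern,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(outCsv)) utils::write.csv(tab, outCsv, row.names = FALSE)
  tab
}

## ---- fixture sets ----------------------------------------------------------

#' Write a complete simulated fixture set
#'
#' Runs [simulateCase()] and emits every file the pipeline consumes — the
#' velocity and phantom series, ROI, contour stack, presence table and a
#' ready-to-run case descriptor — plus the ground truth as JSON and a
#' manifest with per-file MD5 checksums and a hash of the configuration.
#' Re-running with the same seed reproduces byte-identical files.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
writeFixtureSet <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, mode = 2) != 0)
    mrfStop("io_error", "directory %s is not writable", outDir)
  sim <- simulateCase(config)
  writeVelocitySeries(sim$frames, outDir, prefix = "vel")
  writeVelocitySeries(sim$phantom@frames, outDir, prefix = "phantom")
  writeRoi(sim$roi, file.path(outDir, "roi.json"))
  writeContourStack(sim$stack, outDir)
  hasPresence <- !is.null(sim$presence)
  if (hasPresence)
    writePresence(sim$presence, file.path(outDir, "presence.csv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(regurg_volume_ml = tr@regurgVolumeMl,
         forward_volume_ml = tr@forwardVolumeMl,
         severity = tr@severity, jet_pattern = tr@jetPattern,
         t_ed_ms = tr@tEd, t_es_ms = tr@tEs,
         regurg_rate_profile = list(time_ms = tr@regurgRateProfile@times,
                                    rate_ml_s = tr@regurgRateProfile@values),
         volume_profile = list(time_ms = tr@volumeProfile@times,
                               volume_ml = tr@volumeProfile@values)),
    file.path(outDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  desc <- list(velocity_series = "vel_series.json",
               phantom_series = "phantom_series.json",
               roi = "roi.json", contour_stack = "contour_stack.json")
  if (hasPresence) desc$presence <- "presence.csv"
  jsonlite::write_json(desc, file.path(outDir, "case.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  cfgTxt <- tempfile()
  slots <- slotNames(config)
  writeLines(vapply(slots, function(s)
    paste0(s, "=", paste(fmtNum(as.numeric(
      if (is.character(slot(config, s))) 0 else slot(config, s))),
      if (is.character(slot(config, s))) slot(config, s) else "",
      collapse = ",")), character(1)), cfgTxt)
  cfgHash <- unname(tools::md5sum(cfgTxt))
  unlink(cfgTxt)

  files <- setdiff(sort(list.files(outDir, recursive = TRUE)), "manifest.json")
  sums <- unname(tools::md5sum(file.path(outDir, files)))
  manifest <- list(config_hash = cfgHash, seed = config@seed,
                   pattern = config@regurgPattern,
                   regurg_volume_ml = config@regurgVolumeMl,
                   files = as.list(stats::setNames(sums, files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
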