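## Constructors, accessors and show methods.

#' Construct a SampledCurve
#'
#' @param times numeric, ms from the R-wave trigger, strictly increasing.
#' @param values numeric, samples; same length as `times`.
#' @param units character(1), unit label carried with the values.
#' @return A [SampledCurve-class].
#' @export
sampledCurve <- function(times, values, units = "") {
  new("SampledCurve", times = as.numeric(times), values = as.numeric(values),
      units = as.character(units))
}

#' @describeIn sampledCurve sample times (ms).
#' @param curve a [SampledCurve-class].
#' @export
curveTimes <- function(curve) curve@times

#' @describeIn sampledCurve sample values.
#' @export
curveValues <- function(curve) curve@values

#' @describeIn sampledCurve unit label.
#' @export
curveUnits <- function(curve) curve@units

#' @describeIn sampledCurve time span `c(first, last)` in ms.
#' @export
curveSpan <- function(curve) range(curve@times)

setMethod("show", "SampledCurve", function(object) {
  cat(sprintf("SampledCurve: %d samples over [%g, %g] ms%s\n",
              length(object@times), object@times[1],
              object@times[length(object@times)],
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
  cat(sprintf("  values: %g .. %g\n", min(object@values), max(object@values)))
})

#' Construct a SystoleTiming
#'
#' @param tEd end-diastole (systole onset), ms.
#' @param tEs end-systole, ms.
#' @return A [SystoleTiming-class].
#' @export
systoleTiming <- function(tEd, tEs) {
  new("SystoleTiming", tEd = as.numeric(tEd), tEs = as.numeric(tEs))
}

#' @describeIn systoleTiming boundaries of the three equal systolic thirds:
#'   `c(tEd, b1, b2, tEs)` with `b1 = tEd + (tEs-tEd)/3`,
#'   `b2 = tEd + 2(tEs-tEd)/3`.
#' @param timing a [SystoleTiming-class].
#' @export
thirdBoundaries <- function(timing) {
  d <- timing@tEs - timing@tEd
  c(timing@tEd, timing@tEd + d / 3, timing@tEd + 2 * d / 3, timing@tEs)
}

#' @describeIn systoleTiming systolic duration in ms.
#' @export
systolicDuration <- function(timing) timing@tEs - timing@tEd

setMethod("show", "SystoleTiming", function(object) {
  b <- thirdBoundaries(object)
  cat(sprintf("SystoleTiming: systole [%g, %g] ms; thirds at %g, %g ms\n",
              object@tEd, object@tEs, b[2], b[3]))
})

#' Construct a VelocityFrame
#'
#' Through-plane velocities for one cardiac phase.  Pixels at or beyond the
#' velocity-encoding limit indicate aliasing; they raise a classed warning
#' (`mrflow_venc_warning`) and are kept as-is, never unwrapped.
#'
#' @param velocities numeric matrix, cm/s (signed, positive = antegrade).
#' @param pixelSpacing numeric(2), (row, col) spacing in mm.
#' @param triggerTime ms from the R wave.
#' @param venc velocity-encoding limit, cm/s (default 250).
#' @return A [VelocityFrame-class].
#' @export
velocityFrame <- function(velocities, pixelSpacing, triggerTime, venc = 250) {
  fr <- new("VelocityFrame", velocities = velocities,
            pixelSpacing = as.numeric(pixelSpacing),
            triggerTime = as.numeric(triggerTime), venc = as.numeric(venc))
  nal <- sum(abs(velocities) >= venc)
  if (nal > 0)
    mrfWarn("venc_warning",
            "%d pixel(s) at or beyond Venc = %g cm/s; possible aliasing (not unwrapped)",
            nal, venc)
  fr
}

#' @describeIn velocityFrame velocity matrix (cm/s).
#' @param frame a [VelocityFrame-class].
#' @export
frameVelocities <- function(frame) frame@velocities

#' @describeIn velocityFrame pixel area in cm^2.
#' @export
pixelAreaCm2 <- function(frame) prod(frame@pixelSpacing) / 100

setMethod("show", "VelocityFrame", function(object) {
  d <- dim(object@velocities)
  cat(sprintf("VelocityFrame: %d x %d px (%g x %g mm), t = %g ms, Venc %g cm/s\n",
              d[1], d[2], object@pixelSpacing[1], object@pixelSpacing[2],
              object@triggerTime, object@venc))
})

#' Construct an RoiPolygon
#'
#' @param vertices an n x 2 numeric matrix of (row, col) pixel coordinates
#'   (0-based), or anything coercible to one; the ring is implicitly closed.
#' @return An [RoiPolygon-class].
#' @export
roiPolygon <- function(vertices) {
  m <- as.matrix(vertices)
  storage.mode(m) <- "double"
  colnames(m) <- c("row", "col")
  new("RoiPolygon", vertices = m)
}

#' @describeIn roiPolygon vertex matrix.
#' @param roi an [RoiPolygon-class].
#' @export
roiVertices <- function(roi) roi@vertices

setMethod("show", "RoiPolygon", function(object) {
  cat(sprintf("RoiPolygon: %d vertices, bbox rows [%g, %g], cols [%g, %g]\n",
              nrow(object@vertices),
              min(object@vertices[, 1]), max(object@vertices[, 1]),
              min(object@vertices[, 2]), max(object@vertices[, 2])))
})

#' Construct a PhantomSeries
#'
#' @param frames a list of [VelocityFrame-class] objects (a single static
#'   frame, or one per subject phase).
#' @return A [PhantomSeries-class].
#' @export
phantomSeries <- function(frames) {
  if (is(frames, "VelocityFrame")) frames <- list(frames)
  new("PhantomSeries", frames = frames)
}

setMethod("show", "PhantomSeries", function(object) {
  cat(sprintf("PhantomSeries: %d frame(s)\n", length(object@frames)))
})

#' Construct a ContourStack
#'
#' @param contours list (one element per phase) of lists (one per slice) of
#'   [RoiPolygon-class] or `NULL` for slices without cavity at that phase.
#' @param pixelSpacing numeric(2), mm.
#' @param sliceThickness slice thickness, mm (default 8).
#' @param sliceGap inter-slice gap, mm (default 0).
#' @param triggerTimes numeric, cine trigger times, ms (one per phase).
#' @param basalTruncation per-phase fraction in (0, 1] applied to the basal
#'   slice's contribution; recycled if scalar (default 1).
#' @return A [ContourStack-class].
#' @export
contourStack <- function(contours, pixelSpacing, sliceThickness = 8,
                         sliceGap = 0, triggerTimes,
                         basalTruncation = 1) {
  np <- length(contours)
  new("ContourStack", contours = contours,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      sliceGap = as.numeric(sliceGap),
      triggerTimes = as.numeric(triggerTimes),
      basalTruncation = rep_len(as.numeric(basalTruncation), np))
}

#' @describeIn contourStack number of phases.
#' @param stack a [ContourStack-class].
#' @export
nPhases <- function(stack) length(stack@contours)

setMethod("show", "ContourStack", function(object) {
  ns <- if (length(object@contours)) length(object@contours[[1]]) else 0L
  cat(sprintf("ContourStack: %d phase(s) x %d slice(s), %g mm thickness + %g mm gap\n",
              length(object@contours), ns, object@sliceThickness, object@sliceGap))
})

#' Construct a JetPresence record
#'
#' @param present logical, jet visible per systolic frame.
#' @param frameTimes numeric, frame trigger times, ms.
#' @return A [JetPresence-class].
#' @export
jetPresence <- function(present, frameTimes) {
  new("JetPresence", present = as.logical(present),
      frameTimes = as.numeric(frameTimes))
}

setMethod("show", "JetPresence", function(object) {
  cat(sprintf("JetPresence: %d frames, jet visible in %d\n",
              length(object@present), sum(object@present)))
})

setMethod("show", "RegurgProfile", function(object) {
  cat("RegurgProfile\n")
  cat(sprintf("  peak rates by third (ml/s): %s\n",
              paste(signif(object@peakRatesByThird, 4), collapse = " / ")))
  cat(sprintf("  peak %g ml/s, mean %g ml/s, peak-to-average %s\n",
              signif(object@peakRate, 4), signif(object@meanRate, 4),
              if (is.na(object@peakToAverageRatio)) "NA"
              else signif(object@peakToAverageRatio, 4)))
  cat(sprintf("  regurgitant volume %g ml (curve integral %g ml) -> %s\n",
              signif(object@regurgitantVolume, 4),
              signif(object@volumeFromCurve, 4), object@severity))
  if (!is.na(object@jetPattern))
    cat(sprintf("  jet pattern: %s%s\n", object@jetPattern,
                if (object@jetPatternExtension) " (single-third extension)" else ""))
})

#' @describeIn analyzeCase per-third zero-clamped peak rates (ml/s).
#' @param profile a [RegurgProfile-class].
#' @export
peakRatesByThird <- function(profile) profile@peakRatesByThird

#' @describeIn analyzeCase overall peak regurgitant rate (ml/s).
#' @export
peakRate <- function(profile) profile@peakRate

#' @describeIn analyzeCase systolic time-averaged regurgitant rate (ml/s).
#' @export
meanRate <- function(profile) profile@meanRate

#' @describeIn analyzeCase peak-to-average regurgitant rate ratio.
#' @export
peakToAverageRatio <- function(profile) profile@peakToAverageRatio

#' @describeIn analyzeCase regurgitant volume (ml), LVSV minus forward flow.
#' @export
regurgVolume <- function(profile) profile@regurgitantVolume

#' @describeIn analyzeCase severity grade ("mild"/"moderate"/"severe").
#' @export
severity <- function(profile) profile@severity

#' @describeIn analyzeCase jet pattern label (or `NA`).
#' @export
jetPattern <- function(profile) profile@jetPattern

#' @describeIn analyzeCase the signed instantaneous rate curve (ml/s).
#' @export
rateCurve <- function(profile) profile@rateCurve

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %s pattern, RVol %g ml, SV %g ml, EDV %g ml\n",
              object@seed, object@regurgPattern, object@regurgVolumeMl,
              object@svMl, object@edvMl))
  cat(sprintf("  cycle %g ms (systole %g ms), %d cine / %d PC phases, noise %g cm/s\n",
              object@cycleMs, object@systoleMs, object@nPhasesCine,
              object@nPhasesPc, object@noiseVelocityCmS))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: RVol %g ml, forward %g ml, %s, %s jet, systole [%g, %g] ms\n",
              object@regurgVolumeMl, object@forwardVolumeMl, object@severity,
              object@jetPattern, object@tEd, object@tEs))
})
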