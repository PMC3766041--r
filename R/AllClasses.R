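#' @import methods
NULL

#' SampledCurve: a physiological time series
#'
#' A scalar quantity sampled against time from the R-wave trigger.  Times are
#' milliseconds; the value units (ml, ml/s, cm/s, ...) travel with the object
#' as a label.  All flow, volume and regurgitant-rate curves in the package
#' are `SampledCurve` objects.
#'
#' @slot times numeric, milliseconds from the R-wave trigger, strictly
#'   increasing, length >= 2.
#' @slot values numeric, same length as `times`, all finite.
#' @slot units character(1), unit label for the values.
#'
#' @examples
#' sc <- sampledCurve(c(0, 100, 200), c(176, 150, 120), "ml")
#' curveTimes(sc)
#' @export
setClass("SampledCurve",
  representation(times = "numeric", values = "numeric", units = "character"),
  prototype(units = "")
)

setValidity("SampledCurve", function(object) {
  t <- object@times; v <- object@values
  if (length(t) < 2L) return("need at least 2 samples")
  if (length(t) != length(v)) return("times and values must have equal length")
  if (anyNA(t) || any(!is.finite(t))) return("times must be finite")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (any(diff(t) <= 0)) return("times must be strictly increasing")
  if (length(object@units) != 1L) return("units must be a single string")
  TRUE
})

#' SystoleTiming: end-diastole, end-systole and the systolic thirds
#'
#' Marks the ejection period `[tEd, tEs]` and its partition into three equal
#' thirds (early, mid, late).  Thirds are defined in time, not frame counts:
#' boundaries sit at `tEd + (tEs - tEd)/3` and `tEd + 2(tEs - tEd)/3`.
#'
#' @slot tEd numeric(1), end-diastole (systole onset), ms.
#' @slot tEs numeric(1), end-systole, ms.
#' @export
setClass("SystoleTiming",
  representation(tEd = "numeric", tEs = "numeric")
)

setValidity("SystoleTiming", function(object) {
  if (length(object@tEd) != 1L || length(object@tEs) != 1L)
    return("tEd and tEs must be scalars")
  if (!is.finite(object@tEd) || !is.finite(object@tEs))
    return("tEd and tEs must be finite")
  if (object@tEd >= object@tEs) return("tEd must precede tEs")
  TRUE
})

#' VelocityFrame: one phase of a through-plane velocity map
#'
#' A rectangular grid of signed through-plane velocities (cm/s, positive =
#' antegrade) with its pixel geometry and trigger time.  Velocities beyond
#' the velocity-encoding limit (Venc) indicate aliasing and are flagged at
#' construction, never unwrapped.
#'
#' @slot velocities numeric matrix, cm/s.
#' @slot pixelSpacing numeric(2), (row, col) spacing in mm.
#' @slot triggerTime numeric(1), ms from the R wave.
#' @slot venc numeric(1), velocity-encoding limit in cm/s.
#' @export
setClass("VelocityFrame",
  representation(velocities = "matrix", pixelSpacing = "numeric",
                 triggerTime = "numeric", venc = "numeric"),
  prototype(venc = 250)
)

setValidity("VelocityFrame", function(object) {
  v <- object@velocities
  if (!is.numeric(v) || length(dim(v)) != 2L) return("velocities must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) return("velocities must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (row mm, col mm)")
  if (length(object@triggerTime) != 1L || !is.finite(object@triggerTime))
    return("triggerTime must be a finite scalar")
  if (length(object@venc) != 1L || object@venc <= 0)
    return("venc must be a positive scalar")
  TRUE
})

#' RoiPolygon: a region of interest in pixel coordinates
#'
#' An ordered ring of (row, col) vertices, 0-based, implicitly closed.  Used
#' both for the manually traced aortic circumference on phase-contrast
#' images and for endocardial contours on cine images.
#'
#' @slot vertices numeric matrix with columns (row, col), >= 3 rows.
#' @export
setClass("RoiPolygon", representation(vertices = "matrix"))

setValidity("RoiPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3L) return("a polygon needs at least 3 vertices")
  if (anyNA(v) || any(!is.finite(v))) return("vertices must be finite")
  TRUE
})

#' PhantomSeries: stationary-phantom velocity maps for baseline correction
#'
#' Velocity maps acquired of a stationary water phantom with the same
#' geometry as the subject series.  Either one static frame (broadcast to
#' every subject phase) or one frame per phase.
#'
#' @slot frames list of [VelocityFrame-class] objects.
#' @export
setClass("PhantomSeries", representation(frames = "list"))

setValidity("PhantomSeries", function(object) {
  if (length(object@frames) < 1L) return("need at least one phantom frame")
  ok <- vapply(object@frames, is, logical(1), class2 = "VelocityFrame")
  if (!all(ok)) return("all frames must be VelocityFrame objects")
  d1 <- dim(object@frames[[1]]@velocities)
  for (f in object@frames)
    if (!identical(dim(f@velocities), d1)) return("phantom frames must share one grid shape")
  TRUE
})

#' ContourStack: endocardial contours by slice and phase
#'
#' Output of (upstream) endocardial segmentation: one polygon per
#' (slice, phase) cell, or `NULL` where a slice has no cavity at that phase.
#' Carries the geometry needed for Simpson summation: pixel spacing, slice
#' thickness and gap, and the cine trigger times.
#'
#' @slot contours list (length = phases) of lists (length = slices) whose
#'   elements are [RoiPolygon-class] or `NULL`.
#' @slot pixelSpacing numeric(2), mm.
#' @slot sliceThickness numeric(1), mm (default 8).
#' @slot sliceGap numeric(1), mm (default 0).
#' @slot triggerTimes numeric, ms, one per phase, strictly increasing.
#' @slot basalTruncation numeric, per-phase fraction in (0, 1] multiplying
#'   the basal (first) slice's contribution; default 1 for all phases.
#' @export
setClass("ContourStack",
  representation(contours = "list", pixelSpacing = "numeric",
                 sliceThickness = "numeric", sliceGap = "numeric",
                 triggerTimes = "numeric", basalTruncation = "numeric")
)

setValidity("ContourStack", function(object) {
  np <- length(object@contours)
  if (np < 1L) return("need at least one phase")
  if (length(object@triggerTimes) != np)
    return("triggerTimes must have one entry per phase")
  if (np > 1L && any(diff(object@triggerTimes) <= 0))
    return("triggerTimes must be strictly increasing")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    return("sliceThickness must be a positive scalar (mm)")
  if (length(object@sliceGap) != 1L || object@sliceGap < 0)
    return("sliceGap must be a non-negative scalar (mm)")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (mm)")
  if (length(object@basalTruncation) != np ||
      any(object@basalTruncation <= 0 | object@basalTruncation > 1))
    return("basalTruncation must be one fraction in (0, 1] per phase")
  for (ph in object@contours) {
    if (!is.list(ph)) return("each phase must be a list of slice contours")
    for (s in ph)
      if (!is.null(s) && !is(s, "RoiPolygon"))
        return("slice entries must be RoiPolygon or NULL")
  }
  TRUE
})

#' JetPresence: frame-by-frame visibility of the regurgitant jet
#'
#' The result of visual inspection for the presence or absence of the
#' regurgitant jet on each systolic frame.
#'
#' @slot present logical, one flag per systolic frame.
#' @slot frameTimes numeric, trigger time (ms) of each frame.
#' @export
setClass("JetPresence",
  representation(present = "logical", frameTimes = "numeric")
)

setValidity("JetPresence", function(object) {
  if (length(object@present) != length(object@frameTimes))
    return("present and frameTimes must have equal length")
  if (length(object@present) < 1L) return("need at least one frame")
  if (anyNA(object@present)) return("present flags must be TRUE/FALSE")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    return("frameTimes must be strictly increasing")
  TRUE
})

#' RegurgProfile: the full per-case regurgitation result
#'
#' The instantaneous regurgitant-rate curve over systole together with the
#' derived metrics: per-third peak rates, the overall peak, the systolic
#' time-average, the peak-to-average ratio, the regurgitant volume (stroke
#' volume minus forward flow), the severity grade and the jet pattern.
#' `volumeFromCurve` is the trapezoidal integral of the signed rate curve
#' over systole, reported alongside as an internal-consistency (QC) check.
#'
#' @slot rateCurve [SampledCurve-class], ml/s, signed (negatives preserved
#'   for QC; metrics clamp at zero).
#' @slot peakRatesByThird numeric(3), ml/s, zero-clamped peak per third.
#' @slot peakRate numeric(1), max of the per-third peaks.
#' @slot meanRate numeric(1), zero-clamped time-average over systole, ml/s.
#' @slot peakToAverageRatio numeric(1), `peakRate / meanRate`; `NA` when the
#'   mean rate is zero.
#' @slot regurgitantVolume numeric(1), ml, from LVSV minus forward volume.
#' @slot volumeFromCurve numeric(1), ml, signed rate curve integrated over
#'   systole (QC companion to `regurgitantVolume`).
#' @slot severity character(1): "mild", "moderate" or "severe".
#' @slot jetPattern character(1): "early", "holosystolic", "late",
#'   "indeterminate", or `NA` when no presence data were supplied.
#' @slot jetPatternExtension logical(1): `TRUE` when the pattern label comes
#'   from the single-third extension of the early/late definitions.
#' @export
setClass("RegurgProfile",
  representation(rateCurve = "SampledCurve", peakRatesByThird = "numeric",
                 peakRate = "numeric", meanRate = "numeric",
                 peakToAverageRatio = "numeric", regurgitantVolume = "numeric",
                 volumeFromCurve = "numeric", severity = "character",
                 jetPattern = "character", jetPatternExtension = "logical")
)

setValidity("RegurgProfile", function(object) {
  if (length(object@peakRatesByThird) != 3L) return("need exactly 3 per-third peaks")
  if (any(object@peakRatesByThird < 0)) return("per-third peaks are zero-clamped, must be >= 0")
  if (!isTRUE(all.equal(object@peakRate, max(object@peakRatesByThird))))
    return("peakRate must equal the maximum per-third peak")
  if (object@regurgitantVolume < 0) return("regurgitant volume must be >= 0")
  if (!object@severity %in% c("mild", "moderate", "severe"))
    return("severity must be mild/moderate/severe")
  if (!is.na(object@jetPattern) &&
      !object@jetPattern %in% c("early", "holosystolic", "late", "indeterminate"))
    return("unknown jet pattern label")
  TRUE
})

#' SimConfig: configuration of the forward simulator
#'
#' Ground-truth hemodynamic state and acquisition geometry for
#' [simulateCase()].  Defaults mirror a typical clinical acquisition:
#' 20 cine phases and 30 phase-contrast phases over an 800 ms cycle with a
#' 400 ms systole, Venc 250 cm/s, 8 mm slices with no gap, and a cohort-mean
#' ventricle (EDV 176 ml, stroke volume 105 ml).
#'
#' @slot seed integer(1), random stream for this case.
#' @slot nPhasesCine integer(1), cine frames per cycle (default 20).
#' @slot nPhasesPc integer(1), phase-contrast frames per cycle (default 30).
#' @slot cycleMs numeric(1), cardiac cycle length, ms (default 800).
#' @slot systoleMs numeric(1), ejection duration, ms (default 400).
#' @slot edvMl,svMl numeric(1), end-diastolic and stroke volume, ml.
#' @slot regurgPattern character(1): "none", "early", "late", "holosystolic".
#' @slot regurgVolumeMl numeric(1), ml per beat (< svMl).
#' @slot peakShape numeric(1), window exponent shaping the rate profiles.
#' @slot noiseVelocityCmS numeric(1), Gaussian pixel-velocity noise sd, cm/s.
#' @slot baselineOffsetCmS numeric(1), amplitude of the spatially linear
#'   baseline offset field, cm/s.
#' @slot gridShape integer(2), velocity-map grid (rows, cols).
#' @slot pixelSpacingMm numeric(2), phase-contrast pixel spacing, mm.
#' @slot aortaRadiusMm numeric(1), vessel radius, mm.
#' @slot lvLongAxisMm numeric(1), full LV long-axis length, mm.
#' @slot cinePixelSpacingMm numeric(2), cine pixel spacing, mm.
#' @slot sliceThicknessMm,sliceGapMm numeric(1), mm.
#' @slot basalTruncation numeric(1), basal-slice fraction in (0, 1].
#' @slot jetFrames integer(1), systolic frames for jet inspection; `NA`
#'   means use the cine frames falling in systole.
#' @slot phantomMode character(1): "static" (one frame) or "per_phase".
#' @slot venc numeric(1), cm/s.
#' @export
setClass("SimConfig",
  representation(seed = "integer", nPhasesCine = "integer", nPhasesPc = "integer",
                 cycleMs = "numeric", systoleMs = "numeric",
                 edvMl = "numeric", svMl = "numeric",
                 regurgPattern = "character", regurgVolumeMl = "numeric",
                 peakShape = "numeric", noiseVelocityCmS = "numeric",
                 baselineOffsetCmS = "numeric", gridShape = "integer",
                 pixelSpacingMm = "numeric", aortaRadiusMm = "numeric",
                 lvLongAxisMm = "numeric", cinePixelSpacingMm = "numeric",
                 sliceThicknessMm = "numeric", sliceGapMm = "numeric",
                 basalTruncation = "numeric", jetFrames = "integer",
                 phantomMode = "character", venc = "numeric")
)

setValidity("SimConfig", function(object) {
  if (!object@regurgPattern %in% c("none", "early", "late", "holosystolic"))
    return("regurgPattern must be none/early/late/holosystolic")
  if (object@regurgPattern == "none" && object@regurgVolumeMl > 0)
    return("regurgVolumeMl must be 0 when regurgPattern is 'none'")
  if (object@regurgVolumeMl < 0) return("regurgVolumeMl must be >= 0")
  if (object@regurgVolumeMl >= object@svMl)
    return("regurgVolumeMl must be smaller than svMl")
  if (object@systoleMs >= object@cycleMs) return("systoleMs must be < cycleMs")
  if (object@nPhasesCine < 3L || object@nPhasesPc < 3L)
    return("phase counts must be >= 3")
  if (!is.na(object@jetFrames) && object@jetFrames < 3L)
    return("jetFrames must be >= 3")
  if (object@edvMl <= object@svMl) return("edvMl must exceed svMl")
  if (!object@phantomMode %in% c("static", "per_phase"))
    return("phantomMode must be 'static' or 'per_phase'")
  if (object@basalTruncation <= 0 || object@basalTruncation > 1)
    return("basalTruncation must be in (0, 1]")
  if (any(object@gridShape < 8L)) return("gridShape too small")
  if (object@noiseVelocityCmS < 0) return("noise sd must be >= 0")
  TRUE
})

#' GroundTruth: the simulator's configured hemodynamic state
#'
#' The continuous-time profiles and scalar truths behind one simulated case,
#' against which pipeline recovery is checked.
#'
#' @slot regurgRateProfile,aorticFlowProfile,volumeProfile
#'   [SampledCurve-class] ground-truth curves on a fine time grid.
#' @slot regurgVolumeMl,forwardVolumeMl numeric(1), ml.
#' @slot severity character(1).
#' @slot jetPattern character(1) ("none" for the control case).
#' @slot tEd,tEs numeric(1), ms.
#' @export
setClass("GroundTruth",
  representation(regurgRateProfile = "SampledCurve",
                 aorticFlowProfile = "SampledCurve",
                 volumeProfile = "SampledCurve",
                 regurgVolumeMl = "numeric", forwardVolumeMl = "numeric",
                 severity = "character", jetPattern = "character",
                 tEd = "numeric", tEs = "numeric")
)
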