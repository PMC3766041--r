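## LV volumetry: contour areas, Simpson summation of disks, volume curve,
## stroke volume and the instantaneous ejection-rate curve.

#' Area of a contour polygon
#'
#' Shoelace area in pixel units scaled by the pixel spacing; orientation
#' independent.
#'
#' @param polygon an [RoiPolygon-class] (>= 3 vertices).
#' @param pixelSpacing numeric(2), (row, col) spacing in mm.
#' @return numeric(1), cm^2.
#' @export
polygonArea <- function(polygon, pixelSpacing) {
  v <- polygon@vertices
  r <- v[, 1]; c <- v[, 2]
  rn <- c(r[-1], r[1]); cn <- c(c[-1], c[1])
  areaPx <- abs(sum(c * rn - cn * r)) / 2
  areaPx * pixelSpacing[1] * pixelSpacing[2] / 100  # mm^2 -> cm^2
}

#' LV cavity volume at one phase by Simpson summation
#'
#' Sums contour area times disk height (slice thickness + gap, in cm) over
#' the slices of one phase.  Slices without a contour contribute zero (a
#' classed warning `mrflow_contour_warning` is raised).  The basal (first)
#' slice's contribution is multiplied by the stack's per-phase basal
#' truncation fraction.
#'
#' @param stack a [ContourStack-class].
#' @param phase 1-based phase index.
#' @return numeric(1), ml.
#' @export
lvVolume <- function(stack, phase) {
  np <- nPhases(stack)
  if (phase < 1L || phase > np)
    stopArgument("phase %d out of range 1..%d", phase, np)
  slices <- stack@contours[[phase]]
  has <- !vapply(slices, is.null, logical(1))
  if (!any(has))
    stopMissing("phase %d has no contours on any slice", phase)
  if (!all(has))
    mrfWarn("contour_warning",
            "phase %d: %d of %d slice(s) without contour contribute 0 ml",
            phase, sum(!has), length(slices))
  heightCm <- (stack@sliceThickness + stack@sliceGap) / 10
  vol <- 0
  for (i in which(has)) {
    contrib <- polygonArea(slices[[i]], stack@pixelSpacing) * heightCm
    if (i == 1L) contrib <- contrib * stack@basalTruncation[phase]
    vol <- vol + contrib
  }
  vol
}

#' LV volume-versus-time curve
#'
#' [lvVolume()] at every phase, against the cine trigger times.
#'
#' @param stack a [ContourStack-class] with >= 3 phases.
#' @return A [SampledCurve-class] in ml.
#' @export
volumeCurve <- function(stack) {
  np <- nPhases(stack)
  if (np < 3L) stopArgument("need at least 3 phases, got %d", np)
  vols <- vapply(seq_len(np), function(p) lvVolume(stack, p), numeric(1))
  sampledCurve(stack@triggerTimes, vols, "ml")
}

#' Stroke volume from a volume curve
#'
#' End-diastolic minus end-systolic volume, i.e. the range of the curve
#' over the cycle.
#'
#' @param volumeCurve a [SampledCurve-class] in ml.
#' @return numeric(1), ml.
#' @examples
#' vc <- sampledCurve(c(0, 400, 800), c(176, 71, 176), "ml")
#' strokeVolume(vc)  # 105
#' @export
strokeVolume <- function(volumeCurve) {
  max(volumeCurve@values) - min(volumeCurve@values)
}

#' Instantaneous ejection-rate curve
#'
#' The rate of blood exiting the left ventricle: the negated slope of the
#' volume-versus-time curve, so positive values mean blood leaving the
#' ventricle (negative during diastolic filling).
#'
#' @param volumeCurve a [SampledCurve-class] in ml with >= 3 samples.
#' @param smoothWindow optional odd moving-average width applied before
#'   differencing (default none); see [differentiateCurve()].
#' @return A [SampledCurve-class] in ml/s.
#' @export
ejectionRate <- function(volumeCurve, smoothWindow = NULL) {
  d <- differentiateCurve(volumeCurve, smoothWindow = smoothWindow, units = "ml/s")
  sampledCurve(d@times, -d@values, "ml/s")
}
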