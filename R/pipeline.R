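## In-memory end-to-end pipeline: velocity series + contours -> RegurgProfile.

#' Quantify mitral regurgitation for one case
#'
#' Runs the full chain on in-memory objects: aortic flow curve (with
#' phantom baseline correction when supplied), LV volume curve, systole
#' detection, stroke and forward volumes, ejection rate, and the
#' regurgitation analysis.  File-based workflows go through
#' [runQuantify()], which wraps this.
#'
#' @param frames list of [VelocityFrame-class] (aortic phase-contrast
#'   series), or a pre-computed aortic flow [SampledCurve-class] via
#'   `aorticFlow`.
#' @param roi an [RoiPolygon-class] (ignored when `aorticFlow` is given).
#' @param stack a [ContourStack-class].
#' @param phantom a [PhantomSeries-class] or `NULL`; when `NULL` a
#'   `mrflow_baseline_warning` is raised and no correction is applied.
#' @param presence a [JetPresence-class] or `NULL`.
#' @param aorticFlow optional pre-computed flow curve replacing
#'   `frames`/`roi` (e.g. the average of repeated acquisitions).
#' @param smoothWindow optional odd moving-average width for the volume
#'   slope (default none).
#' @param nGrid systolic subtraction grid (default 64).
#' @param forwardWindow `"cycle"` (default) or `"systole"`.
#' @return A list: `profile` ([RegurgProfile-class]), `aorticFlow`,
#'   `volumeCurve`, `ejectionRate` (the slope of the systolic segment of
#'   the volume curve, [SampledCurve-class]), `timing`
#'   ([SystoleTiming-class]), `lvStrokeVolume`, `forwardVolume` (ml).
#' @export
quantifyCase <- function(frames = NULL, roi = NULL, stack, phantom = NULL,
                         presence = NULL, aorticFlow = NULL,
                         smoothWindow = NULL, nGrid = 64L,
                         forwardWindow = c("cycle", "systole")) {
  forwardWindow <- match.arg(forwardWindow)
  if (is.null(aorticFlow)) {
    if (is.null(frames) || is.null(roi))
      stopArgument("need either `aorticFlow` or `frames` + `roi`")
    if (is.null(phantom))
      mrfWarn("baseline_warning",
              "no phantom series supplied; flow curve is not baseline-corrected")
    aorticFlow <- flowCurve(frames, roi, phantom)
  }
  vc <- volumeCurve(stack)
  timing <- detectSystole(vc)
  lvsv <- strokeVolume(vc)
  fwd <- forwardVolume(aorticFlow, window = forwardWindow, timing = timing)
  ## Differentiate the systolic segment only: a central difference at
  ## end-systole would straddle the ejection-to-filling corner of the
  ## volume curve and leak diastolic refill into the last rate sample.
  ## One-sided differences at the segment ends also make the trapezoidal
  ## integral of the slope telescope exactly to the stroke volume.
  sel <- vc@times >= timing@tEd & vc@times <= timing@tEs
  vcSys <- sampledCurve(vc@times[sel], vc@values[sel], vc@units)
  er <- ejectionRate(vcSys, smoothWindow = smoothWindow)
  profile <- analyzeCase(er, aorticFlow, timing, lvsv, fwd,
                         presence = presence, nGrid = nGrid)
  list(profile = profile, aorticFlow = aorticFlow, volumeCurve = vc,
       ejectionRate = er, timing = timing, lvStrokeVolume = lvsv,
       forwardVolume = fwd)
}
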