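## Phase-contrast flow quantification: ROI pixel selection, per-frame flow,
## stationary-phantom baseline correction, flow curves and forward volume.

## Even-odd ray casting (ray towards +col) over all points at once, with
## points lying exactly on an edge counted inside.  `points` is n x 2
## (row, col); returns logical n.
pointsInPolygon <- function(points, vertices, eps = 1e-9) {
  py <- points[, 1]; px <- points[, 2]
  n <- nrow(vertices)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    y1 <- vertices[j, 1]; x1 <- vertices[j, 2]
    y2 <- vertices[i, 1]; x2 <- vertices[i, 2]
    # boundary: zero cross product and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(x2 - x1), abs(y2 - y1), 1)
    onSeg <- abs(cross) <= eps * scale &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onEdge <- onEdge | onSeg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onEdge
}

## logical mask of pixels (0-based centers) of an nr x nc grid inside `roi`
roiPixelMask <- function(roi, nr, nc) {
  centers <- cbind(rep(0:(nr - 1), times = nc), rep(0:(nc - 1), each = nr))
  matrix(pointsInPolygon(centers, roi@vertices), nrow = nr, ncol = nc)
}

#' Instantaneous flow through a region of interest
#'
#' Sums, over pixels whose centers fall inside the polygon (boundary
#' inclusive), velocity (cm/s) times pixel area (cm^2), giving volume flow
#' in cm^3/s = ml/s.  Linear in the velocities and additive over disjoint
#' ROIs.
#'
#' @param frame a [VelocityFrame-class].
#' @param roi an [RoiPolygon-class] traced on the same grid.
#' @return numeric(1), ml/s.
#' @export
roiFlow <- function(frame, roi) {
  d <- dim(frame@velocities)
  vr <- roi@vertices
  if (any(vr[, 1] < -0.5) || any(vr[, 1] > d[1] - 0.5) ||
      any(vr[, 2] < -0.5) || any(vr[, 2] > d[2] - 0.5))
    stopGeometry("ROI extends beyond the %d x %d velocity grid", d[1], d[2])
  mask <- roiPixelMask(roi, d[1], d[2])
  if (!any(mask)) stopGeometry("degenerate ROI: no pixel centers inside polygon")
  sum(frame@velocities[mask]) * pixelAreaCm2(frame)
}

#' Stationary-phantom baseline correction
#'
#' Subtracts, pixel by pixel, the velocity offset measured in a stationary
#' water phantom from a subject frame, removing scanner-induced phase bias.
#' Geometry and trigger time are preserved.
#'
#' @param frame subject [VelocityFrame-class].
#' @param phantom phantom [VelocityFrame-class] on the same grid.
#' @return A corrected [VelocityFrame-class].
#' @export
correctBaseline <- function(frame, phantom) {
  if (!identical(dim(frame@velocities), dim(phantom@velocities)))
    stopGeometry("phantom grid %s does not match subject grid %s",
                 paste(dim(phantom@velocities), collapse = "x"),
                 paste(dim(frame@velocities), collapse = "x"))
  if (!isTRUE(all.equal(frame@pixelSpacing, phantom@pixelSpacing)))
    stopGeometry("phantom pixel spacing does not match subject")
  new("VelocityFrame", velocities = frame@velocities - phantom@velocities,
      pixelSpacing = frame@pixelSpacing, triggerTime = frame@triggerTime,
      venc = frame@venc)
}

#' Flow-versus-time curve from a velocity-map series
#'
#' Applies baseline correction (a single static phantom frame is broadcast
#' to every phase; otherwise phantom frames are matched by phase index) and
#' then [roiFlow()] to each phase.  One ROI is applied to all phases.
#'
#' @param frames list of [VelocityFrame-class] with strictly increasing
#'   trigger times.
#' @param roi an [RoiPolygon-class].
#' @param phantom a [PhantomSeries-class], or `NULL` for no correction.
#' @return A [SampledCurve-class] in ml/s.
#' @export
flowCurve <- function(frames, roi, phantom = NULL) {
  if (length(frames) < 2L) stopArgument("need at least 2 frames")
  tt <- vapply(frames, function(f) f@triggerTime, numeric(1))
  if (any(diff(tt) <= 0)) stopArgument("frame trigger times must be strictly increasing")
  if (!is.null(phantom)) {
    npf <- length(phantom@frames)
    if (npf != 1L && npf != length(frames))
      stopConfig("phantom has %d frame(s) for %d subject phases; need 1 or %d",
                 npf, length(frames), length(frames))
    frames <- lapply(seq_along(frames), function(i) {
      pf <- phantom@frames[[if (npf == 1L) 1L else i]]
      correctBaseline(frames[[i]], pf)
    })
  }
  flows <- vapply(frames, roiFlow, numeric(1), roi = roi)
  sampledCurve(tt, flows, "ml/s")
}

#' Average repeated flow acquisitions
#'
#' Clinical flow measurement repeats the acquisition two or three times and
#' averages.  All curves are resampled onto the first curve's grid
#' restricted to the common time span, then averaged pointwise.
#'
#' @param curves list of [SampledCurve-class] with overlapping spans.
#' @return A [SampledCurve-class], the pointwise mean.
#' @export
averageFlowCurves <- function(curves) {
  if (length(curves) < 1L) stopArgument("need at least one curve")
  if (length(curves) == 1L) return(curves[[1]])
  spans <- vapply(curves, curveSpan, numeric(2))
  lo <- max(spans[1, ]); hi <- min(spans[2, ])
  if (lo >= hi) stopRange("curves have disjoint time spans")
  grid <- curves[[1]]@times
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) stopRange("common span [%g, %g] contains too few samples", lo, hi)
  vals <- vapply(curves, function(cv) interpAt(cv, grid), numeric(length(grid)))
  sampledCurve(grid, rowMeans(vals), curves[[1]]@units)
}

#' Forward volume from the aortic flow curve
#'
#' Net trapezoidal integral of the (signed) aortic flow curve, the forward
#' flow term of the regurgitant-volume computation.  By default integrates
#' the full curve span (the cardiac cycle); with `window = "systole"` only
#' the ejection period is integrated, which requires `timing`.
#'
#' @param aorticFlow a [SampledCurve-class] in ml/s.
#' @param window `"cycle"` (default) or `"systole"`.
#' @param timing a [SystoleTiming-class]; required for `window = "systole"`.
#' @return numeric(1), ml.
#' @export
forwardVolume <- function(aorticFlow, window = c("cycle", "systole"),
                          timing = NULL) {
  window <- match.arg(window)
  if (window == "cycle") return(trapezoidIntegral(aorticFlow))
  if (is.null(timing)) stopArgument("window = 'systole' requires `timing`")
  trapezoidIntegral(aorticFlow, timing@tEd, timing@tEs)
}
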