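## Forward simulator: builds velocity-map series, phantom, contour stack
## and jet-presence data from a configured ground-truth hemodynamic state.
##
## Rate profiles are raised-cosine windows (optionally skewed so the peak
## sits inside the intended third) scaled so their trapezoidal integral on
## the simulator's fine time grid equals the configured volume exactly.
## Velocity maps render a Poiseuille (parabolic) cross-sectional profile in
## a circular vessel, rescaled so the discrete pixel-centre flux equals the
## configured flow; contour radii are likewise calibrated so the Simpson
## disk sum equals the configured cavity volume.  Recovery error in
## noise-free runs therefore reflects the pipeline, not the renderer.

#' Simulator configuration
#'
#' See [SimConfig-class] for the meaning and defaults of every field.
#'
#' @param seed integer random seed for this case.
#' @param nPhasesCine,nPhasesPc frames per cycle (defaults 20, 30).
#' @param cycleMs,systoleMs cycle and ejection durations, ms (800, 400).
#' @param edvMl,svMl end-diastolic and stroke volume, ml (176, 105).
#' @param regurgPattern "none", "early", "late" or "holosystolic".
#' @param regurgVolumeMl regurgitant volume per beat, ml.
#' @param peakShape window exponent of the regurgitant profile (default 1).
#' @param noiseVelocityCmS pixel velocity noise sd, cm/s (default 1).
#' @param baselineOffsetCmS amplitude of the linear offset field (0.5).
#' @param gridShape,pixelSpacingMm phase-contrast grid geometry.
#' @param aortaRadiusMm vessel radius (default 12).
#' @param lvLongAxisMm full LV long-axis length (default 96).
#' @param cinePixelSpacingMm cine pixel spacing, mm.
#' @param sliceThicknessMm,sliceGapMm short-axis stack geometry (8, 0).
#' @param basalTruncation basal-slice fraction (default 1).
#' @param jetFrames systolic frames for jet inspection (`NA` = cine frames).
#' @param phantomMode "static" or "per_phase".
#' @param venc velocity-encoding limit, cm/s (250).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nPhasesCine = 20L, nPhasesPc = 30L,
                      cycleMs = 800, systoleMs = 400,
                      edvMl = 176, svMl = 105,
                      regurgPattern = "holosystolic", regurgVolumeMl = 28,
                      peakShape = 1, noiseVelocityCmS = 1,
                      baselineOffsetCmS = 0.5, gridShape = c(48L, 48L),
                      pixelSpacingMm = c(1.4, 1.4), aortaRadiusMm = 12,
                      lvLongAxisMm = 96, cinePixelSpacingMm = c(1.8, 1.8),
                      sliceThicknessMm = 8, sliceGapMm = 0,
                      basalTruncation = 1, jetFrames = NA_integer_,
                      phantomMode = "static", venc = 250) {
  new("SimConfig", seed = as.integer(seed),
      nPhasesCine = as.integer(nPhasesCine), nPhasesPc = as.integer(nPhasesPc),
      cycleMs = cycleMs, systoleMs = systoleMs, edvMl = edvMl, svMl = svMl,
      regurgPattern = regurgPattern, regurgVolumeMl = regurgVolumeMl,
      peakShape = peakShape, noiseVelocityCmS = noiseVelocityCmS,
      baselineOffsetCmS = baselineOffsetCmS,
      gridShape = as.integer(gridShape), pixelSpacingMm = pixelSpacingMm,
      aortaRadiusMm = aortaRadiusMm, lvLongAxisMm = lvLongAxisMm,
      cinePixelSpacingMm = cinePixelSpacingMm,
      sliceThicknessMm = sliceThicknessMm, sliceGapMm = sliceGapMm,
      basalTruncation = basalTruncation, jetFrames = as.integer(jetFrames),
      phantomMode = phantomMode, venc = venc)
}

## raised-cosine window with peak at fraction `m` of the support, exponent s
cosWindow <- function(u, m = 0.5, s = 1) {
  w <- numeric(length(u))
  inl <- u >= 0 & u <= m
  inr <- u > m & u <= 1
  w[inl] <- (0.5 * (1 - cos(pi * u[inl] / m)))^s
  w[inr] <- (0.5 * (1 - cos(pi * (1 - u[inr]) / (1 - m))))^s
  w
}

## pattern -> support (fractions of systole) and peak position within it;
## early/late peaks are skewed into the intended third
patternWindow <- function(pattern) {
  switch(pattern,
    none         = NULL,
    holosystolic = list(lo = 0, hi = 1, m = 0.5),
    early        = list(lo = 0, hi = 2 / 3, m = 0.35),
    late         = list(lo = 1 / 3, hi = 1, m = 0.65),
    stopConfig("unknown regurgitant pattern '%s'", pattern))
}

## unscaled regurgitant window evaluated at times t (ms) within a systole
## [tEd, tEs]
regurgWindowAt <- function(t, tEd, tEs, pattern, shape) {
  pw <- patternWindow(pattern)
  if (is.null(pw)) return(numeric(length(t)))
  S <- tEs - tEd
  u <- ((t - tEd) / S - pw$lo) / (pw$hi - pw$lo)
  w <- numeric(length(t))
  ok <- u >= 0 & u <= 1
  w[ok] <- cosWindow(u[ok], m = pw$m, s = shape)
  w
}

## trapezoid of values v on grid t (ms), result in units x s
trapzMs <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)]) / 2) / 1000

cumtrapzMs <- function(t, v) {
  c(0, cumsum(diff(t) * (v[-1] + v[-length(v)]) / 2)) / 1000
}

#' Ground-truth regurgitant-rate profile
#'
#' A non-negative raised-cosine-window rate profile supported on full
#' systole (holosystolic), the first two-thirds (early), the last
#' two-thirds (late), or identically zero (none), scaled so its
#' trapezoidal integral over systole equals `regurgVolumeMl`.  For early
#' and late patterns the window is skewed so the peak falls inside the
#' early (respectively late) third.
#'
#' @param pattern "none", "early", "late" or "holosystolic".
#' @param regurgVolumeMl target regurgitant volume, ml.
#' @param timing a [SystoleTiming-class].
#' @param shape window exponent (default 1).
#' @param nPoints samples over systole (default 513).
#' @return A [SampledCurve-class] in ml/s over `[tEd, tEs]`.
#' @export
makeRegurgProfile <- function(pattern, regurgVolumeMl, timing, shape = 1,
                              nPoints = 513L) {
  if (pattern == "none" && regurgVolumeMl > 0)
    stopConfig("regurgVolumeMl > 0 is inconsistent with pattern 'none'")
  t <- seq(timing@tEd, timing@tEs, length.out = nPoints)
  w <- regurgWindowAt(t, timing@tEd, timing@tEs, pattern, shape)
  if (regurgVolumeMl > 0) {
    area <- trapzMs(t, w)
    w <- w * (regurgVolumeMl / area)
  } else w[] <- 0
  sampledCurve(t, w, "ml/s")
}

## calibrated short-axis disk radii (mm) for a target cavity volume
ellipsoidRadii <- function(targetMl, longAxisMm, heightMm) {
  cMm <- longAxisMm / 2
  nSlices <- max(3L, floor(longAxisMm / heightMm))
  z <- -cMm + (seq_len(nSlices) - 0.5) * heightMm
  shape <- sqrt(pmax(0, 1 - (z / cMm)^2))  # relative radius per slice
  list(nSlices = nSlices, shape = shape)
}

## a closed ellipse contour in (row, col) pixel coordinates
ellipseContour <- function(centerPx, radiusMm, spacingMm, nVertices = 64L) {
  th <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  roiPolygon(cbind(centerPx[1] + (radiusMm / spacingMm[1]) * sin(th),
                   centerPx[2] + (radiusMm / spacingMm[2]) * cos(th)))
}

#' Simulate one complete case
#'
#' Builds, deterministically for a fixed seed, everything the analysis
#' pipeline consumes: the phase-contrast velocity series for the proximal
#' aorta (parabolic vessel profile + spatially linear baseline offset +
#' Gaussian noise), the stationary-phantom series (offset field + noise),
#' the aortic ROI, the cine endocardial contour stack (ellipsoidal LV
#' rasterised per phase), the jet-presence record (jet "visible" wherever
#' the ground-truth regurgitant rate exceeds 5% of its peak), and the
#' [GroundTruth-class].
#'
#' The hemodynamics are conservative by construction: the ejection rate
#' equals aortic plus regurgitant rate at every systolic time point, the LV
#' volume curve is end-diastolic volume minus the cumulative integral of
#' the ejection rate, and diastolic aortic flow is zero (competent aortic
#' valve).
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `frames` (list of [VelocityFrame-class]),
#'   `phantom` ([PhantomSeries-class]), `roi` ([RoiPolygon-class]),
#'   `stack` ([ContourStack-class]), `presence` ([JetPresence-class] or
#'   `NULL` for the control case), `truth` ([GroundTruth-class]), and
#'   `config`.
#' @export
simulateCase <- function(config) {
  validObject(config)
  set.seed(config@seed)
  S <- config@systoleMs; C <- config@cycleMs
  timing <- systoleTiming(0, S)

  ## --- ground-truth rate profiles on a fine grid -------------------------
  tF <- seq(0, C, by = 0.5)
  rg <- regurgWindowAt(tF, 0, S, config@regurgPattern, config@peakShape)
  if (config@regurgVolumeMl > 0)
    rg <- rg * (config@regurgVolumeMl / trapzMs(tF, rg))
  forwardMl <- config@svMl - config@regurgVolumeMl
  ao <- regurgWindowAt(tF, 0, S, "holosystolic", 1)
  ao <- ao * (forwardMl / trapzMs(tF, ao))
  refill <- numeric(length(tF))
  inD <- tF >= S
  uD <- (tF[inD] - S) / (C - S)
  refill[inD] <- cosWindow(uD, 0.5, 1)
  refill <- refill * (config@svMl / trapzMs(tF, refill))
  eject <- ao + rg - refill
  vol <- config@edvMl - cumtrapzMs(tF, eject)

  inSys <- tF <= S
  truth <- new("GroundTruth",
    regurgRateProfile = sampledCurve(tF[inSys], rg[inSys], "ml/s"),
    aorticFlowProfile = sampledCurve(tF, ao, "ml/s"),
    volumeProfile = sampledCurve(tF, vol, "ml"),
    regurgVolumeMl = config@regurgVolumeMl, forwardVolumeMl = forwardMl,
    severity = classifySeverity(config@regurgVolumeMl),
    jetPattern = config@regurgPattern, tEd = 0, tEs = S)

  ## --- phase-contrast velocity series ------------------------------------
  nr <- config@gridShape[1]; nc <- config@gridShape[2]
  sp <- config@pixelSpacingMm
  r0 <- (nr - 1) / 2; c0 <- (nc - 1) / 2
  rr <- matrix(0:(nr - 1), nr, nc)
  cc <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  dMm <- sqrt(((rr - r0) * sp[1])^2 + ((cc - c0) * sp[2])^2)
  parab <- pmax(0, 1 - (dMm / config@aortaRadiusMm)^2)
  fluxUnit <- sum(parab) * prod(sp) / 100   # ml/s at unit peak velocity
  if (fluxUnit <= 0)
    stopConfig("aorta (radius %g mm) covers no pixel on the %d x %d grid",
               config@aortaRadiusMm, nr, nc)
  ## spatially linear offset field, 0 .. baselineOffsetCmS across the grid
  ## diagonal (non-zero mean over a central ROI, as eddy-current offsets are)
  offset <- config@baselineOffsetCmS * 0.5 * (rr / (nr - 1) + cc / (nc - 1))
  roiR <- config@aortaRadiusMm + 2.5
  if ((roiR / min(sp)) > min(r0, c0, nr - 1 - r0, nc - 1 - c0))
    stopConfig("vessel ROI (radius %g mm) extends off the grid", roiR)
  roi <- ellipseContour(c(r0, c0), roiR, sp, nVertices = 24L)

  tPc <- (0:(config@nPhasesPc - 1)) * C / config@nPhasesPc
  aoAt <- stats::approx(tF, ao, xout = tPc, ties = "ordered")$y
  frames <- vector("list", config@nPhasesPc)
  for (i in seq_along(tPc)) {
    v <- parab * (aoAt[i] / fluxUnit) + offset
    if (config@noiseVelocityCmS > 0)
      v <- v + matrix(stats::rnorm(nr * nc, 0, config@noiseVelocityCmS), nr, nc)
    frames[[i]] <- velocityFrame(v, sp, tPc[i], venc = config@venc)
  }

  nPhantom <- if (config@phantomMode == "static") 1L else config@nPhasesPc
  phantomFrames <- lapply(seq_len(nPhantom), function(i) {
    v <- offset
    if (config@noiseVelocityCmS > 0)
      v <- v + matrix(stats::rnorm(nr * nc, 0, config@noiseVelocityCmS), nr, nc)
    velocityFrame(v, sp, tPc[i], venc = config@venc)
  })
  phantom <- phantomSeries(phantomFrames)

  ## --- cine contour stack -------------------------------------------------
  tCine <- (0:(config@nPhasesCine - 1)) * C / config@nPhasesCine
  volAt <- stats::approx(tF, vol, xout = tCine, ties = "ordered")$y
  heightMm <- config@sliceThicknessMm + config@sliceGapMm
  geo <- ellipsoidRadii(config@edvMl, config@lvLongAxisMm, heightMm)
  csp <- config@cinePixelSpacingMm
  unitArea <- polygonArea(ellipseContour(c(0, 0), 1, csp), csp)  # cm^2 at r = 1 mm
  w <- rep(1, geo$nSlices); w[1] <- config@basalTruncation
  contours <- lapply(seq_along(tCine), function(p) {
    ## calibrate radii so the Simpson disk sum equals the target volume
    volUnit <- heightMm / 10 * unitArea * sum(w * geo$shape^2)
    s <- sqrt(volAt[p] / volUnit)
    lapply(seq_len(geo$nSlices), function(i) {
      rMm <- s * geo$shape[i]
      if (rMm <= 0) return(NULL)
      ellipseContour(c(64, 64), rMm, csp)
    })
  })
  stack <- contourStack(contours, pixelSpacing = csp,
                        sliceThickness = config@sliceThicknessMm,
                        sliceGap = config@sliceGapMm,
                        triggerTimes = tCine,
                        basalTruncation = config@basalTruncation)

  ## --- jet presence -------------------------------------------------------
  presence <- NULL
  if (config@regurgPattern != "none") {
    tJet <- if (is.na(config@jetFrames)) tCine[tCine < S]
            else (0:(config@jetFrames - 1)) * S / config@jetFrames
    rgAt <- stats::approx(tF, rg, xout = tJet, ties = "ordered")$y
    presence <- jetPresence(rgAt > 0.05 * max(rg), tJet)
  }

  list(frames = frames, phantom = phantom, roi = roi, stack = stack,
       presence = presence, truth = truth, config = config)
}
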