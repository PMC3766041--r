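## Core curve operations: interpolation, trapezoidal integration, numerical
## differentiation, systole detection.  Times are ms throughout; integrals
## are returned in curve-units x seconds (so ml/s integrates to ml).

## linear interpolation of a curve at arbitrary times; no extrapolation
interpAt <- function(curve, at) {
  sp <- curveSpan(curve)
  tol <- 1e-9 * max(1, abs(sp[2]))
  if (any(at < sp[1] - tol) || any(at > sp[2] + tol))
    stopRange("requested time(s) outside curve span [%g, %g] ms", sp[1], sp[2])
  at <- pmin(pmax(at, sp[1]), sp[2])
  stats::approx(curve@times, curve@values, xout = at, method = "linear",
                ties = "ordered")$y
}

#' Trapezoidal integration of a sampled curve
#'
#' Point-by-point trapezoidal (Newton-Cotes) integration over `[t0, t1]`.
#' Endpoints that are not sample points are obtained by linear
#' interpolation; the rule is therefore additive over adjacent intervals
#' and linear in the curve's values.  A curve in ml/s integrates to ml.
#'
#' @param curve a [SampledCurve-class].
#' @param t0,t1 integration bounds in ms; default the full curve span.
#' @return numeric(1), integral in curve-units x seconds.
#' @examples
#' flow <- sampledCurve(c(0, 400), c(150, 150), "ml/s")
#' trapezoidIntegral(flow)  # 60 ml
#' @export
trapezoidIntegral <- function(curve, t0 = NULL, t1 = NULL) {
  sp <- curveSpan(curve)
  if (is.null(t0)) t0 <- sp[1]
  if (is.null(t1)) t1 <- sp[2]
  if (t0 >= t1) stopArgument("degenerate interval: t0 (%g) must be < t1 (%g)", t0, t1)
  tol <- 1e-9 * max(1, abs(sp[2]))
  if (t0 < sp[1] - tol || t1 > sp[2] + tol)
    stopRange("interval [%g, %g] outside curve span [%g, %g]", t0, t1, sp[1], sp[2])
  t0 <- max(t0, sp[1]); t1 <- min(t1, sp[2])
  inner <- curve@times > t0 & curve@times < t1
  tt <- c(t0, curve@times[inner], t1)
  vv <- c(interpAt(curve, t0), curve@values[inner], interpAt(curve, t1))
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / 1000
}

#' Numerical derivative of a sampled curve
#'
#' Rate of change per second on the same time grid: central differences at
#' interior points, one-sided differences at the endpoints.  Exact for
#' linear data everywhere and for quadratics at interior points.  An
#' optional odd-width moving average can be applied to the values before
#' differencing (default: none).
#'
#' @param curve a [SampledCurve-class] with >= 3 samples.
#' @param smoothWindow `NULL` (no smoothing) or an odd integer >= 3, the
#'   moving-average width in samples.
#' @param units unit label for the result.
#' @return A [SampledCurve-class] of rates (curve-units per second).
#' @export
differentiateCurve <- function(curve, smoothWindow = NULL, units = "") {
  t <- curve@times; v <- curve@values
  n <- length(t)
  if (n < 3L) stopArgument("differentiation needs at least 3 samples, got %d", n)
  if (!is.null(smoothWindow)) {
    w <- as.integer(smoothWindow)
    if (w < 3L || w %% 2L == 0L)
      stopArgument("smoothWindow must be an odd integer >= 3, got %s", smoothWindow)
    half <- w %/% 2L
    v <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mean(curve@values[lo:hi])
    }, numeric(1))
  }
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  sampledCurve(t, d * 1000, units)  # per-ms -> per-s
}

#' Resample a curve onto a new time grid
#'
#' Linear interpolation at each grid time; no extrapolation.  Resampling a
#' curve onto its own grid is the identity.
#'
#' @param curve a [SampledCurve-class].
#' @param grid numeric, strictly increasing times (ms) within the curve span.
#' @return A [SampledCurve-class] on `grid`.
#' @export
resampleLinear <- function(curve, grid) {
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stopArgument("grid must be strictly increasing with >= 2 points")
  sampledCurve(grid, interpAt(curve, grid), curve@units)
}

#' Locate systole on a left ventricular volume curve
#'
#' For an R-wave-gated volume curve spanning one cardiac cycle,
#' end-diastole is the time of maximum volume among samples in the first
#' third of the cycle (the first sample for a well-gated acquisition) and
#' end-systole is the time of the global minimum.  A non-unique minimum
#' resolves to the earliest occurrence with a classed warning
#' (`mrflow_timing_warning`).
#'
#' @param volumeCurve a [SampledCurve-class] of LV volumes (ml) over one cycle.
#' @return A [SystoleTiming-class].
#' @export
detectSystole <- function(volumeCurve) {
  t <- volumeCurve@times; v <- volumeCurve@values
  firstThird <- t <= t[1] + (t[length(t)] - t[1]) / 3
  iEd <- which(firstThird)[which.max(v[firstThird])]
  vmin <- min(v)
  iEsAll <- which(v == vmin)
  if (length(iEsAll) > 1L)
    mrfWarn("timing_warning",
            "global volume minimum is not unique (%d samples); using the earliest",
            length(iEsAll))
  iEs <- iEsAll[1]
  if (t[iEs] <= t[iEd])
    stopRange("end-systole (%g ms) does not follow end-diastole (%g ms)",
              t[iEs], t[iEd])
  systoleTiming(t[iEd], t[iEs])
}

## third index (1, 2, 3) of a time within systole using the half-open
## convention [tEd, b1), [b1, b2), [b2, tEs]
thirdOfTime <- function(timing, at) {
  b <- thirdBoundaries(timing)
  findInterval(at, b[2:3]) + 1L
}

## third index of a frame by its interval midpoint, ties to the earlier
## third (frames tile systole; the last frame reuses the preceding width)
thirdOfFrameMidpoint <- function(timing, frameTimes) {
  n <- length(frameTimes)
  widths <- if (n > 1L) c(diff(frameTimes), frameTimes[n] - frameTimes[n - 1L])
            else systolicDuration(timing)
  mids <- frameTimes + widths / 2
  b <- thirdBoundaries(timing)
  idx <- findInterval(mids, b[2:3]) + 1L
  tol <- 1e-9 * max(1, abs(b[4]))
  idx[abs(mids - b[2]) <= tol] <- 1L   # tie on a boundary -> earlier third
  idx[abs(mids - b[3]) <= tol] <- 2L
  idx
}
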