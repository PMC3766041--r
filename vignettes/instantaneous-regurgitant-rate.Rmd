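---
title: "Quantifying the systolic temporal variation of mitral regurgitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the systolic temporal variation of mitral regurgitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The measurement problem

Mitral regurgitation (MR) is a leak from the left ventricle (LV) back into
the left atrium during systole.  Its severity is conventionally graded by
the regurgitant volume per beat, but the *rate* of leakage is far from
constant across systole: some jets are confined to early systole, some to
late systole, and even holosystolic jets wax and wane.  Point-in-time
measures (PISA radius, vena contracta width on a single frame) can
therefore over- or underestimate the beat-averaged severity.

Cardiovascular MR (CMR) supplies the two time-resolved signals needed to
resolve the leak in time:

* the **LV volume curve** $V(t)$, from Simpson summation of short-axis
  endocardial contours at every cine phase, and
* the **aortic flow curve** $Q_{ao}(t)$, from through-plane phase-contrast
  velocity maps of the proximal aorta.

During systole, blood leaving the ventricle either enters the aorta or
leaks through the mitral valve.  The instantaneous regurgitant rate is
therefore the pointwise difference

$$ R(t) \;=\; -\frac{dV}{dt}(t) \;-\; Q_{ao}(t), $$

i.e. the rate of blood exiting the LV minus the rate of its appearance in
the aorta.  Integrals use the point-by-point trapezoidal (Newton–Cotes)
rule throughout, so a rate curve in ml/s integrates to a volume in ml.

Systole is divided into three equal thirds — early, mid, late — and the
profile is summarised by the zero-clamped peak rate per third, the overall
peak, the systolic mean rate, and the **peak-to-average regurgitant rate
ratio** (1 for a constant leak, larger the more temporally concentrated the
leak).  The regurgitant volume is taken from the stroke-volume difference

$$ RVol = LVSV - V_{forward}, $$

graded mild (< 30 ml), moderate (30–59 ml) or severe (≥ 60 ml), and the
jet's temporal pattern (early / holosystolic / late) is classified from
frame-by-frame jet visibility using a ≥ 50 % per-third rule.

## The processing chain and its parameters

`quantifyCase()` composes the stages; each is exported on its own.

**Aortic flow.**  `roiFlow()` sums velocity × pixel area over pixels whose
*centres* fall inside the user-traced aortic polygon (boundary-inclusive
ray casting — a deterministic rule that an exhaustive per-pixel oracle can
check exactly).  Scanner-induced baseline phase offsets are removed by
subtracting a stationary-phantom acquisition pixel by pixel
(`correctBaseline()`); a single static phantom frame is broadcast to all
phases, or per-phase phantoms are matched by index (default static).
Velocities at or beyond the encoding limit (Venc, default 250 cm/s) are
flagged as possible aliasing, never unwrapped: the subtraction method is
known to degrade at high velocities, and we surface that rather than
silently repair it.  Repeated flow acquisitions are averaged pointwise on
the first acquisition's grid (`averageFlowCurves()`).

**LV volumetry.**  Contours are taken as given (segmentation lives
upstream); `lvVolume()` sums shoelace area × disk height
(thickness + gap, defaults 8 mm + 0 mm) over slices.  An optional basal
truncation fraction (default 1) scales the basal slice's contribution,
standing in for long-axis-based basal-plane placement without long-axis
image analysis.  Slices missing a contour at some phase contribute zero
with a warning; we do not interpolate them.

**Timing.**  End-diastole is the volume maximum among samples in the first
third of the cycle (the first sample for well-gated series); end-systole
is the global volume minimum (earliest, with a warning, if tied).  The
thirds are defined in *time* — equal durations, boundaries at exactly
1/3 and 2/3 of systole — not in frame counts, which is exact under unequal
sampling.  When frames must be assigned to thirds (jet classification), a
frame belongs to the third containing its interval midpoint, ties going to
the earlier third.

**The subtraction.**  Cine (default 20 phases/cycle) and phase-contrast
(default 30) series live on different grids, so both curves are resampled
onto a common uniform systolic grid (64 points, configurable) before the
pointwise difference.  The ejection rate is the derivative of the
*systolic segment* of the volume curve: central differences at interior
samples, one-sided at the segment ends.  Two reasons: a central difference
at end-systole would straddle the ejection-to-filling corner of the volume
curve and leak diastolic refill into the last rate sample; and with
one-sided ends the trapezoidal integral of the slope telescopes exactly to
the stroke volume, so the conservation identity
$\int_{systole} R(t)\,dt = LVSV - V_{forward,sys}$ holds to numerical
precision on noise-free data.  Whether to pre-smooth the volume slope is
exposed (`smoothWindow`, odd moving-average width) and **off by default**;
the clinical software computes "the slope" without stating an estimator,
and we prefer the unsmoothed estimate with the smoothing choice visible.

**Signs and clamps.**  The signed difference curve is preserved in the
result (negative excursions are a useful QC signal for cine/PC timing
mismatch), but the per-third peaks and the systolic mean clamp at zero —
a negative regurgitant rate is not physiologically meaningful for MR
metrics.  `RVol` comes from the stroke-volume difference, the primary
definition; the signed rate-curve integral is reported alongside
(`volumeFromCurve`) so the two routes can be compared per case.  A
negative `LVSV − forward` difference clamps to 0 ml with a warning.  The
peak-to-average ratio is reported missing (never infinite) when the mean
rate is zero.  Forward volume defaults to the net integral over the full
cycle; a systole-only window is available
(`forwardWindow = "systole"`), since with a competent aortic valve the two
coincide.

**Jet patterns.**  Presence triplets map (T,T,T) → holosystolic,
(T,T,F) → early, (F,T,T) → late.  Single-third presence (T,F,F)/(F,F,T)
is not covered by the clinical taxonomy; we extend it to early/late with
an explicit `extension` flag rather than failing.  Non-contiguous
combinations — (T,F,T), (F,T,F) — and absent jets are `indeterminate`
with a warning.

## What the simulator emulates

`simulateCase()` generates every input the pipeline consumes from a
configured hemodynamic state, conservative by construction: the ejection
rate equals aortic plus regurgitant rate at every systolic instant, the
volume curve is EDV minus the cumulative outflow integral, diastolic
aortic flow is zero (competent aortic valve, matching the exclusion of
aortic regurgitation from the intended population), and diastole refills
the stroke volume.

* **Rate profiles** are raised-cosine windows scaled so their trapezoidal
  integral equals the configured volume exactly: full-systole support for
  holosystolic jets, the first two-thirds for early, the last two-thirds
  for late.  For early/late patterns the window is skewed (peak at 35 % /
  65 % of the support): a symmetric window on a two-thirds support would
  peak exactly on a third boundary, making "the peak occurs in the early
  third" ill-defined.
* **Velocity maps** render the aortic flow as a parabolic (Poiseuille)
  profile in a circular vessel (radius 12 mm) plus a spatially linear
  baseline offset (0–0.5 cm/s across the grid) plus white Gaussian pixel
  noise (sd 1 cm/s); the phantom series encodes the offset field plus its
  own noise.  Pixel velocities are rescaled so the discrete pixel-centre
  flux equals the configured flow; likewise contour radii are calibrated
  so the Simpson disk sum equals the configured cavity volume.  Noise-free
  recovery error therefore measures the *pipeline*, not the renderer's
  discretisation.
* **Contours** rasterise an ellipsoidal ventricle (long axis 96 mm,
  64-vertex rings, 12 slices of 8 mm) whose per-phase cross-sections track
  the volume profile.
* **Jet presence** flags a frame visible when the ground-truth regurgitant
  rate at its trigger time exceeds 5 % of its peak — a simulator
  convention standing in for visual inspection, and configurable.

Defaults mirror a routine clinical acquisition and the cohort-mean
ventricle: 800 ms cycle, 400 ms systole, 20 cine and 30 phase-contrast
phases, EDV 176 ml, stroke volume 105 ml, Venc 250 cm/s.

What the simulator does **not** emulate: k-space/coil image formation and
artefacts, phase wraps, eddy-current fields beyond spatially linear,
papillary-muscle anatomy, ROI tracking across phases (one ROI serves all
phases; auto-tracking is deliberately out of scope), beat-to-beat
variability, or segmentation error in the contours.  Passing recovery
tests therefore demonstrates the correctness and conditioning of the
computation chain, not robustness to real-world image degradation.

## Numerical choices and degenerate inputs

* No extrapolation anywhere: integration bounds and resampling grids must
  lie within a curve's span, and a curve not covering systole is a range
  error.  Silent extrapolation would corrupt the conservation checks.
* Trapezoid endpoints interior to a sampling interval are obtained by
  linear interpolation, keeping the rule additive over adjacent intervals.
* The per-third sample assignment uses half-open intervals
  [t~ED~, b₁), [b₁, b₂), [b₂, t~ES~]; third boundaries are exact thirds.
  The published worked example rounds a third of 0.4 s to 0.13 s; the
  package always uses the exact third, and reproduces the printed 28 ml
  figure by passing the printed 0.13 s durations to `volumeFromRates()`
  explicitly.
* Temporal resolution bounds the fidelity of the recovered *curve shape*:
  a central difference over 40 ms cine spacing averages the true ejection
  rate over an 80 ms window, so at 20 phases/cycle the recovered rate
  curve is a smoothed version of the truth (tens of ml/s RMSE against the
  instantaneous profile) even though its integral — the regurgitant
  volume — is recovered to well under 1 ml.  The test suite checks both:
  pointwise convergence at refined sampling (100 phases), and exact
  volume/severity/pattern recovery at routine sampling.
* Problem sizes in the tests and the acceptance study (50 noise-free
  conservation cases, 52 noisy recovery cases, 9 pattern cases, 200
  ROI-oracle draws, 100 paired trend draws on a 48 × 48 grid) were chosen
  to exercise every pattern and severity band while keeping a full run in
  the order of a minute.

## Known limitations

* One ROI per series: vessel motion across phases is not tracked.
* The regurgitant volume definition charges *all* non-aortic outflow to
  the mitral valve; aortic regurgitation or shunts violate it (they are
  exclusion criteria for the method).
* `detectSystole()` assumes an R-wave-gated single cycle; arrhythmic or
  multi-beat curves are out of scope.
* Severity grading uses the volumetric AHA/ACC cut-offs only; no
  regurgitant-fraction or orifice-area grading.
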