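# mrflow

Quantifies the **instantaneous mitral regurgitant rate** — and its
variation across systole — from cardiovascular magnetic resonance (CMR)
derived data.

## The problem and who this is for

Mitral regurgitation (MR) leaks blood from the left ventricle (LV) back
into the left atrium during systole.  Severity is graded by the
regurgitant volume per beat, but the leak *rate* varies through systole:
jets can be confined to early or late systole, and point-in-time measures
(PISA, vena contracta on one frame) can badly over- or underestimate the
beat-averaged severity.  `mrflow` is for imaging scientists and
cardiology researchers working with CMR flow and volumetry who want the
time-resolved leak profile, not just the per-beat total.

CMR provides two time-resolved signals: the LV volume curve `V(t)` from
Simpson summation of short-axis endocardial contours, and the aortic flow
curve `Q_ao(t)` from through-plane phase-contrast velocity mapping of the
proximal aorta (with stationary-phantom baseline correction).  By mass
conservation the instantaneous regurgitant rate is the pointwise
difference between the rate of blood exiting the ventricle and the rate
of its appearance in the aorta:

    R(t) = -dV/dt(t) - Q_ao(t)        [ml/s]

Systole is split into three equal thirds (early / mid / late) and the
profile is summarised by per-third peak rates, the systolic mean, and the
**peak-to-average regurgitant rate ratio** (1 for a constant leak, larger
for a temporally concentrated one).  The regurgitant volume
`RVol = LVSV − forward flow` grades severity (mild < 30 ml,
moderate 30–59 ml, severe ≥ 60 ml), and frame-by-frame jet visibility
classifies the pattern (early / holosystolic / late, jet "present" in a
third if visible on ≥ 50 % of its frames).

Integration is point-by-point trapezoidal; derivatives are central
differences (one-sided at segment ends); everything runs on
delimited-text/JSON inputs, and a forward simulator generates complete
synthetic cases with known ground truth so the whole chain is testable
without scans.

## A worked example

Simulate a mild early-pattern case (RVol 28 ml, stroke volume 105 ml,
default acquisition geometry and noise) and quantify it:

```r
library(mrflow)

cfg <- simConfig(seed = 8, regurgPattern = "early", regurgVolumeMl = 28)
sim <- simulateCase(cfg)
res <- quantifyCase(frames = sim$frames, roi = sim$roi, stack = sim$stack,
                    phantom = sim$phantom, presence = sim$presence)
res$timing
#> SystoleTiming: systole [0, 400] ms; thirds at 133.333, 266.667 ms
res$profile
#> RegurgProfile
#>   peak rates by third (ml/s): 185.7 / 154 / 18.29
#>   peak 185.7 ml/s, mean 70.03 ml/s, peak-to-average 2.652
#>   regurgitant volume 27.93 ml (curve integral 27.96 ml) -> mild
#>   jet pattern: early
```

Reading the output: the jet is concentrated in the first two thirds of
systole (per-third peaks 185.7 / 154 / 18.3 ml/s), the configured 28 ml
regurgitant volume is recovered as 27.9 ml (graded mild), the
stroke-volume route and the rate-curve integral agree to 0.03 ml (a
per-case QC check), and the high peak-to-average ratio (2.65) flags the
strong temporal concentration.  A naïve constant-rate extrapolation of
the early-systolic peak would have called this jet severe:

```r
volumeFromRates(c(178, 39, 0), 0.13)   # per-third rates x 0.13 s thirds
#> 28.21                                # -> 28 ml, mild
178 * 0.4                              # peak rate assumed all systole
#> 71.2                                 # -> would misgrade as severe
```

File-based workflows use `writeFixtureSet()` / `runQuantify()` (JSON case
descriptors binding velocity-map series, ROI, contour stack and presence
files), or the thin CLI in `inst/cli/mrflow`
(`mrflow simulate | quantify | report`).

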