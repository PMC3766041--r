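# Instantaneous regurgitant rate, per-third metrics, severity and jet pattern.

stepRateCurve <- function(rates, timing = systoleTiming(0, 400)) {
  b <- thirdBoundaries(timing)
  eps <- 1e-3
  sampledCurve(c(b[1], b[2] - eps, b[2] + eps, b[3] - eps, b[3] + eps, b[4]),
               rep(rates, each = 2), "ml/s")
}

test_that("equal ejection and aortic curves give the zero control curve", {
  t <- seq(0, 400, by = 20)
  flow <- 400 * sin(pi * t / 400)
  tm <- systoleTiming(0, 400)
  rc <- regurgitantRateCurve(sampledCurve(t, flow), sampledCurve(t, flow), tm)
  expect_true(all(abs(curveValues(rc)) < 1e-12))
  expect_length(curveValues(rc), 64)
})

test_that("constant excess ejection appears as a constant regurgitant rate", {
  t <- seq(0, 400, by = 25)
  tm <- systoleTiming(0, 400)
  rc <- regurgitantRateCurve(sampledCurve(t, rep(400, 17)),
                             sampledCurve(t, rep(250, 17)), tm)
  expect_equal(curveValues(rc), rep(150, 64))

  short <- sampledCurve(c(0, 300), c(1, 1))
  expect_error(regurgitantRateCurve(short, sampledCurve(t, rep(0, 17)), tm),
               class = "mrflow_range_error")
})

test_that("recovered rate curve converges to the configured profile with sampling", {
  # at refined temporal sampling the pipeline reproduces the ground-truth
  # profile closely; at routine 20-phase cine the slope estimator smooths the
  # true curve over an 80 ms window and the pointwise error is larger while
  # the integral (regurgitant volume) stays exact
  simFine <- simNoiseFree(10, "early", 28, nPhasesCine = 100L, nPhasesPc = 100L)
  resFine <- runPipeline(simFine)
  tr <- simFine$truth@regurgRateProfile
  g <- curveTimes(rateCurve(resFine$profile))
  rmseFine <- sqrt(mean((curveValues(rateCurve(resFine$profile)) -
                           approx(curveTimes(tr), curveValues(tr), g)$y)^2))
  expect_lt(rmseFine, 5)

  simDef <- simNoiseFree(10, "early", 28)
  resDef <- runPipeline(simDef)
  trD <- simDef$truth@regurgRateProfile
  gD <- curveTimes(rateCurve(resDef$profile))
  rmseDef <- sqrt(mean((curveValues(rateCurve(resDef$profile)) -
                          approx(curveTimes(trD), curveValues(trD), gD)$y)^2))
  expect_lt(rmseDef, 40)
  expect_equal(regurgVolume(resDef$profile), 28, tolerance = 0.1)
})

test_that("per-third metrics split the worked-example step profile", {
  m <- perThirdMetrics(stepRateCurve(c(178, 39, 0)), systoleTiming(0, 400))
  expect_equal(m$peakRatesByThird, c(178, 39, 0))
  expect_equal(m$peakRate, 178)

  z <- perThirdMetrics(sampledCurve(c(0, 200, 400), c(0, 0, 0)),
                       systoleTiming(0, 400))
  expect_equal(z$peakRatesByThird, c(0, 0, 0))
  expect_equal(z$meanRate, 0)
  expect_true(is.na(z$peakToAverageRatio))

  cst <- perThirdMetrics(sampledCurve(seq(0, 400, 50), rep(100, 9)),
                         systoleTiming(0, 400))
  expect_equal(cst$meanRate, 100)
  expect_equal(cst$peakRate, 100)
  expect_equal(cst$peakToAverageRatio, 1)
})

test_that("printed-thirds arithmetic reproduces the mean and ratio", {
  # rates 178/39/0 with thirds of exactly 0.13 s
  vol <- volumeFromRates(c(178, 39, 0), 0.13)
  meanRate <- vol / (3 * 0.13)
  expect_equal(vol, 28.21)
  expect_equal(meanRate, 72.333, tolerance = 1e-4)
  expect_equal(178 / meanRate, 2.4608, tolerance = 1e-4)
})

test_that("negative rate excursions are kept in the curve but not the metrics", {
  tm <- systoleTiming(0, 300)
  rc <- sampledCurve(seq(0, 300, 25), c(-20, -10, 50, 80, 60, 30, 10, -5, -15,
                                        -20, -10, 0, 5), "ml/s")
  m <- perThirdMetrics(rc, tm)
  expect_true(all(m$peakRatesByThird >= 0))
  expect_equal(m$peakRatesByThird[1], 80)
  expect_equal(m$peakRatesByThird[3], 5)
  # the clamped mean is what the ratio uses
  clamped <- sampledCurve(curveTimes(rc), pmax(curveValues(rc), 0))
  expect_equal(m$meanRate, trapezoidIntegral(clamped) / 0.3)
})

test_that("regurgitant volume is the stroke-volume/forward-flow difference", {
  expect_equal(regurgitantVolume(105, 105), 0)
  expect_equal(regurgitantVolume(105, 45), 60)
  expect_warning(v <- regurgitantVolume(100, 104), class = "mrflow_volume_warning")
  expect_equal(v, 0)

  sim <- simulateCase(simConfig(seed = 14, regurgPattern = "holosystolic",
                                regurgVolumeMl = 28))
  res <- runPipeline(sim)
  expect_equal(regurgVolume(res$profile), 28, tolerance = 1.5)
})

test_that("per-third rate reconstruction matches the printed arithmetic", {
  expect_equal(volumeFromRates(c(178, 39, 0), 0.13), 28.21)
  expect_equal(round(volumeFromRates(c(178, 39, 0), 0.13)), 28)
  expect_equal(volumeFromRates(c(150, 150, 150), 0.4 / 3), 60)
  expect_equal(volumeFromRates(c(0, 0, 0), 0.13), 0)
  expect_error(volumeFromRates(c(10, 10, 10), -0.1), class = "mrflow_argument_error")
  expect_error(volumeFromRates(c(10, 10), 0.1), class = "mrflow_argument_error")
})

test_that("severity grading follows the AHA/ACC cut-offs", {
  expect_equal(classifySeverity(28), "mild")
  expect_equal(classifySeverity(0), "mild")
  expect_equal(classifySeverity(29.999), "mild")
  expect_equal(classifySeverity(30), "moderate")
  expect_equal(classifySeverity(59.999), "moderate")
  expect_equal(classifySeverity(60), "severe")
  expect_error(classifySeverity(-1), class = "mrflow_argument_error")

  # monotone step function of volume
  v <- seq(0, 120, by = 0.5)
  lvl <- match(classifySeverity(v), c("mild", "moderate", "severe"))
  expect_true(all(diff(lvl) >= 0))

  # invariant under consistent rate/duration rescaling (ml/s with s vs
  # ml/ms with ms): the reconstructed volume, hence the grade, is unchanged
  rates <- c(178, 39, 0)
  expect_identical(classifySeverity(volumeFromRates(rates, 0.13)),
                   classifySeverity(volumeFromRates(rates / 1000, 130)))
})

test_that("jet patterns follow the >= 50% per-third visibility rule", {
  tm <- systoleTiming(0, 360)
  ft <- seq(0, 320, by = 40)  # 9 frames, 3 per third
  expect_equal(as.character(classifyJetPattern(jetPresence(rep(TRUE, 9), ft), tm)),
               "holosystolic")
  expect_equal(as.character(classifyJetPattern(
    jetPresence(c(rep(TRUE, 6), rep(FALSE, 3)), ft), tm)), "early")
  expect_equal(as.character(classifyJetPattern(
    jetPresence(c(rep(FALSE, 3), rep(TRUE, 6)), ft), tm)), "late")

  # exactly half the frames visible in a third counts as present
  ft6 <- seq(0, 300, by = 60)  # 6 frames: 2/2/2 per third
  half <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(as.character(classifyJetPattern(jetPresence(half, ft6), tm)),
               "holosystolic")

  # single-third presence maps to early/late with the extension flag
  expect_warning(
    lab <- classifyJetPattern(jetPresence(c(rep(TRUE, 3), rep(FALSE, 6)), ft), tm),
    class = "mrflow_pattern_warning")
  expect_equal(as.character(lab), "early")
  expect_true(attr(lab, "extension"))

  # non-contiguous presence is indeterminate
  expect_warning(
    ind <- classifyJetPattern(jetPresence(c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3)), ft), tm),
    class = "mrflow_pattern_warning")
  expect_equal(as.character(ind), "indeterminate")

  # a third without frames is an error
  expect_error(classifyJetPattern(jetPresence(c(TRUE, TRUE, TRUE), c(0, 20, 40)), tm),
               class = "mrflow_argument_error")
})

test_that("pattern classification is invariant to frame-count refinement", {
  # presence defined by a time interval (jet visible 0..240 ms of a 360 ms
  # systole, i.e. the first two thirds)
  tm <- systoleTiming(0, 360)
  for (n in c(9, 18, 30)) {
    ft <- (0:(n - 1)) * 360 / n
    pres <- jetPresence(ft < 240, ft)
    expect_equal(as.character(classifyJetPattern(pres, tm)), "early")
  }
})

test_that("the composed analysis populates a coherent profile", {
  t <- seq(0, 800, by = 25)
  flow <- 400 * pmax(0, sin(pi * t / 400)) * (t <= 400)
  ao <- sampledCurve(t, flow, "ml/s")
  tm <- systoleTiming(0, 400)
  # control: ejection equals aortic flow, stroke volume equals forward volume
  fv <- forwardVolume(ao)
  ctrl <- analyzeCase(ao, ao, tm, fv, fv)
  expect_equal(peakRatesByThird(ctrl), c(0, 0, 0))
  expect_equal(regurgVolume(ctrl), 0)
  expect_equal(severity(ctrl), "mild")
  expect_true(is.na(jetPattern(ctrl)))

  simSev <- simulateCase(simConfig(seed = 15, regurgPattern = "holosystolic",
                                   regurgVolumeMl = 70))
  resSev <- runPipeline(simSev)
  expect_equal(severity(resSev$profile), "severe")
  expect_equal(jetPattern(resSev$profile), "holosystolic")

  simMild <- simulateCase(simConfig(seed = 16, regurgPattern = "early",
                                    regurgVolumeMl = 15))
  resMild <- runPipeline(simMild)
  expect_equal(severity(resMild$profile), "mild")
  expect_gt(peakToAverageRatio(resMild$profile),
            peakToAverageRatio(resSev$profile))
})

test_that("mass conservation holds through the pipeline without noise", {
  for (p in c("early", "late", "holosystolic")) {
    sim <- simNoiseFree(20 + match(p, c("early", "late", "holosystolic")), p, 45)
    res <- runPipeline(sim)
    fwdSys <- forwardVolume(res$aorticFlow, "systole", res$timing)
    expect_lt(abs(res$profile@volumeFromCurve - (res$lvStrokeVolume - fwdSys)),
              0.5)
  }
})
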