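test_that("trapezoidal integration reproduces closed-form areas", {
  const <- sampledCurve(seq(0, 400, by = 20), rep(150, 21), "ml/s")
  expect_equal(trapezoidIntegral(const), 60)
  expect_equal(trapezoidIntegral(const, 100, 300), 30)

  zero <- sampledCurve(c(0, 50, 400), c(0, 0, 0))
  expect_equal(trapezoidIntegral(zero, 10, 390), 0)

  ramp <- sampledCurve(c(0, 1000), c(0, 100), "ml/s")
  expect_equal(trapezoidIntegral(ramp), 50)
})

test_that("trapezoid on coarse nodes equals the composed fine-grid rule", {
  t <- seq(0, 900, length.out = 10)
  curve <- sampledCurve(t, 200 * sin(pi * t / 900), "ml/s")
  # compose the same rule over each sub-interval of a 10,000-point refinement
  # of the piecewise-linear interpolant: identical by construction of the rule
  fine <- seq(0, 900, length.out = 10000)
  fine <- sort(union(fine, t))
  vFine <- approx(t, curveValues(curve), xout = fine)$y
  expect_equal(trapezoidIntegral(curve), oracleTrapz(fine, vFine), tolerance = 1e-12)
  # and the analytic integral is approached within the classical error bound
  analytic <- 200 * (900 / 1000) * 2 / pi
  h <- diff(t)[1] / 1000
  bound <- (900 / 1000) * h^2 / 12 * 200 * (pi / 0.9)^2
  expect_lt(abs(trapezoidIntegral(curve) - analytic), bound)
})

test_that("integration is linear in values and additive over intervals", {
  set.seed(42)
  for (i in 1:20) {
    t <- sort(runif(15, 0, 800)); t <- t + seq_along(t) * 1e-6
    a <- sampledCurve(t, rnorm(15)); b <- sampledCurve(t, rnorm(15))
    comb <- sampledCurve(t, 2 * curveValues(a) + 3 * curveValues(b))
    expect_equal(trapezoidIntegral(comb),
                 2 * trapezoidIntegral(a) + 3 * trapezoidIntegral(b),
                 tolerance = 1e-9)
    mid <- runif(1, t[2], t[14])
    expect_equal(trapezoidIntegral(a, t[1], mid) + trapezoidIntegral(a, mid, t[15]),
                 trapezoidIntegral(a), tolerance = 1e-9)
  }
})

test_that("integration rejects degenerate and out-of-span intervals", {
  cv <- sampledCurve(c(0, 100, 200), c(1, 2, 3))
  expect_error(trapezoidIntegral(cv, 150, 150), class = "mrflow_argument_error")
  expect_error(trapezoidIntegral(cv, 150, 100), class = "mrflow_argument_error")
  expect_error(trapezoidIntegral(cv, -10, 100), class = "mrflow_range_error")
  expect_error(trapezoidIntegral(cv, 100, 250), class = "mrflow_range_error")
})

test_that("differentiation is exact for linear and (interior) quadratic data", {
  lin <- sampledCurve(seq(0, 400, by = 50), seq(176, 76, by = -12.5), "ml")
  d <- differentiateCurve(lin)
  expect_equal(curveValues(d), rep(-250, 9))

  flat <- sampledCurve(seq(0, 400, by = 50), rep(100, 9))
  expect_equal(curveValues(differentiateCurve(flat)), rep(0, 9))

  t <- seq(0, 300, by = 30)
  quad <- sampledCurve(t, 0.002 * t^2 - 0.5 * t + 150, "ml")
  dq <- differentiateCurve(quad)
  interior <- 2:(length(t) - 1)
  expect_equal(curveValues(dq)[interior], (0.004 * t[interior] - 0.5) * 1000)

  expect_error(differentiateCurve(sampledCurve(c(0, 1), c(0, 1))),
               class = "mrflow_argument_error")
  expect_error(differentiateCurve(quad, smoothWindow = 4),
               class = "mrflow_argument_error")
})

test_that("derivative then integral recovers volume differences", {
  set.seed(7)
  for (i in 1:10) {
    # arbitrary sampled curve: full-span recovery is exact (the trapezoid
    # of the difference scheme telescopes to the endpoint difference)
    t <- seq(0, 600, by = 60)
    v <- cumsum(c(150, rnorm(10, 0, 20)))
    cv <- sampledCurve(t, v, "ml")
    d <- differentiateCurve(cv)
    expect_equal(trapezoidIntegral(d), v[11] - v[1], tolerance = 1e-9)
    # sub-interval recovery is exact when the segment is differentiated on
    # its own (one-sided at the segment ends), as the pipeline does over
    # systole
    seg <- sampledCurve(t[2:10], v[2:10], "ml")
    expect_equal(trapezoidIntegral(differentiateCurve(seg)), v[10] - v[2],
                 tolerance = 1e-9)
  }
  # for globally linear volume curves any sub-interval is exact directly
  lin <- sampledCurve(seq(0, 600, 60), 176 - 0.25 * seq(0, 600, 60), "ml")
  dl <- differentiateCurve(lin)
  expect_equal(trapezoidIntegral(dl, 60, 540), -0.25 * 480, tolerance = 1e-9)
})

test_that("moving-average pre-smoothing damps derivative noise", {
  set.seed(19)
  t <- seq(0, 800, by = 20)
  v <- 176 - 0.2 * t + rnorm(length(t), 0, 3)
  raw <- differentiateCurve(sampledCurve(t, v))
  sm <- differentiateCurve(sampledCurve(t, v), smoothWindow = 5)
  interior <- 4:(length(t) - 3)
  expect_lt(sd(curveValues(sm)[interior] + 200),
            sd(curveValues(raw)[interior] + 200))
})

test_that("linear resampling interpolates and never extrapolates", {
  cv <- sampledCurve(c(0, 100), c(0, 10))
  expect_equal(curveValues(resampleLinear(cv, c(25, 50, 75))), c(2.5, 5, 7.5))

  t <- seq(0, 500, by = 25)
  pw <- sampledCurve(t, cumsum(rnorm(21)))
  expect_equal(curveValues(resampleLinear(pw, t)), curveValues(pw))

  set.seed(11)
  grid <- sort(runif(30, 1, 499))
  rs <- resampleLinear(pw, grid)
  # brute-force two-neighbour interpolation oracle
  oracle <- vapply(grid, function(g) {
    i <- max(which(t <= g))
    if (t[i] == g) return(curveValues(pw)[i])
    w <- (g - t[i]) / (t[i + 1] - t[i])
    (1 - w) * curveValues(pw)[i] + w * curveValues(pw)[i + 1]
  }, numeric(1))
  expect_equal(curveValues(rs), oracle, tolerance = 1e-12)

  expect_error(resampleLinear(pw, c(-5, 100)), class = "mrflow_range_error")
  expect_error(resampleLinear(pw, c(100, 600)), class = "mrflow_range_error")
})

test_that("systole detection finds the emptying interval", {
  t <- seq(0, 700, by = 50)
  v <- ifelse(t <= 300, 176 - 105 * (t / 300), 71 + 105 * (t - 300) / 400)
  tm <- detectSystole(sampledCurve(t, v, "ml"))
  expect_equal(tm@tEd, 0)
  expect_equal(tm@tEs, 300)

  b <- thirdBoundaries(systoleTiming(0, 400))
  expect_equal(b[2], 400 / 3)
  expect_equal(b[3], 800 / 3)

  # configured end-systole recovered exactly from a noise-free simulated curve
  sim <- simNoiseFree(3, "holosystolic", 28, cycleMs = 800, systoleMs = 350)
  tmSim <- detectSystole(sim$truth@volumeProfile)
  expect_equal(tmSim@tEs, 350)

  # duplicated minimum resolves to the earliest occurrence, with a warning
  vDup <- c(176, 120, 71, 71, 120, 176)
  expect_warning(tmDup <- detectSystole(sampledCurve(seq(0, 500, by = 100), vDup)),
                 class = "mrflow_timing_warning")
  expect_equal(tmDup@tEs, 200)
})

test_that("systolic thirds always tile systole with equal durations", {
  set.seed(5)
  for (i in 1:50) {
    tEd <- runif(1, 0, 100); tEs <- tEd + runif(1, 50, 600)
    b <- thirdBoundaries(systoleTiming(tEd, tEs))
    d <- diff(b)
    expect_equal(d[1], d[2], tolerance = 1e-15)
    expect_equal(d[2], d[3], tolerance = 1e-15)
    expect_identical(b[1], tEd)
    expect_identical(b[4], tEs)
  }
})

test_that("curve invariants are enforced at construction", {
  expect_error(sampledCurve(c(0, 0), c(1, 2)), "increasing")
  expect_error(sampledCurve(c(0), c(1)), "2 samples")
  expect_error(sampledCurve(c(0, 1), c(1, NA)), "finite")
  expect_error(systoleTiming(400, 400), "precede")
})
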