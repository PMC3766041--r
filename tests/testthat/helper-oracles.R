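# Independent oracles used across the suite.  These deliberately re-derive
# results by different algorithms (scalar ray casting in the orthogonal
# direction, fine-grid integration, sub-pixel rasterisation) so that they
# do not share code paths with the package implementation.

# Scalar point-in-polygon by ray casting towards +row (the package
# implementation is vectorised and casts towards +col); boundary counts
# as inside.
oraclePointInPolygon <- function(r, c, verts, eps = 1e-9) {
  n <- nrow(verts)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    r1 <- verts[j, 1]; c1 <- verts[j, 2]
    r2 <- verts[i, 1]; c2 <- verts[i, 2]
    # on-segment check
    cr <- (c2 - c1) * (r - r1) - (r2 - r1) * (c - c1)
    if (abs(cr) <= eps * max(abs(c2 - c1), abs(r2 - r1), 1) &&
        c >= min(c1, c2) - eps && c <= max(c1, c2) + eps &&
        r >= min(r1, r2) - eps && r <= max(r1, r2) + eps)
      return(TRUE)
    # edge crossed by the ray {col = c, row > r}?
    if ((c1 > c) != (c2 > c)) {
      rAt <- (r2 - r1) * (c - c1) / (c2 - c1) + r1
      if (rAt > r) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Exhaustive pixel-centre inclusion mask for an nr x nc grid (0-based centres)
oracleRoiMask <- function(roi, nr, nc) {
  verts <- roiVertices(roi)
  m <- matrix(FALSE, nr, nc)
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1))
    m[r + 1, c + 1] <- oraclePointInPolygon(r, c, verts)
  m
}

# A random simple polygon: a star-shaped ring around a centre point,
# kept inside the (nr x nc) grid
randomSimplePolygon <- function(nr, nc, nVerts = sample(4:10, 1)) {
  ctr <- c(stats::runif(1, nr * 0.3, nr * 0.7), stats::runif(1, nc * 0.3, nc * 0.7))
  maxRad <- min(ctr[1], nr - 1 - ctr[1], ctr[2], nc - 1 - ctr[2])
  th <- sort(stats::runif(nVerts, 0, 2 * pi))
  rad <- stats::runif(nVerts, 0.25, 0.95) * maxRad
  roiPolygon(cbind(ctr[1] + rad * sin(th), ctr[2] + rad * cos(th)))
}

# Sub-pixel rasterisation estimate of a polygon area (cm^2)
oraclePolygonArea <- function(poly, spacingMm, sub = 0.1) {
  verts <- roiVertices(poly)
  rs <- seq(min(verts[, 1]) - 1, max(verts[, 1]) + 1, by = sub)
  cs <- seq(min(verts[, 2]) - 1, max(verts[, 2]) + 1, by = sub)
  cnt <- 0
  for (r in rs) cnt <- cnt + sum(vapply(cs, function(c)
    oraclePointInPolygon(r, c, verts), logical(1)))
  cnt * sub^2 * spacingMm[1] * spacingMm[2] / 100
}

# Trapezoid on an explicit (t, v) grid, ms -> s units
oracleTrapz <- function(t, v) sum(diff(t) * (v[-1] + v[-length(v)]) / 2) / 1000

# A small noise-free default-geometry simulation, memoised per pattern/volume
simNoiseFree <- function(seed, pattern, vol, ...) {
  simulateCase(simConfig(seed = seed, regurgPattern = pattern,
                         regurgVolumeMl = vol, noiseVelocityCmS = 0, ...))
}

runPipeline <- function(sim, ...) {
  suppressWarnings(quantifyCase(frames = sim$frames, roi = sim$roi,
                                stack = sim$stack, phantom = sim$phantom,
                                presence = sim$presence, ...))
}
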