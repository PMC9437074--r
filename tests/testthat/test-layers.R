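test_that("epidermal decades run from 1 at the DEJ to K at the surface", {
  seg <- flatSeg(dejUm = 20)       # surface 0, DEJ 20 um, z-step 1 um
  part <- epidermalSublayers(seg, K = 10L)
  idx <- sublayerIndex(part)
  expect_equal(idx[1, 1, 20], 1L)   # plane 20 = depth 19 um, DEJ-adjacent
  expect_equal(idx[1, 1, 2], 10L)   # depth 1 um, surface-adjacent
  expect_equal(idx[1, 1, 25], 0L)   # dermis voxel not in the partition
  # uniform thickness: each decade holds exactly 1/K of epidermal voxels
  counts <- tabulate(idx[idx > 0L], nbins = 10L)
  expect_true(all(counts == counts[1]))
  expect_equal(sum(counts), sum(seg@labels %in% c(LABEL_SC, LABEL_LED)))
})

test_that("dermal bands follow depth below the DEJ with flagged remainder", {
  seg <- flatSeg(n = 40L, nz = 80L, dejUm = 20)
  part <- dermalSublayers(seg, bandUm = 20, nBands = 2L)
  idx <- sublayerIndex(part)
  expect_equal(idx[1, 1, 46], 2L)       # 25 um below the DEJ -> band 2
  expect_equal(idx[1, 1, 21], 1L)       # first dermal plane -> band 1
  expect_equal(idx[1, 1, 75], 3L)       # beyond 40 um -> remainder band
  # a single 50 um band equals the union of 10 um bands 1-5
  b50 <- sublayerIndex(dermalSublayers(seg, 50, 1L)) == 1L
  b10 <- sublayerIndex(dermalSublayers(seg, 10, 5L))
  expect_identical(b50, b10 >= 1L & b10 <= 5L)
  # flat DEJ: bands are horizontal slabs
  expect_true(all(apply(idx, 3L, function(m) length(unique(as.vector(m)))) == 1L))
})

test_that("thickness maps are additive exactly", {
  seg <- segCal()
  tm <- thicknessMaps(seg)
  expect_equal(tm$sc + tm$led, tm$epidermis)
  expect_equal(morphologyMetrics(seg)$meanEpidermalThicknessUm,
               morphologyMetrics(seg)$meanScThicknessUm +
                 morphologyMetrics(seg)$meanLedThicknessUm)
})

test_that("normalized DEJ area: flat, tilted and sinusoidal closed forms", {
  expect_equal(dejNormalizedArea(matrix(7.3, 41, 41), 0.5), 1.0)
  # plane tilted at angle theta: ratio = 1 / cos(theta)
  for (theta in c(0.2, 0.7, 1.1)) {
    p <- 0.8
    z <- outer(seq_len(60) * p * tan(theta), rep(1, 60))
    expect_equal(dejNormalizedArea(z, p), 1 / cos(theta), tolerance = 1e-6)
  }
  # sinusoid vs quadrature oracle
  A <- 10; P <- 50; p <- 1
  g <- (seq_len(100) - 1) * p
  z <- A * outer(sin(2 * pi * g / P), sin(2 * pi * g / P))
  f <- function(x, y) {
    zx <- A * (2 * pi / P) * cos(2 * pi * x / P) * sin(2 * pi * y / P)
    zy <- A * (2 * pi / P) * sin(2 * pi * x / P) * cos(2 * pi * y / P)
    sqrt(1 + zx^2 + zy^2)
  }
  gg <- seq(0, P, length.out = 401L)[-401L]
  expect_equal(dejNormalizedArea(z, p), mean(outer(gg, gg, f)),
               tolerance = 0.01)
})

test_that("normalized DEJ area is rotation-invariant and scale-consistent", {
  set.seed(1)
  z <- mpskin:::gaussSmooth2d(matrix(rnorm(64 * 64, sd = 5), 64, 64), 3)
  a <- dejNormalizedArea(z, 1)
  rot <- t(z)[, rev(seq_len(64))]   # 90 degree rotation
  expect_equal(dejNormalizedArea(rot, 1), a, tolerance = 1e-3)
  # doubling pixel size and heights together preserves the ratio
  expect_equal(dejNormalizedArea(2 * z, 2), a, tolerance = 1e-9)
  expect_gte(a, 1)
})

test_that("morphology metrics recover a flat phantom's configured layers", {
  ph <- generatePhantom(phantomConfig(dims = c(48L, 48L, 32L),
                                      scThicknessUm = 15, ledThicknessUm = 35,
                                      dejAmplitudeUm = 0, seed = 41L))
  seg <- segmentStack(ph$stack)
  m <- morphologyMetrics(seg)
  zs <- zStepUm(ph$stack)
  expect_lt(abs(m$meanScThicknessUm - 15), zs)
  expect_lt(abs(m$meanEpidermalThicknessUm - 50), zs)
  # a perfectly flat junction measured on the plane grid keeps a small
  # roughness excess (sparse SHG onsets land on neighbouring planes)
  expect_lt(abs(m$dejNormalizedArea - 1), 0.1)
  # determinism: identical stack gives identical metrics
  expect_identical(m, morphologyMetrics(segmentStack(ph$stack)))
})
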