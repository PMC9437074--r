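test_that("SAAID and SHGto2PEF closed forms and consistency", {
  expect_equal(saaidIndex(c(elastin = 0.1, collagen = 0.3)), 0.5)
  expect_equal(saaidIndex(c(elastin = 0.2, collagen = 0.2)), 0)
  expect_equal(saaidIndex(c(elastin = 0, collagen = 0.2)), 1)
  expect_equal(shgTo2pefRatio(c(elastin = 0.1, collagen = 0.2)), 2)
  expect_equal(shgTo2pefRatio(c(elastin = 0.15, collagen = 0.15)), 1)
  expect_warning(r0 <- shgTo2pefRatio(c(elastin = 0, collagen = 0.2)), "zero")
  expect_true(is.na(r0))
  expect_warning(s0 <- saaidIndex(c(elastin = 0, collagen = 0)), "zero")
  expect_true(is.na(s0))
  # SAAID = (r - 1) / (r + 1) wherever both are defined
  for (e in c(0.02, 0.1, 0.3)) for (c_ in c(0.05, 0.2, 0.4)) {
    dens <- c(elastin = e, collagen = c_)
    r <- shgTo2pefRatio(dens)
    expect_equal(saaidIndex(dens), (r - 1) / (r + 1), tolerance = 1e-12)
  }
})

test_that("ImbrN is the Jaccard overlap: bounds, symmetry, brute force", {
  seg <- flatSeg(n = 40L, nz = 40L, dejUm = 20)
  d <- dim(labels3d(seg))
  dermis <- labels3d(seg) == LABEL_DERMIS
  a <- dermis & array(rep(c(TRUE, FALSE), length.out = prod(d)), d)
  expect_equal(imbricationIndex(list(elastin = a, collagen = a), seg), 1)
  b <- dermis & !a
  expect_equal(imbricationIndex(list(elastin = a, collagen = b), seg), 0)
  set.seed(7)
  for (i in 1:20) {
    m1 <- array(runif(1000) < 0.3, c(10, 10, 10))
    m2 <- array(runif(1000) < 0.3, c(10, 10, 10))
    scope <- array(TRUE, c(10, 10, 10))
    got <- imbricationIndex(list(elastin = m1, collagen = m2), seg,
                            scope = scope)
    # brute-force voxel counting oracle
    inter <- 0L; un <- 0L
    for (v in seq_len(1000)) {
      inter <- inter + (m1[v] && m2[v])
      un <- un + (m1[v] || m2[v])
    }
    expect_identical(got, inter / un)
    expect_identical(got, imbricationIndex(list(elastin = m2, collagen = m1),
                                           seg, scope = scope))
  }
  empty <- array(FALSE, c(10, 10, 10))
  expect_warning(
    na <- imbricationIndex(list(elastin = empty, collagen = empty), seg,
                           scope = array(TRUE, c(10, 10, 10))), "empty union")
  expect_true(is.na(na))
})

test_that("tolerance dilation can only increase the overlap", {
  ph <- phSmall()
  seg <- truthSegmentation(ph$truth)
  masks <- list(elastin = ph$truth$elastinMask,
                collagen = ph$truth$collagenMask)
  raw <- imbricationIndex(masks, seg)
  dil <- imbricationIndex(masks, seg, toleranceUm = 1.5)
  expect_gte(dil, raw)
})

test_that("fiber densities: identities and recovery against truth", {
  seg <- flatSeg(n = 40L, nz = 40L, dejUm = 20)
  dermis <- labels3d(seg) == LABEL_DERMIS
  expect_equal(fiberDensity(list(elastin = dermis, collagen = dermis), seg),
               c(elastin = 1, collagen = 1))
  half <- dermis
  half[21:40, , ] <- FALSE
  other <- dermis & !half
  expect_equal(fiberDensity(list(elastin = half, collagen = other), seg),
               c(elastin = 0.5, collagen = 0.5))
  # Otsu masks vs truth at high signal-to-noise
  ph <- generatePhantom(phantomConfig(dims = c(48L, 48L, 24L),
                                      surfaceDepthUm = 4, scThicknessUm = 8,
                                      ledThicknessUm = 16, dejAmplitudeUm = 4,
                                      elastinFraction = 0.08,
                                      photonBudget = 1000, seed = 51L))
  tseg <- truthSegmentation(ph$truth)
  fm <- fiberMasks(ph$stack, tseg)
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice(fm$elastin, ph$truth$elastinMask), 0.8)
  expect_gte(dice(fm$collagen, ph$truth$collagenMask), 0.8)
  dens <- fiberDensity(fm, tseg)
  expect_lt(abs(dens[["elastin"]] - ph$truth$metrics$elastinDensityDermis),
            0.02)
  # all-zero SHG gives an empty collagen mask
  ints <- intensities(ph$stack)
  ints[, , , 5] <- 0L
  noShg <- MultiphotonStack(ints, acquisitionMeta(ph$stack))
  expect_equal(sum(fiberMasks(noShg, tseg)$collagen), 0L)
})

test_that("z-profiles: conservation across nested bands", {
  ph <- phDermal()
  seg <- truthSegmentation(ph$truth)
  masks <- list(elastin = ph$truth$elastinMask,
                collagen = ph$truth$collagenMask)
  p10 <- dermalSublayers(seg, 10, 4L)
  prof <- dermalZProfiles(masks, seg, p10)
  expect_equal(nrow(prof), 5L)
  expect_true(prof$isRemainder[5])
  # a 20 um band density equals the voxel-weighted mean of its two 10 um
  # halves (densities combine linearly; the ratios do not)
  p20 <- dermalSublayers(seg, 20, 2L)
  prof20 <- dermalZProfiles(masks, seg, p20)
  w <- prof$nVoxels[1:2]
  expect_equal(prof20$elastinDensity[1],
               sum(prof$elastinDensity[1:2] * w) / sum(w))
  # whole-dermis density is the weighted mean over all bands + remainder
  dens <- fiberDensity(masks, seg)
  expect_equal(dens[["elastin"]],
               sum(prof$elastinDensity * prof$nVoxels) / sum(prof$nVoxels))
  # depth-constant fiber occupancy gives a flat regular-band profile
  expect_lt(diff(range(prof$collagenDensity[1:4])), 0.05)
})

test_that("layer mean intensity: uniform scopes and attenuation direction", {
  seg <- flatSeg(n = 40L, nz = 40L, dejUm = 20)
  ints <- array(0L, c(40L, 40L, 40L, 5L))
  ints[, , , 1:4] <- 25L
  ints[, , 21:40, 5] <- 60L
  st <- MultiphotonStack(ints, AcquisitionMeta(1, 1))
  m <- layerMeanIntensity(st, seg, LABEL_DERMIS)
  expect_equal(m[["pef"]], 100)
  expect_equal(m[["shg"]], 60)
  expect_error(layerMeanIntensity(st, seg, array(FALSE, c(40, 40, 40))),
               "empty scope")
  # thicker, melanin-rich epidermis pushes the dermis deeper; without gain
  # compensation its SHG mean drops (the attenuation confound)
  mk <- function(led, melf) {
    ph <- generatePhantom(phantomConfig(
      dims = c(48L, 48L, 32L), surfaceDepthUm = 4, scThicknessUm = 8,
      ledThicknessUm = led, melBasalFraction = melf, dejAmplitudeUm = 4,
      compensateAttenuation = FALSE, seed = 61L))
    layerMeanIntensity(ph$stack, truthSegmentation(ph$truth),
                       LABEL_DERMIS)[["shg"]]
  }
  expect_lt(mk(40, 0.4), mk(16, 0.1))
})
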