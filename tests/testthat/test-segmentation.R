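test_that("noise-free phantom surfaces are recovered within one z-step", {
  ph <- phCalNoiseFree()
  seg <- segmentStack(ph$stack)
  zs <- zStepUm(ph$stack)
  expect_lt(max(abs(depthValues(surfaceMap(seg)) - ph$truth$surface)), zs)
  expect_lt(median(abs(depthValues(dejMap(seg)) - ph$truth$dej)), zs)
  expect_lt(median(abs(depthValues(scLedMap(seg)) - ph$truth$scLed)), zs)
})

test_that("segmentation recovers labels and thicknesses at default budget", {
  ph <- phCal()
  seg <- segCal()
  zs <- zStepUm(ph$stack)
  expect_gte(mean(labels3d(seg) == ph$truth$labels), 0.95)
  tm <- thicknessMaps(seg)
  expect_lt(abs(mean(tm$epidermis) -
                ph$truth$metrics$meanEpidermalThicknessUm), zs)
  expect_lt(abs(mean(tm$sc) - ph$truth$metrics$meanScThicknessUm), zs)
  # the sinusoidal undulation survives detection: the recovered map tracks
  # the true pattern (projection onto the known waveform). Papilla tips are
  # partially clipped — at 15 % collagen occupancy the few SHG voxels in a
  # narrow dermal peak are below the onset detector's resolution — so the
  # recovered amplitude is attenuated but the phase structure is preserved
  u <- ph$truth$dej - mean(ph$truth$dej)
  m <- depthValues(dejMap(seg))
  ampHat <- sum((m - mean(m)) * u) / sum(u * u) * 10
  expect_gt(ampHat, 5.5)
  expect_lt(ampHat, 11)
  expect_gt(cor(as.vector(m), as.vector(u)), 0.75)
})

test_that("surface ordering invariant holds after projection", {
  seg <- segCal()
  s <- depthValues(surfaceMap(seg))
  b <- depthValues(scLedMap(seg))
  d <- depthValues(dejMap(seg))
  expect_true(all(s <= b + 1e-9))
  expect_true(all(b <= d + 1e-9))
})

test_that("degenerate stacks raise the documented errors", {
  # pure noise: no skin
  noise <- MultiphotonStack(
    array(stats::rpois(32 * 32 * 12 * 5, 1), c(32, 32, 12, 5)),
    AcquisitionMeta(1, 2))
  expect_error(detectSkinSurface(noise), "no skin detected")
  # SHG absent: no dermis
  ph <- phSmall()
  ints <- intensities(ph$stack)
  ints[, , , 5] <- 0L
  noShg <- MultiphotonStack(ints, acquisitionMeta(ph$stack))
  surf <- detectSkinSurface(noShg)
  expect_error(detectDejSurface(noShg, surf), "no dermis detected")
  # SHG from the first plane on: epidermis collapses
  ints2 <- intensities(ph$stack)
  shg <- ints2[, , , 5]
  shg[] <- as.integer(stats::rpois(length(shg), 40))
  ints2[, , , 5] <- shg
  allShg <- MultiphotonStack(ints2, acquisitionMeta(ph$stack))
  expect_error(segmentStack(allShg), "empty epidermis")
})

test_that("SC/LED boundary lands at the brightness drop", {
  ph <- phCal()   # SC brightness 2x LED, SC thickness 15 um
  seg <- segCal()
  scThick <- mean(depthValues(scLedMap(seg)) - depthValues(surfaceMap(seg)))
  expect_lt(abs(scThick - 15), zStepUm(ph$stack))
})

test_that("uniform-brightness epidermis falls back to the prior fraction", {
  cfg <- phantomConfig(dims = c(48L, 48L, 24L), surfaceDepthUm = 4,
                       scThicknessUm = 10, ledThicknessUm = 22,
                       dejAmplitudeUm = 4, scBrightness = 1, seed = 31L)
  ph <- generatePhantom(cfg)
  surf <- detectSkinSurface(ph$stack)
  dej <- detectDejSurface(ph$stack, surf)
  expect_warning(b <- splitScLed(ph$stack, surf, dej), "without SC/LED contrast")
  frac <- mean((depthValues(b) - depthValues(surf)) /
               (depthValues(dej) - depthValues(surf)))
  expect_lt(abs(frac - 0.2), 0.05)
  # zero-thickness SC with the collapse option: boundary within one z-step
  # of the surface
  cfg0 <- phantomConfig(dims = c(48L, 48L, 24L), surfaceDepthUm = 4,
                        scThicknessUm = 1e-6, ledThicknessUm = 30,
                        dejAmplitudeUm = 4, seed = 32L)
  ph0 <- generatePhantom(cfg0)
  p0 <- segmentationParams(noContrastBoundary = "surface",
                           scContrastMin = 1.3)
  surf0 <- detectSkinSurface(ph0$stack, p0)
  dej0 <- detectDejSurface(ph0$stack, surf0, p0)
  expect_warning(b0 <- splitScLed(ph0$stack, surf0, dej0, p0), "surface")
  expect_lt(median(depthValues(b0) - depthValues(surf0)),
            zStepUm(ph0$stack))
})

test_that("fresh Poisson noise changes mean epidermal thickness < 2 %", {
  cfg <- phantomConfig(dims = c(64L, 64L, 32L), seed = 7L)
  rs <- generateRepeatSeries(cfg, 3L)
  thick <- vapply(rs, function(r) {
    seg <- segmentStack(r$stack)
    mean(depthValues(dejMap(seg)) - depthValues(surfaceMap(seg)))
  }, numeric(1))
  expect_lt(diff(range(thick)) / mean(thick), 0.02)
})
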