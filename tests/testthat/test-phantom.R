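test_that("phantom generation is deterministic given config and seed", {
  cfg <- phantomConfig(dims = c(48L, 48L, 16L), scThicknessUm = 8,
                       ledThicknessUm = 16, dejAmplitudeUm = 4, seed = 7L)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(intensities(a$stack), intensities(b$stack))
  expect_identical(a$truth$melaninMask, b$truth$melaninMask)
  c_ <- generatePhantom(phantomConfig(dims = c(48L, 48L, 16L),
                                      scThicknessUm = 8, ledThicknessUm = 16,
                                      dejAmplitudeUm = 4, seed = 8L))
  expect_false(identical(intensities(a$stack), intensities(c_$stack)))
})

test_that("truth masks are subsets of their generating layers", {
  ph <- phSmall()
  epi <- ph$truth$labels %in% c(LABEL_SC, LABEL_LED)
  dermis <- ph$truth$labels == LABEL_DERMIS
  expect_true(all(epi[ph$truth$melaninMask]))
  expect_true(all(dermis[ph$truth$elastinMask]))
  expect_true(all(dermis[ph$truth$collagenMask]))
})

test_that("flat DEJ gives unit normalized area; sinusoid matches quadrature", {
  flat <- generatePhantom(phantomConfig(dims = c(32L, 32L, 16L),
                                        scThicknessUm = 6, ledThicknessUm = 12,
                                        dejAmplitudeUm = 0, seed = 1L))
  expect_equal(flat$truth$metrics$dejNormalizedArea, 1.0, tolerance = 1e-9)

  A <- 10; P <- 50
  cfg <- phantomConfig(dims = c(96L, 96L, 40L), pixelSizeUm = 1,
                       dejAmplitudeUm = A, dejPeriodUm = P, seed = 2L,
                       elastinFraction = 0, collagenFraction = 0.05,
                       melBasalFraction = 0)
  ph <- generatePhantom(cfg)
  # quadrature oracle: surface integral of the analytic heightfield
  # z(x, y) = A sin(2 pi x / P) sin(2 pi y / P) over one period
  f <- function(x, y) {
    zx <- A * (2 * pi / P) * cos(2 * pi * x / P) * sin(2 * pi * y / P)
    zy <- A * (2 * pi / P) * sin(2 * pi * x / P) * cos(2 * pi * y / P)
    sqrt(1 + zx^2 + zy^2)
  }
  g <- seq(0, P, length.out = 401L)[-401L]
  oracle <- mean(outer(g, g, f))
  expect_equal(ph$truth$metrics$dejNormalizedArea, oracle, tolerance = 0.01)
})

test_that("melanin voxels concentrate counts in the first time channel", {
  ph <- phSmall()
  ints <- intensities(ph$stack)
  tot <- ints[, , , 1] + ints[, , , 2] + ints[, , , 3] + ints[, , , 4]
  frac1 <- ints[, , , 1] / pmax(tot, 1)
  mel <- ph$truth$melaninMask
  led <- ph$truth$labels == LABEL_LED & !mel
  expect_gt(mean(frac1[mel]), mean(frac1[led]) + 0.1)
  # closed-form check: channel integrals of the two mono-exponentials
  fm <- flimChannelFractions <- mpskin:::flimChannelFractions
  expect_gt(fm(0.2)[1], fm(1.8)[1])
  expect_equal(sum(fm(0.2)), 1)
})

test_that("raising the configured elastin fraction raises truth density", {
  mk <- function(f) generatePhantom(phantomConfig(
    dims = c(48L, 48L, 24L), scThicknessUm = 8, ledThicknessUm = 16,
    dejAmplitudeUm = 4, elastinFraction = f,
    seed = 5L))$truth$metrics$elastinDensityDermis
  d <- vapply(c(0.03, 0.08, 0.15), mk, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("geometrically impossible configurations are rejected", {
  expect_error(phantomConfig(dejAmplitudeUm = 40, ledThicknessUm = 35),
               "amplitude")
  expect_error(phantomConfig(elastinFraction = 1.5), "\\[0, 1\\]")
  expect_error(phantomConfig(bogus = 1), "unknown phantom")
})

test_that("repeat series share truth and apply the injected drift", {
  cfg <- phantomConfig(dims = c(48L, 48L, 16L), scThicknessUm = 8,
                       ledThicknessUm = 16, dejAmplitudeUm = 4, seed = 11L)
  rs <- generateRepeatSeries(cfg, 3L)
  expect_length(rs, 3L)
  expect_identical(rs[[1]]$truth$surface, rs[[3]]$truth$surface)
  expect_identical(rs[[1]]$truth$melaninMask, rs[[3]]$truth$melaninMask)
  expect_false(identical(intensities(rs[[1]]$stack),
                         intensities(rs[[2]]$stack)))

  drift <- generateRepeatSeries(cfg, 2L, driftUm = c(0, 0, 2.346))
  expect_equal(drift[[2]]$truth$surface,
               drift[[1]]$truth$surface + 2.346)
})

test_that("per-layer means converge across repeats as the budget grows", {
  spread <- vapply(c(30, 200, 2000), function(budget) {
    cfg <- phantomConfig(dims = c(48L, 48L, 16L), scThicknessUm = 8,
                         ledThicknessUm = 16, dejAmplitudeUm = 4,
                         photonBudget = budget, seed = 13L)
    rs <- generateRepeatSeries(cfg, 3L)
    m <- vapply(rs, function(r)
      layerMeanIntensity(r$stack, truthSegmentation(r$truth),
                         LABEL_LED)[["pef"]], numeric(1))
    diff(range(m)) / mean(m)
  }, numeric(1))
  expect_lt(spread[3], spread[1])
})

test_that("a null cohort carries no systematic group difference", {
  cfg <- phantomConfig(dims = c(48L, 48L, 20L), scThicknessUm = 8,
                       ledThicknessUm = 16, dejAmplitudeUm = 4)
  coh <- generateCohort(cfg, cfg, nPerGroup = 3L, roisPerSubject = 2L,
                        seed = 17L)
  expect_length(coh, 12L)
  expect_equal(sort(unique(vapply(coh, `[[`, character(1), "group"))),
               c("old", "young"))
  thick <- vapply(coh, function(r)
    r$truth$metrics$meanEpidermalThicknessUm, numeric(1))
  grp <- vapply(coh, `[[`, character(1), "group")
  d <- cohenD(thick[grp == "young"], thick[grp == "old"])
  expect_lt(abs(d$d), 2)          # no systematic gap beyond sampling noise
  expect_true(all(vapply(coh, `[[`, numeric(1), "roi") %in% 1:2))
})
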