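test_that("folded F: construction, closed form and swap invariance", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9, 3.3, 1.8, 4.0, 2.5)
  same <- foldedFTest(x, x)
  expect_equal(same$F, 1)
  expect_equal(same$p, 1)
  set.seed(2)
  a <- rnorm(10, sd = 2)
  b <- rnorm(10, sd = 1)
  ff <- foldedFTest(a, b)
  expect_equal(ff$F, max(var(a), var(b)) / min(var(a), var(b)))
  expect_equal(ff$p, min(1, 2 * pf(ff$F, 9, 9, lower.tail = FALSE)))
  expect_gte(ff$F, 1)
  sw <- foldedFTest(b, a)
  expect_equal(sw$F, ff$F)
  expect_equal(sw$p, ff$p)
  expect_error(foldedFTest(rep(1, 5), rep(2, 5)), "zero")
})

test_that("Student t matches the pooled-variance formula; antisymmetric", {
  a <- c(19.8, 21.2, 20.5, 22.1, 19.1, 20.9)
  b <- c(18.0, 19.4, 18.8, 17.6, 19.9)
  tt <- twoSampleT(a, b)
  sp2 <- (5 * var(a) + 4 * var(b)) / 9
  oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 5))
  expect_equal(tt$t, oracle, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(abs(oracle), 9, lower.tail = FALSE))
  expect_equal(twoSampleT(b, a)$t, -tt$t)
  same <- twoSampleT(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # paired variant reduces to the one-sample t on differences
  pp <- twoSampleT(a[1:5], b, paired = TRUE)
  dd <- a[1:5] - b
  expect_equal(pp$t, mean(dd) / (sd(dd) / sqrt(5)), tolerance = 1e-12)
})

test_that("Cohen's d: bands, scale invariance and degenerate input", {
  expect_equal(esBand(0), "none")
  expect_equal(esBand(0.1), "very weak")
  expect_equal(esBand(-0.4), "weak")
  expect_equal(esBand(0.65), "moderate")
  expect_equal(esBand(0.9), "strong")
  expect_equal(esBand(0.8), "strong")       # band edges are left-closed
  expect_equal(esBand(1.3), "very strong")
  expect_equal(esBand(-2), "very strong")
  a <- c(10, 11, 12, 13, 14)
  b <- c(12, 13, 14, 15, 16)
  cd <- cohenD(a, b)
  expect_equal(cd$d, (mean(a) - mean(b)) / sqrt(var(a)), tolerance = 1e-12)
  expect_equal(cohenD(3 * a, 3 * b)$d, cd$d, tolerance = 1e-12)
  expect_equal(cohenD(a, a)$d, 0)
  expect_equal(cohenD(a, a)$band, "none")
  expect_error(cohenD(rep(1, 4), rep(1, 4)), "pooled SD")
})

test_that("null calibration: both tests reject at about the nominal rate", {
  set.seed(10)
  nrep <- 1000
  rejF <- rejT <- 0L
  for (i in seq_len(nrep)) {
    a <- rnorm(10); b <- rnorm(10)
    if (foldedFTest(a, b)$p < 0.05) rejF <- rejF + 1L
    if (twoSampleT(a, b)$p < 0.05) rejT <- rejT + 1L
  }
  expect_lt(abs(rejF / nrep - 0.05), 0.025)
  expect_lt(abs(rejT / nrep - 0.05), 0.025)
})

test_that("ROI robustness: degenerate, biased and insufficient inputs", {
  mkTab <- function(vals) {
    do.call(rbind, lapply(seq_along(vals), function(s)
      data.frame(subject = s, roi = 1:4, metric = "m",
                 value = vals[[s]])))
  }
  # duplicated ROIs: F = 1, p = 1 everywhere, nothing flagged
  dup <- mkTab(lapply(1:8, function(s) rep(s, 4)))
  res <- roiRobustness(dup)
  expect_true(all(res$F == 1))
  expect_true(all(res$pF == 1))
  expect_true(all(res$pT == 1))
  expect_false(any(res$flagged))
  # a strong systematic bias on ROIs 3-4 is flagged
  set.seed(5)
  bias <- mkTab(lapply(1:8, function(s) s + c(0, 0, 50, 50) + rnorm(4, 0, .1)))
  expect_true(any(roiRobustness(bias)$flagged))
  # fewer than 4 ROIs per subject is an error
  expect_error(roiRobustness(dup[dup$roi < 4, ]), "at least 4")
})

test_that("Pearson matrix handles exact and degenerate correlations", {
  x <- c(1.5, 2.3, 0.8, 4.1, 3.3, 2.0)
  df <- data.frame(a = x, b = -x, c = 2 * x + 1)
  r <- pearsonMatrix(df)
  expect_equal(unname(r["a", "a"]), 1)
  expect_equal(unname(r["a", "b"]), -1)
  expect_equal(unname(r["a", "c"]), 1)
  expect_warning(rc <- pearsonMatrix(cbind(df, k = rep(7, 6))), "constant")
  expect_true(is.na(rc["k", "a"]))
  expect_error(pearsonMatrix(df[1:2, ]), "3 rows")
})

test_that("uncompensated SHG dermal mean anticorrelates with melanin load", {
  # cohort of phantoms varying in epidermal thickness and melanin; the
  # uncompensated SHG mean in the dermis drops as the overburden grows
  leds <- c(14, 18, 24, 30, 36, 42)
  mels <- c(0.08, 0.15, 0.2, 0.3, 0.38, 0.45)
  vals <- t(vapply(seq_along(leds), function(i) {
    ph <- generatePhantom(phantomConfig(
      dims = c(48L, 48L, 32L), surfaceDepthUm = 4, scThicknessUm = 8,
      ledThicknessUm = leds[i], melBasalFraction = mels[i],
      dejAmplitudeUm = 4, compensateAttenuation = FALSE,
      seed = 80L + i))
    seg <- truthSegmentation(ph$truth)
    mel <- melaninMask(ph$stack, seg)
    c(shg = layerMeanIntensity(ph$stack, seg, LABEL_DERMIS)[["shg"]],
      mel = melaninDensity(mel, seg, "epidermis"))
  }, numeric(2)))
  r <- pearsonMatrix(vals)
  expect_lt(r["shg", "mel"], 0)
})
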