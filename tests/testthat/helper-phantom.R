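# Shared phantom fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- make()
  .fixtureCache[[key]]
}

# Small general-purpose noisy phantom (fast).
phSmall <- function() cached("small", function()
  generatePhantom(phantomConfig(dims = c(48L, 48L, 24L), surfaceDepthUm = 4,
                                scThicknessUm = 10, ledThicknessUm = 22,
                                dejAmplitudeUm = 6, seed = 101L)))

# Default-geometry phantom at the calibration scale used for recovery tests.
phCal <- function() cached("cal", function()
  generatePhantom(phantomConfig(dims = c(64L, 64L, 32L), seed = 3L)))

phCalNoiseFree <- function() cached("calnf", function()
  generatePhantom(phantomConfig(dims = c(64L, 64L, 32L), seed = 5L,
                                poissonNoise = FALSE)))

segCal <- function() cached("segcal", function() segmentStack(phCal()$stack))

# Thin-epidermis phantom with ~60 um of imaged dermis (for z-profile tests).
phDermal <- function() cached("dermal", function()
  generatePhantom(phantomConfig(dims = c(48L, 48L, 40L), surfaceDepthUm = 4,
                                scThicknessUm = 8, ledThicknessUm = 16,
                                dejAmplitudeUm = 4, seed = 71L)))

# Analytic flat segmentation on a unit grid: surface 0, SC/LED boundary at
# scUm, DEJ at dejUm; z-step 1 um, pixel 1 um, nz planes.
flatSeg <- function(n = 40L, nz = 30L, scUm = 4, dejUm = 20) {
  surface <- matrix(0, n, n)
  scLed <- matrix(scUm, n, n)
  dej <- matrix(dejUm, n, n)
  depth <- array(rep(0:(nz - 1L), each = n * n), c(n, n, nz))
  labels <- (depth >= 0) + (depth >= scUm) + (depth >= dejUm)
  storage.mode(labels) <- "integer"
  new("LayerSegmentation", labels = labels,
      surface = DepthMap(surface, "surface"),
      scLed = DepthMap(scLed, "sc_led"),
      dej = DepthMap(dej, "dej"),
      zStepUm = 1, pixelSizeUm = 1)
}
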