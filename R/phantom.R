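# Synthetic multiphoton skin phantom with full ground truth.
#
# The phantom emulates a combined 2PEF-FLIM (4 time channels) / SHG z-stack
# of human skin: a flat-to-tilted skin surface, a stratum corneum of constant
# thickness following the surface, a living epidermis bounded below by an
# undulated DEJ, melanin concentrated at the basal layer with a short
# fluorescence lifetime, and a superficial dermis containing tubular elastin
# (2PEF-emitting) and fibrillar collagen (SHG-emitting) networks grown as
# persistent random walks dilated to a configured radius. Per-voxel FLIM
# channel counts integrate a shifted mono-exponential decay over each
# temporal bin, are depth-attenuated (optionally compensated by the
# instrument-style exponential excitation gain) and Poisson-sampled.

#' Create a phantom configuration
#'
#' All arguments have defaults describing a young ventral-forearm
#' acquisition; see [PhantomConfig-class] for the meaning and units of each
#' parameter. Validity is checked (e.g. the DEJ undulation amplitude must
#' stay below the living-epidermis thickness).
#'
#' @param ... named [PhantomConfig-class] slot values overriding the
#'   defaults.
#' @return a validated [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(dims = c(64L, 64L, 32L), seed = 7L)
#' @export
phantomConfig <- function(...) {
  defaults <- list(
    dims = c(128L, 128L, 70L),
    pixelSizeUm = 130.3 / 128, zStepUm = 2.346,
    nTimeChannels = 4L, timeChannelWidthNs = 2.08, peakOffsetNs = 1.33,
    surfaceDepthUm = 5, surfaceTiltUm = 0,
    scThicknessUm = 15, ledThicknessUm = 35,
    dejAmplitudeUm = 10, dejPeriodUm = 50, dejWaveform = "sinusoid",
    melBasalFraction = 0.3, melDecayNorm = 0.25,
    melLifetimeNs = 0.2, backgroundLifetimeNs = 1.8, elastinLifetimeNs = 0.4,
    scBrightness = 2,
    elastinFraction = 0.05, elastinRadiusUm = 1, elastinWaviness = 0.3,
    collagenFraction = 0.15, collagenRadiusUm = 1,
    fiberOverlapBias = 0.2,
    attenuationLengthUm = 50, compensateAttenuation = TRUE,
    photonBudget = 200, noiseFloor = 1, poissonNoise = TRUE,
    seed = 1L
  )
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    stop("unknown phantom parameters: ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  defaults$dims <- as.integer(defaults$dims)
  defaults$nTimeChannels <- as.integer(defaults$nTimeChannels)
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list(Class = "PhantomConfig"), defaults))
}

#' Phantom presets for the aging-contrast study conditions
#'
#' \code{"young_forearm"} is the default configuration: thick undulated
#' epidermis, moderate basal melanin, sparse thin elastin. \code{"old_temple"}
#' carries the aging signature seen on chronically exposed skin: thinner
#' epidermis, flattened DEJ, and elastosis (elastin density raised to three
#' times the young value) with slightly wavier fibers and higher
#' elastin/collagen co-location.
#'
#' @param name \code{"young_forearm"} or \code{"old_temple"}.
#' @param ... overrides passed on to [phantomConfig()].
#' @return a [PhantomConfig-class].
#' @export
phantomPreset <- function(name = c("young_forearm", "old_temple"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    young_forearm = list(),
    old_temple = list(
      scThicknessUm = 12, ledThicknessUm = 25,
      dejAmplitudeUm = 4,
      melBasalFraction = 0.35,
      elastinFraction = 0.15, elastinWaviness = 0.45,
      fiberOverlapBias = 0.35
    )
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(phantomConfig, base)
}

# True surfaces and layer labels implied by a configuration.
phantomGeometry <- function(config) {
  d <- config@dims
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  xs <- (seq_len(nx) - 1) * config@pixelSizeUm
  ys <- (seq_len(ny) - 1) * config@pixelSizeUm
  surface <- matrix(config@surfaceDepthUm, nx, ny) +
    outer(xs / max(xs[nx], 1), rep(1, ny)) * config@surfaceTiltUm
  scLed <- surface + config@scThicknessUm
  sx <- sin(2 * pi * outer(xs, rep(1, ny)) / config@dejPeriodUm)
  sy <- sin(2 * pi * outer(rep(1, nx), ys) / config@dejPeriodUm)
  u <- switch(config@dejWaveform,
    sinusoid = config@dejAmplitudeUm * sx * sy,
    # papillae-like bumps: squared sinusoid grid, re-centred to mean ~0
    bumps = config@dejAmplitudeUm * (2 * (sx * sy)^2 - 1) * 0.999
  )
  dej <- surface + config@scThicknessUm + config@ledThicknessUm + u
  depth <- depthVolume(d, config@zStepUm)
  labels <- (depth >= repMap(surface, nz)) + (depth >= repMap(scLed, nz)) +
    (depth >= repMap(dej, nz))
  storage.mode(labels) <- "integer"
  list(surface = surface, scLed = scLed, dej = dej, depth = depth,
       labels = labels)
}

# Melanin occupancy mask: probability decays exponentially with normalized
# height above the DEJ (h = 0 at the DEJ, 1 at the surface). Consumes RNG.
phantomMelanin <- function(config, geom) {
  nz <- config@dims[3L]
  h <- (repMap(geom$dej, nz) - geom$depth) /
    repMap(geom$dej - geom$surface, nz)
  p <- config@melBasalFraction * exp(-pmin(pmax(h, 0), 1) / config@melDecayNorm)
  epi <- geom$labels == LABEL_SC | geom$labels == LABEL_LED
  draw <- array(stats::runif(length(p)), dim(p))
  epi & draw < p
}

# Grow one fiber network of tubes until the target dermal volume fraction is
# reached. Returns the mask plus the raw walk paths (used to seed biased
# elastin walks along collagen). Consumes RNG.
growFiberNetwork <- function(config, geom, targetFraction, radiusUm,
                             waviness, seedPaths = NULL, overlapBias = 0) {
  d <- config@dims
  dermis <- geom$labels == LABEL_DERMIS
  nDermis <- sum(dermis)
  mask <- array(FALSE, d)
  paths <- list()
  if (targetFraction <= 0 || nDermis == 0L) return(list(mask = mask, paths = paths))
  offs <- ballOffsets(radiusUm, config@pixelSizeUm, config@zStepUm)
  dermisIdx <- which(dermis)
  nSteps <- max(16L, round(0.6 * d[1L]))
  unit <- function(v) v / sqrt(sum(v^2))
  maxFibers <- 5000L
  for (f in seq_len(maxFibers)) {
    if (sum(mask & dermis) / nDermis >= targetFraction) break
    fromSeed <- !is.null(seedPaths) && length(seedPaths) > 0L &&
      stats::runif(1) < overlapBias
    if (fromSeed) {
      sp <- seedPaths[[sample.int(length(seedPaths), 1L)]]
      j <- sample.int(nrow(sp$points), 1L)
      pos <- sp$points[j, ] + stats::rnorm(3, sd = 0.5)
      dir <- unit(sp$dirs[j, ] + 0.3 * stats::rnorm(3))
    } else {
      # start at a uniformly random column and a uniformly random depth
      # below the local DEJ: lateral coverage is uniform under the undulated
      # junction (no collagen-free pockets at papillae peaks, as in real
      # papillary dermis) while the depth profile stays uniform
      i <- sample.int(d[1L], 1L)
      j <- sample.int(d[2L], 1L)
      maxDepth <- (d[3L] - 1L) * config@zStepUm
      depth <- stats::runif(1, geom$dej[i, j], maxDepth)
      z <- min(max(round(depth / config@zStepUm) + 1L, 1L), d[3L])
      while (z < d[3L] && geom$labels[i, j, z] != LABEL_DERMIS) z <- z + 1L
      pos <- c(i, j, z)
      dir <- unit(stats::rnorm(3) * c(1, 1, 0.3))
    }
    pts <- matrix(0, nSteps, 3L)
    dirs <- matrix(0, nSteps, 3L)
    for (s in seq_len(nSteps)) {
      pts[s, ] <- pos
      dirs[s, ] <- dir
      pos <- pos + dir
      dir <- unit(dir + waviness * stats::rnorm(3) * c(1, 1, 0.3))
    }
    vox <- unique(round(pts))
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1L] & vox[, 2] >= 1 &
      vox[, 2] <= d[2L] & vox[, 3] >= 1 & vox[, 3] <= d[3L]
    vox <- vox[ok, , drop = FALSE]
    if (nrow(vox) == 0L) next
    mask <- paintDilated(mask, vox, offs)
    paths[[length(paths) + 1L]] <- list(points = pts, dirs = dirs)
  }
  list(mask = mask & dermis, paths = paths)
}

# Expected per-channel count rates (list of 5 arrays) for the configured
# structures; no randomness.
phantomEmission <- function(config, geom, melanin, elastin, collagen) {
  d <- config@dims
  n <- config@nTimeChannels
  # structure codes: 1 bg(none), 2 SC, 3 LED, 4 melanin, 5 dermis base,
  # 6 elastin
  struct <- array(1L, d)
  struct[geom$labels == LABEL_SC] <- 2L
  struct[geom$labels == LABEL_LED] <- 3L
  struct[geom$labels == LABEL_DERMIS] <- 5L
  struct[elastin] <- 6L
  struct[melanin] <- 4L
  bright <- c(0, config@scBrightness, 1, 1.2, 0.15, 1)
  taus <- c(NA, config@backgroundLifetimeNs, config@backgroundLifetimeNs,
            config@melLifetimeNs, config@backgroundLifetimeNs,
            config@elastinLifetimeNs)
  fr <- matrix(0, 6L, n)
  for (s in 2:6)
    fr[s, ] <- flimChannelFractions(taus[s], config@peakOffsetNs,
                                    config@timeChannelWidthNs, n)
  att <- if (config@compensateAttenuation) array(1, d)
         else exp(-geom$depth / config@attenuationLengthUm)
  base <- config@photonBudget * bright[struct] * att
  lam <- vector("list", n + 1L)
  for (c in seq_len(n))
    lam[[c]] <- base * array(fr[cbind(as.vector(struct), c)], d) +
      config@noiseFloor
  lam[[n + 1L]] <- config@photonBudget * att * collagen + config@noiseFloor
  lam
}

phantomCounts <- function(lam, poisson) {
  d <- dim(lam[[1L]])
  ints <- array(0L, c(d, length(lam)))
  for (c in seq_along(lam)) {
    v <- if (poisson) stats::rpois(length(lam[[c]]), as.vector(lam[[c]]))
         else as.integer(round(as.vector(lam[[c]])))
    ints[, , , c] <- v
  }
  ints
}

# Layer segmentation built directly from the true surfaces (the geometric
# oracle against which measured segmentations are compared).
#' Build a LayerSegmentation from phantom ground truth
#'
#' @param truth the truth component returned by [generatePhantom()].
#' @return a [LayerSegmentation-class] whose labels and depth maps are the
#'   phantom's exact ground truth.
#' @export
truthSegmentation <- function(truth) {
  new("LayerSegmentation",
      labels = truth$labels,
      surface = DepthMap(truth$surface, "surface"),
      scLed = DepthMap(truth$scLed, "sc_led"),
      dej = DepthMap(truth$dej, "dej"),
      zStepUm = truth$config@zStepUm,
      pixelSizeUm = truth$config@pixelSizeUm)
}

# True metric values computed from the masks and surfaces with the same
# analytic definitions as the measurement path.
phantomTruthMetrics <- function(config, geom, melanin, elastin, collagen) {
  seg <- new("LayerSegmentation",
             labels = geom$labels,
             surface = DepthMap(geom$surface, "surface"),
             scLed = DepthMap(geom$scLed, "sc_led"),
             dej = DepthMap(geom$dej, "dej"),
             zStepUm = config@zStepUm, pixelSizeUm = config@pixelSizeUm)
  epi <- geom$labels == LABEL_SC | geom$labels == LABEL_LED
  dermis <- geom$labels == LABEL_DERMIS
  part <- epidermalSublayers(seg, K = 10L)
  band50 <- dermalSublayers(seg, bandUm = 50, nBands = 1L)
  in50 <- sublayerIndex(band50) == 1L
  basal10 <- epi & (repMap(geom$dej, config@dims[3L]) - geom$depth) <= 10 &
    (repMap(geom$dej, config@dims[3L]) - geom$depth) >= 0
  eD <- sum(elastin & in50) / sum(in50)
  cD <- sum(collagen & in50) / sum(in50)
  list(
    meanScThicknessUm = mean(geom$scLed - geom$surface),
    meanLedThicknessUm = mean(geom$dej - geom$scLed),
    meanEpidermalThicknessUm = mean(geom$dej - geom$surface),
    dejNormalizedArea = dejNormalizedArea(seg@dej, config@pixelSizeUm),
    melaninGlobalDensity = sum(melanin & epi) / sum(epi),
    melaninBasal10Density = sum(melanin & basal10) / sum(basal10),
    # thin phantoms can sample fewer planes than sublayers; NA entries in
    # the truth profile are expected there, no flag needed
    melaninZProfile = suppressWarnings(melaninZProfile(melanin, part)),
    elastinDensityDermis = sum(elastin) / sum(dermis),
    collagenDensityDermis = sum(collagen) / sum(dermis),
    elastinDensity50 = eD,
    collagenDensity50 = cD,
    shgTo2pef = if (eD > 0) cD / eD else NA_real_,
    saaid = if (eD + cD > 0) (cD - eD) / (cD + eD) else NA_real_,
    imbrn = {
      un <- sum((elastin | collagen) & in50)
      if (un > 0) sum(elastin & collagen & in50) / un else NA_real_
    }
  )
}

#' Generate a synthetic skin phantom stack with ground truth
#'
#' Deterministic given \code{(config, seed)}: identical configurations
#' produce bit-identical stacks. The truth sidecar carries the exact
#' surfaces, the melanin/elastin/collagen voxel masks, the structure
#' lifetimes, and the true metric values derived from the masks.
#'
#' @param config a [PhantomConfig-class].
#' @return a list with components \code{stack} (a
#'   [MultiphotonStack-class]) and \code{truth} (a list: \code{surface},
#'   \code{scLed}, \code{dej} depth maps in um; \code{labels};
#'   \code{melaninMask}, \code{elastinMask}, \code{collagenMask};
#'   \code{lifetimesNs}; \code{metrics}; \code{config}).
#' @examples
#' ph <- generatePhantom(phantomConfig(dims = c(48L, 48L, 24L),
#'                                     dejAmplitudeUm = 5, seed = 2L))
#' ph$stack
#' ph$truth$metrics$meanEpidermalThicknessUm
#' @export
generatePhantom <- function(config) {
  validObject(config)
  geom <- phantomGeometry(config)
  res <- withSeed(config@seed, {
    mel <- phantomMelanin(config, geom)
    col <- growFiberNetwork(config, geom, config@collagenFraction,
                            config@collagenRadiusUm, waviness = 0.25)
    ela <- growFiberNetwork(config, geom, config@elastinFraction,
                            config@elastinRadiusUm, config@elastinWaviness,
                            seedPaths = col$paths,
                            overlapBias = config@fiberOverlapBias)
    lam <- phantomEmission(config, geom, mel, ela$mask, col$mask)
    ints <- phantomCounts(lam, config@poissonNoise)
    list(mel = mel, ela = ela$mask, col = col$mask, ints = ints, lam = lam)
  })
  meta <- AcquisitionMeta(config@pixelSizeUm, config@zStepUm,
                          config@nTimeChannels, config@timeChannelWidthNs)
  stack <- MultiphotonStack(res$ints, meta, roiId = "phantom")
  truth <- list(
    surface = geom$surface, scLed = geom$scLed, dej = geom$dej,
    labels = geom$labels,
    melaninMask = res$mel, elastinMask = res$ela, collagenMask = res$col,
    lifetimesNs = c(melanin = config@melLifetimeNs,
                    background = config@backgroundLifetimeNs,
                    elastin = config@elastinLifetimeNs),
    metrics = phantomTruthMetrics(config, geom, res$mel, res$ela, res$col),
    config = config
  )
  list(stack = stack, truth = truth, .lambda = res$lam)
}

# Shift a 3D array by integer voxels (content moves by +s), edge-filled.
shiftArray3d <- function(a, s, fill) {
  d <- dim(a)
  idx <- function(n, sh) {
    i <- seq_len(n) - sh
    i[i < 1L] <- NA
    i[i > n] <- NA
    i
  }
  out <- array(fill, d)
  ix <- idx(d[1L], s[1L]); iy <- idx(d[2L], s[2L]); iz <- idx(d[3L], s[3L])
  okx <- !is.na(ix); oky <- !is.na(iy); okz <- !is.na(iz)
  out[okx, oky, okz] <- a[ix[okx], iy[oky], iz[okz]]
  out
}

#' Generate a repeat series of stacks from the same underlying skin
#'
#' Emulates the repeatability experiment where the same skin region is
#' re-imaged every few minutes: the structural truth is generated once, and
#' each repeat draws fresh Poisson noise, optionally after a small rigid
#' drift of the whole volume.
#'
#' @param config a [PhantomConfig-class].
#' @param nRepeats number of repeats (>= 2).
#' @param driftUm length-3 numeric (dx, dy, dz) drift in micrometres applied
#'   cumulatively between consecutive repeats (rounded to whole voxels).
#' @return a list of \code{nRepeats} elements, each with \code{stack} and
#'   \code{truth} (truth surfaces shifted by the injected drift).
#' @export
generateRepeatSeries <- function(config, nRepeats = 3L,
                                 driftUm = c(0, 0, 0)) {
  stopifnot(nRepeats >= 2L)
  base <- generatePhantom(config)
  lam <- base$.lambda
  driftVox <- c(round(driftUm[1] / config@pixelSizeUm),
                round(driftUm[2] / config@pixelSizeUm),
                round(driftUm[3] / config@zStepUm))
  out <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    s <- as.integer(driftVox * (r - 1L))
    lamr <- if (all(s == 0L)) lam
            else lapply(lam, shiftArray3d, s = s, fill = config@noiseFloor)
    ints <- withSeed(config@seed + r, phantomCounts(lamr, config@poissonNoise))
    stack <- MultiphotonStack(ints, AcquisitionMeta(
      config@pixelSizeUm, config@zStepUm, config@nTimeChannels,
      config@timeChannelWidthNs), roiId = sprintf("repeat_%d", r))
    tr <- base$truth
    if (any(s != 0L)) {
      shMap <- function(m) {
        d <- dim(m)
        ix <- pmin(pmax(seq_len(d[1L]) - s[1L], 1L), d[1L])
        iy <- pmin(pmax(seq_len(d[2L]) - s[2L], 1L), d[2L])
        m[ix, iy] + s[3L] * config@zStepUm
      }
      tr$surface <- shMap(tr$surface)
      tr$scLed <- shMap(tr$scLed)
      tr$dej <- shMap(tr$dej)
      tr$labels <- shiftArray3d(tr$labels, s, fill = LABEL_BACKGROUND)
      for (mk in c("melaninMask", "elastinMask", "collagenMask"))
        tr[[mk]] <- shiftArray3d(tr[[mk]], s, fill = FALSE)
    }
    out[[r]] <- list(stack = stack, truth = tr)
  }
  out
}

# Multiplicative lognormal perturbation of the structural parameters of a
# configuration, emulating between-subject variability. Consumes RNG.
perturbConfig <- function(config, cv, seed) {
  fields <- c("scThicknessUm", "ledThicknessUm", "dejAmplitudeUm",
              "melBasalFraction", "elastinFraction", "collagenFraction")
  f <- exp(stats::rnorm(length(fields), sd = cv))
  args <- list(seed = as.integer(seed))
  for (i in seq_along(fields)) args[[fields[i]]] <- slot(config, fields[i]) * f[i]
  args$melBasalFraction <- min(args$melBasalFraction, 0.95)
  args$elastinFraction <- min(args$elastinFraction, 0.6)
  args$collagenFraction <- min(args$collagenFraction, 0.6)
  args$dejAmplitudeUm <- min(args$dejAmplitudeUm, 0.9 * args$ledThicknessUm)
  base <- sapply(slotNames("PhantomConfig"), function(s) slot(config, s),
                 simplify = FALSE)
  base[names(args)] <- args
  do.call(phantomConfig, base)
}

#' Generate a two-group phantom cohort
#'
#' Builds the two-level structure of the clinical studies: per-subject random
#' perturbation of the group configuration (between-subject variability) plus
#' independent acquisition noise per ROI.
#'
#' @param youngConfig,oldConfig group-level [PhantomConfig-class]s.
#' @param nPerGroup subjects per group (>= 2).
#' @param roisPerSubject adjacent ROIs acquired per subject.
#' @param betweenSubjectCv coefficient of variation of the multiplicative
#'   between-subject perturbation of the structural parameters.
#' @param seed integer seed for the whole cohort.
#' @return a data-frame-like list of records; each element has
#'   \code{subject}, \code{group}, \code{roi}, \code{stack}, \code{truth}.
#' @export
generateCohort <- function(youngConfig, oldConfig, nPerGroup = 5L,
                           roisPerSubject = 2L, betweenSubjectCv = 0.1,
                           seed = 1L) {
  stopifnot(nPerGroup >= 2L)
  records <- list()
  subjSeed <- 0L
  withSeed(seed, {
    for (g in c("young", "old")) {
      gcfg <- if (g == "young") youngConfig else oldConfig
      for (i in seq_len(nPerGroup)) {
        subjSeed <- subjSeed + 1L
        scfg <- perturbConfig(gcfg, betweenSubjectCv,
                              seed = seed + 100L * subjSeed)
        for (r in seq_len(roisPerSubject)) {
          rcfg <- scfg
          rcfg@seed <- as.integer(seed + 100L * subjSeed + r)
          ph <- generatePhantom(rcfg)
          records[[length(records) + 1L]] <- list(
            subject = sprintf("%s_%02d", g, i), group = g, roi = r,
            stack = ph$stack, truth = ph$truth)
        }
      }
    }
  })
  records
}
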