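# 3D skin layer segmentation: skin surface, SC/LED boundary and DEJ as
# regularized depth maps, composed into a voxel label volume.
#
# The surface detectors are deliberately simple and deterministic: columnwise
# threshold/gradient criteria on Gaussian-smoothed volumes, a
# smoothness-constrained minimal-cost surface (dynamic programming over a
# cost volume, max slope in z per lateral pixel) for the DEJ, and 5x5 median
# regularization of every map.

#' Segmentation parameters
#'
#' @param smoothSigmaVox length-3 Gaussian smoothing sigmas (x, y, z) in
#'   voxels applied to the intensity volumes before detection.
#' @param shgPresenceSigmaVox smoothing sigmas for the binary SHG-presence
#'   volume driving the DEJ cost; wider laterally because the collagen
#'   network is sparse at the voxel level.
#' @param backgroundK the background threshold is the top-plane mean plus
#'   \code{backgroundK} standard deviations (default 3).
#' @param minCoverage minimum fraction of columns that must cross the
#'   surface threshold; below it the stack is declared skin-free.
#' @param dejOccupancyFraction fraction of the deep-dermis SHG occupancy
#'   level above which a voxel counts as collagen-occupied in the DEJ
#'   changepoint cost.
#' @param dejPenalty changepoint penalty per occupancy-free plane below a
#'   candidate DEJ placement (occupied planes score +1).
#' @param maxSlopePlanes maximum DEJ depth change (in z-planes) between
#'   laterally adjacent pixels in the minimal-cost surface.
#' @param dejSlopePenalty soft cost per plane of lateral slope in the DEJ
#'   dynamic program (on the changepoint-score scale); damps plane-to-plane
#'   jitter on flat junctions without forbidding genuine undulation.
#' @param medianSize side of the square median-regularization window.
#' @param mapSmoothSigmaPx Gaussian smoothing sigma (pixels) applied to each
#'   regularized depth map; removes the z-quantization staircase that would
#'   otherwise inflate the normalized DEJ area.
#' @param priorScFraction fallback SC fraction of the epidermal thickness
#'   used when no SC/LED intensity contrast is detectable.
#' @param scContrastMin minimum top-band / mid-band intensity ratio required
#'   to trust the steepest-drop SC/LED detector.
#' @param noContrastBoundary where to place the SC/LED boundary when no
#'   contrast is found: \code{"prior"} (default; the prior fraction) or
#'   \code{"surface"} (collapse the SC to zero thickness).
#' @return a named list of parameters.
#' @export
segmentationParams <- function(smoothSigmaVox = c(1, 1, 1),
                               shgPresenceSigmaVox = c(2.5, 2.5, 0),
                               backgroundK = 3,
                               minCoverage = 0.5,
                               dejOccupancyFraction = 0.45,
                               dejPenalty = 1,
                               maxSlopePlanes = 2L,
                               dejSlopePenalty = 2,
                               medianSize = 5L,
                               mapSmoothSigmaPx = 2,
                               priorScFraction = 0.2,
                               scContrastMin = 1.15,
                               noContrastBoundary = c("prior", "surface")) {
  list(smoothSigmaVox = smoothSigmaVox,
       shgPresenceSigmaVox = shgPresenceSigmaVox, backgroundK = backgroundK,
       minCoverage = minCoverage,
       dejOccupancyFraction = dejOccupancyFraction, dejPenalty = dejPenalty,
       maxSlopePlanes = as.integer(maxSlopePlanes),
       dejSlopePenalty = dejSlopePenalty,
       medianSize = as.integer(medianSize),
       mapSmoothSigmaPx = mapSmoothSigmaPx,
       priorScFraction = priorScFraction, scContrastMin = scContrastMin,
       noContrastBoundary = match.arg(noContrastBoundary))
}

# First z index (per column) where the smoothed volume exceeds thr for two
# consecutive planes; NA when never.
firstCrossing <- function(sm, thr) {
  d <- dim(sm)
  v <- sm > thr
  v <- v[, , -d[3L], drop = FALSE] & v[, , -1L, drop = FALSE]
  m <- matrix(v, d[1L] * d[2L], d[3L] - 1L)
  any1 <- rowSums(m) > 0
  first <- max.col(m, ties.method = "first")
  first[!any1] <- NA_integer_
  matrix(first, d[1L], d[2L])
}

#' Detect the skin surface
#'
#' Per column, the surface is the first depth at which the Gaussian-smoothed
#' total-2PEF volume exceeds the detection threshold for two consecutive
#' planes, followed by 2D median regularization. The threshold is the larger
#' of the background level (top-plane mean + k standard deviations) and half
#' the column's maximum, so the crossing sits at the half-rise of the
#' smoothed signal edge rather than at its noise-level toe.
#'
#' @param stack a [MultiphotonStack-class].
#' @param params see [segmentationParams()].
#' @return a [DepthMap-class] named \code{"surface"}.
#' @export
detectSkinSurface <- function(stack, params = segmentationParams()) {
  tp <- gaussSmooth3d(totalPef(stack), params$smoothSigmaVox)
  top <- tp[, , 1L]
  bgThr <- mean(top) + params$backgroundK * stats::sd(top)
  colMax <- apply(tp, c(1L, 2L), max)
  thr <- repMap(pmax(colMax / 2, bgThr), dim(tp)[3L])
  cross <- firstCrossing(tp, thr)
  # columns whose maximum never clears the background level carry no skin
  cross[colMax <= bgThr] <- NA_integer_
  if (mean(!is.na(cross)) < params$minCoverage)
    stop("no skin detected: too few columns cross the background threshold")
  cross[is.na(cross)] <- stats::median(cross, na.rm = TRUE)
  # the surface lies between the last background plane and the first tissue
  # plane; place it midway
  depth <- pmax((cross - 1.5) * zStepUm(stack), 0)
  depth <- medianFilter2d(depth, params$medianSize)
  if (params$mapSmoothSigmaPx > 0)
    depth <- gaussSmooth2d(depth, params$mapSmoothSigmaPx)
  DepthMap(depth, "surface")
}

# Minimal-cost surface through a cost volume with a lateral slope constraint:
# dynamic programming along x independently for each y line, then median
# regularization across the map. Returns z indices (nx x ny).
minCostSurface <- function(cost, maxSlope, slopePenalty = 0) {
  d <- dim(cost)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  zidx <- matrix(0L, nx, ny)
  shifts <- -maxSlope:maxSlope
  for (y in seq_len(ny)) {
    C <- t(cost[, y, ])                  # nz x nx
    D <- matrix(0, nz, nx)
    ptr <- matrix(0L, nz, nx)
    D[, 1L] <- C[, 1L]
    for (x in 2:nx) {
      cand <- matrix(Inf, nz, length(shifts))
      for (t in seq_along(shifts)) {
        s <- shifts[t]
        src <- seq_len(nz) + s
        ok <- src >= 1L & src <= nz
        cand[ok, t] <- D[src[ok], x - 1L] + slopePenalty * abs(s)
      }
      best <- max.col(-cand, ties.method = "first")
      ptr[, x] <- seq_len(nz) + shifts[best]
      D[, x] <- C[, x] + cand[cbind(seq_len(nz), best)]
    }
    z <- which.min(D[, nx])
    zs <- integer(nx)
    zs[nx] <- z
    for (x in nx:2) {
      z <- ptr[z, x]
      zs[x - 1L] <- z
    }
    zidx[, y] <- zs
  }
  zidx
}

#' Detect the dermal-epidermal junction
#'
#' The DEJ is extracted as a smoothness-constrained minimal-cost surface
#' through a changepoint cost on the SHG-presence volume: voxels with SHG
#' above background are smoothed with a wide lateral kernel (the collagen
#' network is sparse at the voxel level) into an occupancy volume, and each
#' candidate depth is scored by the occupancy below it minus a penalty for
#' occupancy-free planes below, so the minimal-cost surface sits where
#' collagen occupancy turns on. A dynamic program per image line enforces a
#' maximum lateral slope; the resulting map is median-regularized and
#' clamped to lie at or below the skin surface.
#'
#' @param stack a [MultiphotonStack-class].
#' @param surface the skin-surface [DepthMap-class].
#' @param params see [segmentationParams()].
#' @return a [DepthMap-class] named \code{"dej"}.
#' @export
detectDejSurface <- function(stack, surface,
                             params = segmentationParams()) {
  shRaw <- shgVolume(stack)
  d <- dim(shRaw)
  nz <- d[3L]
  topShg <- shRaw[, , 1L]
  # background level from the top plane, guarded by Otsu on the whole volume
  # for stacks whose first plane already carries SHG signal
  thr <- min(mean(topShg) + params$backgroundK * stats::sd(topShg),
             otsuThreshold(as.vector(shRaw)))
  if (max(shRaw) <= thr)
    stop("no dermis detected: SHG signal absent everywhere")
  occ <- gaussSmooth3d((shRaw > thr) * 1, params$shgPresenceSigmaVox)
  # presence indicator: occupancy above a fraction of the deep-dermis level
  deepRef <- mean(occ[, , max(1L, nz - nz %/% 4L):nz])
  if (deepRef <= 0)
    stop("no dermis detected: SHG occupancy vanishes at depth")
  ind <- occ > params$dejOccupancyFraction * deepRef
  # changepoint score: each plane at or below the surface contributes +1 if
  # occupied, -penalty if not; cost(z) = -(score of placing the DEJ at z)
  pen <- params$dejPenalty
  g <- ind * (1 + pen) - pen
  revcum <- apply(g, c(1L, 2L), function(v) rev(cumsum(rev(v))))
  cost <- -aperm(revcum, c(2L, 3L, 1L))
  # forbid placements at or above the skin surface
  surfIdx <- round(depthValues(surface) / zStepUm(stack)) + 1L
  big <- max(abs(cost)) * nz + 1
  depthIdx <- array(rep(seq_len(nz), each = d[1L] * d[2L]), d)
  cost[depthIdx <= repMap(surfIdx, nz)] <- big
  zidx <- minCostSurface(cost, params$maxSlopePlanes, params$dejSlopePenalty)
  # the junction lies between the last epidermal plane and the occupancy
  # onset plane; the unbiased continuous estimate is their midpoint (voxel
  # labelling assigns the onset plane itself to the dermis — half-voxel
  # rounding convention, see segmentStack)
  depth <- pmax((zidx - 1.5) * zStepUm(stack), 0)
  depth <- medianFilter2d(depth, params$medianSize)
  if (params$mapSmoothSigmaPx > 0)
    depth <- gaussSmooth2d(depth, params$mapSmoothSigmaPx)
  depth <- pmax(depth, depthValues(surface))
  DepthMap(depth, "dej")
}

#' Split the epidermis into stratum corneum and living epidermis
#'
#' Per column, the SC/LED boundary is placed at the steepest drop of the
#' smoothed total-2PEF intensity below the surface (the SC is brighter than
#' the LED), restricted to the upper part of the epidermis, then clamped to
#' \code{[surface, dej]} and median-regularized. Columns without a detectable
#' SC/LED contrast fall back to a configured prior fraction of the epidermal
#' thickness (with a warning); epidermides thinner than 2 z-steps get the
#' midpoint.
#'
#' @param stack a [MultiphotonStack-class].
#' @param surface,dej the bounding [DepthMap-class]s.
#' @param params see [segmentationParams()].
#' @return a [DepthMap-class] named \code{"sc_led"}.
#' @export
splitScLed <- function(stack, surface, dej,
                       params = segmentationParams()) {
  tp <- gaussSmooth3d(totalPef(stack), params$smoothSigmaVox)
  d <- dim(tp)
  nz <- d[3L]
  zs <- zStepUm(stack)
  surf <- depthValues(surface)
  dejv <- depthValues(dej)
  epi <- dejv - surf
  m <- matrix(aperm(tp, c(3L, 1L, 2L)), nz)   # nz x (nx*ny)
  grad <- m[-1L, , drop = FALSE] - m[-nz, , drop = FALSE]  # at z+1/2
  surfIdx <- pmax(1L, pmin(nz, round(surf / zs) + 1L))
  dejIdx <- pmax(1L, pmin(nz, round(dejv / zs) + 1L))
  ncol_ <- ncol(m)
  bound <- numeric(ncol_)
  nFallback <- 0L
  nThin <- 0L
  for (j in seq_len(ncol_)) {
    s <- surfIdx[j]; e <- dejIdx[j]
    if (e - s < 2L) {                      # epidermis thinner than 2 z-steps
      bound[j] <- (surf[j] + dejv[j]) / 2
      nThin <- nThin + 1L
      next
    }
    # search the steepest drop within the top 60 % of the epidermis
    hi <- s + max(2L, ceiling(0.6 * (e - s)))
    hi <- min(hi, e - 1L)
    zrange <- s:hi
    g <- grad[pmin(zrange, nz - 1L), j]
    k <- zrange[which.min(g)]
    # contrast check: intensity above the candidate vs mid-epidermis
    above <- mean(m[s:k, j])
    midlo <- min(e - 1L, k + 1L)
    below <- mean(m[midlo:(e - 1L), j])
    if (below <= 0 || above / below < params$scContrastMin) {
      nFallback <- nFallback + 1L
      bound[j] <- if (params$noContrastBoundary == "surface") surf[j]
                  else surf[j] + params$priorScFraction * epi[j]
    } else {
      bound[j] <- (k - 1L) * zs + zs / 2   # drop sits between k and k+1
    }
  }
  if (nThin > 0L)
    warning(nThin, " columns with epidermis thinner than 2 z-steps; ",
            "boundary set to the midpoint")
  if (nFallback > 0L)
    warning(nFallback, " columns without SC/LED contrast; boundary set to ",
            if (params$noContrastBoundary == "surface") "the surface"
            else sprintf("the prior fraction (%.2f of epidermal thickness)",
                         params$priorScFraction))
  bmap <- matrix(bound, d[1L], d[2L])
  bmap <- medianFilter2d(bmap, params$medianSize)
  if (params$mapSmoothSigmaPx > 0)
    bmap <- gaussSmooth2d(bmap, params$mapSmoothSigmaPx)
  bmap <- pmin(pmax(bmap, surf), dejv)
  DepthMap(bmap, "sc_led")
}

#' Segment a stack into background, SC, LED and dermis
#'
#' Composes [detectSkinSurface()], [detectDejSurface()] and [splitScLed()],
#' enforces the depth ordering surface <= sc_led <= dej by projection, and
#' labels every voxel by comparing its plane depth with the three maps.
#'
#' @param stack a [MultiphotonStack-class].
#' @param params see [segmentationParams()].
#' @return a [LayerSegmentation-class].
#' @export
segmentStack <- function(stack, params = segmentationParams()) {
  surface <- detectSkinSurface(stack, params)
  dej <- detectDejSurface(stack, surface, params)
  if (mean(depthValues(dej) - depthValues(surface)) < 2 * zStepUm(stack))
    stop("empty epidermis: DEJ collapses onto the skin surface")
  scLed <- splitScLed(stack, surface, dej, params)
  b <- pmin(pmax(depthValues(scLed), depthValues(surface)),
            depthValues(dej))
  scLed <- DepthMap(b, "sc_led")
  d <- dim(stack)[1:3]
  depth <- depthVolume(d, zStepUm(stack))
  nz <- d[3L]
  tol <- 1e-6   # guard against round-off in the regularized maps
  # half-voxel convention at the DEJ: the map is the continuous mid-plane
  # estimate, and the voxel plane nearest below it (the occupancy onset
  # plane, half a z-step deeper) is the first dermal plane
  labels <- (depth >= repMap(depthValues(surface), nz) - tol) +
    (depth >= repMap(b, nz) - tol) +
    (depth >= repMap(depthValues(dej), nz) + zStepUm(stack) / 2 - tol)
  storage.mode(labels) <- "integer"
  new("LayerSegmentation", labels = labels, surface = surface,
      scLed = scLed, dej = dej, zStepUm = zStepUm(stack),
      pixelSizeUm = pixelSizeUm(stack))
}
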