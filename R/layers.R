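# Sublayer partitions and 3D morphological metrics: thickness-normalized
# epidermal sublayers, DEJ-shape-following dermal bands, thickness maps and
# the normalized DEJ area.

#' Thickness-normalized epidermal sublayers
#'
#' Divides the epidermis of every column into K sublayers of equal
#' normalized thickness that follow the 3D shape of the DEJ and the skin
#' surface. A voxel at depth z gets index
#' \code{ceiling(K * (dej - z) / (dej - surface))} clamped to [1, K], so
#' index 1 touches the DEJ and index K the stratum corneum. Columns with zero
#' epidermal thickness are excluded (with a warning).
#'
#' @param seg a [LayerSegmentation-class].
#' @param K number of sublayers (default 10).
#' @return a [SublayerPartition-class] of kind \code{epidermal_normalized}.
#' @export
epidermalSublayers <- function(seg, K = 10L) {
  K <- as.integer(K)
  d <- dim(seg@labels)
  nz <- d[3L]
  depth <- depthVolume(d, seg@zStepUm)
  surf <- repMap(seg@surface@values, nz)
  dej <- repMap(seg@dej@values, nz)
  thick <- dej - surf
  epi <- seg@labels == LABEL_SC | seg@labels == LABEL_LED
  zero <- seg@dej@values - seg@surface@values <= 0
  if (any(zero))
    warning(sum(zero), " zero-thickness columns excluded from the partition")
  idx <- array(0L, d)
  ok <- epi & thick > 0
  k <- ceiling(K * (dej[ok] - depth[ok]) / thick[ok])
  idx[ok] <- pmin(pmax(as.integer(k), 1L), K)
  new("SublayerPartition", index = idx, kind = "epidermal_normalized",
      nSublayers = K, bandThicknessUm = NA_real_)
}

#' Fixed-thickness dermal bands following the DEJ shape
#'
#' Divides the imaged dermis into bands of fixed physical thickness measured
#' axially below the DEJ map: band k holds voxels at depth-below-DEJ
#' \code{[(k-1) * bandUm, k * bandUm)}. Dermal voxels deeper than
#' \code{nBands * bandUm} fall in the flagged remainder band (index
#' \code{nBands + 1}), which headline metrics exclude.
#'
#' @param seg a [LayerSegmentation-class].
#' @param bandUm band thickness in micrometres (10, 20 and 50 are typical).
#' @param nBands number of regular bands.
#' @return a [SublayerPartition-class] of kind \code{dermal_fixed}.
#' @export
dermalSublayers <- function(seg, bandUm = 20, nBands = 2L) {
  nBands <- as.integer(nBands)
  d <- dim(seg@labels)
  nz <- d[3L]
  depth <- depthVolume(d, seg@zStepUm)
  below <- depth - repMap(seg@dej@values, nz)
  idx <- array(0L, d)
  dermis <- seg@labels == LABEL_DERMIS
  band <- as.integer(floor(pmax(below[dermis], 0) / bandUm)) + 1L
  band[band > nBands] <- nBands + 1L
  idx[dermis] <- band
  new("SublayerPartition", index = idx, kind = "dermal_fixed",
      nSublayers = nBands, bandThicknessUm = as.numeric(bandUm))
}

#' Per-column thickness maps
#'
#' @param seg a [LayerSegmentation-class].
#' @return a list of three numeric matrices (micrometres): \code{sc},
#'   \code{led}, \code{epidermis}; by construction
#'   \code{epidermis = sc + led} pointwise.
#' @export
thicknessMaps <- function(seg) {
  list(sc = seg@scLed@values - seg@surface@values,
       led = seg@dej@values - seg@scLed@values,
       epidermis = seg@dej@values - seg@surface@values)
}

#' Normalized DEJ area (3D undulation index)
#'
#' Ratio of the 3D area of the DEJ heightfield to the area of its projection
#' on a horizontal plane: 1 for a flat junction, larger the more undulated
#' the DEJ. The heightfield is triangulated with two triangles per pixel quad
#' (same diagonal everywhere) and the 3D triangle areas are summed.
#'
#' @param dej a [DepthMap-class] or a numeric depth matrix (micrometres).
#' @param pixelSizeUm lateral pixel size, micrometres.
#' @return a number >= 1.
#' @examples
#' dejNormalizedArea(matrix(5, 32, 32), 1)        # flat: exactly 1
#' @export
dejNormalizedArea <- function(dej, pixelSizeUm) {
  z <- if (is(dej, "DepthMap")) dej@values else dej
  p <- pixelSizeUm
  n <- nrow(z); m <- ncol(z)
  z11 <- z[-n, -m]; z21 <- z[-1L, -m]; z12 <- z[-n, -1L]; z22 <- z[-1L, -1L]
  b <- z21 - z11; c_ <- z22 - z11; d_ <- z12 - z11
  a1 <- 0.5 * p * sqrt(b^2 + (b - c_)^2 + p^2)
  a2 <- 0.5 * p * sqrt((d_ - c_)^2 + d_^2 + p^2)
  sum(a1 + a2) / ((n - 1L) * (m - 1L) * p^2)
}

#' Morphological metrics of a segmented stack
#'
#' Mean SC, LED and epidermal thickness plus the normalized DEJ area.
#' The mean epidermal thickness equals the sum of the SC and LED means
#' exactly.
#'
#' @param seg a [LayerSegmentation-class].
#' @return a named list: \code{meanScThicknessUm}, \code{meanLedThicknessUm},
#'   \code{meanEpidermalThicknessUm}, \code{dejNormalizedArea}.
#' @export
morphologyMetrics <- function(seg) {
  tm <- thicknessMaps(seg)
  list(meanScThicknessUm = mean(tm$sc),
       meanLedThicknessUm = mean(tm$led),
       meanEpidermalThicknessUm = mean(tm$epidermis),
       dejNormalizedArea = dejNormalizedArea(seg@dej, seg@pixelSizeUm))
}
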