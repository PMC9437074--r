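# Dermal fiber quantification: elastin (2PEF) and fibrillar collagen (SHG)
# masks, 3D densities, the SHGto2PEF ratio, the 3D SAAID density index, the
# normalized imbrication index ImbrN, z-dermal profiles and per-layer mean
# intensities.

#' Threshold the dermal 2PEF and SHG signals into fiber masks
#'
#' Within the dermis only, the total-2PEF volume is thresholded into a
#' "mainly elastin" mask and the SHG volume into a fibrillar-collagen mask.
#' The default threshold is Otsu's method on the within-dermis intensity
#' histogram, per channel and per stack; the \code{k_sigma} alternative uses
#' the background (above-surface) mean plus k standard deviations. The
#' thresholds used are recorded in the result for provenance.
#'
#' @param stack a [MultiphotonStack-class].
#' @param seg a [LayerSegmentation-class].
#' @param method \code{"otsu"} (default) or \code{"k_sigma"}.
#' @param k multiplier for the \code{k_sigma} method.
#' @return a list: \code{elastin}, \code{collagen} (logical 3D masks,
#'   subsets of the dermis labels) and \code{thresholds} (named numeric).
#' @export
fiberMasks <- function(stack, seg, method = c("otsu", "k_sigma"), k = 3) {
  method <- match.arg(method)
  dermis <- seg@labels == LABEL_DERMIS
  if (!any(dermis)) stop("dermis is empty")
  tp <- totalPef(stack)
  sh <- shgVolume(stack)
  thr <- function(vol) {
    v <- vol[dermis]
    if (method == "otsu") {
      if (max(v) == 0) return(0)
      otsuThreshold(v)
    } else {
      bg <- vol[seg@labels == LABEL_BACKGROUND]
      if (length(bg) < 2L) bg <- v
      mean(bg) + k * stats::sd(bg)
    }
  }
  tPef <- thr(tp)
  tShg <- thr(sh)
  list(elastin = dermis & tp > tPef,
       collagen = dermis & sh > tShg,
       thresholds = c(pef = tPef, shg = tShg))
}

# Resolve a scope argument into a logical volume: NULL = whole dermis,
# a SublayerPartition + band = that band, or a logical array used as-is.
resolveScope <- function(seg, scope = NULL, band = NULL) {
  if (is.null(scope)) return(seg@labels == LABEL_DERMIS)
  if (is(scope, "SublayerPartition")) {
    if (is.null(band)) stop("give the band index with a partition scope")
    return(sublayerIndex(scope) == as.integer(band))
  }
  if (is.logical(scope) && length(dim(scope)) == 3L) return(scope)
  stop("scope must be NULL, a SublayerPartition, or a logical 3D array")
}

#' 3D fiber densities
#'
#' Fraction of scope voxels covered by each fiber mask.
#'
#' @param masks result of [fiberMasks()] (or any list with logical
#'   \code{elastin} and \code{collagen} volumes).
#' @param seg a [LayerSegmentation-class].
#' @param scope \code{NULL} for the whole imaged dermis, a
#'   [SublayerPartition-class] (with \code{band}), or a logical 3D array.
#' @param band band index when \code{scope} is a partition.
#' @return named numeric: \code{elastin}, \code{collagen} densities in
#'   [0, 1].
#' @export
fiberDensity <- function(masks, seg, scope = NULL, band = NULL) {
  sc <- resolveScope(seg, scope, band)
  n <- sum(sc)
  if (n == 0L) stop("empty scope")
  c(elastin = sum(masks$elastin & sc) / n,
    collagen = sum(masks$collagen & sc) / n)
}

#' SHGto2PEF collagen-to-elastin densities ratio
#'
#' @param densities named numeric with \code{elastin} and \code{collagen}
#'   (as returned by [fiberDensity()]).
#' @return collagen density / elastin density; \code{NA} (with a warning)
#'   when the elastin density is zero.
#' @export
shgTo2pefRatio <- function(densities) {
  e <- densities[["elastin"]]; c_ <- densities[["collagen"]]
  if (e == 0) {
    warning("elastin density is zero; SHGto2PEF undefined")
    return(NA_real_)
  }
  c_ / e
}

#' 3D SAAID fibers density index
#'
#' The SHG-to-autofluorescence aging index of dermis on densities:
#' (collagen - elastin) / (collagen + elastin), in [-1, 1]. Decreases with
#' aging as elastin (elastosis) accumulates.
#'
#' @inheritParams shgTo2pefRatio
#' @return index in [-1, 1]; \code{NA} (with a warning) when both densities
#'   are zero.
#' @export
saaidIndex <- function(densities) {
  e <- densities[["elastin"]]; c_ <- densities[["collagen"]]
  if (e + c_ == 0) {
    warning("both fiber densities are zero; SAAID undefined")
    return(NA_real_)
  }
  (c_ - e) / (c_ + e)
}

#' Normalized imbrication index (ImbrN)
#'
#' Jaccard overlap of the elastin and collagen masks within the scope:
#' intersection volume / union volume, in [0, 1]. Large values mean the two
#' fiber networks are spatially correlated (entangled); low values that they
#' are mutually exclusive. An optional tolerance dilation (default 0) dilates
#' both masks by a physical radius before the overlap, accommodating
#' one-voxel offsets between the networks.
#'
#' @param masks list with logical \code{elastin} and \code{collagen} volumes.
#' @param seg a [LayerSegmentation-class] (for the default whole-dermis
#'   scope and voxel geometry).
#' @param scope,band see [fiberDensity()].
#' @param toleranceUm dilation radius in micrometres (default 0: raw masks).
#' @return index in [0, 1]; \code{NA} (with a warning) for an empty union.
#' @export
imbricationIndex <- function(masks, seg, scope = NULL, band = NULL,
                             toleranceUm = 0) {
  sc <- resolveScope(seg, scope, band)
  e <- masks$elastin
  c_ <- masks$collagen
  if (toleranceUm > 0) {
    e <- dilateMask3d(e, toleranceUm, seg@pixelSizeUm, seg@zStepUm)
    c_ <- dilateMask3d(c_, toleranceUm, seg@pixelSizeUm, seg@zStepUm)
  }
  un <- sum((e | c_) & sc)
  if (un == 0L) {
    warning("empty union of fiber masks in scope; ImbrN undefined")
    return(NA_real_)
  }
  sum(e & c_ & sc) / un
}

#' z-dermal distribution profiles of the fiber metrics
#'
#' Per sublayer of a dermal partition: elastin and collagen densities,
#' SHGto2PEF ratio, SAAID and ImbrN. The remainder band (variable thickness,
#' often low signal) is reported but flagged so headline analyses can
#' exclude it.
#'
#' @param masks result of [fiberMasks()].
#' @param seg a [LayerSegmentation-class].
#' @param partition a dermal [SublayerPartition-class].
#' @return a data.frame with one row per band: \code{band},
#'   \code{depthFromUm}, \code{depthToUm}, \code{isRemainder},
#'   \code{nVoxels}, \code{elastinDensity}, \code{collagenDensity},
#'   \code{shgTo2pef}, \code{saaid}, \code{imbrn}.
#' @export
dermalZProfiles <- function(masks, seg, partition) {
  if (partition@kind != "dermal_fixed")
    stop("dermalZProfiles needs a dermal_fixed partition")
  K <- partition@nSublayers
  T_ <- partition@bandThicknessUm
  rows <- lapply(seq_len(K + 1L), function(k) {
    sc <- sublayerIndex(partition) == k
    n <- sum(sc)
    if (n == 0L)
      return(data.frame(band = k, depthFromUm = (k - 1) * T_,
                        depthToUm = if (k <= K) k * T_ else NA_real_,
                        isRemainder = k > K, nVoxels = 0L,
                        elastinDensity = NA_real_,
                        collagenDensity = NA_real_, shgTo2pef = NA_real_,
                        saaid = NA_real_, imbrn = NA_real_))
    dens <- fiberDensity(masks, seg, scope = sc)
    un <- sum((masks$elastin | masks$collagen) & sc)
    data.frame(
      band = k,
      depthFromUm = (k - 1) * T_,
      depthToUm = if (k <= K) k * T_ else NA_real_,
      isRemainder = k > K,
      nVoxels = n,
      elastinDensity = dens[["elastin"]],
      collagenDensity = dens[["collagen"]],
      shgTo2pef = if (dens[["elastin"]] > 0)
        dens[["collagen"]] / dens[["elastin"]] else NA_real_,
      saaid = if (sum(dens) > 0)
        (dens[["collagen"]] - dens[["elastin"]]) / sum(dens) else NA_real_,
      imbrn = if (un > 0)
        sum(masks$elastin & masks$collagen & sc) / un else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Mean signal intensities within a segmented scope
#'
#' Arithmetic mean of the raw counts within the scope, for the summed 2PEF
#' time channels and for the SHG channel.
#'
#' @param stack a [MultiphotonStack-class].
#' @param seg a [LayerSegmentation-class].
#' @param scope a label code ([LABEL_SC], [LABEL_LED], [LABEL_DERMIS]), a
#'   logical 3D array, or \code{NULL} for the whole stack.
#' @return named numeric: \code{pef}, \code{shg}.
#' @export
layerMeanIntensity <- function(stack, seg = NULL, scope = NULL) {
  tp <- totalPef(stack)
  sh <- shgVolume(stack)
  sc <- if (is.null(scope)) array(TRUE, dim(tp))
        else if (is.numeric(scope) && length(scope) == 1L) {
          if (is.null(seg)) stop("label scopes need a segmentation")
          seg@labels == as.integer(scope)
        } else if (is.logical(scope)) scope
        else stop("scope must be NULL, a label code, or a logical array")
  if (!any(sc)) stop("empty scope")
  c(pef = mean(tp[sc]), shg = mean(sh[sc]))
}
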