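# Constructors, accessors and show methods for the S4 containers.

#' Construct acquisition metadata
#'
#' @param pixelSizeUm lateral pixel size, micrometres.
#' @param zStepUm z-step between planes, micrometres.
#' @param nTimeChannels number of temporally binned 2PEF channels.
#' @param timeChannelWidthNs temporal bin width, nanoseconds.
#' @param shgChannelIndex 1-based index of the SHG channel.
#' @param excitationPowerProfile optional 2-column matrix (depth um, mW).
#' @return an [AcquisitionMeta-class] object.
#' @examples
#' AcquisitionMeta(pixelSizeUm = 0.255, zStepUm = 2.346)
#' @export
AcquisitionMeta <- function(pixelSizeUm, zStepUm, nTimeChannels = 4L,
                            timeChannelWidthNs = 2.08,
                            shgChannelIndex = nTimeChannels + 1L,
                            excitationPowerProfile = NULL) {
  new("AcquisitionMeta",
      pixelSizeUm = as.numeric(pixelSizeUm),
      zStepUm = as.numeric(zStepUm),
      nTimeChannels = as.integer(nTimeChannels),
      timeChannelWidthNs = as.numeric(timeChannelWidthNs),
      shgChannelIndex = as.integer(shgChannelIndex),
      excitationPowerProfile = excitationPowerProfile)
}

#' Construct a multiphoton stack
#'
#' @param intensities 4D non-negative array (x, y, z, channel).
#' @param meta an [AcquisitionMeta-class] object.
#' @param roiId character ROI identifier.
#' @return a [MultiphotonStack-class] object.
#' @export
MultiphotonStack <- function(intensities, meta, roiId = "roi") {
  storage.mode(intensities) <- "integer"
  new("MultiphotonStack", intensities = intensities, meta = meta,
      roiId = as.character(roiId))
}

#' @rdname MultiphotonStack-class
#' @export
setMethod("intensities", "MultiphotonStack", function(x) x@intensities)

#' @rdname MultiphotonStack-class
#' @export
setMethod("acquisitionMeta", "MultiphotonStack", function(x) x@meta)

#' @rdname MultiphotonStack-class
#' @export
setMethod("roiId", "MultiphotonStack", function(x) x@roiId)

#' @rdname MultiphotonStack-class
#' @export
setMethod("dim", "MultiphotonStack", function(x) dim(x@intensities))

#' @rdname AcquisitionMeta-class
#' @export
setMethod("pixelSizeUm", "AcquisitionMeta", function(x) x@pixelSizeUm)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("pixelSizeUm", "MultiphotonStack", function(x) x@meta@pixelSizeUm)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("zStepUm", "AcquisitionMeta", function(x) x@zStepUm)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("zStepUm", "MultiphotonStack", function(x) x@meta@zStepUm)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("zStepUm", "LayerSegmentation", function(x) x@zStepUm)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("nTimeChannels", "AcquisitionMeta", function(x) x@nTimeChannels)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("nTimeChannels", "MultiphotonStack",
          function(x) x@meta@nTimeChannels)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("timeChannelWidthNs", "AcquisitionMeta",
          function(x) x@timeChannelWidthNs)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("timeChannelWidthNs", "MultiphotonStack",
          function(x) x@meta@timeChannelWidthNs)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("shgChannelIndex", "AcquisitionMeta", function(x) x@shgChannelIndex)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("shgChannelIndex", "MultiphotonStack",
          function(x) x@meta@shgChannelIndex)

#' Construct a depth map
#'
#' @param values numeric matrix of depths (micrometres).
#' @param name one of \code{"surface"}, \code{"sc_led"}, \code{"dej"}.
#' @return a [DepthMap-class] object.
#' @export
DepthMap <- function(values, name) {
  new("DepthMap", values = values, name = name)
}

#' @rdname DepthMap-class
#' @export
setMethod("depthValues", "DepthMap", function(x) x@values)

#' @rdname LayerSegmentation-class
#' @export
setMethod("labels3d", "LayerSegmentation", function(x) x@labels)
#' @rdname LayerSegmentation-class
#' @export
setMethod("surfaceMap", "LayerSegmentation", function(x) x@surface)
#' @rdname LayerSegmentation-class
#' @export
setMethod("scLedMap", "LayerSegmentation", function(x) x@scLed)
#' @rdname LayerSegmentation-class
#' @export
setMethod("dejMap", "LayerSegmentation", function(x) x@dej)

#' @rdname SublayerPartition-class
#' @export
setMethod("sublayerIndex", "SublayerPartition", function(x) x@index)
#' @rdname SublayerPartition-class
#' @export
setMethod("nSublayers", "SublayerPartition", function(x) x@nSublayers)

setMethod("show", "AcquisitionMeta", function(object) {
  cat("AcquisitionMeta:", object@nTimeChannels, "time channels x",
      object@timeChannelWidthNs, "ns + SHG (channel",
      paste0(object@shgChannelIndex, ");"),
      object@pixelSizeUm, "um/pixel,", object@zStepUm, "um z-step\n")
})

setMethod("show", "MultiphotonStack", function(object) {
  d <- dim(object@intensities)
  cat("MultiphotonStack '", object@roiId, "': ",
      d[1], " x ", d[2], " x ", d[3], " voxels, ", d[4], " channels\n",
      sep = "")
  show(object@meta)
  cat("  depth range: 0 -", round((d[3] - 1) * object@meta@zStepUm, 2),
      "um; max count:", max(object@intensities), "\n")
})

setMethod("show", "DepthMap", function(object) {
  cat("DepthMap '", object@name, "' (", nrow(object@values), " x ",
      ncol(object@values), "): depth ", round(min(object@values), 2), " - ",
      round(max(object@values), 2), " um\n", sep = "")
})

setMethod("show", "LayerSegmentation", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 4L)
  cat("LayerSegmentation:", paste(dim(object@labels), collapse = " x "),
      "voxels\n  background:", tab[1], " SC:", tab[2], " LED:", tab[3],
      " dermis:", tab[4], "\n")
})

setMethod("show", "SublayerPartition", function(object) {
  cat("SublayerPartition (", object@kind, "): K = ", object@nSublayers,
      if (object@kind == "dermal_fixed")
        paste0(", band ", object@bandThicknessUm, " um + remainder"),
      "; voxels in partition: ", sum(object@index > 0L), "\n", sep = "")
})

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig: ", paste(object@dims, collapse = " x "), " voxels, ",
      object@pixelSizeUm, " um/pixel, ", object@zStepUm, " um z-step\n",
      "  SC ", object@scThicknessUm, " um, LED ", object@ledThicknessUm,
      " um, DEJ ", object@dejWaveform, " amplitude ", object@dejAmplitudeUm,
      " um / period ", object@dejPeriodUm, " um\n",
      "  melanin basal fraction ", object@melBasalFraction,
      " (lifetime ", object@melLifetimeNs, " ns), elastin ",
      object@elastinFraction, ", collagen ", object@collagenFraction,
      ", overlap bias ", object@fiberOverlapBias, "\n",
      "  photon budget ", object@photonBudget, ", seed ", object@seed, "\n",
      sep = "")
})
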