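#' @rdname MultiphotonStack-class
#' @param object,x a \code{MultiphotonStack}.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname MultiphotonStack-class
#' @export
setGeneric("acquisitionMeta", function(x) standardGeneric("acquisitionMeta"))

#' @rdname MultiphotonStack-class
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname AcquisitionMeta-class
#' @param x an \code{AcquisitionMeta} (or an object carrying one).
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname AcquisitionMeta-class
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))

#' @rdname AcquisitionMeta-class
#' @export
setGeneric("nTimeChannels", function(x) standardGeneric("nTimeChannels"))

#' @rdname AcquisitionMeta-class
#' @export
setGeneric("timeChannelWidthNs",
           function(x) standardGeneric("timeChannelWidthNs"))

#' @rdname AcquisitionMeta-class
#' @export
setGeneric("shgChannelIndex", function(x) standardGeneric("shgChannelIndex"))

#' @rdname DepthMap-class
#' @param x a \code{DepthMap}.
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))

#' @rdname LayerSegmentation-class
#' @param x a \code{LayerSegmentation}.
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))

#' @rdname LayerSegmentation-class
#' @export
setGeneric("surfaceMap", function(x) standardGeneric("surfaceMap"))

#' @rdname LayerSegmentation-class
#' @export
setGeneric("scLedMap", function(x) standardGeneric("scLedMap"))

#' @rdname LayerSegmentation-class
#' @export
setGeneric("dejMap", function(x) standardGeneric("dejMap"))

#' @rdname SublayerPartition-class
#' @param x a \code{SublayerPartition}.
#' @export
setGeneric("sublayerIndex", function(x) standardGeneric("sublayerIndex"))

#' @rdname SublayerPartition-class
#' @export
setGeneric("nSublayers", function(x) standardGeneric("nSublayers"))
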