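#' @import methods
NULL

#' Acquisition metadata for a multiphoton z-stack
#'
#' Describes the sampling of a combined 2PEF-FLIM/SHG acquisition: lateral
#' pixel size, axial z-step, the number and temporal width of the FLIM time
#' channels, and which channel carries the SHG signal. All indices are 1-based;
#' the physical depth of plane \code{k} is \code{(k - 1) * zStepUm(meta)}
#' micrometres below the first acquired plane.
#'
#' @slot pixelSizeUm lateral pixel size in micrometres (isotropic in x, y).
#' @slot zStepUm axial step between consecutive planes, micrometres.
#' @slot nTimeChannels number of temporally binned 2PEF channels (>= 2).
#' @slot timeChannelWidthNs width of one temporal bin, nanoseconds.
#' @slot shgChannelIndex 1-based index of the SHG channel; must not collide
#'   with the time channels \code{1:nTimeChannels}.
#' @slot excitationPowerProfile optional two-column matrix (depth um, mW)
#'   recording the depth-dependent excitation power, or \code{NULL}.
#'
#' @seealso [AcquisitionMeta()] for the user-facing constructor.
#' @export
setClass("AcquisitionMeta",
  representation(
    pixelSizeUm = "numeric",
    zStepUm = "numeric",
    nTimeChannels = "integer",
    timeChannelWidthNs = "numeric",
    shgChannelIndex = "integer",
    excitationPowerProfile = "ANY"
  )
)

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@zStepUm) != 1L || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    msg <- c(msg, "zStepUm must be a single positive number")
  if (length(object@nTimeChannels) != 1L || object@nTimeChannels < 2L)
    msg <- c(msg, "nTimeChannels must be >= 2")
  if (length(object@timeChannelWidthNs) != 1L || object@timeChannelWidthNs <= 0)
    msg <- c(msg, "timeChannelWidthNs must be positive")
  if (length(object@shgChannelIndex) != 1L ||
      object@shgChannelIndex %in% seq_len(object@nTimeChannels))
    msg <- c(msg, "shgChannelIndex must not be a time-channel index")
  p <- object@excitationPowerProfile
  if (!is.null(p) && (!is.matrix(p) || ncol(p) != 2L))
    msg <- c(msg, "excitationPowerProfile must be NULL or a 2-column matrix")
  if (length(msg)) msg else TRUE
})

#' Multichannel multiphoton z-stack
#'
#' The universal input container: a 4D non-negative integer volume indexed
#' (x, y, z, channel), where channels \code{1:nTimeChannels} are the
#' temporally binned 2PEF-FLIM channels (ascending time) and the last channel
#' is SHG. The z axis follows the acquisition convention: plane 1 is the
#' shallowest plane and depth increases with z index.
#'
#' @slot intensities 4D array of non-negative counts, dims (nx, ny, nz,
#'   nTimeChannels + 1).
#' @slot meta an [AcquisitionMeta-class] object.
#' @slot roiId character identifier of the acquired region of interest.
#'
#' @seealso [MultiphotonStack()] constructor, [readStack()], [writeStack()].
#' @export
setClass("MultiphotonStack",
  representation(
    intensities = "array",
    meta = "AcquisitionMeta",
    roiId = "character"
  )
)

setValidity("MultiphotonStack", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 4L)
    msg <- c(msg, "intensities must be a 4D (x, y, z, channel) array")
  else {
    if (d[4L] != object@meta@nTimeChannels + 1L)
      msg <- c(msg, sprintf("channel count mismatch: expected %d, got %d",
                            object@meta@nTimeChannels + 1L, d[4L]))
    if (d[1L] < 32L || d[2L] < 32L || d[3L] < 8L)
      msg <- c(msg, "spatial dims must be at least 32 x 32 x 8")
  }
  if (anyNA(object@intensities))
    msg <- c(msg, "intensities contain missing values")
  else if (min(object@intensities) < 0)
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@roiId) != 1L)
    msg <- c(msg, "roiId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Per-column surface depth map
#'
#' One depth value (micrometres below the first acquired plane) per lateral
#' (x, y) position, describing one of the three skin surfaces: the skin
#' surface, the stratum corneum / living epidermis boundary, or the
#' dermal-epidermal junction (DEJ).
#'
#' @slot values numeric matrix (nx x ny) of depths in micrometres.
#' @slot name one of \code{"surface"}, \code{"sc_led"}, \code{"dej"}.
#' @export
setClass("DepthMap",
  representation(values = "matrix", name = "character")
)

setValidity("DepthMap", function(object) {
  msg <- character()
  if (!all(is.finite(object@values)))
    msg <- c(msg, "depth values must be finite everywhere")
  if (length(object@name) != 1L ||
      !object@name %in% c("surface", "sc_led", "dej"))
    msg <- c(msg, "name must be one of 'surface', 'sc_led', 'dej'")
  if (length(msg)) msg else TRUE
})

#' Voxel label volume of the segmented skin layers
#'
#' Labels every voxel as background (above the skin surface), stratum corneum
#' (SC), living epidermis (LED) or dermis, consistently with the three depth
#' maps that generated it. Label codes are exported as [LABEL_BACKGROUND],
#' [LABEL_SC], [LABEL_LED], [LABEL_DERMIS].
#'
#' @slot labels 3D integer array over \{0 background, 1 SC, 2 LED, 3 dermis\}.
#' @slot surface,scLed,dej the three [DepthMap-class]s (ordered
#'   surface <= scLed <= dej pointwise).
#' @slot zStepUm axial step of the source stack, micrometres.
#' @slot pixelSizeUm lateral pixel size of the source stack, micrometres.
#' @export
setClass("LayerSegmentation",
  representation(
    labels = "array",
    surface = "DepthMap",
    scLed = "DepthMap",
    dej = "DepthMap",
    zStepUm = "numeric",
    pixelSizeUm = "numeric"
  )
)

#' @rdname LayerSegmentation-class
#' @format NULL
#' @export
LABEL_BACKGROUND <- 0L
#' @rdname LayerSegmentation-class
#' @format NULL
#' @export
LABEL_SC <- 1L
#' @rdname LayerSegmentation-class
#' @format NULL
#' @export
LABEL_LED <- 2L
#' @rdname LayerSegmentation-class
#' @format NULL
#' @export
LABEL_DERMIS <- 3L

setValidity("LayerSegmentation", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!all(object@labels %in% 0:3))
    msg <- c(msg, "labels must be in {0, 1, 2, 3}")
  s <- object@surface@values; b <- object@scLed@values; d <- object@dej@values
  if (!all(dim(s) == dim(b)) || !all(dim(s) == dim(d)))
    msg <- c(msg, "depth maps must share dimensions")
  else if (any(s > b + 1e-9) || any(b > d + 1e-9))
    msg <- c(msg, "depth ordering violated: need surface <= sc_led <= dej")
  # the SC may legitimately be empty (zero-thickness stratum corneum); the
  # living epidermis and dermis may not
  for (lab in c(LABEL_LED, LABEL_DERMIS))
    if (!any(object@labels == lab))
      msg <- c(msg, sprintf("layer %d is empty", lab))
  if (length(msg)) msg else TRUE
})

#' Sublayer partition of the epidermis or dermis
#'
#' Maps each voxel to a sublayer index. Two kinds exist:
#' \describe{
#'   \item{\code{epidermal_normalized}}{K thickness-normalized epidermal
#'     sublayers following the 3D shape of the DEJ and skin surface; index 1
#'     touches the DEJ and index K the stratum corneum.}
#'   \item{\code{dermal_fixed}}{fixed-thickness dermal bands following the
#'     DEJ shape; band k occupies depths-below-DEJ [(k-1)T, kT); dermal voxels
#'     deeper than \code{nSublayers * T} fall in a flagged remainder band
#'     (index \code{nSublayers + 1}).}
#' }
#'
#' @slot index 3D integer array; 0 = not in the partition, 1..K = sublayer,
#'   K+1 = remainder band (dermal kind only).
#' @slot kind \code{"epidermal_normalized"} or \code{"dermal_fixed"}.
#' @slot nSublayers number of regular sublayers K.
#' @slot bandThicknessUm band thickness T in micrometres (dermal kind;
#'   \code{NA} for the epidermal kind).
#' @export
setClass("SublayerPartition",
  representation(
    index = "array",
    kind = "character",
    nSublayers = "integer",
    bandThicknessUm = "numeric"
  )
)

setValidity("SublayerPartition", function(object) {
  msg <- character()
  if (!object@kind %in% c("epidermal_normalized", "dermal_fixed"))
    msg <- c(msg, "kind must be 'epidermal_normalized' or 'dermal_fixed'")
  kmax <- object@nSublayers + (object@kind == "dermal_fixed")
  if (any(object@index < 0L) || any(object@index > kmax))
    msg <- c(msg, "sublayer indices out of range")
  if (object@kind == "dermal_fixed" &&
      (!is.finite(object@bandThicknessUm) || object@bandThicknessUm <= 0))
    msg <- c(msg, "dermal_fixed partitions need a positive bandThicknessUm")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic skin phantom
#'
#' Describes the geometry, optical structure and acquisition noise of a
#' synthetic multiphoton skin z-stack with known ground truth. Defaults
#' emulate a young ventral-forearm acquisition: a 130.3 x 130.3 um^2 field of
#' view sampled on a 128 x 128 grid (4x spatially binned), 70 planes at
#' 2.346 um z-step, 4 FLIM time channels of 2.08 ns with the intensity peak
#' at 1.33 ns, an undulated sinusoidal DEJ, melanin concentrated at the basal
#' layer with a short fluorescence lifetime, and a dermis of tubular elastin
#' (2PEF) and collagen (SHG) fibers.
#'
#' @slot dims integer (nx, ny, nz) voxel grid.
#' @slot pixelSizeUm,zStepUm lateral / axial sampling, micrometres.
#' @slot nTimeChannels,timeChannelWidthNs,peakOffsetNs FLIM binning: number of
#'   temporal bins, bin width (ns), and the arrival-time offset of the
#'   intensity peak (ns).
#' @slot surfaceDepthUm depth of the skin surface below plane 1 (um).
#' @slot surfaceTiltUm total surface depth increase across the field in x (um).
#' @slot scThicknessUm,ledThicknessUm mean stratum corneum / living epidermis
#'   thickness (um); the DEJ mid-depth is surface + SC + LED.
#' @slot dejAmplitudeUm,dejPeriodUm,dejWaveform DEJ undulation: amplitude and
#'   lateral period in um, waveform \code{"sinusoid"} or \code{"bumps"}
#'   (papillae-like rectified bumps). Amplitude must stay below the LED
#'   thickness.
#' @slot melBasalFraction melanin occupancy probability at the DEJ (basal
#'   layer), in [0, 1].
#' @slot melDecayNorm e-folding constant of the melanin occupancy decay over
#'   normalized epidermal height above the DEJ (0 = DEJ, 1 = surface).
#' @slot melLifetimeNs,backgroundLifetimeNs,elastinLifetimeNs fluorescence
#'   lifetimes (ns) of melanin, the epidermal background fluorophores
#'   (keratin/NAD(P)H) and elastin.
#' @slot scBrightness 2PEF brightness of the SC relative to the LED.
#' @slot elastinFraction,elastinRadiusUm,elastinWaviness elastin network:
#'   target dermal volume fraction, fiber tube radius (um), direction jitter
#'   of the persistent random walk in [0, 1].
#' @slot collagenFraction,collagenRadiusUm collagen network: target dermal
#'   volume fraction and fiber radius (um).
#' @slot fiberOverlapBias fraction in [0, 1] of elastin fibers seeded along
#'   existing collagen paths; drives the true imbrication (ImbrN).
#' @slot attenuationLengthUm depth-attenuation e-folding length of the
#'   detected signal (um).
#' @slot compensateAttenuation if \code{TRUE}, apply the instrument-style
#'   exponential excitation-gain profile that exactly cancels the attenuation.
#' @slot photonBudget mean total 2PEF counts per voxel for a unit-brightness
#'   structure at the surface.
#' @slot noiseFloor mean background counts per channel.
#' @slot poissonNoise if \code{FALSE}, emitted counts are the rounded expected
#'   values (noise-free phantom) instead of Poisson draws.
#' @slot seed integer RNG seed; identical (config, seed) gives bit-identical
#'   stacks.
#' @seealso [phantomConfig()], [generatePhantom()], [phantomPreset()].
#' @export
setClass("PhantomConfig",
  representation(
    dims = "integer",
    pixelSizeUm = "numeric", zStepUm = "numeric",
    nTimeChannels = "integer", timeChannelWidthNs = "numeric",
    peakOffsetNs = "numeric",
    surfaceDepthUm = "numeric", surfaceTiltUm = "numeric",
    scThicknessUm = "numeric", ledThicknessUm = "numeric",
    dejAmplitudeUm = "numeric", dejPeriodUm = "numeric",
    dejWaveform = "character",
    melBasalFraction = "numeric", melDecayNorm = "numeric",
    melLifetimeNs = "numeric", backgroundLifetimeNs = "numeric",
    elastinLifetimeNs = "numeric",
    scBrightness = "numeric",
    elastinFraction = "numeric", elastinRadiusUm = "numeric",
    elastinWaviness = "numeric",
    collagenFraction = "numeric", collagenRadiusUm = "numeric",
    fiberOverlapBias = "numeric",
    attenuationLengthUm = "numeric", compensateAttenuation = "logical",
    photonBudget = "numeric", noiseFloor = "numeric",
    poissonNoise = "logical",
    seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < c(32L, 32L, 8L)))
    msg <- c(msg, "dims must be (nx, ny, nz) with nx, ny >= 32 and nz >= 8")
  for (s in c("pixelSizeUm", "zStepUm", "scThicknessUm", "ledThicknessUm",
              "dejPeriodUm", "attenuationLengthUm"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  for (s in c("melBasalFraction", "elastinFraction", "collagenFraction",
              "fiberOverlapBias"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, paste(s, "must be in [0, 1]"))
  if (object@dejAmplitudeUm < 0)
    msg <- c(msg, "dejAmplitudeUm must be >= 0")
  if (object@dejAmplitudeUm >= object@ledThicknessUm)
    msg <- c(msg, "DEJ undulation amplitude must be below the LED thickness")
  if (!object@dejWaveform %in% c("sinusoid", "bumps"))
    msg <- c(msg, "dejWaveform must be 'sinusoid' or 'bumps'")
  if (object@nTimeChannels < 2L)
    msg <- c(msg, "nTimeChannels must be >= 2")
  if (length(msg)) msg else TRUE
})
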