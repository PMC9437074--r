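# Reading, writing and validating multichannel multiphoton z-stacks.
#
# On-disk convention: one multipage 16-bit TIFF per stack, page order
# channel-fastest (page = (z - 1) * nChannels + channel), time channels in
# ascending time order, SHG last; acquisition metadata in a YAML sidecar
# "<path>.yaml" written next to the TIFF. The sidecar can be overridden or
# supplied by hand for TIFFs produced elsewhere.

sidecarPath <- function(path) paste0(path, ".yaml")

#' Write a multiphoton stack to a multipage TIFF plus YAML sidecar
#'
#' Intensities are stored losslessly as 16-bit unsigned integers (counts up
#' to 65535), page order channel-fastest, together with a YAML sidecar
#' carrying the acquisition metadata so that
#' \code{readStack(writeStack(s))} reproduces \code{s} exactly.
#'
#' @param stack a [MultiphotonStack-class].
#' @param path destination TIFF filename; the sidecar is written to
#'   \code{paste0(path, ".yaml")}.
#' @return \code{path}, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "MultiphotonStack"))
  validObject(stack)
  ints <- stack@intensities
  if (max(ints) > 65535L)
    stop("intensities exceed the 16-bit storage range (65535)")
  d <- dim(ints)
  pages <- vector("list", d[3L] * d[4L])
  i <- 0L
  for (z in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
    i <- i + 1L
    # tiff stores floats in [0,1]; k/65535 round-trips exactly at 16 bits
    pages[[i]] <- t(ints[, , z, ch]) / 65535
  }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
    TRUE
  }, error = function(e) stop("cannot write stack to '", path, "': ",
                              conditionMessage(e)))
  meta <- stack@meta
  side <- list(
    roi_id = stack@roiId,
    dims = as.integer(d[1:3]),
    n_channels = as.integer(d[4L]),
    channel_order = "time_ascending_then_shg",
    pixel_size_um = meta@pixelSizeUm,
    z_step_um = meta@zStepUm,
    n_time_channels = as.integer(meta@nTimeChannels),
    time_channel_width_ns = meta@timeChannelWidthNs,
    shg_channel_index = as.integer(meta@shgChannelIndex)
  )
  if (!is.null(meta@excitationPowerProfile))
    side$excitation_power_profile <-
      lapply(seq_len(nrow(meta@excitationPowerProfile)), function(i)
        as.numeric(meta@excitationPowerProfile[i, ]))
  yaml::write_yaml(side, sidecarPath(path), precision = 15L)
  invisible(path)
}

#' Read a multiphoton stack from a multipage TIFF
#'
#' Expects the on-disk convention produced by [writeStack()]: a multipage
#' TIFF (channel-fastest page order) with a YAML sidecar holding the
#' acquisition metadata. A sidecar written by hand lets TIFF exports from
#' other software be read, provided pixel size, z-step and channel layout are
#' declared; missing metadata is an error, never silently defaulted.
#'
#' @param path TIFF filename.
#' @param sidecar optional explicit sidecar path (default
#'   \code{paste0(path, ".yaml")}).
#' @return a validated [MultiphotonStack-class].
#' @export
readStack <- function(path, sidecar = sidecarPath(path)) {
  if (!file.exists(path)) stop("unreadable file: '", path, "'")
  if (!file.exists(sidecar))
    stop("missing metadata: no sidecar '", sidecar,
         "' (pixel_size_um / z_step_um unknown)")
  side <- yaml::read_yaml(sidecar)
  need <- c("pixel_size_um", "z_step_um", "n_time_channels",
            "time_channel_width_ns", "shg_channel_index", "dims")
  miss <- setdiff(need, names(side))
  if (length(miss))
    stop("missing metadata in sidecar: ", paste(miss, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  d <- as.integer(side$dims)
  nch <- as.integer(side$n_time_channels) + 1L
  if (length(pages) != d[3L] * nch)
    stop("channel count mismatch: expected ", d[3L] * nch, " pages (",
         nch, " channels x ", d[3L], " planes), found ", length(pages))
  ints <- array(0L, c(d, nch))
  i <- 0L
  for (z in seq_len(d[3L])) for (ch in seq_len(nch)) {
    i <- i + 1L
    pg <- pages[[i]]
    if (is.na(nrow(pg)) || anyNA(pg))
      stop("missing voxel values in plane ", z, ", channel ", ch)
    ints[, , z, ch] <- as.integer(round(t(pg) * 65535))
  }
  prof <- NULL
  if (!is.null(side$excitation_power_profile))
    prof <- do.call(rbind, lapply(side$excitation_power_profile, as.numeric))
  meta <- AcquisitionMeta(
    pixelSizeUm = side$pixel_size_um,
    zStepUm = side$z_step_um,
    nTimeChannels = side$n_time_channels,
    timeChannelWidthNs = side$time_channel_width_ns,
    shgChannelIndex = side$shg_channel_index,
    excitationPowerProfile = prof
  )
  MultiphotonStack(ints, meta,
                   roiId = if (is.null(side$roi_id)) "roi" else side$roi_id)
}

#' Quality-check a multiphoton stack
#'
#' Screens a stack for acquisition problems analogous to the quality check
#' applied to clinical z-stacks (stacks with important volunteer movements
#' are excluded): inter-plane lateral motion (estimated by phase correlation
#' between consecutive total-2PEF planes), saturated voxels, empty planes and
#' an empty volume. Findings are returned, not raised.
#'
#' @param stack a [MultiphotonStack-class].
#' @param motionFractionFov flag a plane when its estimated lateral shift
#'   relative to the previous plane exceeds this fraction of the field of
#'   view (default 0.05).
#' @param saturationLevel count value treated as detector saturation.
#' @param maxSaturatedFraction flag when the fraction of saturated voxels
#'   exceeds this value.
#' @return a character vector of findings; empty for a clean stack.
#' @export
validateStack <- function(stack, motionFractionFov = 0.05,
                          saturationLevel = 65535L,
                          maxSaturatedFraction = 0.01) {
  stopifnot(is(stack, "MultiphotonStack"))
  findings <- character()
  tp <- totalPef(stack)
  if (max(stack@intensities) == 0L)
    return("empty volume: all intensities are zero")
  planeSums <- apply(tp, 3L, sum)
  empty <- which(planeSums == 0)
  if (length(empty))
    findings <- c(findings, sprintf("empty plane at z=%d", empty))
  satFrac <- mean(stack@intensities >= saturationLevel)
  if (satFrac > maxSaturatedFraction)
    findings <- c(findings, sprintf(
      "saturated-voxel fraction %.3f exceeds %.3f", satFrac,
      maxSaturatedFraction))
  d <- dim(tp)
  maxShift <- motionFractionFov * min(d[1L], d[2L])
  for (z in 2:d[3L]) {
    if (planeSums[z] == 0 || planeSums[z - 1L] == 0) next
    cc <- crossCorrelationShift(tp[, , z - 1L], tp[, , z])
    # flag only when a nonzero shift aligns the planes clearly better than
    # no shift: consecutive planes image different depths, so a weak or
    # ambiguous correlation peak is expected and is not motion
    if (sqrt(sum(cc$shift^2)) > maxShift && cc$gain > 0.15)
      findings <- c(findings, sprintf(
        "motion at z=%d: lateral shift (%d, %d) pixels", z,
        cc$shift[1L], cc$shift[2L]))
  }
  findings
}

# Integer lateral shift between two planes by FFT cross-correlation of the
# mean-subtracted images; `gain` is the correlation improvement of the best
# shift over zero shift (both on the normalized correlation surface).
crossCorrelationShift <- function(a, b) {
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  n <- length(a)
  denom <- stats::sd(a0) * stats::sd(b0) * n
  if (denom == 0) return(list(shift = c(0L, 0L), gain = 0))
  cc <- Re(stats::fft(stats::fft(a0) * Conj(stats::fft(b0)),
                      inverse = TRUE)) / n / denom
  ij <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  d <- dim(a)
  sh <- ij - 1L
  # shifts beyond half the field wrap to negative displacements
  sh <- ifelse(sh > d / 2, sh - d, sh)
  list(shift = -as.integer(sh), gain = max(cc) - cc[1L, 1L])
}
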