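# End-to-end orchestration: one call from a stack to its full metric record,
# batch quantification with provenance, and group comparison. A thin
# command-line wrapper over these functions ships in
# system.file("scripts", "mpskin.R", package = "mpskin").

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline with its default, plus a
#' provenance block (package version and a config hash stable under field
#' reordering).
#'
#' @param segmentation see [segmentationParams()].
#' @param pseudoFlim see [pseudoFlimParams()].
#' @param fiberMethod \code{"otsu"} or \code{"k_sigma"}.
#' @param epidermalK number of thickness-normalized epidermal sublayers.
#' @param dermalBandUm,dermalNBands dermal band thickness (um) and count for
#'   the z-profile partition.
#' @param summaryBandUm thickness of the single DEJ-following dermal band in
#'   which the headline fiber metrics are computed (default 50 um).
#' @param alpha significance threshold for contrasts.
#' @return a named list with a \code{provenance} block.
#' @export
pipelineConfig <- function(segmentation = segmentationParams(),
                           pseudoFlim = pseudoFlimParams(),
                           fiberMethod = c("otsu", "k_sigma"),
                           epidermalK = 10L,
                           dermalBandUm = 20, dermalNBands = 2L,
                           summaryBandUm = 50,
                           alpha = 0.05) {
  cfg <- list(segmentation = segmentation, pseudoFlim = pseudoFlim,
              fiberMethod = match.arg(fiberMethod),
              epidermalK = as.integer(epidermalK),
              dermalBandUm = dermalBandUm,
              dermalNBands = as.integer(dermalNBands),
              summaryBandUm = summaryBandUm, alpha = alpha)
  cfg$provenance <- list(
    package = "mpskin",
    version = as.character(utils::packageVersion("mpskin")),
    configHash = configHash(cfg))
  cfg
}

# Recursively sort list fields by name so the hash ignores field order.
canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else x
}

#' Hash of a configuration, stable under field reordering
#' @param cfg a named list.
#' @return a character hash.
#' @export
configHash <- function(cfg) {
  cfg$provenance <- NULL
  rlang::hash(canonicalize(cfg))
}

#' Quantify one stack: full metric record
#'
#' Runs segmentation, sublayer construction, melanin Pseudo-FLIM detection
#' and fiber quantification, and assembles one row of metrics per ROI:
#' layer thicknesses, normalized DEJ area, melanin densities and z-profile,
#' fiber densities / SHGto2PEF / SAAID / ImbrN in the summary dermal band,
#' whole-dermis densities, per-layer mean intensities, and provenance.
#'
#' @param stack a [MultiphotonStack-class].
#' @param config see [pipelineConfig()].
#' @return a list: \code{metrics} (one-row data.frame), \code{profiles}
#'   (dermal z-profile data.frame), \code{melaninProfile} (length-K vector),
#'   \code{seg}, \code{melaninMask}, \code{fiberMasks}.
#' @export
quantifyStack <- function(stack, config = pipelineConfig()) {
  seg <- segmentStack(stack, config$segmentation)
  morph <- morphologyMetrics(seg)
  epart <- epidermalSublayers(seg, config$epidermalK)
  dpart <- dermalSublayers(seg, config$dermalBandUm, config$dermalNBands)
  band50 <- dermalSublayers(seg, config$summaryBandUm, 1L)
  mel <- melaninMask(stack, seg, config$pseudoFlim)
  melProf <- melaninZProfile(mel, epart)
  fm <- fiberMasks(stack, seg, method = config$fiberMethod)
  in50 <- sublayerIndex(band50) == 1L
  dens50 <- fiberDensity(fm, seg, scope = in50)
  densAll <- fiberDensity(fm, seg)
  profiles <- dermalZProfiles(fm, seg, dpart)
  mEpi <- layerMeanIntensity(stack, seg,
                             seg@labels == LABEL_SC | seg@labels == LABEL_LED)
  mDer <- layerMeanIntensity(stack, seg, LABEL_DERMIS)
  row <- data.frame(
    roi = roiId(stack),
    meanScThicknessUm = morph$meanScThicknessUm,
    meanLedThicknessUm = morph$meanLedThicknessUm,
    meanEpidermalThicknessUm = morph$meanEpidermalThicknessUm,
    dejNormalizedArea = morph$dejNormalizedArea,
    melaninGlobalDensity = melaninDensity(mel, seg, "epidermis"),
    melaninLedDensity = melaninDensity(mel, seg, "led"),
    melaninBasal10Density = melaninDensity(mel, seg, "basal10"),
    elastinDensity50 = dens50[["elastin"]],
    collagenDensity50 = dens50[["collagen"]],
    shgTo2pef50 = shgTo2pefRatio(dens50),
    saaid50 = saaidIndex(dens50),
    imbrn50 = imbricationIndex(fm, seg, scope = in50),
    elastinDensityDermis = densAll[["elastin"]],
    collagenDensityDermis = densAll[["collagen"]],
    pefMeanEpidermis = mEpi[["pef"]],
    shgMeanDermis = mDer[["shg"]],
    pefMeanDermis = mDer[["pef"]],
    configHash = config$provenance$configHash,
    stringsAsFactors = FALSE)
  for (k in seq_along(melProf))
    row[[sprintf("melaninZ%02d", k)]] <- melProf[k]
  list(metrics = row, profiles = profiles, melaninProfile = melProf,
       seg = seg, melaninMask = mel, fiberMasks = fm)
}

#' Batch-quantify stacks to CSV
#'
#' Reads each TIFF, quantifies it, and appends one metrics row per ROI to
#' \code{<outDir>/metrics.csv} and the dermal z-profiles to
#' \code{<outDir>/profiles.csv}. Per-stack failures are logged to stderr and
#' the run continues; the number of failures is returned in the result's
#' \code{"failures"} attribute.
#'
#' @param paths character vector of stack TIFF paths.
#' @param outDir output directory (created if needed).
#' @param config see [pipelineConfig()].
#' @return the metrics data.frame, invisibly.
#' @export
cmdQuantify <- function(paths, outDir, config = pipelineConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); profs <- list(); fail <- 0L
  for (p in paths) {
    res <- tryCatch({
      st <- readStack(p)
      q <- quantifyStack(st, config)
      q$metrics$source <- p
      q$profiles$roi <- roiId(st)
      q
    }, error = function(e) {
      message("mpskin: FAILED on '", p, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { fail <- fail + 1L; next }
    rows[[length(rows) + 1L]] <- res$metrics
    profs[[length(profs) + 1L]] <- res$profiles
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  if (length(profs))
    utils::write.csv(do.call(rbind, profs),
                     file.path(outDir, "profiles.csv"), row.names = FALSE)
  jsonlite::write_json(config[setdiff(names(config), "provenance")],
                       file.path(outDir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  attr(metrics, "failures") <- fail
  invisible(metrics)
}

#' Generate a phantom to disk
#'
#' Writes the stack TIFF (+ YAML sidecar), the true depth maps as CSV, and
#' the true metrics as JSON into \code{outDir}.
#'
#' @param config a [PhantomConfig-class].
#' @param outDir output directory.
#' @return the paths written, invisibly.
#' @export
cmdPhantom <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ph <- generatePhantom(config)
  stackPath <- file.path(outDir, "phantom.tif")
  writeStack(ph$stack, stackPath)
  for (nm in c("surface", "scLed", "dej"))
    utils::write.csv(ph$truth[[nm]],
                     file.path(outDir, sprintf("truth_%s_um.csv", nm)),
                     row.names = FALSE)
  met <- ph$truth$metrics
  met$melaninZProfile <- as.numeric(met$melaninZProfile)
  jsonlite::write_json(met, file.path(outDir, "truth_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(stackPath, file.path(outDir, "truth_metrics.json")))
}

#' Compare metric distributions between two groups
#'
#' For every metric column: group means, folded F homogeneity test, pooled
#' Student t contrast, Cohen's d and its interpretation band. Values are
#' expected to be subject-level (ROI-averaged); use [aggregateRois()] first
#' when starting from per-ROI rows.
#'
#' @param metrics a data.frame of subject-level metric values.
#' @param group name of the grouping column (exactly 2 levels).
#' @param metricCols metric column names (default: all numeric columns).
#' @return a data.frame with one row per metric: means, \code{F}, \code{pF},
#'   \code{t}, \code{p}, \code{d}, \code{band}.
#' @export
compareGroups <- function(metrics, group = "group", metricCols = NULL) {
  g <- factor(metrics[[group]])
  if (nlevels(g) != 2L)
    stop("need exactly 2 groups, found ", nlevels(g))
  if (is.null(metricCols))
    metricCols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  lv <- levels(g)
  rows <- lapply(metricCols, function(m) {
    a <- metrics[[m]][g == lv[1L]]
    b <- metrics[[m]][g == lv[2L]]
    ff <- foldedFTest(a, b)
    cd <- cohenD(a, b)
    data.frame(metric = m, groupA = lv[1L], groupB = lv[2L],
               meanA = mean(a), meanB = mean(b),
               F = ff$F, pF = ff$p, t = cd$t, p = cd$p,
               d = cd$d, band = cd$band, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average per-ROI metric rows to subject level
#'
#' @param metrics data.frame with per-ROI rows.
#' @param subject,group column names identifying the subject and group.
#' @param metricCols metric columns (default: all numeric).
#' @return one row per subject with ROI-averaged metric values.
#' @export
aggregateRois <- function(metrics, subject = "subject", group = "group",
                          metricCols = NULL) {
  if (is.null(metricCols))
    metricCols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  sp <- split(metrics, metrics[[subject]])
  rows <- lapply(sp, function(s) {
    out <- data.frame(subject = s[[subject]][1L], group = s[[group]][1L],
                      stringsAsFactors = FALSE)
    for (m in metricCols) out[[m]] <- mean(s[[m]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
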