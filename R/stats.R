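# Descriptive and inferential layer: folded F variance test, Student t
# contrasts, Cohen's d with interpretation bands, ROI-robustness comparison
# and Pearson correlation screening.

#' Folded F test for homogeneity of variances
#'
#' The F statistic is the ratio of the greater of the two sample variances
#' to the lesser, so F >= 1 by construction; the two-sided p-value folds the
#' F distribution with (n_hi - 1, n_lo - 1) degrees of freedom.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return a list: \code{F}, \code{p}, \code{df}.
#' @examples
#' foldedFTest(rnorm(10, sd = 2), rnorm(10, sd = 1))
#' @export
foldedFTest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) stop("both variances are zero; folded F undefined")
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1L, length(b) - 1L)
  } else {
    f <- vb / va; df <- c(length(b) - 1L, length(a) - 1L)
  }
  p <- min(1, 2 * stats::pf(f, df[1L], df[2L], lower.tail = FALSE))
  list(F = f, p = p, df = df)
}

#' Student t contrast between two samples
#'
#' Pooled-variance two-sample Student t by default, or a paired t test. The
#' significance threshold used throughout is 5 % two-sided with no
#' multiplicity adjustment (the analyses are exploratory).
#'
#' @param a,b numeric vectors; equal length required when \code{paired}.
#' @param paired logical.
#' @return a list: \code{t}, \code{p}, \code{df}.
#' @export
twoSampleT <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  ht <- if (paired) stats::t.test(a, b, paired = TRUE)
        else stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Effect-size interpretation band for Cohen's d
#'
#' Bands on |d|: very weak [0, 0.3), weak [0.3, 0.5), moderate [0.5, 0.8),
#' strong [0.8, 1.3), very strong [1.3, Inf); \code{"none"} iff d = 0.
#'
#' @param d Cohen's d.
#' @return a character band label.
#' @export
esBand <- function(d) {
  if (d == 0) return("none")
  a <- abs(d)
  if (a < 0.3) "very weak"
  else if (a < 0.5) "weak"
  else if (a < 0.8) "moderate"
  else if (a < 1.3) "strong"
  else "very strong"
}

#' Cohen's d effect size with t contrast
#'
#' d = (mean(a) - mean(b)) / pooled SD, with the pooled between-subject SD as
#' denominator (the subject-level simplification of the mixed-model variance
#' for balanced ROI-averaged designs), plus the unpaired Student t contrast
#' and the interpretation band.
#'
#' @param a,b numeric vectors of per-subject (ROI-averaged) metric values.
#' @return a list: \code{d}, \code{band}, \code{t}, \code{p}.
#' @export
cohenD <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("pooled SD is zero; Cohen's d undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  tt <- twoSampleT(a, b)
  list(d = d, band = esBand(d), t = tt$t, p = tt$p)
}

#' ROI-robustness comparison
#'
#' Tests whether metric distributions built from the first 2 ROIs per subject
#' differ from those built from the first 3 or 4: for each metric, subject
#' means over the first k ROIs (k in \code{subsetSizes}, acquisition order,
#' deterministic) are compared between k = 2 and each larger k with the
#' folded F test and the Student t test. A metric is flagged when any
#' p-value falls below \code{alpha}.
#'
#' @param perRoi a data.frame with columns \code{subject}, \code{roi}
#'   (ordered acquisition index), \code{metric}, \code{value}.
#' @param subsetSizes ROI subset sizes; the first is the reference.
#' @param alpha significance threshold (default 0.05).
#' @return a data.frame with one row per (metric, comparison):
#'   \code{metric}, \code{comparison}, \code{F}, \code{pF}, \code{t},
#'   \code{pT}, \code{flagged}.
#' @export
roiRobustness <- function(perRoi, subsetSizes = c(2L, 3L, 4L),
                          alpha = 0.05) {
  need <- c("subject", "roi", "metric", "value")
  if (!all(need %in% names(perRoi)))
    stop("perRoi needs columns: ", paste(need, collapse = ", "))
  kmax <- max(subsetSizes)
  cnt <- table(perRoi$subject, perRoi$metric)
  if (any(cnt < kmax))
    stop("need at least ", kmax, " ROIs per subject and metric")
  ref <- subsetSizes[1L]
  rows <- list()
  for (m in unique(perRoi$metric)) {
    dm <- perRoi[perRoi$metric == m, ]
    dm <- dm[order(dm$subject, dm$roi), ]
    subjMeans <- function(k) {
      sapply(split(dm, dm$subject),
             function(s) mean(s$value[order(s$roi)][seq_len(k)]))
    }
    va <- subjMeans(ref)
    for (k in subsetSizes[-1L]) {
      vb <- subjMeans(k)
      ff <- foldedFTest(va, vb)
      tt <- twoSampleT(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, comparison = sprintf("%dvs%d", ref, k),
        F = ff$F, pF = ff$p, t = tt$t, pT = tt$p,
        flagged = ff$p < alpha || tt$p < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson r over all metric pairs with pairwise-complete observations;
#' constant columns give \code{NA} entries (with a warning).
#'
#' @param metrics a numeric data.frame or matrix (rows = ROIs or subjects,
#'   columns = metrics), >= 3 rows.
#' @return the correlation matrix.
#' @export
pearsonMatrix <- function(metrics) {
  m <- as.matrix(metrics)
  if (nrow(m) < 3L) stop("need at least 3 rows")
  const <- apply(m, 2L, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant columns give undefined correlations: ",
            paste(colnames(m)[const], collapse = ", "))
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}
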