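#' ARSER-style rhythmicity detection
#'
#' The full pipeline per gene: linear detrending, autoregressive spectral
#' period candidates in `[periodMin, periodMax]` (union of Yule-Walker,
#' Burg and exact-ML fits, AIC order selection; a fallback period of
#' `fallbackPeriod` hours is tested when no spectral peak falls in the
#' band, so every gene receives a p-value), harmonic regression at each
#' candidate with AIC model selection and residual-sum-of-squares
#' refinement of the selected period, an F test of the harmonic terms,
#' and Benjamini-Hochberg FDR correction over all genes of the dataset.
#' A gene is called rhythmic when its q-value is at most `qThreshold`.
#'
#' Genes with degenerate (constant) profiles or numerically failing fits
#' are flagged, assigned p-value 1 and called non-rhythmic.
#'
#' @param x numeric matrix, genes x timepoints (one expression value per
#'   gene per timepoint).
#' @param times uniformly spaced sampling times in hours.
#' @param qThreshold FDR threshold for the rhythmic call.
#' @param periodMin,periodMax allowed period band (hours).
#' @param maxOrder maximum AR order (default `floor(ncol(x)/3)`).
#' @param nFreq spectral frequency-grid resolution.
#' @param fallbackPeriod period tested when no spectral candidate exists.
#' @param refine refine the selected period against the regression RSS.
#' @return [S4Vectors::DataFrame] with columns `rhythmic`, `period`,
#'   `phase`, `amplitude`, `meanLevel`, `pvalue`, `qvalue`,
#'   `nCandidates`, `flagged`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' x <- rbind(cos24 = 4 * cos(2 * pi * t / 24), flat = rep(0, 12))
#' arserDetect(x, t)$rhythmic
#' @export
arserDetect <- function(x, times, qThreshold = 0.05, periodMin = 20,
                        periodMax = 28, maxOrder = NULL, nFreq = 512L,
                        fallbackPeriod = 24, refine = TRUE) {
  x <- as.matrix(x)
  assertUniformTimes(times)
  if (ncol(x) != length(times))
    stop("ncol(x) must equal length(times)")
  if (is.null(maxOrder)) maxOrder <- max(1L, ncol(x) %/% 3L)
  core <- .arserCoreCpp(x, as.numeric(times), periodMin, periodMax,
                        as.integer(maxOrder), as.integer(nFreq),
                        fallbackPeriod, refine)
  q <- bhFDR(core$pvalue)
  res <- S4Vectors::DataFrame(
    rhythmic = core$flagged == 0L & q <= qThreshold,
    period = core$period, phase = core$phase,
    amplitude = core$amplitude, meanLevel = core$meanLevel,
    pvalue = core$pvalue, qvalue = q,
    nCandidates = core$nCandidates, flagged = core$flagged == 1L,
    row.names = rownames(x))
  res
}
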