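## HAYSTACK-style pattern-correlation detector.
##
## Shape definitions (one 24 h cycle, before centring/normalisation):
##   cosine     cos(2*pi*t/24)
##   sine       sin(2*pi*t/24)
##   box        +1 on the first half-cycle, -1 on the second
##   spike      1 at t = 0, 0 elsewhere on the cycle
##   rigid      cosine with the trough clipped at its 25th percentile
##              (-sqrt(2)/2 for a cosine over a full cycle)
##   asymmetric sawtooth rising over the first third of the cycle and
##              falling over the remaining two thirds

shapeFun <- function(shape) {
  switch(shape,
    cosine = function(u, period) cos(2 * pi * u / period),
    sine = function(u, period) sin(2 * pi * u / period),
    box = function(u, period) ifelse((u %% period) < period / 2, 1, -1),
    spike = function(u, period)
      ifelse(abs((u %% period)) < 1e-8 |
               abs((u %% period) - period) < 1e-8, 1, 0),
    rigid = function(u, period) pmax(cos(2 * pi * u / period), -sqrt(2) / 2),
    asymmetric = function(u, period) {
      v <- u %% period
      ifelse(v < period / 3, v / (period / 3),
             1 - (v - period / 3) / (2 * period / 3))
    },
    stop("unknown shape '", shape, "'"))
}

#' Build a phase-shifted cycling pattern library
#'
#' Samples each named 24 h-periodic shape at the dataset's timepoints for
#' every phase shift on `[0, period)` at `phaseStep` spacing, then centres
#' each template and normalises it to unit norm. Templates that are
#' constant on the sampling grid (e.g. a spike falling between sampling
#' times) are excluded with a warning.
#'
#' @param timepoints uniformly spaced sampling times (hours).
#' @param shapes character vector of shape tags; the six standard shapes
#'   are `"asymmetric"`, `"box"`, `"cosine"`, `"rigid"`, `"sine"`,
#'   `"spike"`.
#' @param phaseStep phase-shift grid spacing in hours.
#' @param period template period in hours.
#' @return A [PatternLibrary-class].
#' @examples
#' lib <- buildPatternLibrary(seq(0, 44, by = 4))
#' length(lib)
#' @export
buildPatternLibrary <- function(timepoints,
                                shapes = c("asymmetric", "box", "cosine",
                                           "rigid", "sine", "spike"),
                                phaseStep = 1.0, period = 24) {
  assertUniformTimes(timepoints)
  phases <- seq(0, period - 1e-9, by = phaseStep)
  rows <- list()
  tagS <- character(0)
  tagP <- numeric(0)
  nDropped <- 0L
  for (s in sort(shapes)) {
    f <- shapeFun(s)
    for (ph in phases) {
      v <- f(timepoints - ph, period)
      v <- v - mean(v)
      nrm <- sqrt(sum(v^2))
      if (nrm < 1e-8) { nDropped <- nDropped + 1L; next }
      rows[[length(rows) + 1L]] <- v / nrm
      tagS <- c(tagS, s)
      tagP <- c(tagP, ph)
    }
  }
  if (nDropped > 0L)
    warning(nDropped, " template(s) degenerate (constant on the sampling ",
            "grid) and excluded")
  ## deterministic tie-break order for best-pattern selection:
  ## lowest phase shift first, then shape tag lexicographic
  o <- order(tagP, tagS)
  new("PatternLibrary",
      templates = do.call(rbind, rows)[o, , drop = FALSE],
      shape = tagS[o], phaseShift = tagP[o],
      timepoints = as.numeric(timepoints), period = period)
}

#' HAYSTACK-style rhythmicity detection
#'
#' Correlates every gene profile with every template of a phase-shifted
#' cycling-pattern library and applies the classical cutoff set: a gene
#' is called rhythmic when its best Pearson correlation is at least
#' `corrCut`, its fold change is at least `foldCut`, and the correlation
#' p-value (one-sided t-distribution transform of r with n-2 degrees of
#' freedom) is at most `pCut`. Before the fold change (row maximum over
#' row minimum) is computed, expression values below
#' `backgroundCut` x (dataset 95th percentile) are raised to that floor,
#' which protects against division blow-up on near-zero baselines.
#'
#' Zero-variance genes have undefined correlation; they are flagged and
#' called non-rhythmic.
#'
#' @param x numeric matrix, genes x timepoints.
#' @param times sampling times in hours.
#' @param library a [PatternLibrary-class] built on the same timepoints
#'   (built automatically when omitted).
#' @param pCut,foldCut,corrCut,backgroundCut the four cutoffs.
#' @return [S4Vectors::DataFrame] with columns `rhythmic`, `period`,
#'   `phase`, `amplitude`, `meanLevel`, `pvalue`, `bestPattern`,
#'   `correlation`, `foldChange`, `flagged`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' x <- rbind(g1 = 5 + 2 * cos(2 * pi * t / 24), g2 = rep(3, 12))
#' haystackDetect(x, t)$rhythmic
#' @export
haystackDetect <- function(x, times, library = NULL, pCut = 0.05,
                           foldCut = 2.0, corrCut = 0.8,
                           backgroundCut = 0.01) {
  x <- as.matrix(x)
  assertUniformTimes(times)
  if (is.null(library)) library <- buildPatternLibrary(times)
  if (length(timepoints(library)) != length(times) ||
      max(abs(timepoints(library) - times)) > 1e-8)
    stop("pattern library was built on different timepoints")
  n <- length(times)
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  degenerate <- ss < 1e-12
  xs <- xc / ifelse(degenerate, 1, ss)
  R <- xs %*% t(library@templates)          # Pearson r per (gene, template)
  best <- max.col(R, ties.method = "first") # templates pre-sorted for ties
  r <- R[cbind(seq_len(nrow(x)), best)]
  r[degenerate] <- NA_real_
  ## background floor and fold change
  floorVal <- backgroundCut * as.numeric(quantile(x, 0.95))
  xf <- pmax(x, floorVal)
  fold <- apply(xf, 1L, max) / apply(xf, 1L, min)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  pval <- pt(tstat, df = n - 2, lower.tail = FALSE)
  rhythmic <- !degenerate & !is.na(r) &
    r >= corrCut & fold >= foldCut & pval <= pCut
  S4Vectors::DataFrame(
    rhythmic = rhythmic,
    period = ifelse(rhythmic, library@period, NA_real_),
    phase = library@phaseShift[best],
    amplitude = (apply(x, 1L, max) - apply(x, 1L, min)) / 2,
    meanLevel = mu,
    pvalue = pval,
    bestPattern = library@shape[best],
    correlation = r,
    foldChange = fold,
    flagged = degenerate,
    row.names = rownames(x))
}
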