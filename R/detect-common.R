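#' Remove a linear trend from a time series
#'
#' Ordinary least-squares residuals of the series regressed on an
#' intercept and time; the residuals are orthogonal to both regressors.
#'
#' @param series numeric vector of expression values.
#' @param times sampling times (hours), same length as `series`.
#' @return numeric vector of detrended values.
#' @examples
#' linearDetrend(2 * (0:5) + 5, 0:5)   # exactly zero
#' @export
linearDetrend <- function(series, times) {
  if (length(series) != length(times) || length(series) < 3L)
    stop("'series' and 'times' must have equal length >= 3")
  tc <- times - mean(times)
  xc <- series - mean(series)
  slope <- sum(tc * xc) / sum(tc * tc)
  as.numeric(xc - slope * tc)
}

#' Candidate periods by autoregressive spectral analysis
#'
#' Fits autoregressive models to a (detrended) uniformly sampled series by
#' Yule-Walker, Burg and exact Gaussian maximum likelihood, selecting the
#' order of each by AIC (up to `maxOrder`), evaluates each fitted AR
#' spectral density on a fine frequency grid, and returns the periods of
#' the local spectral maxima that fall inside `[periodMin, periodMax]`.
#' The union of peaks over the three estimators is returned; the list may
#' be empty.
#'
#' @param series numeric vector (already detrended).
#' @param times uniformly spaced sampling times (hours).
#' @param periodMin,periodMax period band of interest (hours).
#' @param maxOrder maximum AR order (default `floor(length(series)/3)`).
#' @param nFreq frequency-grid resolution.
#' @return numeric vector of candidate periods in hours (possibly empty).
#' @examples
#' t <- seq(0, 44, by = 4)
#' arSpectralPeriods(cos(2 * pi * t / 24), t)
#' @export
arSpectralPeriods <- function(series, times, periodMin = 20,
                              periodMax = 28, maxOrder = NULL,
                              nFreq = 512L) {
  dt <- assertUniformTimes(times)
  if (length(series) != length(times))
    stop("'series' and 'times' must have equal length")
  if (is.null(maxOrder)) maxOrder <- max(1L, length(series) %/% 3L)
  if (all(abs(series - mean(series)) < 1e-12)) return(numeric(0))
  sort(.arCandidatesCpp(as.numeric(series), dt, periodMin, periodMax,
                        as.integer(maxOrder), as.integer(nFreq)))
}

#' Harmonic regression at candidate periods
#'
#' For each candidate period \eqn{\tau} fits
#' \eqn{y = \mu + a\cos(2\pi t/\tau) + b\sin(2\pi t/\tau)} by least
#' squares, selects the best period by AIC and (optionally) refines it by
#' minimising the residual sum of squares, and reports the four cyclic
#' parameters. The p-value is the F test of the harmonic terms against
#' the intercept-only model.
#'
#' @param series numeric vector.
#' @param times sampling times (hours).
#' @param periods non-empty vector of candidate periods (hours).
#' @param refine refine the selected period by RSS minimisation within
#'   `refineWindow` hours of the selected candidate.
#' @param refineWindow half-width (hours) of the refinement bracket.
#' @return list with elements `period`, `amplitude`, `phase` (in
#'   `[0, period)`), `meanLevel` (the fitted intercept), `pvalue`,
#'   `coefficients` (`mu`, `a`, `b`) and `rss`.
#' @examples
#' t <- seq(0, 44, by = 4)
#' y <- 3 + 4 * cos(2 * pi * t / 24)
#' fit <- harmonicRegression(y, t, periods = 24)
#' c(fit$amplitude, fit$meanLevel, fit$phase)
#' @export
harmonicRegression <- function(series, times, periods, refine = FALSE,
                               refineWindow = 0.3) {
  if (length(periods) < 1L) stop("'periods' must be non-empty")
  if (length(series) != length(times) || length(series) < 4L)
    stop("'series' and 'times' must have equal length >= 4")
  n <- length(series)
  fit1 <- function(tau) {
    X <- cbind(1, cos(2 * pi * times / tau), sin(2 * pi * times / tau))
    qr. <- qr(X)
    if (qr.$rank < 3L) return(NULL)
    beta <- qr.coef(qr., series)
    rss <- sum((series - X %*% beta)^2)
    list(tau = tau, beta = beta, rss = rss)
  }
  fits <- lapply(periods, fit1)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("design matrix rank-deficient at every candidate period ",
         "(period aliased with the sampling grid)")
  fits <- fits[ok]
  aic <- vapply(fits, function(f)
    n * log(max(f$rss, 1e-300) / n) + 2 * 4, numeric(1))
  best <- fits[[which.min(aic)]]
  if (refine) {
    lo <- best$tau - refineWindow
    hi <- best$tau + refineWindow
    opt <- optimize(function(tau) {
      f <- fit1(tau)
      if (is.null(f)) Inf else f$rss
    }, c(lo, hi), tol = 1e-9)
    cand <- fit1(opt$minimum)
    if (!is.null(cand) && cand$rss <= best$rss) best <- cand
  }
  beta <- best$beta
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  ph <- (best$tau / (2 * pi)) * atan2(beta[3], beta[2])
  ph <- ph %% best$tau
  rss0 <- sum((series - mean(series))^2)
  p <- if (best$rss <= 1e-18 * rss0) 0 else {
    Fstat <- max(0, ((rss0 - best$rss) / 2) / (best$rss / (n - 3)))
    stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  }
  list(period = best$tau, amplitude = as.numeric(amp),
       phase = as.numeric(ph), meanLevel = as.numeric(beta[1]),
       pvalue = as.numeric(p),
       coefficients = c(mu = beta[1], a = beta[2], b = beta[3]),
       rss = best$rss)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (clipped to 1).
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

## extract (matrix, times) from supported inputs; detectors need a single
## expression value per gene per timepoint
singleReplicateMatrix <- function(object) {
  if (is(object, "RhythmExperiment")) {
    if (nReplicates(object) != 1L)
      stop("detectors operate on single-replicate datasets; use ",
           "resampleDataset(), averageDataset() or replicateExperiment() ",
           "first")
    o <- order(sampleTimes(object))
    list(x = assay(object, "exprs")[, o, drop = FALSE],
         times = sampleTimes(object)[o])
  } else {
    stop("unsupported input of class ", class(object)[1])
  }
}

#' Extract one replicate time course as a single-replicate dataset
#'
#' @param object a [RhythmExperiment-class].
#' @param r replicate index.
#' @return a single-replicate [RhythmExperiment-class] keeping the truth
#'   annotation.
#' @export
replicateExperiment <- function(object, r) {
  stopifnot(is(object, "RhythmExperiment"))
  sel <- which(colData(object)$replicate == r)
  if (!length(sel)) stop("no samples with replicate index ", r)
  o <- sel[order(sampleTimes(object)[sel])]
  rd <- rowData(object)
  RhythmExperiment(assay(object, "exprs")[, o, drop = FALSE],
                   time = sampleTimes(object)[o],
                   replicate = rep(1L, length(o)),
                   truth = if (ncol(rd)) as.data.frame(rd) else NULL)
}

#' Run a rhythmicity detector on a dataset
#'
#' Front end dispatching to [arserDetect()], [haystackDetect()] or
#' [fftnllsDetect()]. All detectors are pure functions of the data and
#' their parameters.
#'
#' @param object a single-replicate [RhythmExperiment-class] or a numeric
#'   matrix (genes x timepoints, with `times` supplied).
#' @param method one of `"arser"`, `"haystack"`, `"fftnlls"`.
#' @param ... passed to the detector.
#' @return a [S4Vectors::DataFrame] with one row per gene; see the
#'   individual detectors for columns. All detectors share `rhythmic`,
#'   `period`, `phase`, `amplitude`, `meanLevel`, `pvalue`, `flagged`.
#' @export
setMethod("detectRhythms", "RhythmExperiment",
          function(object, method = c("arser", "haystack", "fftnlls"),
                   ...) {
  method <- match.arg(method)
  inp <- singleReplicateMatrix(object)
  switch(method,
         arser = arserDetect(inp$x, inp$times, ...),
         haystack = haystackDetect(inp$x, inp$times, ...),
         fftnlls = fftnllsDetect(inp$x, inp$times, ...))
})

#' @rdname detectRhythms-RhythmExperiment-method
#' @param times sampling times in hours (matrix input only).
#' @export
setMethod("detectRhythms", "matrix",
          function(object, method = c("arser", "haystack", "fftnlls"),
                   times, ...) {
  method <- match.arg(method)
  switch(method,
         arser = arserDetect(object, times, ...),
         haystack = haystackDetect(object, times, ...),
         fftnlls = fftnllsDetect(object, times, ...))
})

## rhythmic gene ids from a detector result
callSet <- function(result) rownames(result)[result$rhythmic]
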