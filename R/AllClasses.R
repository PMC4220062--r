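#' RhythmExperiment: replicated time-course expression data
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] for
#' gene x sample expression matrices in which every sample (column) is
#' annotated with a sampling time in hours (`colData(x)$time`) and a
#' replicate index (`colData(x)$replicate`). In destructive time-course
#' sampling each column is a different individual, so a "replicate time
#' course" is the set of columns sharing a replicate index. Ground-truth
#' rhythmicity labels from the simulators, when available, live in
#' `rowData(x)$rhythmic` (plus `period`, `phase`, `waveform`), and the
#' map from (time, replicate) slots to simulated individuals is stored in
#' `metadata(x)$provenance`.
#'
#' @name RhythmExperiment-class
#' @exportClass RhythmExperiment
setClass("RhythmExperiment", contains = "SummarizedExperiment")

setValidity("RhythmExperiment", function(object) {
  cd <- colData(object)
  if (!all(c("time", "replicate") %in% colnames(cd)))
    return("colData must contain 'time' and 'replicate'")
  tm <- cd$time
  rp <- cd$replicate
  if (!is.numeric(tm) || anyNA(tm))
    return("'time' must be numeric with no missing values")
  if (anyNA(rp) || any(rp < 1))
    return("'replicate' must contain positive indices")
  if (anyDuplicated(paste(tm, rp)))
    return("duplicated (time, replicate) sample slots")
  prov <- metadata(object)$provenance
  if (!is.null(prov) && anyDuplicated(prov$individual))
    return("provenance must be injective: an individual may be used at most once")
  TRUE
})

#' Construct a RhythmExperiment
#'
#' @param exprs numeric matrix, genes in rows, samples in columns.
#' @param time numeric vector of sampling times (hours), one per column.
#' @param replicate integer vector of replicate indices, one per column.
#' @param truth optional per-gene truth annotation: a logical vector of
#'   rhythmic flags or a data.frame with at least a `rhythmic` column.
#' @param provenance optional data.frame with columns `time`, `replicate`,
#'   `individual` mapping sample slots to simulated individuals.
#' @return A [RhythmExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' re <- RhythmExperiment(m, time = rep(c(0, 4, 8, 12, 16), 2),
#'                        replicate = rep(1:2, each = 5))
#' timepoints(re)
#' nReplicates(re)
#' @export
RhythmExperiment <- function(exprs, time, replicate, truth = NULL,
                             provenance = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("gene_%05d", seq_len(nrow(exprs)))
  if (length(time) != ncol(exprs) || length(replicate) != ncol(exprs))
    stop("'time' and 'replicate' must have one entry per column of 'exprs'")
  replicate <- as.integer(replicate)
  colnames(exprs) <- sprintf("T%g_R%d", time, replicate)
  cd <- S4Vectors::DataFrame(time = as.numeric(time), replicate = replicate,
                             row.names = colnames(exprs))
  rd <- S4Vectors::DataFrame(row.names = rownames(exprs))
  if (!is.null(truth)) {
    if (is.logical(truth)) truth <- data.frame(rhythmic = truth)
    if (nrow(truth) != nrow(exprs))
      stop("'truth' must have one row per gene")
    rd <- S4Vectors::DataFrame(truth, row.names = rownames(exprs))
  }
  md <- list()
  if (!is.null(provenance)) md$provenance <- provenance
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = cd, rowData = rd, metadata = md)
  new("RhythmExperiment", se)
}

#' SimulatedCohort: per-individual simulated time courses
#'
#' The raw output of the simulators: one complete gene x timepoint
#' expression matrix per simulated individual ("original simulations"),
#' together with the per-gene generating parameters (truth class, period,
#' phase, waveform) and, for free-running simulations, the per-individual
#' free-running period.
#'
#' @slot values numeric array, genes x timepoints x individuals.
#' @slot timepoints numeric vector of sampling times in hours.
#' @slot geneParams [S4Vectors::DataFrame] with columns `class`
#'   ("rhythmic"/"null"), `period`, `phase` (NA for null genes) and
#'   `waveform`.
#' @slot individualPeriods numeric, one free-running period per individual
#'   (all NA except for LL cohorts).
#' @slot mode character: "ld", "ll", "ode" or "noise".
#' @slot seed the seed the cohort was generated under (NA if none given).
#' @exportClass SimulatedCohort
setClass("SimulatedCohort",
         representation(values = "array", timepoints = "numeric",
                        geneParams = "DataFrame",
                        individualPeriods = "numeric",
                        mode = "character", seed = "numeric"))

setValidity("SimulatedCohort", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("'values' must be a 3-d array")
  if (d[2] != length(object@timepoints))
    return("second dimension must match timepoints")
  if (d[1] != nrow(object@geneParams))
    return("first dimension must match geneParams rows")
  if (length(object@individualPeriods) != d[3])
    return("individualPeriods must have one entry per individual")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    return("timepoints must be strictly increasing")
  if (!all(object@geneParams$class %in% c("rhythmic", "null")))
    return("gene class must be 'rhythmic' or 'null'")
  if (any(!is.na(object@geneParams$period[object@geneParams$class == "null"])))
    return("null genes must not carry a period")
  TRUE
})

#' PatternLibrary: phase-shifted cycling templates
#'
#' Unit-normalised, zero-mean 24 h-periodic template vectors sampled at a
#' fixed set of timepoints, one per (shape, phase shift) combination, used
#' by the HAYSTACK-style pattern-correlation detector.
#'
#' @slot templates numeric matrix, one row per template.
#' @slot shape character tag per template.
#' @slot phaseShift numeric phase shift in hours per template.
#' @slot timepoints sampling times the templates were evaluated at.
#' @slot period template period in hours (24 by default).
#' @exportClass PatternLibrary
setClass("PatternLibrary",
         representation(templates = "matrix", shape = "character",
                        phaseShift = "numeric", timepoints = "numeric",
                        period = "numeric"))

setValidity("PatternLibrary", function(object) {
  n <- nrow(object@templates)
  if (length(object@shape) != n || length(object@phaseShift) != n)
    return("shape/phaseShift must have one entry per template row")
  if (ncol(object@templates) != length(object@timepoints))
    return("template columns must match timepoints")
  cm <- rowMeans(object@templates)
  nrm <- sqrt(rowSums(object@templates^2))
  if (n > 0 && (max(abs(cm)) > 1e-8 || max(abs(nrm - 1)) > 1e-8))
    return("templates must be zero-mean with unit norm")
  TRUE
})

#' ConsensusTable: per-gene consensus counts across datasets
#'
#' For each gene, the number of analysed datasets (resampled datasets,
#' replicate time courses, or original simulations) whose rhythmic call
#' set contains the gene.
#'
#' @slot counts named integer vector over the gene universe.
#' @slot nDatasets number of datasets the counts are out of.
#' @exportClass ConsensusTable
setClass("ConsensusTable",
         representation(counts = "integer", nDatasets = "integer"))

setValidity("ConsensusTable", function(object) {
  if (length(object@nDatasets) != 1L || object@nDatasets < 0L)
    return("nDatasets must be a single non-negative integer")
  if (is.null(names(object@counts)))
    return("counts must be named by gene id")
  if (any(object@counts < 0L) || any(object@counts > object@nDatasets))
    return("counts must lie in [0, nDatasets]")
  TRUE
})
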