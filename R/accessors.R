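## Accessors and show methods for the core classes.

#' @describeIn RhythmExperiment-class sampling time (hours) of every column
#' @param object a `RhythmExperiment`
#' @export
setMethod("sampleTimes", "RhythmExperiment",
          function(object) colData(object)$time)

#' @describeIn RhythmExperiment-class sorted unique sampling times
#' @export
setMethod("timepoints", "RhythmExperiment",
          function(object) sort(unique(colData(object)$time)))

#' @describeIn RhythmExperiment-class number of replicates per time point
#' @export
setMethod("nReplicates", "RhythmExperiment",
          function(object) max(colData(object)$replicate))

#' @describeIn RhythmExperiment-class gene identifiers
#' @export
setMethod("geneIds", "RhythmExperiment", function(object) rownames(object))

#' @describeIn RhythmExperiment-class per-gene logical rhythmic flags from
#'   the simulation truth, or NULL for real data
#' @export
setMethod("truthLabels", "RhythmExperiment", function(object, ...) {
  rd <- rowData(object)
  if (!"rhythmic" %in% colnames(rd)) return(NULL)
  stats::setNames(rd$rhythmic, rownames(object))
})

#' @describeIn RhythmExperiment-class slot-to-individual provenance map
#'   (NULL for real data)
#' @export
setMethod("provenance", "RhythmExperiment",
          function(object) metadata(object)$provenance)

setMethod("show", "RhythmExperiment", function(object) {
  cat("RhythmExperiment:", nrow(object), "genes,",
      length(timepoints(object)), "timepoints,",
      nReplicates(object), "replicate(s)\n")
  cat("  times (h):", paste(timepoints(object), collapse = " "), "\n")
  tl <- truthLabels(object)
  if (!is.null(tl))
    cat("  truth: ", sum(tl), " rhythmic / ", sum(!tl), " null\n", sep = "")
  callNextMethod()
})

## genes x timepoints x replicates array view; requires a complete crossing
#' Expression values as a gene x timepoint x replicate array
#'
#' @param object a [RhythmExperiment-class] with a complete
#'   (time, replicate) crossing.
#' @return numeric array with dimensions genes x timepoints x replicates.
#' @export
exprsArray <- function(object) {
  stopifnot(is(object, "RhythmExperiment"))
  tp <- timepoints(object)
  R <- nReplicates(object)
  tm <- sampleTimes(object)
  rp <- colData(object)$replicate
  if (ncol(object) != length(tp) * R)
    stop("dataset is not a complete (time, replicate) crossing")
  a <- array(NA_real_, dim = c(nrow(object), length(tp), R),
             dimnames = list(rownames(object), paste0("T", tp),
                             paste0("R", seq_len(R))))
  x <- assay(object, "exprs")
  for (j in seq_len(ncol(object)))
    a[, match(tm[j], tp), rp[j]] <- x[, j]
  if (anyNA(a)) stop("dataset is not a complete (time, replicate) crossing")
  a
}

## ---- SimulatedCohort ----

#' @describeIn SimulatedCohort-class number of simulated individuals
#' @param object a `SimulatedCohort`
#' @export
setMethod("nIndividuals", "SimulatedCohort",
          function(object) dim(object@values)[3])

#' @describeIn SimulatedCohort-class per-gene generating parameters
#' @export
setMethod("geneParams", "SimulatedCohort", function(object) object@geneParams)

#' @describeIn SimulatedCohort-class per-individual free-running periods
#' @export
setMethod("individualPeriods", "SimulatedCohort",
          function(object) object@individualPeriods)

#' @describeIn SimulatedCohort-class sampling times
#' @export
setMethod("timepoints", "SimulatedCohort", function(object) object@timepoints)

#' @describeIn SimulatedCohort-class gene identifiers
#' @export
setMethod("geneIds", "SimulatedCohort",
          function(object) rownames(object@geneParams))

#' @describeIn SimulatedCohort-class per-gene logical rhythmic flags
#' @export
setMethod("truthLabels", "SimulatedCohort", function(object, ...) {
  stats::setNames(object@geneParams$class == "rhythmic",
                  rownames(object@geneParams))
})

#' @describeIn SimulatedCohort-class gene x timepoint matrix of one
#'   individual
#' @param i individual index
#' @export
setMethod("individualMatrix", "SimulatedCohort", function(object, i) {
  stopifnot(i >= 1, i <= nIndividuals(object))
  m <- object@values[, , i, drop = FALSE]
  dim(m) <- dim(object@values)[1:2]
  dimnames(m) <- list(rownames(object@geneParams),
                      paste0("T", object@timepoints))
  m
})

setMethod("show", "SimulatedCohort", function(object) {
  d <- dim(object@values)
  cat("SimulatedCohort (mode '", object@mode, "'): ", d[1], " genes x ",
      d[2], " timepoints x ", d[3], " individuals\n", sep = "")
  tl <- truthLabels(object)
  cat("  truth: ", sum(tl), " rhythmic / ", sum(!tl), " null\n", sep = "")
  if (any(!is.na(object@individualPeriods)))
    cat("  individual periods (h): mean ",
        round(mean(object@individualPeriods), 2), ", sd ",
        round(sd(object@individualPeriods), 2), "\n", sep = "")
})

## ---- PatternLibrary ----

setMethod("length", "PatternLibrary", function(x) nrow(x@templates))

#' @describeIn PatternLibrary-class sampling times of the templates
#' @param object a `PatternLibrary`
#' @export
setMethod("timepoints", "PatternLibrary", function(object) object@timepoints)

setMethod("show", "PatternLibrary", function(object) {
  cat("PatternLibrary:", length(object), "templates (",
      paste(unique(object@shape), collapse = ", "), ")\n")
  cat("  phase shifts:", length(unique(object@phaseShift)), "on [0,",
      object@period, ") h\n")
})

## ---- ConsensusTable ----

#' @describeIn ConsensusTable-class named per-gene consensus counts
#' @param object a `ConsensusTable`
#' @export
setMethod("geneCounts", "ConsensusTable", function(object) object@counts)

#' @describeIn ConsensusTable-class number of datasets tallied
#' @export
setMethod("nDatasets", "ConsensusTable", function(object) object@nDatasets)

#' @describeIn ConsensusTable-class genes called rhythmic in at least `k`
#'   of the datasets; `k = 1` is the union of the call sets and
#'   `k = nDatasets` their intersection
#' @param k consensus threshold (number of datasets)
#' @export
setMethod("consensusSet", "ConsensusTable", function(object, k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > object@nDatasets)
    stop("'k' must lie in [1, nDatasets]")
  names(object@counts)[object@counts >= k]
})

setMethod("show", "ConsensusTable", function(object) {
  cat("ConsensusTable:", length(object@counts), "genes over",
      object@nDatasets, "datasets\n")
  cat("  genes with count >= 1:", sum(object@counts >= 1L), "\n")
})
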