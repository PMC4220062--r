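#' Resample a replicated dataset into a single-replicate time course
#'
#' Builds one resampled dataset from a replicated time course: at every
#' time point one of the available replicate values is selected uniformly
#' at random, time points being treated independently of one another.
#' In `"per_gene"` mode (the default) the selection is made independently
#' for every (gene, timepoint) cell; in `"per_sample"` mode one replicate
#' is selected per timepoint and applied to all genes (whole-sample
#' selection). Every output value equals some input value at the same
#' (gene, timepoint) - no interpolation ever. A single-replicate input is
#' returned unchanged.
#'
#' @param object a [RhythmExperiment-class] with a complete
#'   (time, replicate) crossing.
#' @param mode `"per_gene"` or `"per_sample"`.
#' @param seed integer seed.
#' @return a single-replicate [RhythmExperiment-class] keeping the truth
#'   annotation.
#' @examples
#' coh <- simulateLD(nRhythmic = 4, nNull = 4, nIndividuals = 36, seed = 1)
#' re <- assembleInitialDatasets(coh, 3, seed = 2)
#' rs <- resampleDataset(re, seed = 3)
#' nReplicates(rs)
#' @export
resampleDataset <- function(object, mode = c("per_gene", "per_sample"),
                            seed = NULL) {
  stopifnot(is(object, "RhythmExperiment"))
  mode <- match.arg(mode)
  if (nrow(object) == 0L) stop("empty dataset")
  a <- exprsArray(object)
  G <- dim(a)[1]; Tn <- dim(a)[2]; R <- dim(a)[3]
  out <- withSeed(seed, {
    if (R == 1L) {
      a[, , 1]
    } else if (mode == "per_gene") {
      pick <- matrix(sample.int(R, G * Tn, replace = TRUE), G, Tn)
      m <- matrix(a[cbind(rep(seq_len(G), Tn),
                          rep(seq_len(Tn), each = G),
                          as.vector(pick))], G, Tn)
      dimnames(m) <- dimnames(a)[1:2]
      m
    } else {
      pick <- sample.int(R, Tn, replace = TRUE)
      m <- sapply(seq_len(Tn), function(ti) a[, ti, pick[ti]])
      dimnames(m) <- dimnames(a)[1:2]
      m
    }
  })
  rd <- rowData(object)
  RhythmExperiment(out, time = timepoints(object),
                   replicate = rep(1L, Tn),
                   truth = if (ncol(rd)) as.data.frame(rd) else NULL)
}

#' Average replicates at each time point
#'
#' @param object a [RhythmExperiment-class].
#' @return a single-replicate [RhythmExperiment-class] whose values are
#'   the arithmetic mean across replicates at each (gene, timepoint).
#' @export
averageDataset <- function(object) {
  stopifnot(is(object, "RhythmExperiment"))
  a <- exprsArray(object)
  m <- rowMeans(a, dims = 2L)
  dimnames(m) <- dimnames(a)[1:2]
  rd <- rowData(object)
  RhythmExperiment(m, time = timepoints(object),
                   replicate = rep(1L, dim(a)[2]),
                   truth = if (ncol(rd)) as.data.frame(rd) else NULL)
}

#' Consensus counts across rhythmic call sets
#'
#' Tallies, for every gene of a common universe, the number of datasets
#' whose rhythmic call set contains the gene.
#'
#' @param callSets list of character vectors of rhythmic gene ids, one
#'   per analysed dataset.
#' @param universe character vector of all gene ids.
#' @return a [ConsensusTable-class].
#' @examples
#' ct <- consensusCounts(list(c("A", "B"), "B", c("B", "C")),
#'                       universe = c("A", "B", "C", "D"))
#' geneCounts(ct)
#' consensusSet(ct, 3)   # intersection
#' @export
consensusCounts <- function(callSets, universe) {
  counts <- stats::setNames(integer(length(universe)), universe)
  for (cs in callSets) {
    if (!all(cs %in% universe))
      stop("call set contains gene ids outside the universe: ",
           paste(head(setdiff(cs, universe), 3), collapse = ", "))
    counts[cs] <- counts[cs] + 1L
  }
  new("ConsensusTable", counts = counts,
      nDatasets = length(callSets))
}

#' Resampling consensus analysis of a replicated dataset
#'
#' The core method: generates `nResamples` resampled datasets (seeded
#' sub-streams derived from `seed`), runs the chosen detector on each,
#' and tallies per-gene consensus counts over the resulting call sets.
#'
#' @param object a [RhythmExperiment-class].
#' @param method detector name (see [detectRhythms()]).
#' @param nResamples number of resampled datasets (36 by default).
#' @param mode resampling granularity, see [resampleDataset()].
#' @param seed master seed for the resampling stage.
#' @param detectorArgs named list of extra detector arguments.
#' @return list with elements `callSets` (length `nResamples`),
#'   `consensus` (a [ConsensusTable-class]) and `manifest` (the per-
#'   dataset sub-seeds and configuration).
#' @examples
#' coh <- simulateLD(nRhythmic = 10, nNull = 10, nIndividuals = 36,
#'                   seed = 1)
#' re <- assembleInitialDatasets(coh, 3, seed = 2)
#' ra <- runResamplingAnalysis(re, nResamples = 5, seed = 3)
#' nDatasets(ra$consensus)
#' @export
runResamplingAnalysis <- function(object, method = "arser",
                                  nResamples = 36,
                                  mode = c("per_gene", "per_sample"),
                                  seed = NULL, detectorArgs = list()) {
  stopifnot(is(object, "RhythmExperiment"))
  if (nResamples < 1) stop("'nResamples' must be >= 1")
  mode <- match.arg(mode)
  subSeeds <- deriveSeeds(seed, nResamples, "resample")
  if (method == "haystack" && is.null(detectorArgs$library))
    detectorArgs$library <-
      suppressWarnings(buildPatternLibrary(timepoints(object)))
  callSets <- vector("list", nResamples)
  for (i in seq_len(nResamples)) {
    rs <- resampleDataset(object, mode = mode, seed = subSeeds[i])
    res <- tryCatch(
      do.call(detectRhythms, c(list(rs, method = method), detectorArgs)),
      error = function(e)
        stop("detector '", method, "' failed on resampled dataset ", i,
             ": ", conditionMessage(e)))
    callSets[[i]] <- callSet(res)
  }
  list(callSets = callSets,
       consensus = consensusCounts(callSets, rownames(object)),
       manifest = list(method = method, nResamples = nResamples,
                       mode = mode, seed = seed, subSeeds = subSeeds))
}
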