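## Scoring detector calls against simulation truth and the benchmark
## machinery: TP/FP against consensus level, replicate-count sensitivity,
## and venn-style overlap counts.

confusionFromSet <- function(set, truth) {
  pos <- names(truth)[truth]
  neg <- names(truth)[!truth]
  tp <- sum(set %in% pos)
  fp <- sum(set %in% neg)
  c(tp = tp, fp = fp, tn = length(neg) - fp, fn = length(pos) - tp)
}

#' Confusion counts at a consensus threshold
#'
#' Scores the consensus set at level `k` against ground-truth labels:
#' `tp` is the number of truth-positive genes in the consensus set, `fp`
#' the number of truth-negative genes in it; `fn` and `tn` follow by
#' complement, so `tp + fn` and `fp + tn` equal the truth class sizes.
#'
#' @param table a [ConsensusTable-class].
#' @param truth named logical vector over the same gene universe.
#' @param k consensus threshold.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionAtConsensus <- function(table, truth, k) {
  stopifnot(is(table, "ConsensusTable"))
  if (is.null(names(truth)) ||
      !setequal(names(truth), names(geneCounts(table))))
    stop("'truth' must be named and share the gene universe of 'table'")
  confusionFromSet(consensusSet(table, k), truth)
}

## internal: run the configured detector on a single-replicate experiment
makeDetector <- function(method, detectorArgs, timepoints) {
  if (method == "haystack" && is.null(detectorArgs$library))
    detectorArgs$library <-
      suppressWarnings(buildPatternLibrary(timepoints))
  function(re) do.call(detectRhythms,
                       c(list(re, method = method), detectorArgs))
}

benchRow <- function(simType, method, kind, k, conf, seed) {
  data.frame(simType = simType, method = method, kind = kind, k = k,
             tp = conf[["tp"]], fp = conf[["fp"]], tn = conf[["tn"]],
             fn = conf[["fn"]],
             seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Full simulation benchmark for one simulation type and detector
#'
#' Runs the complete pipeline: simulate a cohort of individual time
#' courses, assemble the initial replicate datasets by destructive
#' sampling, then score the detector on (i) each individual replicate,
#' (ii) the replicate-averaged dataset, (iii) the consensus across the
#' initial replicates, (iv) the consensus across `nResamples` resampled
#' datasets, and (v) the consensus across the original simulations (the
#' ideal ceiling in which one individual could be measured repeatedly).
#' Confusion counts are emitted for every consensus level.
#'
#' @param simType `"ld"`, `"ll"` or `"ode"`.
#' @param method detector name (see [detectRhythms()]).
#' @param nRhythmic,nNull,nIndividuals,timepoints,snr,noiseSd simulation
#'   parameters, see [simulateLD()].
#' @param nReplicates replicates in the initial dataset.
#' @param nResamples resampled datasets for the consensus.
#' @param seed master seed; simulation, assembly and resampling stages
#'   derive named sub-streams from it.
#' @param kinds subset of dataset kinds to evaluate (all by default).
#' @param detectorArgs named list of extra detector arguments.
#' @return long-form `data.frame` with columns `simType`, `method`,
#'   `kind` (`replicate_<i>`, `averaged`, `initial_consensus`,
#'   `resampled_consensus`, `original_consensus`), `k` (consensus level,
#'   NA for single datasets), `tp`, `fp`, `tn`, `fn`, `seed`.
#' @examples
#' b <- runBenchmark("ld", nRhythmic = 15, nNull = 15, seed = 1,
#'                   nResamples = 4,
#'                   kinds = c("replicates", "resampled_consensus"))
#' head(b)
#' @export
runBenchmark <- function(simType = c("ld", "ll", "ode"), method = "arser",
                         nRhythmic = 8400, nNull = 8400,
                         nIndividuals = 36, nReplicates = 3,
                         nResamples = 36,
                         timepoints = DEFAULT_TIMEPOINTS, snr = 2,
                         noiseSd = 1, seed = NULL,
                         kinds = c("replicates", "averaged",
                                   "initial_consensus",
                                   "resampled_consensus",
                                   "original_consensus"),
                         detectorArgs = list()) {
  simType <- match.arg(simType)
  kinds <- match.arg(kinds, several.ok = TRUE)
  seeds <- deriveSeeds(seed, 3, "benchmark")
  cohort <- switch(simType,
    ld = simulateLD(nRhythmic, nNull, timepoints, nIndividuals, snr,
                    noiseSd, seed = seeds[1]),
    ll = simulateLL(nRhythmic, nNull, timepoints, nIndividuals, snr,
                    noiseSd, seed = seeds[1]),
    ode = simulateODE(nRhythmic, nNull, timepoints, nIndividuals, snr,
                      noiseSd, seed = seeds[1]))
  initial <- assembleInitialDatasets(cohort, nReplicates, seed = seeds[2])
  truth <- truthLabels(initial)
  detector <- makeDetector(method, detectorArgs, timepoints(initial))
  out <- list()
  repCalls <- NULL
  if (any(c("replicates", "initial_consensus") %in% kinds)) {
    repCalls <- lapply(seq_len(nReplicates), function(r)
      callSet(detector(replicateExperiment(initial, r))))
  }
  if ("replicates" %in% kinds) {
    for (r in seq_len(nReplicates))
      out[[length(out) + 1L]] <-
        benchRow(simType, method, paste0("replicate_", r), NA_integer_,
                 confusionFromSet(repCalls[[r]], truth), seed)
  }
  if ("averaged" %in% kinds) {
    avgCalls <- callSet(detector(averageDataset(initial)))
    out[[length(out) + 1L]] <-
      benchRow(simType, method, "averaged", NA_integer_,
               confusionFromSet(avgCalls, truth), seed)
  }
  if ("initial_consensus" %in% kinds) {
    ct <- consensusCounts(repCalls, names(truth))
    for (k in seq_len(nReplicates))
      out[[length(out) + 1L]] <-
        benchRow(simType, method, "initial_consensus", k,
                 confusionAtConsensus(ct, truth, k), seed)
  }
  if ("resampled_consensus" %in% kinds) {
    ra <- runResamplingAnalysis(initial, method = method,
                                nResamples = nResamples, seed = seeds[3],
                                detectorArgs = detectorArgs)
    for (k in seq_len(nResamples))
      out[[length(out) + 1L]] <-
        benchRow(simType, method, "resampled_consensus", k,
                 confusionAtConsensus(ra$consensus, truth, k), seed)
  }
  if ("original_consensus" %in% kinds) {
    origCalls <- lapply(seq_len(nIndividuals(cohort)), function(i)
      callSet(detector(individualExperiment(cohort, i))))
    ct <- consensusCounts(origCalls, names(truth))
    for (k in seq_len(nIndividuals(cohort)))
      out[[length(out) + 1L]] <-
        benchRow(simType, method, "original_consensus", k,
                 confusionAtConsensus(ct, truth, k), seed)
  }
  do.call(rbind, out)
}

#' Replicate-count sensitivity of the consensus analysis
#'
#' From one cohort of `nIndividuals` original simulations, assembles
#' initial datasets with each requested replicate count, scores the
#' consensus across the initial replicates, and (optionally) the
#' consensus across resampled datasets, at every consensus level.
#'
#' @inheritParams runBenchmark
#' @param replicateCounts replicate counts to assemble (each requires
#'   `replicates x timepoints <= nIndividuals`).
#' @param includeResampled also run the resampling consensus for each
#'   replicate count.
#' @return long-form `data.frame` as [runBenchmark()], plus a
#'   `nReplicates` column.
#' @export
replicateSensitivity <- function(simType = "ll", method = "arser",
                                 nRhythmic = 8400, nNull = 8400,
                                 nIndividuals = 72,
                                 replicateCounts = c(2, 3, 4, 5, 6),
                                 nResamples = 36,
                                 timepoints = DEFAULT_TIMEPOINTS,
                                 snr = 2, noiseSd = 1, seed = NULL,
                                 includeResampled = TRUE,
                                 detectorArgs = list()) {
  simType <- match.arg(simType, c("ld", "ll", "ode"))
  if (nIndividuals < max(replicateCounts) * length(timepoints))
    stop("'nIndividuals' must be at least max(replicateCounts) x ",
         "timepoints = ", max(replicateCounts) * length(timepoints))
  seeds <- deriveSeeds(seed, 1 + 2 * length(replicateCounts),
                       "replicate_sensitivity")
  cohort <- switch(simType,
    ld = simulateLD(nRhythmic, nNull, timepoints, nIndividuals, snr,
                    noiseSd, seed = seeds[1]),
    ll = simulateLL(nRhythmic, nNull, timepoints, nIndividuals, snr,
                    noiseSd, seed = seeds[1]),
    ode = simulateODE(nRhythmic, nNull, timepoints, nIndividuals, snr,
                      noiseSd, seed = seeds[1]))
  detector <- makeDetector(method, detectorArgs, timepoints)
  out <- list()
  for (j in seq_along(replicateCounts)) {
    r <- replicateCounts[j]
    initial <- assembleInitialDatasets(cohort, r, seed = seeds[1 + j])
    truth <- truthLabels(initial)
    repCalls <- lapply(seq_len(r), function(rr)
      callSet(detector(replicateExperiment(initial, rr))))
    ct <- consensusCounts(repCalls, names(truth))
    for (k in seq_len(r)) {
      row <- benchRow(simType, method, "initial_consensus", k,
                      confusionAtConsensus(ct, truth, k), seed)
      row$nReplicates <- r
      out[[length(out) + 1L]] <- row
    }
    if (includeResampled) {
      ra <- runResamplingAnalysis(initial, method = method,
                                  nResamples = nResamples,
                                  seed = seeds[1 + length(replicateCounts) + j],
                                  detectorArgs = detectorArgs)
      for (k in seq_len(nResamples)) {
        row <- benchRow(simType, method, "resampled_consensus", k,
                        confusionAtConsensus(ra$consensus, truth, k), seed)
        row$nReplicates <- r
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}

#' Venn-region counts across call sets
#'
#' For every non-empty subset S of the datasets, counts the genes called
#' in exactly the datasets of S (the venn regions of the call sets).
#'
#' @param callSets named list of 2 to 6 character vectors of gene ids.
#' @return named integer vector; names are `&`-joined dataset names and
#'   the sum over all regions equals the size of the union.
#' @examples
#' overlapCounts(list(r1 = c("A", "B"), r2 = "B", r3 = c("B", "C")))
#' @export
overlapCounts <- function(callSets) {
  m <- length(callSets)
  if (m < 2L || m > 6L)
    stop("between 2 and 6 call sets are supported, got ", m)
  if (is.null(names(callSets)))
    names(callSets) <- paste0("set", seq_len(m))
  universe <- unique(unlist(callSets))
  member <- vapply(callSets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(b)
    paste(names(callSets)[b], collapse = "&"))
  regions <- unlist(lapply(seq_len(m), function(sz)
    combn(names(callSets), sz, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(regions)), regions)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  counts
}
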