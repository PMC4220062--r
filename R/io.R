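## Tab-delimited matrix I/O and JSON run manifests.
##
## The native header dialect is `T<time>_R<replicate>` (e.g. T0_R1); the
## reader also accepts the `ZT<time>.<replicate>` dialect common in
## published circadian expression tables.

parseSampleHeader <- function(h) {
  m <- regmatches(h, regexec("^T([0-9]+\\.?[0-9]*)_R([0-9]+)$", h))[[1]]
  if (length(m) == 3L)
    return(list(time = as.numeric(m[2]), replicate = as.integer(m[3])))
  m <- regmatches(h, regexec("^ZT([0-9]+\\.?[0-9]*)\\.([0-9]+)$", h))[[1]]
  if (length(m) == 3L)
    return(list(time = as.numeric(m[2]), replicate = as.integer(m[3])))
  NULL
}

#' Read a replicated expression matrix
#'
#' Reads a tab-delimited expression table (first column gene ids, sample
#' columns named `T<time>_R<rep>` or `ZT<time>.<rep>`) into a
#' [RhythmExperiment-class], inferring the replicate structure from the
#' headers. Ragged rows, unparseable headers and duplicated gene ids are
#' rejected with informative errors.
#'
#' @param path file path.
#' @return A [RhythmExperiment-class].
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged table: line ", which(nf != nf[1])[1],
         " has ", nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated gene id: ", ids[which(duplicated(ids))[1]])
  heads <- colnames(df)[-1]
  parsed <- lapply(heads, parseSampleHeader)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("unparseable sample header(s): ",
         paste(head(heads[bad], 3), collapse = ", "),
         " (expected T<time>_R<rep> or ZT<time>.<rep>)")
  time <- vapply(parsed, `[[`, numeric(1), "time")
  repl <- vapply(parsed, `[[`, integer(1), "replicate")
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- ids
  o <- order(repl, time)
  RhythmExperiment(x[, o, drop = FALSE], time = time[o],
                   replicate = repl[o])
}

#' Write a dataset as tab-delimited text (plus truth sidecar and manifest)
#'
#' Writes `<prefix>_matrix.tsv` (columns `gene_id`, then
#' `T<time>_R<rep>`), a `<prefix>_truth.tsv` sidecar when the dataset
#' carries simulation truth, and a `<prefix>_manifest.json` run manifest.
#'
#' @param object a [RhythmExperiment-class].
#' @param prefix output path prefix.
#' @param manifest optional manifest list (see [makeRunManifest()]).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(object, prefix, manifest = NULL) {
  stopifnot(is(object, "RhythmExperiment"))
  o <- order(colData(object)$replicate, sampleTimes(object))
  x <- assay(object, "exprs")[, o, drop = FALSE]
  df <- data.frame(gene_id = rownames(x), fmtNum(x),
                   check.names = FALSE)
  pMat <- paste0(prefix, "_matrix.tsv")
  write.table(df, pMat, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- pMat
  rd <- rowData(object)
  if ("rhythmic" %in% colnames(rd)) {
    tr <- data.frame(gene_id = rownames(object),
                     rhythmic = rd$rhythmic,
                     period = fmtNum(rd$period),
                     phase = fmtNum(rd$phase),
                     waveform = rd$waveform)
    pTr <- paste0(prefix, "_truth.tsv")
    write.table(tr, pTr, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pTr)
  }
  if (is.null(manifest))
    manifest <- makeRunManifest(config = list(
      nGenes = nrow(object), timepoints = timepoints(object),
      nReplicates = nReplicates(object)))
  prov <- provenance(object)
  if (!is.null(prov)) manifest$provenance <- prov
  pMan <- paste0(prefix, "_manifest.json")
  writeManifest(manifest, pMan)
  invisible(c(paths, pMan))
}

#' Write per-gene detector results
#'
#' Tab-delimited, one row per gene, `gene_id` first, floats at 6
#' significant digits, fixed column order as in the result object.
#'
#' @param results a per-gene result ([S4Vectors::DataFrame] or
#'   data.frame) with gene ids as row names.
#' @param path output path.
#' @export
writeResults <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  out <- data.frame(gene_id = rownames(df), df, check.names = FALSE,
                    row.names = NULL)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus table
#'
#' Tab-delimited with columns `gene_id`, `count`, `n_datasets`.
#'
#' @param table a [ConsensusTable-class].
#' @param path output path.
#' @export
writeConsensus <- function(table, path) {
  stopifnot(is(table, "ConsensusTable"))
  out <- data.frame(gene_id = names(geneCounts(table)),
                    count = as.integer(geneCounts(table)),
                    n_datasets = nDatasets(table))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a run manifest
#'
#' A manifest records everything needed to replay a run: package version,
#' master seed, named per-stage sub-seeds, the configuration snapshot,
#' digests of any input/output files, and a timestamp.
#'
#' @param seed master seed (may be NULL).
#' @param stages named list of per-stage sub-seed vectors.
#' @param config configuration snapshot (named list).
#' @param files character vector of file paths to digest.
#' @return a manifest list.
#' @export
makeRunManifest <- function(seed = NULL, stages = list(),
                            config = list(), files = character()) {
  digests <- if (length(files))
    as.list(tools::md5sum(files)) else list()
  list(tool = "rhythmResample",
       version = as.character(packageVersion("rhythmResample")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, stages = stages, config = config,
       fileDigests = digests)
}

#' Write / validate a run manifest
#'
#' `writeManifest()` writes the manifest as JSON; `validateManifest()`
#' checks a manifest (or a JSON path) against the shipped schema
#' (`inst/extdata/manifest-schema.json`): all required fields present
#' with the expected JSON types.
#'
#' @param manifest a manifest list (for validation, alternatively a path
#'   to a manifest JSON file).
#' @param path output path.
#' @return `writeManifest()`: the path, invisibly. `validateManifest()`:
#'   TRUE, or an error describing the first violation.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeManifest
#' @export
validateManifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- jsonlite::read_json(manifest)
  schema <- jsonlite::read_json(system.file("extdata",
                                            "manifest-schema.json",
                                            package = "rhythmResample"))
  for (field in names(schema$required)) {
    if (!field %in% names(manifest))
      stop("manifest missing required field '", field, "'")
    type <- schema$required[[field]]
    val <- manifest[[field]]
    okay <- switch(type,
                   string = is.character(val) && length(val) == 1L,
                   object = is.list(val),
                   TRUE)
    if (!okay)
      stop("manifest field '", field, "' must be of JSON type ", type)
  }
  TRUE
}

#' Exclude genes with missing values
#'
#' Real datasets may contain missing values; all detectors assume
#' complete uniform series, so genes with any missing value are excluded
#' (and reported) rather than imputed.
#'
#' @param object a [RhythmExperiment-class].
#' @return the filtered object; the removed gene ids are reported in a
#'   message and stored in `metadata(x)$excludedGenes`.
#' @export
dropIncompleteGenes <- function(object) {
  stopifnot(is(object, "RhythmExperiment"))
  bad <- apply(is.na(assay(object, "exprs")), 1L, any)
  if (!any(bad)) return(object)
  message(sum(bad), " gene(s) with missing values excluded from detection")
  out <- object[!bad, ]
  metadata(out)$excludedGenes <- rownames(object)[bad]
  out
}
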