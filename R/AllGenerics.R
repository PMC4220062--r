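#' @export
setGeneric("truthLabels", function(object, ...) standardGeneric("truthLabels"))

#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @export
setGeneric("timepoints", function(object) standardGeneric("timepoints"))

#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))

#' @export
setGeneric("geneParams", function(object) standardGeneric("geneParams"))

#' @export
setGeneric("individualPeriods", function(object) standardGeneric("individualPeriods"))

#' @export
setGeneric("individualMatrix", function(object, i) standardGeneric("individualMatrix"))

#' @export
setGeneric("geneCounts", function(object) standardGeneric("geneCounts"))

#' @export
setGeneric("nDatasets", function(object) standardGeneric("nDatasets"))

#' @export
setGeneric("consensusSet", function(object, k) standardGeneric("consensusSet"))

#' @export
setGeneric("detectRhythms", function(object, ...) standardGeneric("detectRhythms"))
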