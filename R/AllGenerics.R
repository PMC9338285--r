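#' Probe identifiers of a methylation container
#' @param x a BetaMatrix, MValueMatrix, ProbeManifest or model object
#' @return character vector of probe ids, in storage order
#' @export
setGeneric("probeIDs", function(x) standardGeneric("probeIDs"))

#' Sample identifiers of a methylation container
#' @param x a BetaMatrix, MValueMatrix or SampleAnnotation
#' @return character vector of sample ids, in storage order
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Underlying numeric matrix of a methylation container
#' @param x a BetaMatrix or MValueMatrix
#' @return the probes-by-samples numeric matrix
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' Annotation table of a manifest / sample-annotation object
#' @param x a ProbeManifest, SampleAnnotation or SelectionRanking
#' @return data.frame, one row per probe or sample
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

setMethod("probeIDs", "BetaMatrix", function(x) rownames(x@values))
setMethod("probeIDs", "MValueMatrix", function(x) rownames(x@values))
setMethod("probeIDs", "ProbeManifest", function(x) x@table$probe_id)
setMethod("probeIDs", "BinaryModelSpec", function(x) x@probes)
setMethod("probeIDs", "SubtypeModel", function(x) x@probes)
setMethod("probeIDs", "SelectionRanking", function(x) x@table$probe_id)

setMethod("sampleIDs", "BetaMatrix", function(x) colnames(x@values))
setMethod("sampleIDs", "MValueMatrix", function(x) colnames(x@values))
setMethod("sampleIDs", "SampleAnnotation", function(x) x@table$sample_id)

setMethod("assayValues", "BetaMatrix", function(x) x@values)
setMethod("assayValues", "MValueMatrix", function(x) x@values)

setMethod("annotationTable", "ProbeManifest", function(x) x@table)
setMethod("annotationTable", "SampleAnnotation", function(x) x@table)
setMethod("annotationTable", "SelectionRanking", function(x) x@table)

setMethod("dim", "BetaMatrix", function(x) dim(x@values))
setMethod("dim", "MValueMatrix", function(x) dim(x@values))

setMethod("show", "BetaMatrix", function(object) {
  v <- object@values
  cat(sprintf("BetaMatrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "MValueMatrix", function(object) {
  v <- object@values
  cat(sprintf("MValueMatrix: %d probes x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "ProbeManifest", function(object) {
  cat(sprintf("ProbeManifest: %d probes (%d autosomal, %d type II)\n",
              nrow(object@table),
              sum(object@table$chromosome %in% .AUTOSOMES),
              sum(object@table$infinium_type == "II")))
})

setMethod("show", "SampleAnnotation", function(object) {
  cat(sprintf("SampleAnnotation: %d samples\n", nrow(object@table)))
})

setMethod("show", "BinaryModelSpec", function(object) {
  cat(sprintf(
    "BinaryModelSpec [%s]: %d probes, alpha = %g, lambda = %g, threshold = %g\n",
    object@alteration, length(object@probes), object@alpha, object@lambda,
    object@threshold))
})

setMethod("show", "SelectionRanking", function(object) {
  cat(sprintf("SelectionRanking: %d probes, alphas = %s\n",
              nrow(object@table),
              paste(object@metadata$alphas, collapse = ", ")))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf(
    "QCReport: %d probes removed, %d samples removed, %d cells masked\n",
    length(object@removedProbes), length(object@removedSamples),
    sum(object@maskedCells)))
})

setMethod("show", "SubtypeModel", function(object) {
  cat(sprintf("SubtypeModel: random forest, %d probes, classes = %s\n",
              length(object@probes), paste(object@classes, collapse = "/")))
})

setMethod("show", "ClusterMembership", function(object) {
  cat(sprintf("ClusterMembership: %d samples in %d clusters\n",
              length(object@membership), object@k))
})
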