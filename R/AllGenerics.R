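#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("trackProbs", function(x) standardGeneric("trackProbs"))

#' @rdname accessors
#' @export
setGeneric("usageCounts", function(x) standardGeneric("usageCounts"))

#' @rdname accessors
#' @export
setGeneric("siteFrequencies", function(x) standardGeneric("siteFrequencies"))

#' @rdname accessors
#' @export
setGeneric("segmentBounds", function(x) standardGeneric("segmentBounds"))

#' @rdname accessors
#' @export
setGeneric("depthA", function(x) standardGeneric("depthA"))

#' @rdname accessors
#' @export
setGeneric("depthB", function(x) standardGeneric("depthB"))

#' @rdname accessors
#' @export
setGeneric("arrayDerived", function(x) standardGeneric("arrayDerived"))

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname accessors
#' @export
setGeneric("trueGenotypes", function(x) standardGeneric("trueGenotypes"))

#' @rdname accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' Accessors for HapDepth containers
#'
#' @param x a \linkS4class{HaplotypeLibrary}, \linkS4class{SeqDepthSet} or
#'   \linkS4class{GenotypeCalls} object.
#' @return \code{nTracks}: number of tracks; \code{trackProbs}: sites x
#'   tracks probability matrix; \code{usageCounts}: per-track assignment
#'   counts; \code{siteFrequencies}: per-site A-allele frequencies;
#'   \code{segmentBounds}: integer (start, end), 0-based half-open;
#'   \code{depthA}/\code{depthB}: read count matrices;
#'   \code{arrayDerived}: logical matrix of array-derived entries;
#'   \code{pedigree}: pedigree data.frame; \code{trueGenotypes}: true
#'   A-allele counts (sites x individuals) or NULL;
#'   \code{genotypeMatrix}/\code{dosageMatrix}: called genotypes and
#'   dosages.
#' @name accessors
#' @examples
#' lib <- HaplotypeLibrary(0, 4, freqs = rep(0.5, 4))
#' nTracks(lib)
NULL

#' @rdname accessors
setMethod("nTracks", "HaplotypeLibrary", function(x) ncol(x@probs))

#' @rdname accessors
setMethod("trackProbs", "HaplotypeLibrary", function(x) x@probs)

#' @rdname accessors
setMethod("usageCounts", "HaplotypeLibrary", function(x) x@usage)

#' @rdname accessors
setMethod("siteFrequencies", "HaplotypeLibrary", function(x) x@freqs)

#' @rdname accessors
setMethod("segmentBounds", "HaplotypeLibrary",
          function(x) c(start = x@start, end = x@end))

#' @rdname accessors
setMethod("depthA", "SeqDepthSet",
          function(x) SummarizedExperiment::assay(x, "nA"))

#' @rdname accessors
setMethod("depthB", "SeqDepthSet",
          function(x) SummarizedExperiment::assay(x, "nB"))

#' @rdname accessors
setMethod("arrayDerived", "SeqDepthSet",
          function(x) SummarizedExperiment::assay(x, "arrayDerived"))

#' @rdname accessors
setMethod("pedigree", "SeqDepthSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(id = rownames(cd), sire = cd$sire, dam = cd$dam,
             birth = cd$birth, dataClass = cd$dataClass)
})

#' @rdname accessors
setMethod("trueGenotypes", "SeqDepthSet", function(x) {
  tr <- metadata(x)$truth
  if (is.null(tr)) return(NULL)
  tr$mat + tr$pat
})

#' @rdname accessors
setMethod("genotypeMatrix", "GenotypeCalls",
          function(x) SummarizedExperiment::assay(x, "genotype"))

#' @rdname accessors
setMethod("dosageMatrix", "GenotypeCalls",
          function(x) SummarizedExperiment::assay(x, "dosage"))
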