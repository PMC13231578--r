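#' Accessor generics
#'
#' Small accessor generics for the S4 result classes. Each extracts one slot
#' or a derived quantity; none of them recompute anything.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("log2Cpm", function(object, ...) standardGeneric("log2Cpm"))

#' @rdname accessors
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))

#' @rdname accessors
#' @export
setGeneric("precisionWeights", function(object) standardGeneric("precisionWeights"))

#' @rdname accessors
#' @export
setGeneric("keptGenes", function(object) standardGeneric("keptGenes"))

#' @rdname accessors
#' @export
setGeneric("priorDf", function(object) standardGeneric("priorDf"))

#' @rdname accessors
#' @export
setGeneric("priorVar", function(object) standardGeneric("priorVar"))

#' @rdname accessors
#' @export
setGeneric("posteriorVar", function(object) standardGeneric("posteriorVar"))

#' @rdname accessors
#' @export
setGeneric("consensusRho", function(object) standardGeneric("consensusRho"))

#' @rdname accessors
#' @export
setGeneric("contrastName", function(object) standardGeneric("contrastName"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("medianRho", function(object) standardGeneric("medianRho"))

#' @rdname accessors
#' @export
setGeneric("stabilityCategory", function(object) standardGeneric("stabilityCategory"))

#' @rdname accessors
#' @export
setGeneric("replicateRhos", function(object) standardGeneric("replicateRhos"))

#' @rdname accessors
#' @export
setGeneric("responsiveGenes", function(object) standardGeneric("responsiveGenes"))

#' @rdname accessors
#' @export
setGeneric("deltas", function(object) standardGeneric("deltas"))

#' @rdname accessors
#' @export
setGeneric("dampenedFraction", function(object) standardGeneric("dampenedFraction"))

#' @rdname accessors
#' @export
setGeneric("amplifiedFraction", function(object) standardGeneric("amplifiedFraction"))

#' @rdname accessors
#' @export
setGeneric("strengthBand", function(object) standardGeneric("strengthBand"))
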