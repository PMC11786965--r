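#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname accessors
#' @export
setGeneric("survStatus", function(x) standardGeneric("survStatus"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("selectedBlocks", function(x) standardGeneric("selectedBlocks"))

#' @rdname accessors
#' @export
setGeneric("selectionCounts", function(x) standardGeneric("selectionCounts"))

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname accessors
#' @export
setGeneric("blockSizes", function(x) standardGeneric("blockSizes"))

#' @rdname accessors
#' @export
setGeneric("penaltyWeights", function(x, ...) standardGeneric("penaltyWeights"))

#' @rdname accessors
#' @export
setGeneric("finalRank", function(x) standardGeneric("finalRank"))

#' @rdname entryLambda
#' @export
setGeneric("entryLambda", function(path, b) standardGeneric("entryLambda"))
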