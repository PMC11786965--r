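#' Accessors for pvglasso S4 containers
#'
#' Small accessor family: prefer these over direct slot access.
#' `featureNames()` / `sampleNames()` return identifier vectors,
#' `exprMatrix()` the samples x features matrix, `survTime()` /
#' `survStatus()` the outcome vectors; `blocks()`, `blockSizes()` and
#' `penaltyWeights()` expose a [BlockPartition-class]; `selectedFeatures()`,
#' `selectedBlocks()` and `selectionCounts()` expose a
#' [SelectionResult-class]; `finalRank()` an [AggregatedRanking-class].
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return the corresponding component.
#' @name accessors
#' @aliases featureNames sampleNames exprMatrix survTime survStatus nSamples
#'   nFeatures selectedFeatures selectedBlocks selectionCounts blocks
#'   blockSizes finalRank
NULL

#' @rdname accessors
setMethod("featureNames", "SurvivalDataset", function(x) colnames(x@X))
#' @rdname accessors
setMethod("sampleNames", "SurvivalDataset", function(x) rownames(x@X))
#' @rdname accessors
setMethod("exprMatrix", "SurvivalDataset", function(x) x@X)
#' @rdname accessors
setMethod("survTime", "SurvivalDataset", function(x) x@time)
#' @rdname accessors
setMethod("survStatus", "SurvivalDataset", function(x) x@status)
#' @rdname accessors
setMethod("nSamples", "SurvivalDataset", function(x) nrow(x@X))
#' @rdname accessors
setMethod("nFeatures", "SurvivalDataset", function(x) ncol(x@X))

#' @rdname accessors
setMethod("featureNames", "SelectorOutput", function(x) x@features)
#' @rdname accessors
setMethod("featureNames", "AggregatedRanking", function(x) x@features)
#' @rdname accessors
setMethod("finalRank", "AggregatedRanking", function(x)
    stats::setNames(x@finalRank, x@features))

#' @rdname accessors
setMethod("blocks", "BlockPartition", function(x) x@blocks)
#' @rdname accessors
setMethod("blockSizes", "BlockPartition", function(x) x@sizes)

#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(x) x@selectedFeatures)
#' @rdname accessors
setMethod("selectedBlocks", "SelectionResult", function(x) x@selectedBlocks)
#' @rdname accessors
setMethod("selectionCounts", "SelectionResult", function(x) x@counts)

setMethod("show", "SurvivalDataset", function(object) {
    cat("SurvivalDataset:", nrow(object@X), "samples x", ncol(object@X),
        "features\n")
    cat("  events:", sum(object@status), " censored:",
        sum(object@status == 0L), "\n")
    cat("  follow-up range: [", format(min(object@time), digits = 4), ", ",
        format(max(object@time), digits = 4), "]\n", sep = "")
})

setMethod("show", "SelectorOutput", function(object) {
    cat("SelectorOutput <", object@selectorName, ">: ",
        length(object@features), " features\n", sep = "")
    if (length(object@features))
        cat("  top:", paste(utils::head(object@features, 5), collapse = ", "),
            "\n")
})

setMethod("show", "AggregatedRanking", function(object) {
    cat("AggregatedRanking:", length(object@features), "features from",
        ncol(object@perSelectorRank), "selectors\n")
    if (length(object@features))
        cat("  best ranked:",
            paste(utils::head(object@features[order(object@finalRank)], 5),
                  collapse = ", "), "\n")
})

setMethod("show", "BlockPartition", function(object) {
    cat("BlockPartition:", length(object@blocks), "blocks over",
        sum(object@sizes), "features (rhoT =", object@rhoT, ")\n")
    if (length(object@sizes))
        cat("  block sizes:", paste(utils::head(object@sizes, 10),
            collapse = " "), if (length(object@sizes) > 10) "...", "\n")
})

setMethod("show", "GroupLassoPath", function(object) {
    cat("GroupLassoPath:", length(object@lambda), "lambda values,",
        ncol(object@coef), "coefficients,", ncol(object@active), "groups\n")
    cat("  lambda range: [", format(min(object@lambda), digits = 4), ", ",
        format(max(object@lambda), digits = 4), "]; converged: ",
        sum(object@converged), "/", length(object@lambda), "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult: ", length(object@selectedBlocks), " blocks / ",
        length(object@selectedFeatures), " features selected (K = ",
        object@K, ", tau = ", object@tau, ", seed = ", object@seed, ")\n",
        sep = "")
    if (length(object@selectedFeatures))
        cat("  features:", paste(utils::head(object@selectedFeatures, 10),
            collapse = ", "),
            if (length(object@selectedFeatures) > 10) "...", "\n")
})

setMethod("show", "SimScenario", function(object) {
    cat("SimScenario <", object@label, ">: n = ", object@n, ", G = ",
        object@G, ", betas = (", paste(object@betas, collapse = ", "),
        "), target event rate = ", object@targetEventRate, "\n", sep = "")
})
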