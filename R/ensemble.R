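#' Impute per-selector ranks over the union feature set
#'
#' Each selector assigns ranks 1..m to its own selected features in its own
#' order; every union feature it did not select receives rank m + 1 (one
#' past its list), so non-selection is penalized uniformly. A selector with
#' empty output contributes rank 1 to every union feature, i.e. no
#' discrimination.
#'
#' @param outputs list of >= 2 [SelectorOutput-class] objects with a
#'   non-empty union.
#' @return integer matrix, union features x selectors.
#' @export
imputeRanks <- function(outputs) {
    if (length(outputs) < 2L)
        stop("rank aggregation needs at least 2 selectors")
    union <- unique(unlist(lapply(outputs, featureNames)))
    if (length(union) == 0L)
        stop("all selectors returned empty outputs: nothing to aggregate")
    ranks <- vapply(outputs, function(o) {
        m <- length(o@features)
        r <- rep.int(m + 1L, length(union))
        r[match(o@features, union)] <- seq_len(m)
        r
    }, integer(length(union)))
    ## vapply drops to a vector when the union has a single feature
    ranks <- matrix(ranks, nrow = length(union),
                    dimnames = list(union,
                        vapply(outputs, function(o) o@selectorName,
                               character(1))))
    ranks
}

#' Aggregate imputed ranks into a final ranking
#'
#' Mean-rank (Borda-style) aggregation: each union feature's score is the
#' mean of its per-selector imputed ranks; the final rank is the ascending
#' order of that score. Ties are broken first by the number of selectors
#' that actually selected the feature (more is better), then
#' lexicographically by feature name, so runs are bit-reproducible. The
#' result is invariant to the order of the selector list.
#'
#' @param outputs list of [SelectorOutput-class] objects (imputed
#'   internally), or an already-imputed rank matrix from [imputeRanks()]
#'   (in which case the membership tie-break is reconstructed from the
#'   imputation rule: a feature counts as selected by a selector when its
#'   rank is below that selector's column maximum).
#' @return an [AggregatedRanking-class], features ordered by final rank.
#' @export
aggregateRanks <- function(outputs) {
    if (is.matrix(outputs)) {
        ranks <- outputs
        colMax <- apply(ranks, 2L, max)
        selectedBy <- sweep(ranks, 2L, colMax, "<")
    } else {
        ranks <- imputeRanks(outputs)
        selectedBy <- vapply(outputs, function(o)
            rownames(ranks) %in% o@features, logical(nrow(ranks)))
        selectedBy <- matrix(selectedBy, nrow = nrow(ranks))
    }
    m <- nrow(ranks)
    meanRank <- rowMeans(ranks)
    nSelected <- rowSums(selectedBy)
    ord <- order(meanRank, -nSelected, rownames(ranks))
    new("AggregatedRanking",
        features = rownames(ranks)[ord],
        finalRank = seq_len(m),
        perSelectorRank = ranks[ord, , drop = FALSE])
}

#' Resolve an ensemble recipe to its selector list
#'
#' Recipe "ensemble1" is \{lasso, cox, mim\}; "ensemble2" is \{lasso, cox,
#' mim, mrmr\}; "custom" passes `selectors` through (>= 2 required).
#'
#' @param recipe "ensemble1", "ensemble2" or "custom".
#' @param selectors selector names for a custom recipe.
#' @return character vector of selector names.
#' @export
makeEnsemble <- function(recipe = c("ensemble1", "ensemble2", "custom"),
                         selectors = NULL) {
    recipe <- match.arg(recipe)
    out <- switch(recipe,
        ensemble1 = c("lasso", "cox", "mim"),
        ensemble2 = c("lasso", "cox", "mim", "mrmr"),
        custom = as.character(selectors))
    if (length(out) < 2L)
        stop("an ensemble needs at least 2 selectors")
    out
}

#' Run a named selector on a dataset
#'
#' Dispatch table from selector names (as used in recipes and configs) to
#' the base selector implementations; external rankings are supplied via
#' the `external` argument.
#'
#' @param name one of "lasso", "cox", "mim", "mrmr", or a name present in
#'   `external`.
#' @param dataset a [SurvivalDataset-class].
#' @param config a [RunConfig-class].
#' @param external named list of externally computed rankings (passed to
#'   [externalSelectorAdapter()]).
#' @return a [SelectorOutput-class].
#' @export
runSelector <- function(name, dataset, config = runConfig(),
                        external = list()) {
    switch(name,
        cox = univariateCoxSelect(dataset, k = config@k,
                                  alpha = config@alpha),
        lasso = lassoCoxSelect(dataset, seed = config@seed),
        mim = mimSelect(dataset, k = config@k, nBins = config@nBins),
        mrmr = mrmrSelect(dataset, k = config@k, nBins = config@nBins),
        {
            if (!name %in% names(external))
                stop("unknown selector '", name,
                     "' and no external ranking provided")
            externalSelectorAdapter(external[[name]], dataset,
                                    selectorName = name)
        })
}
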