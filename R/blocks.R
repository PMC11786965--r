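#' Partition aggregated features into correlation blocks
#'
#' Greedy rank-seeded clique growth: the best-ranked unassigned feature
#' seeds a new block; the remaining unassigned features are scanned in
#' final-rank order and a feature joins the block only when its absolute
#' correlation with EVERY current member exceeds `rhoT`, so the all-pairs
#' property holds by construction (and is re-verified post hoc). Features
#' with zero variance have undefined correlations and fall into singleton
#' blocks with a warning. Each block b then carries the penalty weight
#' s_b = (minimum final rank among members) x L_b, putting a small penalty
#' on top-ranked blocks.
#'
#' @param dataset a [SurvivalDataset-class] (>= 3 samples for correlation).
#' @param ranking an [AggregatedRanking-class] over a subset of the
#'   dataset's features.
#' @param rhoT within-block minimum absolute pairwise correlation,
#'   in (0, 1); default 0.75.
#' @param method "greedy" (default, rank-seeded clique growth) or
#'   "hclust" (complete-linkage hierarchical clustering on 1 - |corr|,
#'   cut at height 1 - rhoT).
#' @param corMethod correlation flavor, "pearson" (default) or "spearman".
#' @param sizeNormalized use the conventional sqrt(L_b) in place of L_b in
#'   the penalty weight (default FALSE: the literal min-rank x L_b).
#' @return a [BlockPartition-class]; blocks are ordered by their best
#'   member's final rank.
#' @export
buildBlocks <- function(dataset, ranking, rhoT = 0.75,
                        method = c("greedy", "hclust"),
                        corMethod = c("pearson", "spearman"),
                        sizeNormalized = FALSE) {
    method <- match.arg(method)
    corMethod <- match.arg(corMethod)
    feats <- ranking@features            # already in final-rank order
    if (length(feats) < 1L) stop("no features to partition")
    if (nSamples(dataset) < 3L)
        stop("need at least 3 samples to estimate correlations")
    X <- exprMatrix(dataset)[, feats, drop = FALSE]
    C <- suppressWarnings(abs(stats::cor(X, method = corMethod)))
    degenerate <- feats[apply(X, 2L, stats::sd) == 0]
    if (length(degenerate)) {
        warning("constant feature(s) placed in singleton blocks: ",
                paste(degenerate, collapse = ", "))
        C[is.na(C)] <- 0                 # never co-blocked
        diag(C) <- 1
    }
    blocks <- list()
    if (method == "greedy") {
        unassigned <- seq_along(feats)
        while (length(unassigned)) {
            seed <- unassigned[1L]       # best-ranked remaining feature
            members <- seed
            unassigned <- unassigned[-1L]
            for (j in unassigned)
                if (all(C[j, members] > rhoT)) members <- c(members, j)
            unassigned <- setdiff(unassigned, members)
            blocks[[length(blocks) + 1L]] <- feats[members]
        }
    } else {
        if (length(feats) == 1L) blocks <- list(feats) else {
            hc <- stats::hclust(stats::as.dist(1 - C), method = "complete")
            cl <- stats::cutree(hc, h = 1 - rhoT)
            blocks <- split(feats, cl)
            ## order blocks by best member rank; split within clusters with
            ## a violated all-pairs property is not needed for complete
            ## linkage at height 1 - rhoT, which guarantees it
            blocks <- blocks[order(vapply(blocks, function(b)
                min(match(b, feats)), numeric(1)))]
            names(blocks) <- NULL
        }
    }
    ## post-hoc verification of the all-pairs property
    for (b in blocks) {
        if (length(b) < 2L) next
        sub <- C[b, b]
        if (min(sub[upper.tri(sub)]) <= rhoT)
            stop("internal error: block violates the pairwise ",
                 "correlation threshold")
    }
    sizes <- lengths(blocks)
    rk <- finalRank(ranking)
    minRank <- vapply(blocks, function(b) min(rk[b]), numeric(1))
    Leff <- if (sizeNormalized) sqrt(sizes) else sizes
    new("BlockPartition", blocks = blocks, sizes = as.integer(sizes),
        rhoT = rhoT, weights = as.numeric(minRank * Leff))
}

#' Recompute penalty weights for an existing partition
#'
#' s_b = (minimum final rank among the block's members) x L_b.
#'
#' @param x a [BlockPartition-class].
#' @param ranking an [AggregatedRanking-class] covering every block member.
#' @param sizeNormalized use sqrt(L_b) instead of L_b.
#' @return numeric vector of weights s_b.
#' @export
setMethod("penaltyWeights", "BlockPartition",
    function(x, ranking = NULL, sizeNormalized = FALSE) {
        if (is.null(ranking)) return(x@weights)
        rk <- finalRank(ranking)
        miss <- setdiff(unlist(x@blocks), names(rk))
        if (length(miss))
            stop("block member(s) without a final rank: ",
                 paste(miss, collapse = ", "))
        sizes <- x@sizes
        Leff <- if (sizeNormalized) sqrt(sizes) else sizes
        vapply(seq_along(x@blocks), function(b)
            min(rk[x@blocks[[b]]]) * Leff[b], numeric(1))
    })
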