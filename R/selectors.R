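#' Base feature selectors
#'
#' The four base selectors composing the ensembles, each mapping a
#' [SurvivalDataset-class] to a ranked [SelectorOutput-class]:
#' \describe{
#'   \item{univariateCoxSelect}{per-feature single-covariate Cox fits (Wald
#'     test, Breslow ties); keeps features with p < `alpha`, ranks by
#'     ascending p, truncates to the top `k`. Constant features and fits
#'     that fail to converge are skipped with a warning.}
#'   \item{lassoCoxSelect}{L1-penalized Cox over a lambda grid; lambda is
#'     chosen by 5-fold cross-validated partial-likelihood deviance
#'     (minimum mean deviance); nonzero-coefficient features are ranked by
#'     descending |coefficient|. An empty selection (full shrinkage) is
#'     valid.}
#'   \item{mimSelect}{mutual information maximization: features are
#'     discretized by equal-frequency binning and scored by the mutual
#'     information with a discrete survival label (see
#'     [survivalLabel()]); top `k` by descending MI.}
#'   \item{mrmrSelect}{minimum-redundancy maximum-relevance greedy forward
#'     selection maximizing I(f; label) - mean_{s in S} I(f; s) until `k`
#'     features; rank = selection order.}
#' }
#'
#' @param dataset a [SurvivalDataset-class] (>= 2 observed events).
#' @param k top-k truncation (default 25).
#' @param alpha Wald p-value threshold for the univariate Cox selector.
#' @param ties tie handling for the Cox fits ("breslow" or "efron").
#' @param seed integer seed (cross-validation folds; ignored by the
#'   deterministic selectors).
#' @param lambdaGrid penalty grid for the L1 Cox path (default
#'   10^seq(-10, 10, 0.1), descending as glmnet expects).
#' @param nBins equal-frequency bins for the mutual-information selectors.
#' @param labelMode survival label encoding, see [survivalLabel()].
#' @return a [SelectorOutput-class].
#' @name baseSelectors
NULL

#' @rdname baseSelectors
#' @export
univariateCoxSelect <- function(dataset, k = 25, alpha = 0.05,
                                ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    if (sum(survStatus(dataset)) == 0L)
        stop("univariate Cox selection needs at least one observed event")
    X <- exprMatrix(dataset)
    y <- survival::Surv(survTime(dataset), survStatus(dataset))
    skipped <- character()
    pv <- vapply(seq_len(ncol(X)), function(j) {
        x <- X[, j]
        if (stats::sd(x) == 0) return(NA_real_)
        fit <- tryCatch(
            withCallingHandlers(
                survival::coxph(y ~ x, ties = ties),
                warning = function(w) invokeRestart("muffleWarning")),
            error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$coefficients[1L]) ||
            !is.finite(fit$var[1L, 1L]) || fit$var[1L, 1L] <= 0)
            return(NA_real_)
        stats::pchisq((fit$coefficients[1L] / sqrt(fit$var[1L, 1L]))^2,
                      df = 1, lower.tail = FALSE)
    }, numeric(1))
    skipped <- colnames(X)[is.na(pv)]
    if (length(skipped))
        warning("skipped ", length(skipped),
                " feature(s) with degenerate or non-converging fits")
    keep <- which(!is.na(pv) & pv < alpha)
    keep <- keep[order(pv[keep])]
    keep <- utils::head(keep, k)
    selectorOutput("cox", colnames(X)[keep], pv[keep], dataset = dataset)
}

#' @rdname baseSelectors
#' @export
lassoCoxSelect <- function(dataset, seed = 1,
                           lambdaGrid = 10^seq(10, -10, by = -0.1)) {
    if (sum(survStatus(dataset)) < 2L)
        stop("L1 Cox selection needs at least two observed events")
    X <- exprMatrix(dataset)
    y <- survival::Surv(survTime(dataset), survStatus(dataset))
    foldid <- withSeed(seed,
        sample(rep_len(seq_len(5L), nSamples(dataset))))
    muffle <- function(expr) withCallingHandlers(expr,
        warning = function(w) {
            ## glmnet interpolation notes on very wide fixed grids
            if (grepl("collapsing to unique", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    cv <- muffle(glmnet::cv.glmnet(X, y, family = "cox",
                                   lambda = lambdaGrid, foldid = foldid,
                                   type.measure = "deviance"))
    cf <- muffle(as.matrix(stats::coef(cv, s = "lambda.min"))[, 1L])
    nz <- cf[cf != 0]
    ord <- order(abs(nz), decreasing = TRUE)
    selectorOutput("lasso", names(nz)[ord], abs(nz)[ord], dataset = dataset)
}

#' Discrete survival label for mutual-information selectors
#'
#' Mutual information needs a discrete target; a censored outcome has no
#' canonical one. The default ("time-status") crosses the event indicator
#' with the tertile of observed time among events: censored samples form
#' their own class and events fall into 3 time-tertile classes (4 classes
#' total), using both the timing and the censoring information without
#' fitting a model. `"status"` uses the 2-class event indicator only.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param mode "time-status" (default) or "status".
#' @return integer class labels, one per sample.
#' @export
survivalLabel <- function(dataset, mode = c("time-status", "status")) {
    mode <- match.arg(mode)
    status <- survStatus(dataset)
    if (mode == "status") return(status)
    time <- survTime(dataset)
    lab <- integer(length(status))            # censored -> class 0
    ev <- status == 1L
    if (any(ev)) {
        qs <- stats::quantile(time[ev], c(1 / 3, 2 / 3), names = FALSE)
        lab[ev] <- 1L + findInterval(time[ev], qs)
    }
    lab
}

## Equal-frequency discretization into at most nBins classes; duplicate
## quantile breaks (heavy ties) collapse bins.
equalFreqBin <- function(x, nBins) {
    qs <- unique(stats::quantile(x, probs = seq_len(nBins - 1L) / nBins,
                                 names = FALSE))
    findInterval(x, qs)
}

## Mutual information (nats) between two discrete vectors.
discreteMI <- function(a, b) {
    tab <- table(a, b)
    p <- tab / sum(tab)
    pa <- rowSums(p); pb <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' @rdname baseSelectors
#' @export
mimSelect <- function(dataset, k = 25, nBins = 5,
                      labelMode = c("time-status", "status")) {
    if (nBins < 2L) stop("nBins must be >= 2")
    if (nSamples(dataset) < nBins)
        stop("need at least nBins samples for equal-frequency binning")
    X <- exprMatrix(dataset)
    lab <- survivalLabel(dataset, match.arg(labelMode))
    mi <- vapply(seq_len(ncol(X)), function(j)
        discreteMI(equalFreqBin(X[, j], nBins), lab), numeric(1))
    ord <- utils::head(order(mi, decreasing = TRUE), k)
    selectorOutput("mim", colnames(X)[ord], mi[ord], dataset = dataset)
}

#' @rdname baseSelectors
#' @export
mrmrSelect <- function(dataset, k = 25, nBins = 5,
                       labelMode = c("time-status", "status")) {
    if (nBins < 2L) stop("nBins must be >= 2")
    if (nSamples(dataset) < nBins)
        stop("need at least nBins samples for equal-frequency binning")
    X <- exprMatrix(dataset)
    lab <- survivalLabel(dataset, match.arg(labelMode))
    G <- ncol(X)
    binned <- vapply(seq_len(G), function(j) equalFreqBin(X[, j], nBins),
                     integer(nrow(X)))
    rel <- vapply(seq_len(G), function(j) discreteMI(binned[, j], lab),
                  numeric(1))
    k <- min(k, G)
    sel <- integer(0)
    score <- numeric(0)
    redund <- numeric(G)                # running sum of MI to selected set
    candidates <- seq_len(G)
    for (step in seq_len(k)) {
        crit <- if (length(sel) == 0L) rel[candidates] else
            rel[candidates] - redund[candidates] / length(sel)
        pick <- candidates[which.max(crit)]
        sel <- c(sel, pick)
        score <- c(score, max(crit))
        candidates <- setdiff(candidates, pick)
        if (length(candidates))
            redund[candidates] <- redund[candidates] +
                vapply(candidates, function(j)
                    discreteMI(binned[, j], binned[, pick]), numeric(1))
    }
    selectorOutput("mrmr", colnames(X)[sel], score, dataset = dataset)
}

#' Adapter for externally computed selector rankings
#'
#' Wraps a ranking produced outside the package (e.g. random-forest minimal
#' depth / variable importance / variable hunting) into a validated
#' [SelectorOutput-class] usable in any ensemble recipe. Accepts a
#' two-column TSV (feature, score; header optional) in rank order, a
#' character vector, or a data.frame.
#'
#' @param ranking file path, character vector of feature names (best
#'   first), or data.frame with columns feature and score.
#' @param dataset the [SurvivalDataset-class] whose feature universe the
#'   ranking must reference; unknown names are an error.
#' @param selectorName identifier recorded in the output.
#' @return a [SelectorOutput-class].
#' @export
externalSelectorAdapter <- function(ranking, dataset,
                                    selectorName = "external") {
    if (is.character(ranking) && length(ranking) == 1L &&
        file.exists(ranking)) {
        if (file.size(ranking) == 0L)
            return(selectorOutput(selectorName, character(),
                                  dataset = dataset))
        df <- utils::read.delim(ranking, header = FALSE,
                                stringsAsFactors = FALSE)
        if (identical(tolower(df[1L, 1L]), "feature"))
            df <- df[-1L, , drop = FALSE]
        feats <- as.character(df[[1L]])
        scores <- if (ncol(df) >= 2L)
            suppressWarnings(as.numeric(df[[2L]])) else
            rev(seq_along(feats))
        scores[is.na(scores)] <- 0
    } else if (is.data.frame(ranking)) {
        feats <- as.character(ranking[[1L]])
        scores <- if (ncol(ranking) >= 2L) as.numeric(ranking[[2L]]) else
            rev(seq_along(feats))
    } else {
        feats <- as.character(ranking)
        scores <- rev(seq_along(feats))
    }
    selectorOutput(selectorName, feats, scores, dataset = dataset)
}
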