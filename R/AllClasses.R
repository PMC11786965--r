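#' @import methods
NULL

#' SurvivalDataset: expression matrix paired with right-censored outcomes
#'
#' The central container consumed by every stage: a samples x features
#' numeric matrix together with a follow-up time and an event indicator per
#' sample. Times must be strictly positive, status is coded 1 = event
#' observed, 0 = censored, and no missing values are allowed anywhere.
#'
#' @slot X numeric matrix, samples in rows, features in columns; dimnames
#'   carry sample and feature identifiers.
#' @slot time numeric vector of positive follow-up times, one per sample.
#' @slot status integer vector in \{0, 1\}, one per sample.
#'
#' @seealso [survivalDataset()] for the validated constructor,
#'   [assembleDataset()] to build one from expression + clinical tables.
#' @exportClass SurvivalDataset
setClass("SurvivalDataset",
    representation(X = "matrix", time = "numeric", status = "integer"))

setValidity("SurvivalDataset", function(object) {
    msg <- character()
    n <- nrow(object@X)
    if (n < 2L) msg <- c(msg, "need at least 2 samples")
    if (is.null(rownames(object@X)) || is.null(colnames(object@X)))
        msg <- c(msg, "X must carry sample (row) and feature (column) names")
    if (anyDuplicated(colnames(object@X)))
        msg <- c(msg, sprintf("duplicate feature names: %s",
            paste(unique(colnames(object@X)[duplicated(colnames(object@X))]),
                  collapse = ", ")))
    if (anyDuplicated(rownames(object@X)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(object@time) != n || length(object@status) != n)
        msg <- c(msg, "time/status length must match nrow(X)")
    if (anyNA(object@X) || anyNA(object@time) || anyNA(object@status))
        msg <- c(msg, "missing values are not allowed")
    else {
        if (any(object@time <= 0)) msg <- c(msg, "all times must be > 0")
        if (!all(object@status %in% c(0L, 1L)))
            msg <- c(msg, "status must be coded 0 (censored) / 1 (event)")
    }
    if (length(msg)) msg else TRUE
})

#' SelectorOutput: the ranked output of one base feature selector
#'
#' @slot selectorName single string identifying the selector.
#' @slot features character vector of selected features, best first.
#' @slot scores numeric vector aligned to `features`, in the selector's
#'   native scale (p-value, |coefficient|, mutual information, ...).
#' @exportClass SelectorOutput
setClass("SelectorOutput",
    representation(selectorName = "character", features = "character",
                   scores = "numeric"))

setValidity("SelectorOutput", function(object) {
    msg <- character()
    if (length(object@selectorName) != 1L)
        msg <- c(msg, "selectorName must be a single string")
    if (anyDuplicated(object@features))
        msg <- c(msg, "duplicate features in selector output")
    if (length(object@scores) != length(object@features))
        msg <- c(msg, "scores must align with features")
    if (length(msg)) msg else TRUE
})

#' AggregatedRanking: union of selector outputs with a final rank
#'
#' Holds the union feature set of an ensemble, the per-selector imputed
#' ranks and the final aggregated rank (1 = best; a permutation of
#' 1..length(features) after tie-breaking).
#'
#' @slot features character vector, ordered by final rank.
#' @slot finalRank integer vector aligned to `features`.
#' @slot perSelectorRank integer matrix, features x selectors, the imputed
#'   ranks each selector assigns to every union feature.
#' @exportClass AggregatedRanking
setClass("AggregatedRanking",
    representation(features = "character", finalRank = "integer",
                   perSelectorRank = "matrix"))

setValidity("AggregatedRanking", function(object) {
    msg <- character()
    m <- length(object@features)
    if (length(object@finalRank) != m)
        msg <- c(msg, "finalRank must align with features")
    if (m && !identical(sort(object@finalRank), seq_len(m)))
        msg <- c(msg, "finalRank must be a permutation of 1..m")
    if (nrow(object@perSelectorRank) != m)
        msg <- c(msg, "perSelectorRank rows must align with features")
    if (length(msg)) msg else TRUE
})

#' BlockPartition: disjoint correlation blocks with penalty weights
#'
#' Features are grouped so that within each block all pairwise absolute
#' correlations exceed the threshold `rhoT`; each block b of size L_b whose
#' best member has aggregated rank r_b carries the group-lasso penalty
#' weight s_b = r_b * L_b (small penalty on top-ranked blocks).
#'
#' @slot blocks list of character vectors (disjoint, union = feature set).
#' @slot sizes integer vector of block sizes L_b.
#' @slot rhoT the correlation threshold used.
#' @slot weights numeric vector of penalty rescaling factors s_b.
#' @exportClass BlockPartition
setClass("BlockPartition",
    representation(blocks = "list", sizes = "integer", rhoT = "numeric",
                   weights = "numeric"))

setValidity("BlockPartition", function(object) {
    msg <- character()
    B <- length(object@blocks)
    members <- unlist(object@blocks, use.names = FALSE)
    if (anyDuplicated(members)) msg <- c(msg, "blocks must be disjoint")
    if (length(object@sizes) != B || length(object@weights) != B)
        msg <- c(msg, "sizes/weights must align with blocks")
    if (B && !identical(object@sizes, lengths(object@blocks)))
        msg <- c(msg, "sizes must equal lengths(blocks)")
    if (B && any(object@weights <= 0))
        msg <- c(msg, "penalty weights must be strictly positive")
    if (length(object@rhoT) != 1L || object@rhoT <= 0 || object@rhoT >= 1)
        msg <- c(msg, "rhoT must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' CoxGroupProblem: a standardized Cox group-lasso design
#'
#' Internal-facing container pairing a column-standardized design matrix with
#' the survival outcome and a [BlockPartition-class] that defines the
#' coefficient groups and their penalty weights. Built by [coxGroupProblem()].
#'
#' @slot X standardized numeric matrix (mean 0, sd 1 columns).
#' @slot time,status outcome as in [SurvivalDataset-class].
#' @slot partition the [BlockPartition-class] defining groups b = 1..B.
#' @slot groups list of integer column-index vectors, one per block.
#' @exportClass CoxGroupProblem
setClass("CoxGroupProblem",
    representation(X = "matrix", time = "numeric", status = "integer",
                   partition = "BlockPartition", groups = "list"))

setValidity("CoxGroupProblem", function(object) {
    msg <- character()
    if (ncol(object@X) != sum(object@partition@sizes))
        msg <- c(msg, "ncol(X) must equal sum of block sizes")
    if (length(object@time) != nrow(object@X))
        msg <- c(msg, "time length must match nrow(X)")
    if (length(msg)) msg else TRUE
})

#' GroupLassoPath: a fitted regularization path
#'
#' @slot lambda strictly decreasing positive grid.
#' @slot coef matrix [length(lambda) x p] of standardized coefficients.
#' @slot active logical matrix [length(lambda) x B]; TRUE where the block's
#'   coefficient norm is nonzero.
#' @slot converged logical per grid point.
#' @slot iterations integer per grid point.
#' @slot kkt numeric per grid point: the maximum KKT residual at the solution.
#' @exportClass GroupLassoPath
setClass("GroupLassoPath",
    representation(lambda = "numeric", coef = "matrix", active = "matrix",
                   converged = "logical", iterations = "integer",
                   kkt = "numeric"))

setValidity("GroupLassoPath", function(object) {
    msg <- character()
    L <- length(object@lambda)
    if (L > 1 && any(diff(object@lambda) >= 0))
        msg <- c(msg, "lambda grid must be strictly decreasing")
    if (any(object@lambda < 0)) msg <- c(msg, "lambda must be >= 0")
    if (nrow(object@coef) != L || nrow(object@active) != L)
        msg <- c(msg, "coef/active rows must align with lambda")
    if (length(msg)) msg else TRUE
})

#' SelectionResult: the final pseudo-variable-tuned selection
#'
#' @slot selectedBlocks integer indices of selected blocks (into the
#'   partition used at fit time).
#' @slot selectedFeatures character union of selected block members.
#' @slot counts integer per-block selection counts over the K permutations.
#' @slot K number of permutations run.
#' @slot tau selection-fraction threshold; a block is selected iff
#'   counts/K > tau (strict).
#' @slot seed master seed used.
#' @slot partition the [BlockPartition-class] the counts refer to.
#' @slot permutationLog list of per-permutation records (selected block
#'   indices and the V_b importance values of original and pseudo groups).
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(selectedBlocks = "integer", selectedFeatures = "character",
                   counts = "integer", K = "integer", tau = "numeric",
                   seed = "integer", partition = "BlockPartition",
                   permutationLog = "list"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (object@tau < 0 || object@tau > 1) msg <- c(msg, "tau must be in [0,1]")
    if (length(object@counts) &&
        (any(object@counts < 0L) || any(object@counts > object@K)))
        msg <- c(msg, "counts must lie in [0, K]")
    if (length(msg)) msg else TRUE
})

#' SimScenario: a simulation study condition
#'
#' Describes one condition of the correlated-block survival simulator: the
#' sample size, total feature count, Cox log-hazard coefficients of the three
#' latent causal variables, and the target event rate the censoring bound is
#' calibrated to.
#'
#' @slot label scenario label, e.g. "n100_G600_er0.5".
#' @slot n sample count.
#' @slot G total feature count (>= 60 for the uniform-latent design).
#' @slot betas numeric length-3 log-hazard coefficients (beta1..beta3).
#' @slot targetEventRate eta in (0, 1).
#' @slot noiseSd standard deviation of the within-group perturbation noise.
#' @exportClass SimScenario
setClass("SimScenario",
    representation(label = "character", n = "integer", G = "integer",
                   betas = "numeric", targetEventRate = "numeric",
                   noiseSd = "numeric"))

setValidity("SimScenario", function(object) {
    msg <- character()
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (length(object@betas) != 3L) msg <- c(msg, "betas must have length 3")
    if (object@targetEventRate <= 0 || object@targetEventRate >= 1)
        msg <- c(msg, "targetEventRate must be in (0, 1)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' SimTruth: the ground truth behind a simulated dataset
#'
#' @slot causalFeatures names of the observed causal features.
#' @slot latentZ matrix of the latent base variables (never emitted to
#'   selectors; kept for survival generation and diagnostics).
#' @slot achievedEventRate realized event fraction of the draw.
#' @slot censorBound upper bound of the uniform censoring distribution.
#' @exportClass SimTruth
setClass("SimTruth",
    representation(causalFeatures = "character", latentZ = "matrix",
                   achievedEventRate = "numeric", censorBound = "numeric"))

#' RunConfig: parameters steering a full selection run
#'
#' @slot selectors character vector of selector names composing the ensemble.
#' @slot k top-k count for the top-k selectors.
#' @slot alpha p-value threshold for the univariate Cox selector.
#' @slot nBins discretization bins for mutual-information selectors.
#' @slot rhoT correlation-block threshold.
#' @slot K number of pseudo-variable permutations.
#' @slot tau selection-fraction threshold.
#' @slot nLambda,lambdaMinRatio regularization-path grid controls.
#' @slot seed master seed recorded in all outputs.
#' @exportClass RunConfig
setClass("RunConfig",
    representation(selectors = "character", k = "integer", alpha = "numeric",
                   nBins = "integer", rhoT = "numeric", K = "integer",
                   tau = "numeric", nLambda = "integer",
                   lambdaMinRatio = "numeric", seed = "integer"))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (object@rhoT <= 0 || object@rhoT >= 1) msg <- c(msg, "rhoT in (0,1)")
    if (object@K < 1L) msg <- c(msg, "K >= 1")
    if (object@tau < 0 || object@tau > 1) msg <- c(msg, "tau in [0,1]")
    if (object@k < 1L) msg <- c(msg, "k >= 1")
    if (length(msg)) msg else TRUE
})
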