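#' Augment a Cox group-lasso problem with pseudo-variables
#'
#' Pseudo-variables are row-permuted copies of the original features: a
#' single random permutation of sample indices is applied jointly to all
#' columns, so the pseudo copies keep the original correlation structure
#' (their within-block correlation matrix is identical) but are, by
#' construction, unassociated with the outcome. The augmented problem has
#' 2B groups: b = 1..B original, b = B+1..2B their pseudo copies, each
#' pseudo group inheriting its source group's penalty weight s_b.
#'
#' @param problem a [CoxGroupProblem-class] (>= 3 samples).
#' @param seed integer seed for the permutation; `permute = "identity"`
#'   forces the identity permutation (degenerate control: nothing can beat
#'   its own copy).
#' @param permute "joint" (default, one shared row permutation) or
#'   "per-column" (independent permutation per column) or "identity".
#' @return a [CoxGroupProblem-class] with 2B groups.
#' @export
makePseudo <- function(problem, seed, permute = c("joint", "per-column",
                                                  "identity")) {
    permute <- match.arg(permute)
    n <- nrow(problem@X)
    if (n < 3L) stop("need at least 3 samples to permute")
    Xp <- withSeed(seed, switch(permute,
        joint = problem@X[sample.int(n), , drop = FALSE],
        "per-column" = apply(problem@X, 2L, sample),
        identity = problem@X))
    colnames(Xp) <- paste0(colnames(problem@X), ".pseudo")
    part <- problem@partition
    pseudoBlocks <- lapply(part@blocks, function(b) paste0(b, ".pseudo"))
    part2 <- new("BlockPartition",
        blocks = c(part@blocks, pseudoBlocks),
        sizes = c(part@sizes, part@sizes),
        rhoT = part@rhoT,
        weights = c(part@weights, part@weights))
    p <- ncol(problem@X)
    groups2 <- c(problem@groups, lapply(problem@groups, function(g) g + p))
    newCoxGroupProblem(cbind(problem@X, Xp), problem@time, problem@status,
                       part2, groups2)
}

#' Selection under a single pseudo-variable permutation
#'
#' Fits the group-lasso path on the pseudo-augmented problem and selects
#' every original group whose importance V_b (entry penalty level) is
#' strictly larger than the strongest pseudo signal
#' max_\{B+1 <= b <= 2B\} V_b.
#'
#' @param problem a [CoxGroupProblem-class] (original, B groups).
#' @param seed integer seed for this permutation.
#' @param nLambda,lambdaMinRatio,tol,maxIter path controls, see
#'   [fitGroupLassoPath()].
#' @param permute permutation mode, see [makePseudo()].
#' @return list with `selected` (integer block indices), `Vb` (length B),
#'   `VbPseudo` (length B), `pseudoMax`.
#' @export
onePermutationSelect <- function(problem, seed, nLambda = 100,
                                 lambdaMinRatio = 0.001, tol = 1e-7,
                                 maxIter = 5000, permute = "joint") {
    aug <- makePseudo(problem, seed, permute = permute)
    path <- withCallingHandlers(
        fitGroupLassoPath(aug, nLambda = nLambda,
                          lambdaMinRatio = lambdaMinRatio, tol = tol,
                          maxIter = maxIter),
        warning = function(w) {
            ## non-convergence at some grid points: proceed with the
            ## converged points, but keep the caller informed once
            if (grepl("stationarity tolerance", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    B <- length(problem@groups)
    Vb <- vapply(seq_len(B), function(b) entryLambda(path, b), numeric(1))
    VbPseudo <- vapply(seq_len(B), function(b) entryLambda(path, B + b),
                       numeric(1))
    pseudoMax <- max(VbPseudo)
    list(selected = which(Vb > pseudoMax), Vb = Vb, VbPseudo = VbPseudo,
         pseudoMax = pseudoMax)
}

#' Final thresholding of per-block selection counts
#'
#' A block is selected iff it beat the strongest pseudo signal in strictly
#' more than tau * K of the K permutations (count / K > tau; a count of
#' exactly tau * K does not select).
#'
#' @param counts integer per-block counts in [0, K].
#' @param K number of permutations.
#' @param tau threshold in [0, 1].
#' @return integer indices of selected blocks.
#' @export
selectByCounts <- function(counts, K, tau) {
    stopifnot(all(counts >= 0), all(counts <= K))
    which(counts / K > tau)
}

#' Pseudo-variable-assisted group selection over K permutations
#'
#' Runs [onePermutationSelect()] for K independent permutations (with
#' per-iteration seeds derived from the master seed, so results do not
#' depend on execution order), counts how often each original block beats
#' the strongest pseudo signal, and finally selects the blocks whose
#' selection fraction strictly exceeds tau.
#'
#' @param problem a [CoxGroupProblem-class].
#' @param K number of permutations (reference setting 50).
#' @param tau selection-fraction threshold in [0, 1] (reference 0.5);
#'   strict: count/K must exceed tau.
#' @param seed master integer seed.
#' @param nLambda,lambdaMinRatio,tol,maxIter path controls.
#' @param permute permutation mode, see [makePseudo()].
#' @return a [SelectionResult-class].
#' @export
pseudoTunedSelect <- function(problem, K = 50, tau = 0.5, seed = 1,
                              nLambda = 100, lambdaMinRatio = 0.001,
                              tol = 1e-7, maxIter = 5000,
                              permute = "joint") {
    K <- as.integer(K)
    if (K < 1L) stop("K must be >= 1")
    if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
    B <- length(problem@groups)
    counts <- integer(B)
    logs <- vector("list", K)
    for (k in seq_len(K)) {
        res <- onePermutationSelect(problem, seed = deriveSeed(seed, k),
                                    nLambda = nLambda,
                                    lambdaMinRatio = lambdaMinRatio,
                                    tol = tol, maxIter = maxIter,
                                    permute = permute)
        counts[res$selected] <- counts[res$selected] + 1L
        logs[[k]] <- res
    }
    sel <- selectByCounts(counts, K, tau)
    new("SelectionResult",
        selectedBlocks = as.integer(sel),
        selectedFeatures = as.character(
            unlist(problem@partition@blocks[sel], use.names = FALSE)),
        counts = counts, K = K, tau = tau, seed = as.integer(seed),
        partition = problem@partition, permutationLog = logs)
}
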