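#' Build a standardized Cox group-lasso problem
#'
#' Assembles the design for the grouped Cox fit: columns are restricted to
#' the partition's features (in block order), centered and scaled to unit
#' standard deviation, and the partition's penalty weights s_b define the
#' group penalty lambda * sum_b s_b * ||beta_b||_2. The intercept is not
#' identifiable under the partial likelihood and is excluded.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param partition a [BlockPartition-class] over (a subset of) the
#'   dataset's features.
#' @param standardize center/scale columns (default TRUE; constant columns
#'   get scale 1).
#' @return a [CoxGroupProblem-class].
#' @export
coxGroupProblem <- function(dataset, partition, standardize = TRUE) {
    feats <- unlist(partition@blocks, use.names = FALSE)
    miss <- setdiff(feats, featureNames(dataset))
    if (length(miss))
        stop("partition features absent from dataset: ",
             paste(miss, collapse = ", "))
    X <- exprMatrix(dataset)[, feats, drop = FALSE]
    if (standardize) {
        ctr <- colMeans(X)
        scl <- apply(X, 2L, stats::sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
    }
    ends <- cumsum(partition@sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    groups <- lapply(seq_along(ends), function(b) starts[b]:ends[b])
    new("CoxGroupProblem", X = X, time = survTime(dataset),
        status = survStatus(dataset), partition = partition,
        groups = groups)
}

## Internal constructor from raw pieces (already standardized or not);
## used by the pseudo-variable augmentation.
newCoxGroupProblem <- function(X, time, status, partition, groups) {
    new("CoxGroupProblem", X = X, time = as.numeric(time),
        status = as.integer(status), partition = partition, groups = groups)
}

## ---- partial likelihood (Breslow ties) ----------------------------------

## Precompute the sorted structure used by the likelihood and gradient:
## samples ordered by decreasing follow-up time; tieLast[q] is the largest
## sorted position sharing position q's time, so the risk set of an event
## at position q is sorted positions 1..tieLast[q].
plStruct <- function(X, time, status) {
    ord <- order(time, decreasing = TRUE)
    ts <- time[ord]
    r <- rle(ts)
    tieLast <- rep.int(cumsum(r$lengths), r$lengths)
    list(X = X[ord, , drop = FALSE], status = status[ord],
         tieLast = tieLast, n = length(time))
}

plNLL <- function(beta, s) {
    eta <- drop(s$X %*% beta)
    m <- max(eta)
    S <- cumsum(exp(eta - m))[s$tieLast]
    ev <- s$status == 1L
    if (!any(ev)) return(0)
    -(sum(eta[ev] - (log(S[ev]) + m))) / s$n
}

plGrad <- function(beta, s) {
    eta <- drop(s$X %*% beta)
    m <- max(eta)
    w <- exp(eta - m)
    S <- cumsum(w)[s$tieLast]
    contrib <- numeric(s$n)
    ev <- which(s$status == 1L)
    if (length(ev)) {
        add <- rowsum(1 / S[ev], s$tieLast[ev])
        contrib[as.integer(rownames(add))] <- add
    }
    r <- rev(cumsum(rev(contrib)))
    a <- s$status - w * r
    -drop(crossprod(s$X, a)) / s$n
}

#' Negative log partial likelihood and its gradient
#'
#' Breslow handling of tied event times, normalized by the sample count so
#' penalty grids are comparable across n:
#' \deqn{-\frac{1}{n}\sum_{i:\Delta_i=1}\Big[\eta_i -
#'   \log\sum_{k: T_k \ge T_i} e^{\eta_k}\Big]}
#' with \eqn{\eta = X\beta}. The log-sum-exp is max-shifted to avoid
#' overflow; an all-censored outcome gives 0 (empty sum).
#'
#' @param beta coefficient vector of length ncol(X).
#' @param problem a [CoxGroupProblem-class].
#' @return `coxNLL`: a scalar; `coxNLLGradient`: a numeric vector.
#' @export
coxNLL <- function(beta, problem) {
    stopifnot(all(is.finite(beta)))
    plNLL(beta, plStruct(problem@X, problem@time, problem@status))
}

#' @rdname coxNLL
#' @export
coxNLLGradient <- function(beta, problem) {
    plGrad(beta, plStruct(problem@X, problem@time, problem@status))
}

#' Group soft-thresholding operator
#'
#' Proximal operator of t * ||v||_2: returns 0 when ||v||_2 <= t, otherwise
#' shrinks v radially by t.
#'
#' @param v numeric vector.
#' @param t nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
groupSoftThreshold <- function(v, t) {
    stopifnot(t >= 0)
    nv <- sqrt(sum(v^2))
    if (nv <= t) numeric(length(v)) else (1 - t / nv) * v
}

#' Smallest penalty level at which no group enters
#'
#' lambda_max = max_b ||grad_b(-l)(0)||_2 / s_b; at any lambda at or above
#' this value the all-zero coefficient vector satisfies the optimality
#' conditions of the group-lasso objective.
#'
#' @param problem a [CoxGroupProblem-class].
#' @return a positive scalar.
#' @export
lambdaMax <- function(problem) {
    g0 <- coxNLLGradient(numeric(ncol(problem@X)), problem)
    w <- problem@partition@weights
    max(vapply(seq_along(problem@groups), function(b)
        sqrt(sum(g0[problem@groups[[b]]]^2)) / w[b], numeric(1)))
}

## Penalty term sum_b s_b ||beta_b|| for a coefficient vector.
groupPenalty <- function(beta, groups, w) {
    sum(vapply(seq_along(groups), function(b)
        w[b] * sqrt(sum(beta[groups[[b]]]^2)), numeric(1)))
}

## Proximal step: group soft-threshold per block with thresholds
## lambda * s_b * stepsize.
groupProx <- function(v, groups, thr) {
    for (b in seq_along(groups)) {
        idx <- groups[[b]]
        v[idx] <- groupSoftThreshold(v[idx], thr[b])
    }
    v
}

#' Karush-Kuhn-Tucker residual of a group-lasso solution
#'
#' For active groups the stationarity residual
#' ||grad_b + lambda s_b beta_b / ||beta_b|| ||_2, for inactive groups the
#' subgradient violation max(0, ||grad_b||_2 - lambda s_b); returns the
#' maximum over groups.
#'
#' @param beta coefficient vector.
#' @param problem a [CoxGroupProblem-class].
#' @param lambda penalty level.
#' @return a nonnegative scalar.
#' @export
kktResidual <- function(beta, problem, lambda) {
    g <- coxNLLGradient(beta, problem)
    w <- problem@partition@weights
    res <- vapply(seq_along(problem@groups), function(b) {
        idx <- problem@groups[[b]]
        nb <- sqrt(sum(beta[idx]^2))
        if (nb > 0)
            sqrt(sum((g[idx] + lambda * w[b] * beta[idx] / nb)^2))
        else max(0, sqrt(sum(g[idx]^2)) - lambda * w[b])
    }, numeric(1))
    max(res)
}

## Accelerated proximal gradient (FISTA with backtracking) for one lambda.
## Monotone variant: if the accelerated candidate raises the objective the
## momentum is reset and a plain descent step from the incumbent is taken,
## so recorded objectives are non-increasing.
solveOneLambda <- function(s, groups, w, lambda, beta0, L0 = 1,
                           tol = 1e-7, maxIter = 5000, kktTol = 1e-5) {
    pen <- function(b) groupPenalty(b, groups, w)
    beta <- beta0
    v <- beta
    tk <- 1
    L <- L0
    Q <- plNLL(beta, s) + lambda * pen(beta)
    converged <- FALSE
    it <- 0L
    kkt <- function(b) {
        g <- plGrad(b, s)
        max(vapply(seq_along(groups), function(k) {
            idx <- groups[[k]]
            nb <- sqrt(sum(b[idx]^2))
            if (nb > 0)
                sqrt(sum((g[idx] + lambda * w[k] * b[idx] / nb)^2))
            else max(0, sqrt(sum(g[idx]^2)) - lambda * w[k])
        }, numeric(1)))
    }
    descentStep <- function(x, fx, gx) {
        repeat {
            cand <- groupProx(x - gx / L, groups, lambda * w / L)
            d <- cand - x
            fc <- plNLL(cand, s)
            if (fc <= fx + sum(gx * d) + L / 2 * sum(d^2) + 1e-12)
                return(list(beta = cand, f = fc))
            L <<- L * 2
        }
    }
    while (it < maxIter) {
        it <- it + 1L
        st <- descentStep(v, plNLL(v, s), plGrad(v, s))
        Qc <- st$f + lambda * pen(st$beta)
        if (Qc > Q + 1e-15) {      # monotone fallback from the incumbent
            st <- descentStep(beta, plNLL(beta, s), plGrad(beta, s))
            Qc <- st$f + lambda * pen(st$beta)
            v <- st$beta
            tk <- 1
        } else {
            tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
            v <- st$beta + ((tk - 1) / tk1) * (st$beta - beta)
            tk <- tk1
        }
        relChange <- abs(Q - Qc) / max(1, abs(Q))
        beta <- st$beta
        Q <- Qc
        if (relChange < tol) {
            if (kkt(beta) < kktTol) { converged <- TRUE; break }
            ## objective has stalled but stationarity not yet reached:
            ## reset momentum and keep iterating
            v <- beta
            tk <- 1
        }
        L <- max(L / 1.5, 1e-8)
    }
    list(beta = beta, objective = Q, iterations = it,
         converged = converged || kkt(beta) < kktTol, L = L,
         kkt = kkt(beta))
}

#' Fit the Cox group-lasso regularization path
#'
#' Minimizes Q_lambda(beta) = -(1/n) log partial likelihood +
#' lambda * sum_b s_b ||beta_b||_2 over a decreasing lambda grid with warm
#' starts, by accelerated proximal gradient with backtracking line search.
#' The default grid is `nLambda` log-spaced points from the data's
#' [lambdaMax()] down to `lambdaMinRatio` times it, so the first point has
#' the all-zero solution.
#'
#' @param problem a [CoxGroupProblem-class].
#' @param lambda optional explicit decreasing grid.
#' @param nLambda,lambdaMinRatio grid controls when `lambda` is NULL.
#' @param tol relative objective-change tolerance (default 1e-7).
#' @param maxIter iteration cap per grid point (default 5000);
#'   non-convergence is flagged in the path, not fatal.
#' @param kktTol stationarity tolerance required at convergence.
#' @return a [GroupLassoPath-class].
#' @export
fitGroupLassoPath <- function(problem, lambda = NULL, nLambda = 100,
                              lambdaMinRatio = 0.001, tol = 1e-7,
                              maxIter = 5000, kktTol = 1e-5) {
    s <- plStruct(problem@X, problem@time, problem@status)
    if (is.null(lambda)) {
        lmax <- lambdaMax(problem)
        lambda <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                          length.out = nLambda))
    } else {
        lambda <- as.numeric(lambda)
        if (length(lambda) > 1 && any(diff(lambda) >= 0))
            stop("lambda grid must be strictly decreasing")
    }
    gidx <- vapply(problem@groups, range, integer(2))
    if (!all(vapply(problem@groups, function(g)
            identical(as.integer(g), seq.int(min(g), max(g))), logical(1))))
        stop("groups must be contiguous column ranges")
    fit <- .cppFitPath(s$X, as.integer(s$status), as.integer(s$tieLast),
                       t(gidx), problem@partition@weights, lambda,
                       tol, as.integer(maxIter), kktTol)
    coef <- fit$coef
    dimnames(coef) <- list(NULL, colnames(problem@X))
    converged <- as.logical(fit$converged)
    if (!all(converged))
        warning(sum(!converged), " of ", length(lambda),
                " path points did not reach the stationarity tolerance")
    new("GroupLassoPath", lambda = lambda, coef = coef,
        active = matrix(as.logical(fit$active), nrow = length(lambda)),
        converged = converged, iterations = as.integer(fit$iterations),
        kkt = as.numeric(fit$kkt))
}

#' Solve the group lasso at a single penalty level
#'
#' Convenience wrapper used for unpenalized fits (lambda = 0) and oracle
#' comparisons.
#'
#' @inheritParams fitGroupLassoPath
#' @param lambda a single penalty level (>= 0).
#' @return list with `beta`, `objective`, `converged`, `iterations`, `kkt`.
#' @export
solveCoxGroupLasso <- function(problem, lambda, tol = 1e-9,
                               maxIter = 20000, kktTol = 1e-7) {
    s <- plStruct(problem@X, problem@time, problem@status)
    gidx <- vapply(problem@groups, range, integer(2))
    fit <- .cppFitPath(s$X, as.integer(s$status), as.integer(s$tieLast),
                       t(gidx), problem@partition@weights,
                       as.numeric(lambda), tol, as.integer(maxIter), kktTol)
    list(beta = stats::setNames(drop(fit$coef), colnames(problem@X)),
         objective = fit$objective[1L],
         iterations = as.integer(fit$iterations)[1L],
         converged = as.logical(fit$converged)[1L],
         kkt = as.numeric(fit$kkt)[1L])
}

#' Group importance: the entry penalty level V_b
#'
#' V_b = sup\{lambda : block b has a nonzero coefficient\}, read off the
#' fitted grid with no monotone-activity assumption (the supremum over grid
#' points is taken); 0 when the block is never active.
#'
#' @param path a [GroupLassoPath-class].
#' @param b block index (1..B).
#' @return a nonnegative scalar.
#' @name entryLambda
#' @export
setMethod("entryLambda", "GroupLassoPath", function(path, b) {
    if (b < 1L || b > ncol(path@active)) stop("block index out of range: ", b)
    on <- path@active[, b]
    if (!any(on)) 0 else max(path@lambda[on])
})
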