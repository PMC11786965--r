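# Fixtures are generated in code; nothing is stored on disk.

# Small dataset with a genuine signal: hazard increases with the first
# `nCausal` features, the rest are noise.
makeToyDataset <- function(n = 60, p = 10, nCausal = 2, beta = 1.5,
                           censorBound = 3, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("g", seq_len(p))))
    lp <- drop(X[, seq_len(nCausal), drop = FALSE] %*%
                   rep(beta, nCausal))
    U <- rexp(n, rate = exp(lp))
    V <- runif(n, 0, censorBound)
    survivalDataset(X, pmax(pmin(U, V), 1e-12), as.integer(U <= V))
}

# A Cox group-lasso problem over random contiguous groups.
makeToyProblem <- function(n = 40, sizes = c(3, 4, 5), beta0 = NULL,
                           weights = NULL, seed = 1, eventP = 0.7) {
    set.seed(seed)
    p <- sum(sizes)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("g", seq_len(p))))
    lp <- if (is.null(beta0)) rep(0, n) else drop(X %*% beta0)
    U <- rexp(n, rate = exp(lp))
    V <- stats::quantile(U, eventP)
    time <- pmin(U, V)
    status <- as.integer(U <= V)
    status[1] <- 1L   # guarantee at least one event
    blocks <- split(colnames(X), rep(seq_along(sizes), sizes))
    part <- new("BlockPartition", blocks = unname(blocks),
                sizes = as.integer(sizes), rhoT = 0.75,
                weights = if (is.null(weights))
                    as.numeric(seq_along(sizes)) else as.numeric(weights))
    ds <- survivalDataset(X, time, status)
    coxGroupProblem(ds, part)
}

# Objective of the group-lasso problem, for oracle comparisons.
toyObjective <- function(beta, problem, lambda) {
    pen <- sum(vapply(seq_along(problem@groups), function(b)
        problem@partition@weights[b] *
            sqrt(sum(beta[problem@groups[[b]]]^2)), numeric(1)))
    coxNLL(beta, problem) + lambda * pen
}
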