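test_that("partial likelihood matches the closed form and edge cases", {
    X <- matrix(0, 3, 1, dimnames = list(paste0("s", 1:3), "g1"))
    part <- new("BlockPartition", blocks = list("g1"), sizes = 1L,
                rhoT = 0.75, weights = 1)
    ds <- survivalDataset(X, time = c(1, 2, 3), status = c(1, 1, 1))
    prob <- coxGroupProblem(ds, part, standardize = FALSE)
    # risk sets of sizes 3, 2, 1 at beta = 0: (1/3) log 6
    expect_equal(coxNLL(0, prob), log(6) / 3, tolerance = 1e-12)

    dsC <- survivalDataset(X, time = c(1, 2, 3), status = c(0, 0, 0))
    probC <- coxGroupProblem(dsC, part, standardize = FALSE)
    expect_equal(coxNLL(0, probC), 0)
})

test_that("partial likelihood and gradient match the survival package", {
    prob <- makeToyProblem(n = 40, sizes = c(2, 3), seed = 8,
                           beta0 = c(0.5, -0.3, 0, 0.2, 0))
    set.seed(2)
    beta <- rnorm(5) * 0.4
    n <- nrow(prob@X)
    fit <- survival::coxph(
        survival::Surv(prob@time, prob@status) ~ prob@X,
        init = beta, ties = "breslow",
        control = survival::coxph.control(iter.max = 0))
    expect_equal(coxNLL(beta, prob), -fit$loglik[2] / n, tolerance = 1e-8)

    # gradient against central finite differences
    g <- coxNLLGradient(beta, prob)
    h <- 1e-5
    gFD <- vapply(seq_along(beta), function(j) {
        e <- numeric(length(beta)); e[j] <- h
        (coxNLL(beta + e, prob) - coxNLL(beta - e, prob)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), gFD, tolerance = 1e-5)

    # zero gradient at the unpenalized MLE
    mle <- survival::coxph(
        survival::Surv(prob@time, prob@status) ~ prob@X,
        ties = "breslow")
    expect_lt(sqrt(sum(coxNLLGradient(unname(mle$coefficients),
                                      prob)^2)), 1e-6)

    # permutation invariance in the samples
    perm <- sample(n)
    ds2 <- survivalDataset(prob@X[perm, ], prob@time[perm],
                           prob@status[perm])
    prob2 <- coxGroupProblem(ds2, prob@partition, standardize = FALSE)
    expect_equal(coxNLLGradient(beta, prob2), coxNLLGradient(beta, prob),
                 tolerance = 1e-12)
})

test_that("group soft-thresholding follows its closed form", {
    expect_equal(groupSoftThreshold(c(3, 4), 5), c(0, 0))
    expect_equal(groupSoftThreshold(c(3, 4), 2.5), c(1.5, 2.0))
    v <- c(-1.2, 0.7, 3)
    expect_equal(groupSoftThreshold(v, 0), v)
})

test_that("lambdaMax bounds the active set and scales with weights", {
    prob <- makeToyProblem(n = 50, sizes = c(3, 3, 3), seed = 3,
                           beta0 = c(1, 1, 0, 0, 0, 0, 0, 0, 0))
    lmax <- lambdaMax(prob)
    above <- solveCoxGroupLasso(prob, 1.01 * lmax)
    expect_true(all(above$beta == 0))
    below <- solveCoxGroupLasso(prob, 0.5 * lmax)
    expect_gt(sum(below$beta != 0), 0)

    part2 <- prob@partition
    part2@weights <- 2 * part2@weights
    prob2 <- coxGroupProblem(
        survivalDataset(prob@X, prob@time, prob@status),
        part2, standardize = FALSE)
    expect_equal(lambdaMax(prob2), lmax / 2, tolerance = 1e-12)
})

test_that("unpenalized single-feature fit recovers the Cox MLE", {
    for (seed in c(2, 7, 13)) {
        set.seed(seed)
        n <- 60
        x <- rnorm(n)
        U <- rexp(n, exp(0.8 * x))
        time <- pmin(U, quantile(U, 0.8))
        status <- as.integer(U <= quantile(U, 0.8))
        X <- matrix(x, dimnames = list(paste0("s", 1:n), "g1"))
        part <- new("BlockPartition", blocks = list("g1"), sizes = 1L,
                    rhoT = 0.75, weights = 1)
        prob <- coxGroupProblem(survivalDataset(X, time, status), part,
                                standardize = FALSE)
        fit <- solveCoxGroupLasso(prob, 0)
        mle <- survival::coxph(survival::Surv(time, status) ~ x,
                               ties = "breslow")
        expect_equal(unname(fit$beta), unname(mle$coefficients),
                     tolerance = 1e-4)
    }
})

test_that("path solutions satisfy the KKT conditions and warm-start", {
    prob <- makeToyProblem(n = 50, sizes = c(3, 4, 5), seed = 5,
                           beta0 = c(1, -1, 0.5, rep(0, 9)))
    path <- fitGroupLassoPath(prob, nLambda = 30)
    expect_true(all(path@converged))
    # beta = 0 at the top of the grid (lambda = lambdaMax)
    expect_true(all(path@coef[1, ] == 0))
    # recorded KKT residuals honor the stationarity tolerance
    expect_lt(max(path@kkt), 1e-4)
    # independent KKT check through the R-level residual
    for (g in c(5L, 15L, 25L))
        expect_lt(kktResidual(path@coef[g, ], prob, path@lambda[g]), 1e-4)
    # path continuity under warm starts: no wild jumps
    jumps <- sqrt(rowSums(diff(path@coef)^2))
    expect_lt(max(jumps), 10 * max(abs(path@coef)))
})

test_that("active-group count shrinks as the penalty grows", {
    prob <- makeToyProblem(n = 60, sizes = c(3, 3, 3, 3), seed = 9,
                           beta0 = c(1.2, 0, 0, -0.8, rep(0, 8)))
    path <- fitGroupLassoPath(prob, nLambda = 40)
    nActive <- rowSums(path@active)
    # grid is decreasing, so counts should be (weakly) increasing along it
    ok <- mean(diff(nActive) >= 0)
    expect_gte(ok, 0.95)
})

test_that("compiled solver agrees with the pure-R reference", {
    prob <- makeToyProblem(n = 40, sizes = c(2, 3, 2), seed = 12,
                           beta0 = c(0.9, 0, 0, -0.7, 0, 0, 0))
    lmax <- lambdaMax(prob)
    lam <- 0.3 * lmax
    cppFit <- solveCoxGroupLasso(prob, lam)
    s <- pvglasso:::plStruct(prob@X, prob@time, prob@status)
    rFit <- pvglasso:::solveOneLambda(
        s, prob@groups, prob@partition@weights, lam,
        numeric(ncol(prob@X)), tol = 1e-9, maxIter = 20000, kktTol = 1e-7)
    expect_equal(cppFit$objective, rFit$objective, tolerance = 1e-8)
    expect_equal(unname(cppFit$beta), unname(rFit$beta), tolerance = 1e-4)
})

test_that("solver matches a general-purpose convex optimizer", {
    for (seed in c(1, 4, 6)) {
        prob <- makeToyProblem(n = 40, sizes = c(2, 3, 3), seed = seed,
                               beta0 = c(1, 0, 0, -1, rep(0, 4)))
        lam <- 0.3 * lambdaMax(prob)
        mine <- solveCoxGroupLasso(prob, lam)
        oracle <- optim(rep(0.01, ncol(prob@X)), toyObjective,
                        problem = prob, lambda = lam, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
        expect_lte(mine$objective, oracle$value + 1e-6)
        expect_lt(mine$kkt, 1e-5)
    }
})

test_that("entry lambda reads group importance off the path", {
    prob <- makeToyProblem(n = 60, sizes = c(3, 3), seed = 10,
                           beta0 = c(1.5, 1.2, -1, 0, 0, 0),
                           weights = c(1, 1))
    path <- fitGroupLassoPath(prob, nLambda = 30)
    v1 <- entryLambda(path, 1)
    v2 <- entryLambda(path, 2)
    # the causal group enters before the noise group
    expect_gt(v1, v2)
    expect_error(entryLambda(path, 3), "out of range")

    # a group active at every grid point has V_b = the largest grid value
    actAll <- path@active
    actAll[, 1] <- TRUE
    pathAll <- new("GroupLassoPath", lambda = path@lambda,
                   coef = path@coef, active = actAll,
                   converged = path@converged,
                   iterations = path@iterations, kkt = path@kkt)
    expect_equal(entryLambda(pathAll, 1), max(path@lambda))

    # a group never active has V_b = 0
    act <- path@active
    act[, 2] <- FALSE
    path2 <- new("GroupLassoPath", lambda = path@lambda, coef = path@coef,
                 active = act, converged = path@converged,
                 iterations = path@iterations, kkt = path@kkt)
    expect_identical(entryLambda(path2, 2), 0)
})
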