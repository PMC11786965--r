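#' Define a simulation scenario
#'
#' A scenario fixes the sample size, total feature count G, the log-hazard
#' coefficients of the three latent causal variables, and the event rate the
#' censoring bound is calibrated to. The twelve reference conditions (all
#' combinations of n in \{100, 200\}, G in \{600, 1200\} and event rate in
#' \{0.3, 0.5, 0.7\}) are returned by [referenceScenarios()]; their
#' coefficient triples are (-6, 8, -10) at event rate 0.3, (-2, 3, -4) at
#' 0.5 and (-2, -3, 4) at 0.7. Smaller-effect variants are obtained by
#' passing `betas` directly.
#'
#' @param n sample count.
#' @param G total number of features (>= 60: 30 observed causal, 30
#'   correlated non-causal, G - 60 uniform noise).
#' @param eventRate target event fraction eta in (0, 1).
#' @param betas log-hazard coefficients (beta1, beta2, beta3); defaults to
#'   the reference triple for eta in \{0.3, 0.5, 0.7\}.
#' @param noiseSd standard deviation of the within-group perturbation noise
#'   (default 0.3).
#' @param label scenario label; autogenerated as "n<d>_G<G>_er<eta>".
#' @return a [SimScenario-class].
#' @export
simScenario <- function(n, G, eventRate, betas = NULL, noiseSd = 0.3,
                        label = NULL) {
    if (is.null(betas)) {
        ref <- list("0.3" = c(-6, 8, -10), "0.5" = c(-2, 3, -4),
                    "0.7" = c(-2, -3, 4))
        key <- format(eventRate)
        if (!key %in% names(ref))
            stop("no reference coefficient triple for event rate ",
                 eventRate, "; supply betas explicitly")
        betas <- ref[[key]]
    }
    if (is.null(label))
        label <- sprintf("n%d_G%d_er%s", n, G, format(eventRate))
    new("SimScenario", label = label, n = as.integer(n), G = as.integer(G),
        betas = as.numeric(betas), targetEventRate = eventRate,
        noiseSd = noiseSd)
}

#' @rdname simScenario
#' @return for `referenceScenarios`, a named list of the twelve reference
#'   [SimScenario-class] objects, keyed by label.
#' @export
referenceScenarios <- function() {
    grid <- expand.grid(eta = c(0.3, 0.5, 0.7), G = c(1200L, 600L),
                        n = c(100L, 200L))
    out <- lapply(seq_len(nrow(grid)), function(i)
        simScenario(grid$n[i], grid$G[i], grid$eta[i]))
    names(out) <- vapply(out, function(s) s@label, character(1))
    out
}

#' Simulate the uniform-latent correlated feature design
#'
#' Draws six i.i.d. latent base variables z_i ~ U(0, 1) per sample and, for
#' each, ten observed copies v_ij = z_i + (0.01 + 0.5 (j - 1) / 9) * e_ij
#' with e_ij ~ N(0, noiseSd); the correlation with the latent variable
#' decays as j grows. Features v_1j..v_3j are the 30 observed causal
#' variables (the survival outcome depends on z_1..z_3), v_4j..v_6j are 30
#' correlated non-causal variables, and the remaining G - 60 columns are
#' independent U(0, 1) noise. Column order is shuffled so selectors cannot
#' exploit position; the truth records the causal names and the latent
#' matrix (never emitted).
#'
#' @param scenario a [SimScenario-class] with G >= 60.
#' @param seed integer seed.
#' @return list with elements `X` (n x G matrix, shuffled columns) and
#'   `truth` (a [SimTruth-class]; `achievedEventRate`/`censorBound` are
#'   filled in by [simulateScenario()]).
#' @export
simulateFeaturesUniform <- function(scenario, seed) {
    G <- scenario@G; n <- scenario@n
    if (G < 60L) stop("G must be >= 60 (60 correlated features)")
    withSeed(seed, {
        Z <- matrix(stats::runif(n * 6L), n, 6L,
                    dimnames = list(NULL, paste0("z", 1:6)))
        V <- matrix(0, n, 60L)
        vnames <- character(60L)
        for (i in 1:6) for (j in 1:10) {
            k <- (i - 1L) * 10L + j
            V[, k] <- Z[, i] +
                (0.01 + 0.5 * (j - 1) / 9) *
                    stats::rnorm(n, 0, scenario@noiseSd)
            vnames[k] <- sprintf("v%d_%d", i, j)
        }
        colnames(V) <- vnames
        W <- matrix(stats::runif(n * (G - 60L)), n, G - 60L)
        colnames(W) <- if (G > 60L) paste0("w", seq_len(G - 60L)) else NULL
        X <- cbind(V, W)
        X <- X[, sample.int(G), drop = FALSE]
        rownames(X) <- paste0("s", seq_len(n))
        truth <- new("SimTruth",
            causalFeatures = vnames[1:30],
            latentZ = Z,
            achievedEventRate = NA_real_, censorBound = NA_real_)
        list(X = X, truth = truth)
    })
}

#' Simulate the multivariate-normal block feature design
#'
#' Structural emulation of a real-data-derived design: six correlated
#' feature blocks drawn from zero-mean multivariate normal distributions
#' (default sizes 6, 7, 8, 7, 8, 9). In each of the first three blocks one
#' randomly chosen member is held out as the unobserved causal variable;
#' the remaining members of those blocks are the observed causal features
#' and the last three blocks are observed correlated non-causal features.
#' G minus the observed correlated count (42 at the default sizes) U(0, 1)
#' noise columns are appended, and columns are shuffled.
#'
#' @param n sample count.
#' @param G total emitted feature count.
#' @param blockSizes integer vector of six block sizes.
#' @param blockCorr either a single exchangeable within-block correlation,
#'   or a list of six correlation matrices.
#' @param seed integer seed.
#' @param minOffDiag guard: all specified within-block correlations must
#'   be at least this value (default 0.5); set to 0 to disable.
#' @return list with `X` (n x G), `truth` (a [SimTruth-class]; `latentZ`
#'   holds the three held-out causal columns).
#' @export
simulateFeaturesBlockMVN <- function(n, G, blockSizes = c(6, 7, 8, 7, 8, 9),
                                     blockCorr = 0.6, seed = 1,
                                     minOffDiag = 0.5) {
    blockSizes <- as.integer(blockSizes)
    if (length(blockSizes) != 6L) stop("blockSizes must have length 6")
    mats <- if (is.list(blockCorr)) blockCorr else
        lapply(blockSizes, function(L) {
            M <- matrix(blockCorr, L, L); diag(M) <- 1; M
        })
    for (b in 1:6) {
        M <- mats[[b]]
        if (!isTRUE(all.equal(M, t(M))) ||
            any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
            stop("block ", b, " correlation matrix is not positive definite")
        off <- M[upper.tri(M)]
        if (length(off) && any(off < minOffDiag))
            stop("block ", b, " has within-block correlation below ",
                 minOffDiag)
    }
    nCorr <- sum(blockSizes) - 3L
    if (G < nCorr) stop("G must be >= ", nCorr)
    withSeed(seed, {
        obs <- vector("list", 6L)
        latent <- matrix(0, n, 3L, dimnames = list(NULL, paste0("z", 1:3)))
        causal <- character()
        for (b in 1:6) {
            L <- blockSizes[b]
            Xb <- MASS::mvrnorm(n, mu = rep(0, L), Sigma = mats[[b]])
            colnames(Xb) <- sprintf("b%d_%d", b, seq_len(L))
            if (b <= 3L) {
                hide <- sample.int(L, 1L)
                latent[, b] <- Xb[, hide]
                Xb <- Xb[, -hide, drop = FALSE]
                causal <- c(causal, colnames(Xb))
            }
            obs[[b]] <- Xb
        }
        V <- do.call(cbind, obs)
        W <- matrix(stats::runif(n * (G - nCorr)), n, G - nCorr)
        colnames(W) <- if (G > nCorr) paste0("w", seq_len(G - nCorr)) else NULL
        X <- cbind(V, W)[, sample.int(G), drop = FALSE]
        rownames(X) <- paste0("s", seq_len(n))
        truth <- new("SimTruth", causalFeatures = causal, latentZ = latent,
                     achievedEventRate = NA_real_, censorBound = NA_real_)
        list(X = X, truth = truth)
    })
}

#' Simulate right-censored survival outcomes from a Cox model
#'
#' Event times follow a proportional-hazards model with unit baseline
#' hazard, log h(t | z) = beta' z, i.e. U_i ~ Exponential(exp(beta' z_i)).
#' Censoring times are V_i ~ U(0, censorBound), independent of covariates;
#' the observed outcome is T_i = min(U_i, V_i), Delta_i = 1\{U_i <= V_i\}.
#' `censorBound = Inf` disables censoring.
#'
#' @param Z numeric matrix (n x length(betas)) of causal covariate values.
#' @param betas log-hazard coefficients.
#' @param censorBound positive upper bound of the uniform censoring time.
#' @param seed integer seed.
#' @return list with `time`, `status` (integer 0/1), `eventRate`.
#' @export
simulateSurvival <- function(Z, betas, censorBound, seed) {
    Z <- as.matrix(Z)
    if (ncol(Z) != length(betas)) stop("ncol(Z) must match length(betas)")
    if (censorBound <= 0) stop("censorBound must be > 0")
    lp <- drop(Z %*% betas)
    if (any(!is.finite(lp))) stop("non-finite linear predictor")
    withSeed(seed, {
        U <- stats::rexp(nrow(Z), rate = exp(lp))
        V <- if (is.finite(censorBound))
            stats::runif(nrow(Z), 0, censorBound) else Inf
        time <- pmin(U, V)
        status <- as.integer(U <= V)
        ## strictly positive times are required downstream; U(0,c) can in
        ## principle draw 0 at double resolution
        time <- pmax(time, .Machine$double.xmin)
        list(time = time, status = status, eventRate = mean(status))
    })
}

#' Calibrate the censoring bound to a target event rate
#'
#' Monte-Carlo bisection: draws a large reference sample of latent causal
#' variables and exponential event times once, then bisects the uniform
#' censoring bound c until the achieved event fraction P(U <= c * Unif)
#' is within `tol` of the target. Deterministic given the seed.
#'
#' @param betas log-hazard coefficients.
#' @param targetEventRate eta in (0, 1).
#' @param seed integer seed.
#' @param nMC Monte-Carlo sample size (default 50000).
#' @param tol calibration tolerance on the event rate (default 0.01).
#' @param maxIter maximum bisection iterations (default 100).
#' @param drawZ function(n) returning an n x length(betas) draw of the
#'   latent causal variables; defaults to i.i.d. U(0, 1).
#' @return the calibrated censoring bound (scalar).
#' @export
calibrateCensoring <- function(betas, targetEventRate, seed, nMC = 50000,
                               tol = 0.01, maxIter = 100,
                               drawZ = NULL) {
    if (targetEventRate <= 0 || targetEventRate >= 1)
        stop("targetEventRate must be in (0, 1)")
    if (is.null(drawZ))
        drawZ <- function(n) matrix(stats::runif(n * length(betas)), n)
    withSeed(seed, {
        Z <- as.matrix(drawZ(nMC))
        U <- stats::rexp(nMC, rate = exp(drop(Z %*% betas)))
        frac <- stats::runif(nMC)          # V = c * frac under U(0, c)
        rate <- function(c) mean(U <= c * frac)
        lo <- 0; hi <- stats::median(U) * 4
        expand <- 0L
        while (rate(hi) < targetEventRate && expand < 60L) {
            hi <- hi * 2; expand <- expand + 1L
        }
        if (rate(hi) < targetEventRate)
            stop("calibration failed: cannot reach event rate ",
                 targetEventRate, " (achieved ", rate(hi), " at bound ", hi,
                 ")")
        trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            mid <- (lo + hi) / 2
            r <- rate(mid)
            trace <- c(trace, r)
            if (abs(r - targetEventRate) <= tol) return(mid)
            if (r < targetEventRate) lo <- mid else hi <- mid
        }
        stop("censoring calibration did not converge in ", maxIter,
             " iterations; event-rate trace: ",
             paste(format(utils::tail(trace, 8), digits = 3),
                   collapse = ", "))
    })
}

#' Simulate one complete dataset for a scenario
#'
#' Features from [simulateFeaturesUniform()], outcome from
#' [simulateSurvival()] driven by the latent z_1..z_3, censoring bound
#' either supplied or calibrated to the scenario's target event rate.
#'
#' @param scenario a [SimScenario-class].
#' @param seed integer seed.
#' @param censorBound optional precalibrated bound; when NULL it is
#'   calibrated with [calibrateCensoring()] (seed-derived, so repeated
#'   calls agree).
#' @return list with `dataset` (a [SurvivalDataset-class]) and `truth`
#'   (a [SimTruth-class] with achieved event rate and bound filled in).
#' @export
simulateScenario <- function(scenario, seed, censorBound = NULL) {
    if (is.null(censorBound))
        censorBound <- calibrateCensoring(scenario@betas,
            scenario@targetEventRate, seed = deriveSeed(seed, 9241))
    feats <- simulateFeaturesUniform(scenario, seed = deriveSeed(seed, 1))
    surv <- simulateSurvival(feats$truth@latentZ[, 1:3, drop = FALSE],
        scenario@betas, censorBound, seed = deriveSeed(seed, 2))
    ds <- survivalDataset(feats$X, surv$time, surv$status)
    truth <- feats$truth
    truth@achievedEventRate <- surv$eventRate
    truth@censorBound <- censorBound
    list(dataset = ds, truth = truth)
}

#' Generate a paired replicate for stability assessment
#'
#' Two independent draws of the same scenario sharing the causal-name
#' schema: the first for feature selection, the second for assessing
#' selection stability. The repeat index is folded into the seed so a
#' series of pairs is reproducible and pairwise independent.
#'
#' @param scenario a [SimScenario-class].
#' @param seed master integer seed.
#' @param repeatIndex replicate number (folded into the seed).
#' @param censorBound optional precalibrated bound shared by both draws.
#' @return list with `first`, `second` ([SurvivalDataset-class]) and
#'   `truth` (the first draw's [SimTruth-class]; the causal set is common).
#' @export
pairedReplicates <- function(scenario, seed, repeatIndex = 1,
                             censorBound = NULL) {
    if (is.null(censorBound))
        censorBound <- calibrateCensoring(scenario@betas,
            scenario@targetEventRate, seed = deriveSeed(seed, 9241))
    r1 <- simulateScenario(scenario, deriveSeed(seed, repeatIndex, 1),
                           censorBound = censorBound)
    r2 <- simulateScenario(scenario, deriveSeed(seed, repeatIndex, 2),
                           censorBound = censorBound)
    list(first = r1$dataset, second = r2$dataset, truth = r1$truth)
}
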