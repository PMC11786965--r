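test_that("selection metrics follow their definitions on toy sets", {
    causal <- paste0("v", 1:30)
    m <- selectionMetrics(c("v1", "w1", "w2"), causal)
    expect_equal(m$fdr, 2 / 3)
    expect_equal(m$sensitivity, 1 / 30)

    perfect <- selectionMetrics(causal, causal)
    expect_equal(unlist(perfect), c(fdr = 0, sensitivity = 1, f1 = 1))

    none <- selectionMetrics(character(), causal)
    expect_equal(unlist(none), c(fdr = 0, sensitivity = 0, f1 = 0))

    # harmonic-mean identity wherever both terms are positive
    for (seed in 1:10) {
        set.seed(seed)
        sel <- sample(letters, 8)
        cau <- sample(letters, 10)
        m <- selectionMetrics(sel, cau)
        prec <- 1 - m$fdr
        if (prec > 0 && m$sensitivity > 0)
            expect_equal(m$f1,
                         2 * prec * m$sensitivity / (prec + m$sensitivity))
    }
})

test_that("Jaccard stability handles overlap, identity and emptiness", {
    expect_equal(jaccardStability(c("a", "b", "c"), c("b", "c", "d")), 0.5)
    expect_equal(jaccardStability(c("a", "b"), c("a", "b")), 1)
    expect_equal(jaccardStability(c("a"), c("b")), 0)
    expect_equal(jaccardStability(character(), character()), 1)
})

test_that("empirical power counts per-feature selection frequency", {
    sels <- list(c("a", "b"), c("a"), c("a", "c"), c("a", "b"))
    pw <- empiricalPower(sels, causal = c("a", "b", "z"))
    expect_equal(unname(pw), c(1, 0.5, 0))
    expect_error(empiricalPower(list(), "a"), "replicate")
})

test_that("WRF weights selections inversely to their size", {
    folds <- list(c("g", paste0("x", 1:4)),          # |S| = 5
                  c("g", paste0("y", 1:9)),          # |S| = 10
                  "solo",                            # |S| = 1
                  character())                       # empty fold
    tab <- wrf(folds)
    expect_equal(tab$wrf[tab$feature == "g"], 1 / 5 + 1 / 10)
    expect_equal(tab$wrf[tab$feature == "solo"], 1)
    expect_equal(max(tab$wrfNormalized), 1)
    expect_identical(tab$feature[1], "solo")
    # a never-selected feature reports 0
    tab2 <- wrf(folds, features = c("g", "absent"))
    expect_equal(tab2$wrf[tab2$feature == "absent"], 0)
})

test_that("concordance index matches exhaustive pair counting", {
    # perfect discrimination without censoring
    set.seed(2)
    t0 <- sort(rexp(50) + 0.01)
    expect_equal(concordanceIndex(t0, rep(1L, 50), -t0), 1)

    # hand-worked n = 4 instance with one censored sample
    tt <- c(1, 2, 3, 4); ss <- c(1L, 0L, 1L, 0L)
    rk <- c(5, 1, 4, 2)
    # comparable: (1 vs 2,3,4) and (3 vs 4) -> 4 pairs, all concordant
    expect_equal(concordanceIndex(tt, ss, rk), 1)
    rk2 <- c(1, 5, 4, 2)   # sample 1 now has the lowest risk
    expect_equal(concordanceIndex(tt, ss, rk2), (0 + 1) / 4)

    # brute-force oracle on random censored instances
    for (seed in 1:5) {
        set.seed(seed)
        n <- 60
        tt <- rexp(n) + 0.01
        ss <- rbinom(n, 1, 0.6)
        rk <- rnorm(n)
        conc <- 0; ties <- 0; comp <- 0
        for (i in 1:n) for (j in 1:n) {
            if (ss[i] == 1L && tt[i] < tt[j]) {
                comp <- comp + 1
                if (rk[i] > rk[j]) conc <- conc + 1
                else if (rk[i] == rk[j]) ties <- ties + 0.5
            }
        }
        expect_equal(concordanceIndex(tt, ss, rk), (conc + ties) / comp)
    }

    # random risk at large n is chance-level
    set.seed(10)
    n <- 10000
    tt <- rexp(n) + 0.01; ss <- rbinom(n, 1, 0.7)
    expect_equal(concordanceIndex(tt, ss, rnorm(n)), 0.5,
                 tolerance = 0.01)
})

test_that("integrated Brier score hits its closed forms", {
    set.seed(5)
    n <- 80
    tt <- sort(rexp(n)) + 0.01
    ss <- rep(1L, n)
    grid <- as.numeric(quantile(tt, c(.1, .3, .5, .7)))

    # oracle curves: step functions dropping at each true event time
    S <- t(vapply(tt, function(ti) as.numeric(grid < ti),
                  numeric(length(grid))))
    expect_lt(integratedBrier(tt, ss, S, grid)$ibs, 1e-12)

    # constant 0.5 prediction without censoring: Brier 0.25 everywhere
    S5 <- matrix(0.5, n, length(grid))
    out <- integratedBrier(tt, ss, S5, grid)
    expect_equal(out$brier, rep(0.25, length(grid)), tolerance = 1e-12)
    expect_equal(out$ibs, 0.25, tolerance = 1e-12)
})

test_that("IPCW Brier matches the survival package on censored data", {
    set.seed(3)
    n <- 60
    tt <- rexp(n) + 0.01; ss <- rbinom(n, 1, 0.6); x <- rnorm(n)
    fit <- survival::coxph(survival::Surv(tt, ss) ~ x)
    grid <- as.numeric(quantile(tt, c(.2, .4, .6)))
    oracle <- survival::brier(fit, times = grid)
    sf <- survival::survfit(fit, newdata = data.frame(x = x))
    S <- t(vapply(seq_len(n), function(i)
        vapply(grid, function(g) {
            k <- which(sf$time <= g)
            if (!length(k)) 1 else sf$surv[max(k), i]
        }, numeric(1)), numeric(length(grid))))
    mine <- integratedBrier(tt, ss, S, grid)
    expect_equal(mine$brier, unname(oracle$brier), tolerance = 1e-6)
})

test_that("composite score separates risk groups and honors the tie rule", {
    ds <- makeToyDataset(n = 100, p = 5, nCausal = 1, beta = 2, seed = 12)
    cs <- compositeScore(ds, "g1")
    # single gene: score is a monotone transform of that gene
    expect_equal(abs(cor(cs$score, exprMatrix(ds)[, "g1"])), 1,
                 tolerance = 1e-12)
    # median sample goes to the low group
    expect_true(all(cs$group[cs$score <= cs$medianScore] == "low"))
    expect_false(cs$ridge)

    # strong causal gene: log-rank separation at the median split
    ps <- vapply(1:6, function(s) {
        d <- makeToyDataset(n = 100, p = 4, nCausal = 1, beta = 2,
                            seed = 70 + s)
        compositeScore(d, "g1")$logrankP
    }, numeric(1))
    expect_gte(mean(ps < 0.05), 0.8)

    # collinear features trigger the flagged ridge fallback
    X <- exprMatrix(ds)
    X[, "g3"] <- X[, "g2"]
    ds2 <- survivalDataset(X, survTime(ds), survStatus(ds))
    cs2 <- suppressWarnings(compositeScore(ds2, c("g2", "g3")))
    expect_true(is.finite(cs2$logrankChisq))
})

test_that("cross-validation harness is deterministic and calibrated", {
    ds <- makeToyDataset(n = 90, p = 12, nCausal = 2, beta = 1.5,
                         seed = 31)
    sel <- function(d) featureNames(suppressWarnings(
        univariateCoxSelect(d, k = 4)))
    h1 <- cvHarness(ds, sel, folds = 3, repeats = 2, seed = 5)
    h2 <- cvHarness(ds, sel, folds = 3, repeats = 2, seed = 5)
    expect_identical(h1$cIndex, h2$cIndex)
    expect_length(h1$cIndex, 6L)
    expect_gt(h1$meanCIndex, 0.5)   # real signal beats chance
    expect_true(all(h1$wrf$wrf >= 0))

    # a random-risk predictor is chance-level on average
    rnd <- function(train, test, features) {
        set.seed(floor(sum(survTime(test)) * 1e4) %% 100000)
        list(risk = rnorm(nSamples(test)), survival = NULL)
    }
    h3 <- cvHarness(ds, sel, predictor = rnd, folds = 5, repeats = 5,
                    seed = 6)
    expect_lt(abs(mean(h3$cIndex) - 0.5), 0.06)
})
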