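test_that("univariate Cox ranks a strongly hazardous feature first", {
    ds <- makeToyDataset(n = 80, p = 8, nCausal = 1, beta = 2, seed = 4)
    out <- univariateCoxSelect(ds)
    expect_identical(featureNames(out)[1], "g1")
    expect_lt(out@scores[1], 1e-4)

    # oracle: the reported p equals the survival-package Wald p
    y <- survival::Surv(survTime(ds), survStatus(ds))
    x <- exprMatrix(ds)[, "g1"]
    fit <- survival::coxph(y ~ x, ties = "breslow")
    pOracle <- pchisq((fit$coefficients / sqrt(fit$var[1, 1]))^2, 1,
                      lower.tail = FALSE)
    expect_equal(out@scores[1], unname(pOracle), tolerance = 1e-10)
})

test_that("univariate Cox skips degenerate features and honors alpha/k", {
    ds <- makeToyDataset(n = 60, p = 6, seed = 2)
    X <- exprMatrix(ds)
    X[, "g6"] <- 1   # constant
    ds2 <- survivalDataset(X, survTime(ds), survStatus(ds))
    expect_warning(out <- univariateCoxSelect(ds2), "skipped")
    expect_false("g6" %in% featureNames(out))

    # k truncation
    out2 <- suppressWarnings(univariateCoxSelect(ds2, k = 1, alpha = 1 - 1e-12))
    expect_lte(length(featureNames(out2)), 1L)
})

test_that("univariate Cox false-positive count matches its alpha level", {
    hits <- vapply(1:8, function(seed) {
        ds <- makeToyDataset(n = 60, p = 100, nCausal = 0, seed = seed + 50)
        length(featureNames(suppressWarnings(
            univariateCoxSelect(ds, k = 100))))
    }, numeric(1))
    # 100 null features at alpha = 0.05: about 5 discoveries on average
    expect_gt(mean(hits), 1)
    expect_lt(mean(hits), 9)
})

test_that("L1 Cox selector returns coefficients ranked by magnitude", {
    ds <- makeToyDataset(n = 100, p = 20, nCausal = 2, beta = 1.5,
                         seed = 6)
    out <- lassoCoxSelect(ds, seed = 3)
    expect_gt(length(featureNames(out)), 0)
    expect_true(all(diff(out@scores) <= 0))
    expect_true(any(c("g1", "g2") %in% featureNames(out)[1:2]))

    # a grid pinned far above lambda_max shrinks everything away
    empty <- lassoCoxSelect(ds, seed = 3, lambdaGrid = c(1e6, 1e5))
    expect_length(featureNames(empty), 0L)

    # determinism given the seed
    out2 <- lassoCoxSelect(ds, seed = 3)
    expect_identical(featureNames(out), featureNames(out2))
})

test_that("survival label encodes censoring and event-time tertiles", {
    ds <- makeToyDataset(n = 90, p = 3, seed = 5)
    lab <- survivalLabel(ds)
    expect_true(all(lab[survStatus(ds) == 0L] == 0L))
    evLab <- lab[survStatus(ds) == 1L]
    expect_true(all(evLab %in% 1:3))
    # tertile classes are ordered by time
    evT <- survTime(ds)[survStatus(ds) == 1L]
    expect_true(max(evT[evLab == 1]) <= min(evT[evLab == 3]))
    expect_identical(survivalLabel(ds, "status"), survStatus(ds))
})

test_that("MIM scores reach the label entropy on a perfect feature", {
    # balanced deterministic outcome: 30 censored + 3 x 30 event tertiles,
    # so equal-frequency binning recovers the 4 label classes exactly
    set.seed(8)
    n <- 120
    time <- c(runif(30, 0.5, 3.5), rep(c(1, 2, 3), each = 30))
    status <- c(rep(0L, 30), rep(1L, 90))
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:4)))
    ds0 <- survivalDataset(X, time, status)
    lab <- survivalLabel(ds0)
    expect_equal(unname(table(lab)), rep(30L, 4), ignore_attr = TRUE)
    X[, "g1"] <- lab + 1   # feature identical to the label
    ds <- survivalDataset(X, time, status)
    out <- mimSelect(ds, k = 4, nBins = 4)
    expect_identical(featureNames(out)[1], "g1")
    expect_equal(out@scores[1], log(4), tolerance = 1e-10)
})

test_that("MIM of an independent feature vanishes at large n", {
    set.seed(9)
    n <- 10000
    X <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "g1"))
    ds <- survivalDataset(X, rexp(n) + 0.01, rbinom(n, 1, 0.5))
    out <- mimSelect(ds, k = 1)
    expect_lt(out@scores[1], 0.01)
})

test_that("MIM returns exactly k features and guards its inputs", {
    ds <- makeToyDataset(n = 60, p = 40, seed = 3)
    expect_length(featureNames(mimSelect(ds, k = 25)), 25L)
    expect_error(mimSelect(ds, nBins = 1), "nBins")
})

test_that("MRMR suppresses redundant copies and reduces to MIM first", {
    ds <- makeToyDataset(n = 80, p = 6, nCausal = 1, beta = 2, seed = 7)
    X <- exprMatrix(ds)
    X[, "g2"] <- X[, "g1"]          # exact duplicate of the best feature
    ds2 <- survivalDataset(X, survTime(ds), survStatus(ds))
    mim <- mimSelect(ds2, k = 6)
    mrmr <- mrmrSelect(ds2, k = 6)
    # first pick agrees with MIM's first pick (empty redundancy set)
    expect_identical(featureNames(mrmr)[1], featureNames(mim)[1])
    # the duplicate does not occupy the top 2 of MRMR
    top2 <- featureNames(mrmr)[1:2]
    expect_false(all(c("g1", "g2") %in% top2))
})

test_that("external rankings are validated against the feature universe", {
    ds <- makeToyDataset(n = 30, p = 10, seed = 1)
    out <- externalSelectorAdapter(c("g5", "g2", "g9"), ds, "rf")
    expect_identical(featureNames(out), c("g5", "g2", "g9"))
    expect_identical(out@selectorName, "rf")

    expect_error(externalSelectorAdapter(c("g1", "gX"), ds), "gX")

    empty <- withr::local_tempfile(fileext = ".tsv")
    file.create(empty)
    out2 <- externalSelectorAdapter(empty, ds)
    expect_length(featureNames(out2), 0L)

    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("g3\t0.9", "g1\t0.5"), tsv)
    out3 <- externalSelectorAdapter(tsv, ds)
    expect_identical(featureNames(out3), c("g3", "g1"))
    expect_equal(out3@scores, c(0.9, 0.5))
})

test_that("every selector finds signal under vanishing group noise", {
    sc <- simScenario(100, 80, 0.5, noiseSd = 0.01)
    hits <- vapply(1:5, function(r) {
        sim <- simulateScenario(sc, seed = 100 + r, censorBound = 2)
        causal <- sim$truth@causalFeatures
        top1 <- c(
            featureNames(suppressWarnings(
                univariateCoxSelect(sim$dataset)))[1],
            featureNames(mimSelect(sim$dataset))[1])
        mean(top1 %in% causal)
    }, numeric(1))
    expect_gte(mean(hits), 0.8)
})
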