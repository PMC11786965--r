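test_that("expression matrices round-trip losslessly through disk", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,gA,gB\ns1,1,2\ns2,3,4\ns3,5,6", path)
    X <- readExpression(path)
    expect_identical(unname(X), matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
    expect_identical(rownames(X), c("s1", "s2", "s3"))
    expect_identical(colnames(X), c("gA", "gB"))

    X2 <- matrix(rnorm(12), 4, 3,
                 dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
    out <- withr::local_tempfile(fileext = ".csv")
    writeExpression(X2, out)
    expect_equal(readExpression(out), X2)
})

test_that("malformed expression files fail with informative errors", {
    dup <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,g1,g1\ns1,1,2\ns2,3,4", dup)
    expect_error(readExpression(dup), "g1")

    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,g1,g2\ns1,1,2\ns2,oops,4", bad)
    expect_error(readExpression(bad), "non-numeric")
})

test_that("clinical tables are validated on read", {
    ok <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,time,status\ns1,5.0,1\ns2,3.2,0", ok)
    cl <- readClinical(ok)
    expect_equal(cl$time, c(5.0, 3.2))
    expect_identical(cl$status, c(1L, 0L))

    badStatus <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,time,status\ns1,5.0,2", badStatus)
    expect_error(readClinical(badStatus), "status")

    badTime <- withr::local_tempfile(fileext = ".csv")
    writeLines("sample,time,status\ns1,-1,1", badTime)
    expect_error(readClinical(badTime), "positive")
})

test_that("dataset assembly intersects, orders and validates samples", {
    X <- matrix(1:8, 4, 2,
                dimnames = list(paste0("s", 1:4), c("g1", "g2")))
    clin <- data.frame(sample = c("s2", "s1", "s3", "s4"),
                       time = c(2, 1, 3, 4), status = c(1L, 0L, 1L, 0L))
    ds <- assembleDataset(X, clin)
    expect_equal(nSamples(ds), 4L)
    expect_equal(survTime(ds)[match("s2", sampleNames(ds))], 2)

    # extra expression-only sample is dropped with a warning
    expect_warning(ds2 <- assembleDataset(X, clin[1:3, ]), "s4")
    expect_equal(nSamples(ds2), 3L)
    expect_false("s4" %in% sampleNames(ds2))

    # clinical missing a sample present in expression lists the offender
    expect_warning(assembleDataset(X, clin[clin$sample != "s3", ]), "s3")

    # disjoint sample universes are an error
    clinBad <- transform(clin, sample = paste0("x", 1:4))
    expect_error(assembleDataset(X, clinBad), "shared")

    # idempotence: assembling a dataset's own pieces changes nothing
    clin3 <- data.frame(sample = sampleNames(ds), time = survTime(ds),
                        status = survStatus(ds))
    ds3 <- assembleDataset(exprMatrix(ds), clin3)
    expect_equal(exprMatrix(ds3), exprMatrix(ds))
    expect_equal(survTime(ds3), survTime(ds))
})

test_that("SurvivalDataset validity rejects bad inputs", {
    X <- matrix(rnorm(6), 3, 2,
                dimnames = list(paste0("s", 1:3), c("g1", "g2")))
    expect_error(survivalDataset(X, c(1, 2, 0), c(1, 0, 1)), "> 0")
    expect_error(survivalDataset(X, c(1, 2, 3), c(1, 0, 2)), "status")
    Xna <- X; Xna[1, 1] <- NA
    expect_error(survivalDataset(Xna, c(1, 2, 3), c(1, 0, 1)), "missing")
})

test_that("selection results round-trip through JSON", {
    part <- new("BlockPartition",
                blocks = list(c("a", "b"), "c"), sizes = c(2L, 1L),
                rhoT = 0.75, weights = c(2, 3))
    res <- new("SelectionResult", selectedBlocks = 1L,
               selectedFeatures = c("a", "b"), counts = c(40L, 10L),
               K = 50L, tau = 0.5, seed = 7L, partition = part,
               permutationLog = list())
    path <- withr::local_tempfile(fileext = ".json")
    writeSelectionResult(res, path)
    back <- readSelectionResult(path)
    expect_identical(selectedFeatures(back), selectedFeatures(res))
    expect_identical(selectionCounts(back), selectionCounts(res))
    expect_identical(back@K, res@K)
    expect_identical(back@seed, res@seed)
    expect_identical(blocks(back@partition), blocks(part))
})

test_that("run configuration reads from YAML and rejects unknown keys", {
    y <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("selectors: [lasso, cox, mim]", "K: 20", "tau: 0.5",
                 "rhoT: 0.75", "seed: 3"), y)
    cfg <- readRunConfig(y)
    expect_identical(cfg@K, 20L)
    expect_identical(cfg@seed, 3L)
    expect_identical(cfg@selectors, c("lasso", "cox", "mim"))

    bad <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("K: 20", "bogus: 1"), bad)
    expect_error(readRunConfig(bad), "bogus")
})
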