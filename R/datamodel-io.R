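#' Construct a SurvivalDataset
#'
#' Validated constructor pairing a samples x features expression matrix with
#' follow-up time and event status. Row order of `X` must match `time` and
#' `status`.
#'
#' @param X numeric matrix (samples x features) with dimnames; a
#'   features x samples dump can be passed with `transpose = TRUE`.
#' @param time positive follow-up times.
#' @param status event indicator, 1 = event observed, 0 = censored. Other
#'   codings must be mapped by the caller.
#' @param transpose set TRUE when `X` is features x samples.
#' @return a [SurvivalDataset-class].
#' @examples
#' X <- matrix(rnorm(20), 4, 5,
#'     dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
#' survivalDataset(X, time = c(2, 5, 1, 3), status = c(1, 0, 1, 1))
#' @export
survivalDataset <- function(X, time, status, transpose = FALSE) {
    if (transpose) X <- t(X)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (!all(status %in% c(0, 1)))
        stop("status must be coded 0/1 (1 = event); found: ",
             paste(unique(setdiff(status, c(0, 1))), collapse = ", "))
    new("SurvivalDataset", X = X, time = as.numeric(time),
        status = as.integer(status))
}

#' Construct a SelectorOutput
#'
#' @param selectorName identifier for the selector.
#' @param features ranked feature names, best first.
#' @param scores selector-native scores aligned to `features`.
#' @param dataset optional [SurvivalDataset-class]; when given, `features`
#'   are validated against its feature universe.
#' @return a [SelectorOutput-class].
#' @export
selectorOutput <- function(selectorName, features = character(),
                           scores = numeric(length(features)),
                           dataset = NULL) {
    features <- as.character(features)
    if (!is.null(dataset)) {
        unknown <- setdiff(features, featureNames(dataset))
        if (length(unknown))
            stop("unknown feature names: ", paste(unknown, collapse = ", "))
    }
    new("SelectorOutput", selectorName = selectorName, features = features,
        scores = as.numeric(scores))
}

## ---- delimited readers/writers ------------------------------------------

#' Read / write an expression matrix
#'
#' Delimited text with a header row of feature names and sample identifiers
#' in the first column (samples x features on disk). The delimiter is
#' auto-detected by `data.table::fread` unless given.
#'
#' @param path file path.
#' @param sep field delimiter, or "auto".
#' @param transpose TRUE when the file stores features x samples.
#' @return for `readExpression`, a numeric matrix with sample row names and
#'   feature column names.
#' @export
readExpression <- function(path, sep = "auto", transpose = FALSE) {
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    if (ncol(dt) < 2L) stop("expression file needs an ID column plus ",
                            "at least one feature column: ", path)
    ids <- as.character(dt[[1L]])
    feat <- colnames(dt)[-1L]
    dup <- unique(feat[duplicated(feat)])
    if (length(dup))
        stop("duplicate feature name(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    vals <- dt[, -1L, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
        col <- which(bad)[1L]
        row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1L]
        stop(sprintf(
            "non-numeric value in column '%s' near line %d of %s",
            feat[col], if (is.na(row)) NA_integer_ else row + 1L, path))
    }
    X <- as.matrix(vals)
    storage.mode(X) <- "double"
    dimnames(X) <- list(ids, feat)
    if (transpose) t(X) else X
}

#' @rdname readExpression
#' @param X samples x features matrix with dimnames.
#' @export
writeExpression <- function(X, path, sep = ",") {
    df <- data.frame(sample = rownames(X), X, check.names = FALSE)
    data.table::fwrite(df, path, sep = sep)
    invisible(path)
}

#' Read a clinical table
#'
#' Expects columns for sample identifier, follow-up time and event status
#' (names configurable). Status must be coded 0/1 and times strictly
#' positive.
#'
#' @param path file path.
#' @param sampleCol,timeCol,statusCol column names.
#' @param sep field delimiter, or "auto".
#' @return data.frame with columns `sample`, `time`, `status`.
#' @export
readClinical <- function(path, sampleCol = "sample", timeCol = "time",
                         statusCol = "status", sep = "auto") {
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    need <- c(sampleCol, timeCol, statusCol)
    miss <- setdiff(need, colnames(dt))
    if (length(miss))
        stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(sample = as.character(dt[[sampleCol]]),
                      time = as.numeric(dt[[timeCol]]),
                      status = dt[[statusCol]])
    if (anyNA(out$time) || any(out$time <= 0))
        stop("all follow-up times must be positive; offending rows: ",
             paste(which(is.na(out$time) | out$time <= 0), collapse = ", "))
    if (!all(out$status %in% c(0, 1)))
        stop("status values outside {0,1}: ",
             paste(unique(setdiff(out$status, c(0, 1))), collapse = ", "))
    out$status <- as.integer(out$status)
    out
}

#' Assemble a SurvivalDataset from expression and clinical inputs
#'
#' Intersects the sample sets, orders them identically and validates the
#' result. Samples present on only one side are dropped with a warning.
#'
#' @param expr samples x features numeric matrix (e.g. [readExpression()]).
#' @param clinical data.frame as returned by [readClinical()].
#' @return a [SurvivalDataset-class].
#' @export
assembleDataset <- function(expr, clinical) {
    common <- intersect(rownames(expr), clinical$sample)
    if (length(common) < 2L)
        stop("fewer than 2 samples shared between expression and clinical ",
             "tables (", length(common), " in common)")
    extraE <- setdiff(rownames(expr), common)
    extraC <- setdiff(clinical$sample, common)
    if (length(extraE))
        warning("dropping expression-only sample(s): ",
                paste(extraE, collapse = ", "))
    if (length(extraC))
        warning("dropping clinical-only sample(s): ",
                paste(extraC, collapse = ", "))
    idx <- match(common, clinical$sample)
    survivalDataset(expr[common, , drop = FALSE],
                    time = clinical$time[idx],
                    status = clinical$status[idx])
}

## ---- selector / ranking / result serialization ---------------------------

#' Write and read a selector output as rank-ordered TSV
#'
#' Two columns (`feature`, `score`) in rank order; the adapter for external
#' selectors ([externalSelectorAdapter()]) accepts the same layout.
#'
#' @param x a [SelectorOutput-class].
#' @param path file path.
#' @export
writeSelectorOutput <- function(x, path) {
    df <- data.frame(feature = x@features, score = x@scores)
    data.table::fwrite(df, path, sep = "\t")
    invisible(path)
}

#' Write an aggregated ranking as TSV
#'
#' Columns: feature, final rank, then one imputed-rank column per selector.
#'
#' @param x an [AggregatedRanking-class].
#' @param path file path.
#' @export
writeRanking <- function(x, path) {
    df <- data.frame(feature = x@features, final_rank = x@finalRank,
                     x@perSelectorRank, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t")
    invisible(path)
}

#' Serialize / restore a SelectionResult as JSON
#'
#' The JSON records the selected blocks and features, per-block counts, the
#' partition, and the provenance triple (K, tau, seed), so a selection can
#' be audited without rerunning.
#'
#' @param x a [SelectionResult-class].
#' @param path file path.
#' @export
writeSelectionResult <- function(x, path) {
    obj <- list(
        selected_blocks = x@selectedBlocks,
        selected_features = x@selectedFeatures,
        counts = x@counts,
        K = x@K, tau = x@tau, seed = x@seed,
        blocks = x@partition@blocks,
        block_sizes = x@partition@sizes,
        block_weights = x@partition@weights,
        rho_T = x@partition@rhoT)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeSelectionResult
#' @export
readSelectionResult <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    part <- new("BlockPartition",
        blocks = lapply(obj$blocks, as.character),
        sizes = as.integer(obj$block_sizes),
        rhoT = as.numeric(obj$rho_T),
        weights = as.numeric(obj$block_weights))
    new("SelectionResult",
        selectedBlocks = as.integer(obj$selected_blocks),
        selectedFeatures = as.character(obj$selected_features),
        counts = as.integer(obj$counts),
        K = as.integer(obj$K), tau = as.numeric(obj$tau),
        seed = as.integer(obj$seed), partition = part,
        permutationLog = list())
}

## ---- run configuration ----------------------------------------------------

#' Build or read a run configuration
#'
#' Defaults follow the method's reference settings: top-k 25, p-value
#' threshold 0.05, correlation threshold 0.75, K = 50 permutations,
#' selection threshold tau = 0.5.
#'
#' @param selectors selector names; "ensemble1" and "ensemble2" recipes are
#'   resolved by [makeEnsemble()].
#' @param k top-k count for top-k selectors.
#' @param alpha univariate Cox p-value threshold.
#' @param nBins discretization bins for mutual-information scores.
#' @param rhoT within-block minimum absolute pairwise correlation.
#' @param K number of pseudo-variable permutations.
#' @param tau strict selection-fraction threshold.
#' @param nLambda,lambdaMinRatio regularization-path grid controls.
#' @param seed master seed; recorded in all outputs.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(selectors = c("lasso", "cox", "mim"), k = 25,
                      alpha = 0.05, nBins = 5, rhoT = 0.75, K = 50,
                      tau = 0.5, nLambda = 100, lambdaMinRatio = 0.001,
                      seed = 1) {
    new("RunConfig", selectors = selectors, k = as.integer(k),
        alpha = alpha, nBins = as.integer(nBins), rhoT = rhoT,
        K = as.integer(K), tau = tau, nLambda = as.integer(nLambda),
        lambdaMinRatio = lambdaMinRatio, seed = as.integer(seed))
}

#' @rdname runConfig
#' @param path YAML file whose keys match the arguments of `runConfig()`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(runConfig, y)
}
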