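#' Run the full ensemble selection pipeline on one dataset
#'
#' Executes selectors -> rank aggregation -> correlation blocks -> penalty
#' weights -> pseudo-variable-tuned Cox group lasso, and returns the final
#' [SelectionResult-class]. An empty aggregated feature set yields an
#' empty result with an explicit status rather than an error.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param config a [RunConfig-class]; `config@selectors` names the
#'   ensemble members (see [makeEnsemble()] for the reference recipes).
#' @param external named list of externally computed rankings for adapter
#'   selectors.
#' @param verbose emit stage timing messages.
#' @return a [SelectionResult-class]; the `permutationLog` of an empty run
#'   carries a `status` record.
#' @export
runSelect <- function(dataset, config = runConfig(), external = list(),
                      verbose = FALSE) {
    stage <- function(what, expr) {
        t0 <- proc.time()[["elapsed"]]
        res <- force(expr)
        if (verbose)
            message(sprintf("[%s] %.2fs", what,
                            proc.time()[["elapsed"]] - t0))
        res
    }
    emptyResult <- function(status) {
        part <- new("BlockPartition", blocks = list(), sizes = integer(),
                    rhoT = config@rhoT, weights = numeric())
        new("SelectionResult", selectedBlocks = integer(),
            selectedFeatures = character(), counts = integer(),
            K = config@K, tau = config@tau, seed = config@seed,
            partition = part, permutationLog = list(status = status))
    }
    outputs <- stage("selectors", lapply(config@selectors, function(nm)
        runSelector(nm, dataset, config, external = external)))
    if (all(lengths(lapply(outputs, featureNames)) == 0L))
        return(emptyResult("empty aggregated feature set"))
    ranking <- stage("aggregate", aggregateRanks(outputs))
    partition <- stage("blocks",
        buildBlocks(dataset, ranking, rhoT = config@rhoT))
    problem <- stage("problem", coxGroupProblem(dataset, partition))
    stage("pseudo-tuned group lasso",
        pseudoTunedSelect(problem, K = config@K, tau = config@tau,
                          seed = config@seed, nLambda = config@nLambda,
                          lambdaMinRatio = config@lambdaMinRatio))
}

#' Benchmark feature selection methods over simulated scenarios
#'
#' Reproduces the simulation benchmarking loop: for every scenario and
#' replicate, a paired dataset draw is generated; each method selects
#' features on the first replicate (FDR / sensitivity / F1 against the
#' known causal set) and again on the second (Jaccard stability between
#' the two selections). Per-feature empirical power is accumulated across
#' replicates from the first-replicate selections.
#'
#' Methods: "ensemble1" / "ensemble2" run the full pipeline of
#' [runSelect()]; "lasso", "cox", "mim", "mrmr" are the base selectors
#' used standalone (their ranked output is the selection).
#'
#' @param scenarios list of [SimScenario-class] (e.g. a subset of
#'   [referenceScenarios()]).
#' @param methods character vector of method names.
#' @param repeats replicates per scenario.
#' @param seed master seed; replicate seeds are derived per (scenario,
#'   replicate), so the run is order-independent.
#' @param config base [RunConfig-class] for the ensemble methods (K, tau,
#'   rhoT, path controls).
#' @param verbose emit progress messages.
#' @return list with `results` (tidy data.frame: scenario, replicate,
#'   method, n_selected, fdr, sensitivity, f1, stability) and `power`
#'   (data.frame: scenario, method, feature, power).
#' @export
runBenchmark <- function(scenarios, methods = c("ensemble1", "lasso"),
                         repeats = 20, seed = 1, config = runConfig(),
                         verbose = FALSE) {
    if (!length(methods)) stop("methods must be non-empty")
    if (inherits(scenarios, "SimScenario")) scenarios <- list(scenarios)
    rows <- list()
    powerRows <- list()
    for (si in seq_along(scenarios)) {
        sc <- scenarios[[si]]
        bound <- calibrateCensoring(sc@betas, sc@targetEventRate,
                                    seed = deriveSeed(seed, si, 9241))
        perMethodSel <- stats::setNames(
            replicate(length(methods), list(), simplify = FALSE), methods)
        causalSet <- NULL
        for (r in seq_len(repeats)) {
            repSeed <- deriveSeed(seed, si, r)
            pair <- pairedReplicates(sc, seed = repSeed,
                                     censorBound = bound)
            causal <- pair$truth@causalFeatures
            if (is.null(causalSet)) causalSet <- causal
            for (m in methods) {
                selA <- tryCatch(
                    benchmarkSelect(m, pair$first, config, repSeed),
                    error = function(e) {
                        warning("method ", m, " failed on ", sc@label,
                                " replicate ", r, ": ",
                                conditionMessage(e))
                        NULL
                    })
                if (is.null(selA)) next
                selB <- tryCatch(
                    benchmarkSelect(m, pair$second, config,
                                    deriveSeed(repSeed, 2)),
                    error = function(e) character(0))
                met <- selectionMetrics(selA, causal)
                rows[[length(rows) + 1L]] <- data.frame(
                    scenario = sc@label, replicate = r, method = m,
                    n_selected = length(selA), fdr = met$fdr,
                    sensitivity = met$sensitivity, f1 = met$f1,
                    stability = jaccardStability(selA, selB))
                perMethodSel[[m]][[length(perMethodSel[[m]]) + 1L]] <- selA
            }
            if (verbose)
                message(sprintf("%s replicate %d/%d done", sc@label, r,
                                repeats))
        }
        for (m in methods) {
            if (!length(perMethodSel[[m]])) next
            pw <- empiricalPower(perMethodSel[[m]], causal = causalSet)
            powerRows[[length(powerRows) + 1L]] <- data.frame(
                scenario = sc@label, method = m, feature = names(pw),
                power = as.numeric(pw))
        }
    }
    list(results = do.call(rbind, rows),
         power = do.call(rbind, powerRows))
}

## Resolve one benchmark method to a selected feature set.
benchmarkSelect <- function(method, dataset, config, seed) {
    if (method %in% c("ensemble1", "ensemble2")) {
        cfg <- config
        cfg@selectors <- makeEnsemble(method)
        cfg@seed <- as.integer(seed)
        selectedFeatures(runSelect(dataset, cfg))
    } else {
        cfg <- config
        cfg@seed <- as.integer(seed)
        featureNames(runSelector(method, dataset, cfg))
    }
}

#' Tidy benchmark summary
#'
#' Mean of each metric per scenario x method, the shape used for the
#' benchmark figures.
#'
#' @param benchmark result of [runBenchmark()].
#' @return data.frame with per-(scenario, method) means of fdr,
#'   sensitivity, f1, stability and the mean selected-set size.
#' @export
summarizeBenchmark <- function(benchmark) {
    res <- benchmark$results
    agg <- stats::aggregate(
        res[, c("fdr", "sensitivity", "f1", "stability", "n_selected")],
        by = list(scenario = res$scenario, method = res$method), mean)
    agg[order(agg$scenario, agg$method), , drop = FALSE]
}
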