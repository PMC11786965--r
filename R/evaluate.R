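#' Selection quality against a known causal set
#'
#' FDR is the proportion of false positives among the selected features
#' (0 for an empty selection, by convention); sensitivity the proportion
#' of causal features recovered; F1 the harmonic mean of precision
#' (1 - FDR) and sensitivity, defined as 0 when both vanish.
#'
#' @param selected character vector of selected features.
#' @param causal non-empty character vector of true causal features.
#' @return named list with `fdr`, `sensitivity`, `f1`.
#' @export
selectionMetrics <- function(selected, causal) {
    if (length(causal) == 0L) stop("causal set must be non-empty")
    selected <- unique(selected)
    fdr <- if (length(selected) == 0L) 0 else
        length(setdiff(selected, causal)) / length(selected)
    sens <- length(intersect(selected, causal)) / length(causal)
    prec <- 1 - fdr
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    list(fdr = fdr, sensitivity = sens, f1 = f1)
}

#' Jaccard stability of two selections
#'
#' |A intersect B| / |A union B|; two empty selections count as perfectly
#' stable (1).
#'
#' @param setA,setB character vectors (selections from paired replicates).
#' @return a scalar in [0, 1].
#' @export
jaccardStability <- function(setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    u <- union(setA, setB)
    if (length(u) == 0L) return(1)
    length(intersect(setA, setB)) / length(u)
}

#' Per-feature empirical power across replicates
#'
#' For each causal feature, the fraction of simulation replicates in which
#' it was selected: 1 means it was identified in every replicate, 0 that
#' it was never selected.
#'
#' @param selections list of per-replicate selected feature sets.
#' @param causal character vector of causal features.
#' @return named numeric vector over `causal`.
#' @export
empiricalPower <- function(selections, causal) {
    if (length(selections) == 0L) stop("need at least one replicate")
    hits <- vapply(causal, function(g)
        mean(vapply(selections, function(s) g %in% s, logical(1))),
        numeric(1))
    hits
}

#' Weighted relative frequency of selection across folds
#'
#' Each fold's selection contributes weight 1/|S_f| to each of its members
#' (a larger selected set adds less weight per feature), rewarding sparse,
#' consistent selection. Reported raw and max-normalized to [0, 1].
#'
#' @param foldSelections list of per-fold selected feature sets; empty
#'   folds contribute nothing.
#' @param features optional universe to report on; defaults to the union
#'   of all fold selections.
#' @return data.frame with columns `feature`, `wrf`, `wrfNormalized`,
#'   sorted by decreasing raw WRF.
#' @export
wrf <- function(foldSelections, features = NULL) {
    if (length(foldSelections) == 0L) stop("need at least one fold")
    if (is.null(features))
        features <- unique(unlist(foldSelections))
    raw <- stats::setNames(numeric(length(features)), features)
    for (s in foldSelections) {
        s <- unique(s)
        if (length(s) == 0L) next
        inS <- intersect(s, features)
        raw[inS] <- raw[inS] + 1 / length(s)
    }
    norm <- if (length(raw) && max(raw) > 0) raw / max(raw) else raw
    out <- data.frame(feature = features, wrf = as.numeric(raw),
                      wrfNormalized = as.numeric(norm))
    out[order(-out$wrf, out$feature), , drop = FALSE]
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs — an observed event versus any sample with
#' longer follow-up — in which the earlier-event sample has the higher
#' predicted risk; risk ties count 0.5. Returns NA when no pair is
#' comparable.
#'
#' @param time follow-up times.
#' @param status event indicator (1 = event).
#' @param risk predicted risk scores (higher = shorter expected survival).
#' @return a scalar in [0, 1], or NA.
#' @export
concordanceIndex <- function(time, status, risk) {
    stopifnot(length(time) == length(status),
              length(time) == length(risk))
    conc <- 0; ties <- 0; comp <- 0
    for (i in which(status == 1L)) {
        later <- which(time > time[i])
        if (!length(later)) next
        comp <- comp + length(later)
        conc <- conc + sum(risk[i] > risk[later])
        ties <- ties + sum(risk[i] == risk[later])
    }
    if (comp == 0) return(NA_real_)
    (conc + 0.5 * ties) / comp
}

## Kaplan-Meier estimate of the censoring survival function G(t);
## returns a step-function evaluator with an optional left limit.
censoringKM <- function(time, status) {
    fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
    tt <- fit$time; ss <- fit$surv
    function(t, left = FALSE) {
        vapply(seq_along(t), function(i) {
            k <- which(if (left) tt < t[i] else tt <= t[i])
            if (!length(k)) 1 else ss[max(k)]
        }, numeric(1))
    }
}

#' Integrated Brier score with IPCW weighting
#'
#' Time-dependent Brier score
#' BS(t) = mean_i [ S_i(t)^2 1\{T_i <= t, event\} / G(T_i^-)
#'                + (1 - S_i(t))^2 1\{T_i > t\} / G(t) ],
#' with G the Kaplan-Meier estimate of the censoring survival, integrated
#' over the grid by the trapezoid rule and normalized by the grid span.
#' 0 is perfect prediction. Grid times where G vanishes are dropped with
#' a warning.
#'
#' @param time,status observed outcome.
#' @param survProb matrix [n x length(grid)] of predicted survival
#'   probabilities S_i(t) evaluated on `grid`.
#' @param grid increasing evaluation times; defaults to event times up to
#'   the 90th percentile of follow-up (keeps the censoring weights
#'   stable).
#' @return list with `ibs`, `grid`, `brier` (pointwise scores).
#' @export
integratedBrier <- function(time, status, survProb, grid = NULL) {
    n <- length(time)
    if (is.null(grid)) {
        grid <- sort(unique(time[status == 1L]))
        grid <- grid[grid <= stats::quantile(time, 0.9)]
    }
    if (length(grid) < 2L) stop("need an evaluation grid of length >= 2")
    survProb <- as.matrix(survProb)
    stopifnot(nrow(survProb) == n, ncol(survProb) == length(grid))
    G <- censoringKM(time, status)
    Gt <- G(grid)
    ok <- Gt > 0
    if (!all(ok)) {
        warning("truncating grid where the censoring survival vanishes")
        grid <- grid[ok]; survProb <- survProb[, ok, drop = FALSE]
        Gt <- Gt[ok]
        if (length(grid) < 2L) stop("grid collapsed after truncation")
    }
    GTi <- G(time, left = TRUE)
    bs <- vapply(seq_along(grid), function(j) {
        t <- grid[j]; S <- survProb[, j]
        died <- time <= t & status == 1L
        alive <- time > t
        contrib <- numeric(n)
        contrib[died] <- S[died]^2 / GTi[died]
        contrib[alive] <- (1 - S[alive])^2 / Gt[j]
        mean(contrib)
    }, numeric(1))
    span <- diff(range(grid))
    ibs <- sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) /
        span
    list(ibs = ibs, grid = grid, brier = bs)
}

#' Composite risk score from selected genes
#'
#' Linear combination of the selected genes' expressions weighted by their
#' coefficients in a multivariable Cox proportional-hazards fit. Samples
#' are split at the median score (a sample exactly at the median goes to
#' the "low" group), and the log-rank statistic between the halves is
#' reported. A non-converging fit (e.g. collinearity) falls back to a
#' ridge-stabilized fit, flagged in the result.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param features non-empty character vector of selected genes.
#' @return list with `score` (named per-sample), `group` ("high"/"low"),
#'   `medianScore`, `coefficients`, `logrankChisq`, `logrankP`, `ridge`
#'   (TRUE when the fallback was used).
#' @export
compositeScore <- function(dataset, features) {
    if (length(features) < 1L) stop("need at least one selected feature")
    miss <- setdiff(features, featureNames(dataset))
    if (length(miss)) stop("unknown feature(s): ",
                           paste(miss, collapse = ", "))
    X <- exprMatrix(dataset)[, features, drop = FALSE]
    y <- survival::Surv(survTime(dataset), survStatus(dataset))
    ridge <- FALSE
    cf <- tryCatch({
        fit <- survival::coxph(y ~ X)
        if (any(!is.finite(fit$coefficients))) stop("non-finite coefficient")
        fit$coefficients
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(cf)) {
        ridge <- TRUE
        gfit <- glmnet::glmnet(cbind(X, 0), y, family = "cox", alpha = 0,
                               lambda = 0.01)
        cf <- as.numeric(stats::coef(gfit))[seq_len(ncol(X))]
    }
    names(cf) <- features
    score <- drop(X %*% cf)
    names(score) <- sampleNames(dataset)
    med <- stats::median(score)
    group <- ifelse(score > med, "high", "low")
    lr <- survival::survdiff(y ~ factor(group, levels = c("low", "high")))
    list(score = score, group = group, medianScore = med,
         coefficients = cf, logrankChisq = lr$chisq,
         logrankP = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE),
         ridge = ridge)
}

#' Default Cox predictor adapter for the cross-validation harness
#'
#' Fits a (ridge-stabilized when necessary) multivariable Cox model on the
#' training fold restricted to the selected features and returns held-out
#' risk scores plus Breslow-estimator survival curves.
#'
#' @param train,test [SurvivalDataset-class] folds.
#' @param features selected features (fit on the training fold).
#' @return list with `risk` (per test sample) and `survival` (list with
#'   `times` and matrix `prob` [n_test x length(times)]).
#' @export
coxPredictor <- function(train, test, features) {
    if (length(features) == 0L) {
        nt <- nSamples(test)
        times <- sort(unique(survTime(train)[survStatus(train) == 1L]))
        km <- survival::survfit(survival::Surv(survTime(train),
                                               survStatus(train)) ~ 1)
        prob <- matrix(rep(vapply(times, function(t) {
            k <- which(km$time <= t)
            if (!length(k)) 1 else km$surv[max(k)]
        }, numeric(1)), each = nt), nt)
        return(list(risk = rep(0, nt),
                    survival = list(times = times, prob = prob)))
    }
    cs <- compositeScore(train, features)
    cf <- cs$coefficients
    Xte <- exprMatrix(test)[, features, drop = FALSE]
    risk <- drop(Xte %*% cf)
    ## Breslow baseline cumulative hazard on the training fold
    lpTr <- drop(exprMatrix(train)[, features, drop = FALSE] %*% cf)
    tt <- survTime(train); ss <- survStatus(train)
    evT <- sort(unique(tt[ss == 1L]))
    H0 <- vapply(evT, function(t) {
        sum(vapply(tt[ss == 1L & tt <= t], function(td)
            1 / sum(exp(lpTr[tt >= td])), numeric(1)))
    }, numeric(1))
    prob <- outer(exp(risk), H0, function(r, h) exp(-h * r))
    list(risk = risk, survival = list(times = evT, prob = prob))
}

#' Repeated k-fold cross-validation harness
#'
#' Selection is refit within every training fold; the supplied predictor
#' adapter is fit on the training fold's selected features and evaluated
#' on the held-out fold by concordance index and (when survival curves are
#' returned) integrated Brier score. Fold selections feed the weighted
#' relative frequency table. Folds with fewer than 2 events are skipped
#' with a warning.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param selector function(dataset) returning a character vector of
#'   selected features.
#' @param predictor adapter function(train, test, features), see
#'   [coxPredictor()] (the default).
#' @param folds,repeats cross-validation geometry (default 5 x 5).
#' @param seed integer seed for fold assignment.
#' @return list with `cIndex` and `ibs` (per fold-fit, NA where
#'   unavailable), `meanCIndex`, `meanIBS`, `wrf` table, and
#'   `foldSelections`.
#' @export
cvHarness <- function(dataset, selector, predictor = coxPredictor,
                      folds = 5, repeats = 5, seed = 1) {
    n <- nSamples(dataset)
    cidx <- numeric(0); ibs <- numeric(0)
    sels <- list()
    for (r in seq_len(repeats)) {
        assign <- withSeed(deriveSeed(seed, r),
                           sample(rep_len(seq_len(folds), n)))
        for (f in seq_len(folds)) {
            teIdx <- which(assign == f)
            trIdx <- setdiff(seq_len(n), teIdx)
            tr <- survivalDataset(exprMatrix(dataset)[trIdx, , drop = FALSE],
                                  survTime(dataset)[trIdx],
                                  survStatus(dataset)[trIdx])
            te <- survivalDataset(exprMatrix(dataset)[teIdx, , drop = FALSE],
                                  survTime(dataset)[teIdx],
                                  survStatus(dataset)[teIdx])
            if (sum(survStatus(tr)) < 2L || sum(survStatus(te)) < 1L) {
                warning("fold with too few events skipped")
                next
            }
            feats <- selector(tr)
            sels[[length(sels) + 1L]] <- feats
            pred <- predictor(tr, te, feats)
            cidx <- c(cidx, concordanceIndex(survTime(te), survStatus(te),
                                             pred$risk))
            ibs <- c(ibs, if (!is.null(pred$survival) &&
                              length(pred$survival$times) >= 2L) {
                tryCatch(integratedBrier(survTime(te), survStatus(te),
                    pred$survival$prob, grid = pred$survival$times)$ibs,
                    error = function(e) NA_real_)
            } else NA_real_)
        }
    }
    list(cIndex = cidx, ibs = ibs,
         meanCIndex = mean(cidx, na.rm = TRUE),
         meanIBS = if (all(is.na(ibs))) NA_real_ else mean(ibs, na.rm = TRUE),
         wrf = wrf(sels), foldSelections = sels)
}
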