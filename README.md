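# pvglasso

Ensemble feature selection for high-dimensional right-censored survival
data, with pseudo-variable-assisted tuning.

## The problem and who this is for

In transcriptomic survival studies (thousands of genes, a few hundred
patients, heavy censoring) the goal is often to *prioritize* a small set
of genes associated with outcome rather than to squeeze out the last bit
of predictive accuracy. Single selectors are unstable: the lasso keeps
one arbitrary member of each correlated gene group, univariate Cox
screens return floods of correlated duplicates, and information-theoretic
filters ignore censoring. `pvglasso` implements a selection ensemble for
analysts who want a reproducible, low-false-discovery gene list:

1. **Aggregate** several base selectors (univariate Cox, L1-penalized
   Cox, mutual-information maximization, minimum-redundancy
   maximum-relevance) into one Borda-style ranking over the union of
   their selections.
2. **Block** the aggregated features so that within each block all
   pairwise absolute correlations exceed a threshold (default 0.75).
3. **Fit a Cox group lasso** over the blocks, minimizing
   `Q_lambda(beta) = -(1/n) log PL(beta) + lambda * sum_b s_b ||beta_b||_2`,
   where `PL` is the Breslow partial likelihood and
   `s_b = (min aggregated rank in block b) * L_b` shrinks top-ranked
   blocks least.
4. **Tune by pseudo-variables**: row-permuted copies of all features act
   as negative controls. A block's importance is its entry penalty level
   `V_b = sup{lambda : block b active}`; per permutation, a block is
   selected iff it strictly beats the strongest pseudo block, and the
   final selection keeps blocks chosen in more than `tau = 0.5` of
   `K = 50` permutations.

The package also ships the simulation designs used to characterize the
method (correlated latent-group features, Cox outcomes with calibrated
event rates) and a metric suite: FDR, sensitivity, F1, Jaccard
stability, per-feature empirical power, weighted relative selection
frequency, Harrell's C-index and the IPCW integrated Brier score.

## Worked example

Simulate one scaled scenario (n = 100 samples, G = 200 features of which
30 are causal, target event rate 0.5), then run the ensemble selection:

```r
library(pvglasso)

sc  <- simScenario(n = 100, G = 200, eventRate = 0.5)  # betas (-2, 3, -4)
sim <- simulateScenario(sc, seed = 42)
sim$dataset
#> SurvivalDataset: 100 samples x 200 features
#>   events: 52  censored: 48
#>   follow-up range: [0.02271, 6.526]

cfg <- runConfig(selectors = makeEnsemble("ensemble1"),
                 K = 20, nLambda = 50, lambdaMinRatio = 0.01, seed = 7)
res <- runSelect(sim$dataset, cfg)
res
#> SelectionResult: 1 blocks / 10 features selected (K = 20, tau = 0.5, seed = 7)
#>   features: v3_5, v3_9, v3_4, v3_1, v3_3, v3_6, v3_8, v3_2, v3_7, v3_10

selectionMetrics(selectedFeatures(res), sim$truth@causalFeatures)
#> $fdr
#> [1] 0
#> $sensitivity
#> [1] 0.3333333
#> $f1
#> [1] 0.5
```

The run selected exactly one correlation block — the ten observed copies
of the third latent causal variable (the one with the largest
coefficient, |beta_3| = 4) — with no false positives: FDR 0, and a third
of the 30 causal features recovered. At this scaled size the weaker
latent groups (|beta_1| = 2) often stay below the pseudo-variable bar;
that conservatism is the point of the tuning rule.

A shell entry point wrapping the same functions is installed at
`inst/scripts/pvglasso` (`simulate`, `select`, `benchmark` subcommands).

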