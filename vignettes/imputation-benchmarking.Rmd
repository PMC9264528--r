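---
title: "Benchmarking missing-value imputation for label-free proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation for label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqimpute)
```

## The problem

Label-free quantification (LFQ) proteomics produces protein-by-sample
intensity matrices in which a large share of cells is missing: a protein
may be detected in one run and not another because its peptides ionised
poorly, eluted with interference, or fell below the detection limit. In a
typical brain-cortex study of 45 non-human-primate samples, only a few
hundred of ~1,600 quantified proteins are observed in every sample.
Downstream analyses (age-association regressions, correlation and
clustering work) either discard incomplete proteins — losing most of the
data — or impute. `lfqimpute` provides the machinery to decide *how* to
impute: it injects missingness of known mechanism into complete data,
runs a panel of imputation algorithms, and measures both the accuracy of
the imputed values and the bias they induce in the analyses a
proteomicist actually runs.

## Missingness mechanisms

The three standard mechanisms are simulated on the log2 intensity scale:

* **MCAR** (missing completely at random): cells are deleted uniformly at
  random; exactly `round(rate * n_observed)` of them.
* **MAR** (missing at random): a randomly chosen *driver* protein is
  paired with a distinct *victim*; the victim loses its values in samples
  where the driver's standardized value exceeds a random cutpoint. High
  abundance of one protein thereby causes missingness in another —
  missingness depends only on observed values. Pairing repeats until the
  target rate is reached; the last pairing may overshoot and the realized
  rate is recorded rather than trimmed.
* **MNAR** (missing not at random): proteins are visited in random order;
  each visited protein loses all values below a random cutpoint, i.e. its
  smallest values — the classic below-detection-limit censoring where
  missingness depends on the unobserved value itself.
* **MIX** applies the three sequentially (MCAR, then MAR, then MNAR) at
  equal thirds of the target cell count; the final MNAR round is
  truncated so the global rate is hit exactly.

Cutpoints are drawn as `qnorm(pchisq(c, df))` with `c ~ chi-squared(df)`,
which places them on each protein's standardized scale and makes the
mechanism scale-free. Because the CDF of a draw from its own distribution
is uniform, this induced cutpoint is standard normal for every `df`; the
`chi2_df` knob is kept in the interface for compatibility and sensitivity
work, but under this mapping it does not change the distribution.

Two bookkeeping rules matter for interpretation. First, an injection
never removes a protein's last two observations: a protein with fewer
observations would be discarded by the presence filter in a real
pipeline, not imputed, and several imputers are undefined on it. Second,
every deleted cell is recorded with its true value and mechanism label,
so evaluation never needs a second copy of the data.

## The imputation panel

Single-imputation (SI) methods fill each missing cell with one value;
proteins are the imputation unit (rows), samples the observations:

| method | idea | key parameters |
|---|---|---|
| `zero` | missing = 0 | — |
| `mean` | protein's observed mean | — |
| `knn` | average of the k nearest proteins at that sample | `k_neighbors` (10) |
| `seqknn` | kNN in order of increasing missingness, completed proteins join the pool | `k_neighbors` |
| `svd` | iterative low-rank SVD reconstruction from a mean-filled start | `rank`, `tol` |
| `bpca` | EM for probabilistic PCA with an ARD prior; posterior-mean reconstruction | `rank`, `tol`, `max_iter` |
| `lls` | least squares on the k most-correlated proteins | `k_neighbors` |
| `grr` | ridge-penalized `lls` in the principal-component basis, penalty by GCV | `ridge_lambda` |
| `rf` | iterative random forests (median start, visit by missingness, stop when the change first rises) | `max_iter` (10), `n_trees` (100), `seed` |
| `impseq` | sequential robust (M-estimation) regression ordered by missingness | `k_neighbors` |

Multiple imputation (`mice_impute()`) runs chained equations with either
a Bayesian normal conditional (`mice_norm`) or a random-forest
terminal-node-donor conditional (`mice_rf`), producing m = 5 completed
matrices by default; downstream regressions are pooled by Rubin's rules
(`pool_rubin()`): pooled estimate = mean of estimates, total variance
`T = U + (1 + 1/m) B`, reference t distribution with the Barnard–Rubin
small-sample degrees of freedom when the complete-data df is supplied.

All imputers guarantee bit-exact pass-through of observed cells and are
deterministic given their parameters (the forest methods given `seed`).

## Evaluation statistics

* **Percent bias** of one imputed cell: `100 * |imputed - true| / |true|`;
  a cell is *correctly imputed* when its bias is strictly below 5%.
  Bias is computed on the log2 values as analysed; zero-truth cells
  (absent on the log scale in practice) are flagged and excluded from
  fraction-correct with a count reported.
* **Regression bias**: per-protein OLS of abundance on age, fit on truth
  and on imputed data; the shifts in slope and p-value are tested against
  zero with one-sample t-tests, Bonferroni-corrected for the experiment
  grid (the correction family is the number of condition cells, recorded
  in the output).
* **Cronbach's alpha** (`k/(k-1) * (1 - sum(var_i)/var(total))`, proteins
  as items, samples as observations): a summary of the inter-protein
  correlation structure. A method that systematically inflates or
  deflates alpha is distorting correlations and will mislead multivariate
  analyses. Under MI, alpha uses one completed dataset (the convention
  for non-poolable statistics).
* **Leave-one-out structural evaluation**: on a matrix with built-in
  missingness and a retained truth layer, one observed cell at a time is
  masked, the whole matrix imputed, and the imputed value compared with
  truth — accuracy measured while preserving the exact missingness
  structure of the data, stratified by the protein's missing fraction.

Protein-missingness strata are half-open `[lo, hi)` bins (so a protein
at exactly 20% falls in the 20–30% bin) with a terminal `[30%, 100%]`
overflow bin; the convention is stated in all outputs.

## The synthetic generator

The generator replaces the unavailable study data. Its defaults encode
the study conditions: 45 samples with ages uniform on 7–23 years and a
35 F : 10 M sex split; 296 proteins (the size of the fully observed set
the evaluations use) in equicorrelated blocks of 8 with within-block
correlation 0.8 on the log2 scale; per-protein baselines `N(20, 2)` log2
units; 10% of proteins carry a true age slope `N(0, 0.03)` log2 units
per year; residual SD 0.3 log2 units (~23% CV on the raw scale),
reflecting how stable relative protein abundance is across such cohorts —
stable enough that even protein-mean imputation is fairly accurate, a
property the benchmark inherits from the data it emulates.

What the generator does *not* emulate: peptide-level structure and
roll-up, intensity-dependent variance (heteroscedasticity), heavy-tailed
or skewed residuals, batch effects, and real LC-MS missingness whose
mechanism blends are unknown. Passing benchmarks on this generator shows
that a method exploits block-correlation structure at realistic
signal-to-noise; it does not certify performance on data whose
correlation structure is weaker or whose missingness is more adversarial
than the mechanisms modelled here.

`generate_structured_dataset()` additionally builds matrices whose
missingness is part of the data (for the leave-one-out evaluation), with
a 75% per-protein cap mirroring the usual "drop proteins with > 75%
missing" rule, and carries the full truth layer internally.

## Numerical choices

* **BPCA**: the latent dimension defaults to half the mean per-protein
  observation count. The EM noise update carries a posterior-uncertainty
  term of order `sigma^2 * q / mean(observations per protein)`; with `q`
  at or above the observation count the iteration is marginally unstable
  and can drift into a degenerate optimum in which every factor dies and
  the imputation collapses to the grand mean. The factor-of-two margin
  removes the drift; a guard stops the loop with a warning if the noise
  estimate ever exceeds the data variance. Convergence is declared when
  the RMS change of the imputed cells falls below `tol` times the SD of
  the observed values (a scale-free criterion); a small ridge keeps the
  loading update invertible in the noiseless limit.
* **missForest stopping**: iteration stops the first time the change in
  imputed values increases, returning the previous iterate — so `rf`
  typically runs 2–5 sweeps.
* **GRR**: ridge is applied in the SVD basis; with `ridge_lambda = NULL`
  the penalty scale is chosen by closed-form GCV on a log grid and then
  refined one Hoerl–Kennard step to per-component penalties
  `sigma^2 / alpha_j^2`. A fixed scalar `ridge_lambda` reproduces the
  exact limits: agreement with `lls` as the penalty vanishes, and the
  protein mean as it grows without bound.
* **LLS/GRR neighbours**: candidates need at least 5 samples jointly
  observed with the target; neighbour rows enter the regression from a
  row-mean-prefilled copy so a neighbour's own missing cells never
  disqualify it. When fewer than k usable neighbours exist the method
  warns and uses all of them; with none it warns and falls back to the
  protein mean.
* **mice_norm** deliberately uses the unridged normal system: with
  all-protein predictors and the protein count approaching the sample
  count, the conditional model is rank deficient and the imputation
  raises a structured "system is computationally singular" error rather
  than silently regularising — this reproduces a documented failure mode
  of chained-equations MI on wide proteomics matrices. The optional
  `predictor_top_k` filter (off by default) restores feasibility by
  restricting each conditional to the most-correlated proteins.
* **Rubin pooling with B = 0** uses the Barnard–Rubin observed-data df,
  which is slightly below the complete-data df, so the pooled p-value
  approaches (but does not exactly equal) the single-imputation p-value;
  estimate and total variance match exactly.

## Experiment design and replicate units

`accuracy_screen()`, `regression_bias()`, `alpha_bias()` and
`rf_deepdive()` reproduce the four benchmark experiments at configurable
scale; `run_experiment()` drives them from a config list or YAML file and
writes results, summaries and a manifest from which every number is
re-derivable (all per-task seeds descend from one master seed).

One statistical subtlety is worth making explicit. Within one injection
iteration the per-protein regression deltas share the injection and the
imputation, so they are not independent replicates; and a single
generated dataset has a chance nonzero mean age slope to which any
imputation attenuation couples, shifting the mean slope delta away from
zero even for a method that is unbiased over the data-generating process.
The package's bias checks therefore treat the independent synthetic
dataset as the replicate unit when testing method unbiasedness (several
datasets, several injections each, t-test over per-dataset means), while
`summarise_bias()` also offers the conventional pooled t-test over all
deltas for comparability with single-dataset designs.

Default problem sizes are desk-sized by choice — 296 x 45 matrices,
10 injection seeds per condition, 10–50 iterations for bias grids,
hundreds (not thousands) of leave-one-out draws — so a full benchmark
runs in minutes on one core; every size is a parameter and can be raised.

## Known limitations

* The MAR driver standardization uses the driver's currently observed
  values, so very late pairings standardize on fewer samples.
* `seqknn` and `impseq` require at least one complete protein to seed
  their pools and raise structured errors otherwise — consistent with how
  these methods behave on sparse real data.
* BPCA's default latent dimension trades a little structure coverage for
  stability; matrices whose signal subspace genuinely exceeds half the
  per-protein observation count need an explicit `rank` (and more data).
* MI is feasible only well below ~50 proteins per model without predictor
  selection; this is a property of the method the package reproduces, not
  a limit it removes.
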