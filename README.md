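# lfqimpute

Benchmarking missing-value imputation for label-free quantitative (LFQ)
proteomics.

LFQ experiments deliver protein × sample intensity matrices in which a
large fraction of cells is missing — often only a few hundred of more
than a thousand quantified proteins are observed in every sample. Whether
the downstream biology (age-association regressions, correlation and
clustering analyses) survives imputation depends on *which* algorithm
fills the gaps and *why* the values were missing in the first place.
`lfqimpute` is for proteomics analysts who need to make that choice on
evidence: it injects missingness of known mechanism into complete data,
imputes with a panel of algorithms, and measures both the accuracy of the
recovered values and the bias imputation induces in the analyses that
follow.

The package provides:

* **Mechanism-specific missingness injection** — MCAR (uniform deletion),
  MAR (a victim protein loses values in samples where a driver protein's
  standardized value exceeds a chi-squared-derived cutpoint), MNAR (a
  protein's values below a random cutpoint, i.e. its smallest values, are
  censored), and their sequential equal-parts mixture — with full truth
  bookkeeping of every deleted cell.
* **Ten single-imputation algorithms** implemented from their algorithmic
  descriptions: zero, protein mean, kNN, sequential kNN, iterative SVD,
  Bayesian PCA (EM with automatic relevance determination), local least
  squares (LLS), generalized ridge regression (GRR, GCV-chosen penalty),
  iterative random forest (the missForest scheme), and sequential robust
  regression (ImpSeq).
* **Multiple imputation by chained equations** (normal and random-forest
  conditionals) with Rubin's-rules pooling
  (`T = U + (1 + 1/m) B`, Barnard–Rubin degrees of freedom).
* **Evaluation statistics**: per-cell percent bias
  (`100·|imputed − true|/|true|`) and the fraction of cells imputed
  within 5%; per-protein age-regression slope and p-value shifts;
  Cronbach's-alpha shifts (items = proteins); Bonferroni-corrected
  one-sample t-tests; and a leave-one-out structural evaluation for
  matrices whose missingness is part of the data.
* **A synthetic-data generator** emulating a 45-sample primate
  prefrontal-cortex cohort (ages 7–23 years): 296 proteins in
  equicorrelated blocks (r = 0.8) on the log2 scale, a subset carrying
  true age slopes — so the whole pipeline runs without access to raw
  study data.
* **Experiment drivers** (`run_experiment()`, `accuracy_screen()`,
  `regression_bias()`, `alpha_bias()`, `rf_deepdive()`) with
  master-seeded reproducibility, tidy tibble outputs, `plot_*()`
  functions, and broom-style `tidy()`/`glance()` methods.

## Worked example

Generate a synthetic study, censor 20% of the cells with the mixture
mechanism, impute with generalized ridge regression, and ask two
questions: how close are the imputed values to truth, and did imputation
move the age-association results?

```r
library(lfqimpute)
library(dplyr)

dat <- generate_complete_dataset(synth_config(n_proteins = 120, seed = 42))
dat$matrix
#> <abundance_matrix> 120 proteins x 45 samples [log scale], 0 missing (0.0%)

inj <- inject_missing(dat$matrix,
                      missingness_spec("MIX", global_rate = 0.2, seed = 7))
inj
#> <injection_result> 1080 cells deleted (realized rate 0.2000)
#>
#>  MAR MCAR MNAR
#>  387  360  333

imp <- impute(inj$masked_matrix, method = "grr")

cells <- inj$deleted_cells
idx <- cbind(match(cells$protein, protein_ids(imp)),
             match(cells$sample, sample_ids(imp)))
fraction_correct(percent_bias(imp$values[idx], cells$true_value))
#> [1] 0.9916667

fits_true <- regress_covariate(dat$matrix, dat$metadata)
fits_imp  <- regress_covariate(imp, dat$metadata)
compare_regressions(fits_true, fits_imp) |>
  summarise(mean_delta_beta = mean(delta_beta), mean_delta_p = mean(delta_p))
#> # A tibble: 1 × 2
#>   mean_delta_beta mean_delta_p
#>             <dbl>        <dbl>
#> 1        0.000268     -0.00973
```

Reading the numbers: 99.2% of the 1,080 deleted cells were recovered
within 5% of their true log2 intensity, and across the 120 proteins the
age-regression slopes moved by 0.0003 log2 units/year on average (age
slopes in the generator have SD 0.03, so two orders of magnitude
smaller) with p-values shifting by −0.01 on average — imputation neither
destroyed the values nor distorted the downstream inference here. The
one warning flags a protein so heavily censored that GRR had no usable
neighbours and fell back to its mean, exactly the situation a presence
filter (`filter_presence()`) removes in a real pipeline.

Larger experiments run through the config interface:

```r
run_experiment(list(
  experiment = "accuracy_screen",
  synthetic = list(n_proteins = 296, n_samples = 45),
  grid = list(methods = c("grr", "lls", "bpca", "rf"),
              mechanisms = "MIX", rates = c(0.1, 0.2, 0.3),
              n_iterations = 10),
  master_seed = 1,
  output_dir = "screen_out"))
```

which writes `results.tsv`, `summary.tsv` and a `manifest.json` from
which every number can be re-derived.

## Documentation

The methods vignette (`vignettes/imputation-benchmarking.Rmd`) documents
the missingness models, the imputation algorithms and their numerical
choices, what the synthetic generator does and does not emulate, and the
statistical design of the bias experiments.
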