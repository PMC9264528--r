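#' Configuration for the synthetic LFQ generator
#'
#' Describes a synthetic label-free proteomics study: a cohort of primate
#' brain cortex samples spanning a known age range, and a set of proteins
#' whose log2 abundances fall into equicorrelated blocks, with a subset of
#' proteins carrying a true linear age effect.
#'
#' @param n_samples Number of samples (animals). Default 45.
#' @param n_proteins Number of proteins. Default 296, the size of the
#'   fully observed protein set the evaluation experiments work on.
#' @param block_sizes Integer vector of correlated-block sizes. `NULL`
#'   (default) partitions the proteins into blocks of 8 (last block takes
#'   the remainder). Use `0` correlation for independent proteins.
#' @param within_block_correlation Pairwise correlation of the stochastic
#'   component of proteins sharing a block, in `[0, 1)`. Default 0.8.
#' @param age_range Length-2 numeric, years; ages are drawn uniformly over
#'   it. Default `c(7, 23)`.
#' @param age_effect_fraction Fraction of proteins with a nonzero age
#'   slope. Default 0.1.
#' @param age_slope_sd SD of the age slopes (log2 units per year) for
#'   affected proteins. Default 0.03.
#' @param noise_sd SD of the within-protein stochastic component
#'   (log2 units). Default 0.3 (~23% CV on the raw scale), emulating the
#'   stability of relative protein abundance across brain cortex samples
#'   that makes even mean imputation fairly accurate.
#' @param baseline_mean,baseline_sd Mean and SD of the per-protein baseline
#'   log2 intensity. Defaults 20 and 2.
#' @param seed Integer seed; the same seed reproduces the same dataset
#'   bit-for-bit.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 45, n_proteins = 296,
                         block_sizes = NULL,
                         within_block_correlation = 0.8,
                         age_range = c(7, 23),
                         age_effect_fraction = 0.1,
                         age_slope_sd = 0.03,
                         noise_sd = 0.3,
                         baseline_mean = 20, baseline_sd = 2,
                         seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_proteins = as.integer(n_proteins),
              block_sizes = block_sizes,
              within_block_correlation = within_block_correlation,
              age_range = age_range,
              age_effect_fraction = age_effect_fraction,
              age_slope_sd = age_slope_sd,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  bad <- function(field, msg) {
    rlang::abort(sprintf("invalid `%s`: %s", field, msg),
                 class = "lfq_validation_error")
  }
  if (is.na(cfg$n_samples) || cfg$n_samples < 3) bad("n_samples", "need >= 3")
  if (is.na(cfg$n_proteins) || cfg$n_proteins < 1) bad("n_proteins", "need >= 1")
  r <- cfg$within_block_correlation
  if (!is.numeric(r) || r < 0 || r >= 1)
    bad("within_block_correlation", "must be in [0, 1)")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) < 0)
    bad("age_range", "must be an ordered pair")
  if (cfg$age_effect_fraction < 0 || cfg$age_effect_fraction > 1)
    bad("age_effect_fraction", "must be in [0, 1]")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (cfg$baseline_sd < 0) bad("baseline_sd", "must be >= 0")
  if (!is.null(cfg$block_sizes)) {
    bs <- cfg$block_sizes
    if (any(bs < 1)) bad("block_sizes", "all block sizes must be positive")
    if (sum(bs) > cfg$n_proteins)
      bad("block_sizes", "block sizes exceed n_proteins")
  }
  invisible(cfg)
}

# Partition protein indices into correlation blocks. Proteins not covered by
# the configured blocks become singletons (uncorrelated with everything).
resolve_blocks <- function(cfg) {
  p <- cfg$n_proteins
  bs <- cfg$block_sizes
  if (is.null(bs)) {
    full <- p %/% 8L
    bs <- rep(8L, full)
    if (p %% 8L) bs <- c(bs, p %% 8L)
  }
  left <- p - sum(bs)
  if (left > 0) bs <- c(bs, rep(1L, left))
  rep(seq_along(bs), bs)
}

#' Generate a complete synthetic LFQ dataset
#'
#' Draws a fully observed proteins x samples log2 abundance matrix plus the
#' matching sample metadata. Each protein i in block b, sample j:
#' \deqn{y_{ij} = \mu_i + \beta_i \, age_j +
#'       \sigma(\sqrt{\rho}\, f_{bj} + \sqrt{1-\rho}\, e_{ij})}
#' with block factors f and residuals e standard normal, so proteins within
#' a block have stochastic-component correlation \eqn{\rho}. A fraction of
#' proteins carries a true age slope \eqn{\beta_i \sim N(0, sd)}; ages are
#' uniform over `age_range`; sexes are assigned 35 F : 10 M proportions
#' (unused by the default analyses).
#'
#' @param config A [synth_config()].
#' @return A list with elements `matrix` (a complete [abundance_matrix()],
#'   log scale) and `metadata` (tibble `sample_id`, `age_years`, `sex`),
#'   plus attribute-style element `age_slopes` (named vector of true
#'   slopes, zero for unaffected proteins).
#' @export
generate_complete_dataset <- function(config) {
  validate_synth_config(config)
  withr::local_seed(config$seed)
  p <- config$n_proteins; n <- config$n_samples
  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  n_m <- round(n * 10 / 45)
  sex <- sample(c(rep("M", n_m), rep("F", n - n_m)))
  block <- resolve_blocks(config)
  rho <- config$within_block_correlation
  f <- matrix(stats::rnorm(max(block) * n), max(block), n)   # block factors
  e <- matrix(stats::rnorm(p * n), p, n)
  z <- sqrt(rho) * f[block, , drop = FALSE] + sqrt(1 - rho) * e
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  slopes <- numeric(p)
  n_eff <- round(p * config$age_effect_fraction)
  if (n_eff > 0) {
    idx <- sample.int(p, n_eff)
    slopes[idx] <- stats::rnorm(n_eff, 0, config$age_slope_sd)
  }
  vals <- baseline + outer(slopes, ages) + config$noise_sd * z
  rownames(vals) <- sprintf("P%04d", seq_len(p))
  colnames(vals) <- sprintf("S%02d", seq_len(n))
  names(slopes) <- rownames(vals)
  meta <- tibble::tibble(sample_id = colnames(vals), age_years = ages,
                         sex = sex)
  list(matrix = abundance_matrix(vals, scale = "log"), metadata = meta,
       age_slopes = slopes)
}

#' Generate a synthetic dataset with built-in structured missingness
#'
#' Emulates a full LFQ protein table in which missingness is part of the
#' data rather than injected for evaluation: a complete matrix is drawn as
#' in [generate_complete_dataset()], missingness is introduced per
#' `missing_profile` with a per-protein cap, and the true values of all
#' cells are retained in a hidden truth layer so leave-one-out evaluation
#' can compare imputations of real-looking data against truth.
#'
#' @param config A [synth_config()].
#' @param missing_profile A [missingness_spec()] describing mechanism and
#'   global rate of the built-in missingness.
#' @param max_protein_missing Maximum per-protein missing fraction; proteins
#'   never exceed it (the LFQ convention of discarding proteins with > 75%
#'   missing data). Default 0.75.
#' @return An [abundance_matrix()] with `NA`s, log scale, truth layer
#'   attached; the sample metadata is attached as attribute `metadata`.
#' @export
generate_structured_dataset <- function(config, missing_profile,
                                        max_protein_missing = 0.75) {
  if (missing_profile$global_rate > max_protein_missing) {
    rlang::abort(
      "requested global rate exceeds `max_protein_missing`; infeasible.",
      class = "lfq_validation_error")
  }
  full <- generate_complete_dataset(config)
  if (missing_profile$global_rate == 0) {
    out <- full$matrix
    out$truth <- full$matrix$values
  } else {
    inj <- inject_missing(full$matrix, missing_profile,
                          max_protein_missing = max_protein_missing)
    out <- inj$masked_matrix
    out$truth <- full$matrix$values
  }
  attr(out, "metadata") <- full$metadata
  attr(out, "age_slopes") <- full$age_slopes
  out
}

#' Write a synthetic dataset to a directory
#'
#' Convenience wrapper producing `matrix.tsv` and `metadata.tsv` in the
#' layout [read_protein_table()] reads back.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_lfq <- function(config, dir) {
  dat <- generate_complete_dataset(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_tsv(dat$matrix, file.path(dir, "matrix.tsv"))
  write_metadata_tsv(dat$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
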