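# Experiment orchestration: the four benchmark experiments are grids over
# mechanism x rate x method (x protein count), each cell run for several
# independently seeded iterations on synthetic complete data.

derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(2^31 - 2, n))
}

#' Imputation accuracy screen
#'
#' The core accuracy experiment: inject missingness into a complete
#' matrix, impute with each method, and record the fraction of deleted
#' cells recovered within the percent-bias threshold, overall and by
#' protein-missingness stratum.
#'
#' @param complete A complete [abundance_matrix()].
#' @param methods Character vector of [impute()] methods.
#' @param mechanisms Injection mechanisms, default `"MIX"`.
#' @param rates Global missingness rates, default `c(0.1, 0.2, 0.3)`.
#' @param n_iterations Injection repeats per condition, default 10.
#' @param master_seed Seed from which all per-task seeds derive.
#' @param chi2_df Cutpoint degrees of freedom.
#' @param threshold Percent-bias correctness cutoff, default 5.
#' @param strata Protein-missingness bin cut points.
#' @param ... Passed to [impute()].
#' @return A tibble with one row per (iteration, mechanism, rate, method,
#'   stratum) plus an `"overall"` stratum row: `n_cells`, `n_correct`,
#'   `fraction_correct`, `mean_pct_bias`, `n_zero_truth`.
#' @export
accuracy_screen <- function(complete, methods,
                            mechanisms = "MIX", rates = c(0.1, 0.2, 0.3),
                            n_iterations = 10L, master_seed = 1L,
                            chi2_df = 1L, threshold = 5,
                            strata = c(0, .05, .10, .20, .30), ...) {
  grid <- tidyr::expand_grid(iteration = seq_len(n_iterations),
                             mechanism = mechanisms, rate = rates)
  seeds <- derive_seeds(master_seed, nrow(grid) + 1)
  out <- purrr::pmap_dfr(
    cbind(grid, seed = seeds[-1]),
    function(iteration, mechanism, rate, seed) {
      spec <- missingness_spec(mechanism, rate, chi2_df = chi2_df,
                               seed = seed)
      inj <- inject_missing(complete, spec)
      strat <- stratify_protein_missingness(inj, bins = strata)
      cells <- dplyr::left_join(inj$deleted_cells,
                                dplyr::select(strat, "protein", "bin"),
                                by = "protein")
      purrr::map_dfr(methods, function(method) {
        imp <- impute(inj$masked_matrix, method = method, seed = seed, ...)
        idx <- cbind(match(cells$protein, rownames(imp$values)),
                     match(cells$sample, colnames(imp$values)))
        bias <- percent_bias(imp$values[idx], cells$true_value)
        per_bin <- tibble::tibble(bin = as.character(cells$bin),
                                  bias = bias) |>
          dplyr::bind_rows(tibble::tibble(bin = "overall", bias = bias)) |>
          dplyr::group_by(.data$bin) |>
          dplyr::summarise(
            n_cells = dplyr::n(),
            n_correct = sum(is.finite(.data$bias) & .data$bias < threshold),
            fraction_correct = .data$n_correct / .data$n_cells,
            mean_pct_bias = mean(.data$bias[is.finite(.data$bias)]),
            n_zero_truth = sum(!is.finite(.data$bias)),
            .groups = "drop")
        dplyr::mutate(per_bin, iteration = iteration, mechanism = mechanism,
                      rate = rate, method = method, seed = seed,
                      .before = 1)
      })
    })
  dplyr::rename(out, stratum = "bin")
}

# run one (mechanism, rate, n_proteins, iteration) regression-bias task for
# all methods; returns per-protein delta rows, or failure rows
regression_bias_task <- function(complete, meta, mechanism, rate,
                                 n_proteins, methods, seed, chi2_df,
                                 mi_m, maxit, predictor_top_k, ...) {
  spec <- missingness_spec(mechanism, rate, chi2_df = chi2_df, seed = seed)
  inj <- inject_missing(complete, spec)
  keep <- withr::with_seed(seed + 1L,
                           sample(protein_ids(complete), n_proteins))
  sub_masked <- subset_abundance(inj$masked_matrix, proteins = keep)
  sub_truth <- subset_abundance(complete, proteins = keep)
  truth_fits <- regress_covariate(sub_truth, meta)
  purrr::map_dfr(methods, function(method) {
    res <- tryCatch({
      fits <- if (method %in% c("mice_norm", "mice_rf")) {
        mi <- mice_impute(sub_masked, method = method,
                          n_imputations = mi_m, maxit = maxit, seed = seed,
                          predictor_top_k = predictor_top_k)
        pool_regressions(mi, meta)
      } else {
        regress_covariate(impute(sub_masked, method = method, seed = seed,
                                 ...), meta)
      }
      dplyr::mutate(compare_regressions(truth_fits, fits),
                    status = "ok")
    }, lfq_error = function(e) {
      tibble::tibble(protein = NA_character_, status = paste0(
        "failed: ", if (inherits(e, "lfq_singular_error")) "singular"
                    else conditionMessage(e)))
    })
    dplyr::mutate(res, method = method, .before = 1)
  })
}

#' Regression-bias experiment
#'
#' Measures whether imputation shifts downstream age-association results:
#' per iteration, missingness is injected into the complete matrix, a
#' random protein subset is sampled (after injection, so the subset carries
#' realistic missingness), the subset is imputed (single methods directly;
#' MICE methods through Rubin's-rules pooling), and per-protein slope and
#' p-value differences against the complete-data fits are recorded.
#' MI failures on near-singular systems are recorded as
#' `"failed: singular"` rows, never silent gaps.
#'
#' @inheritParams accuracy_screen
#' @param meta Sample metadata (`sample_id`, `age_years`).
#' @param n_proteins_list Protein subset sizes, default `c(10, 20, 30, 40)`.
#' @param rates Global rates, default `c(0.1, 0.2)`.
#' @param mi_m,maxit Imputation count and cycles for the MICE methods.
#' @param predictor_top_k Optional MICE predictor filter.
#' @return Tibble of per-protein `delta_beta` / `delta_p` rows tagged by
#'   condition; summarise with [summarise_bias()].
#' @export
regression_bias <- function(complete, meta, methods,
                            mechanisms = "MIX", rates = c(0.1, 0.2),
                            n_proteins_list = c(10L, 20L, 30L, 40L),
                            n_iterations = 10L, master_seed = 1L,
                            chi2_df = 1L, mi_m = 5L, maxit = 5L,
                            predictor_top_k = NULL, ...) {
  grid <- tidyr::expand_grid(iteration = seq_len(n_iterations),
                             mechanism = mechanisms, rate = rates,
                             n_proteins = n_proteins_list)
  seeds <- derive_seeds(master_seed, nrow(grid))
  purrr::pmap_dfr(
    cbind(grid, seed = seeds),
    function(iteration, mechanism, rate, n_proteins, seed) {
      rows <- regression_bias_task(complete, meta, mechanism, rate,
                                   n_proteins, methods, seed, chi2_df,
                                   mi_m, maxit, predictor_top_k, ...)
      dplyr::mutate(rows, iteration = iteration, mechanism = mechanism,
                    rate = rate, n_proteins = n_proteins, seed = seed,
                    .before = 1)
    })
}

#' Cronbach's-alpha bias experiment
#'
#' Per iteration: sample a random protein subset from the complete data,
#' record its Cronbach's alpha, inject missingness into the subset, impute
#' (MICE methods contribute their first completed dataset, the convention
#' for alpha under MI), and record the imputed-minus-true alpha shift.
#'
#' @inheritParams regression_bias
#' @param n_proteins_list Subset sizes, default `c(10, 20, 30)`.
#' @return Tibble with one row per (condition, iteration, method):
#'   `true_alpha`, `imputed_alpha`, `delta_alpha`, `status`.
#' @export
alpha_bias <- function(complete, methods,
                       mechanisms = "MIX", rates = c(0.1, 0.2),
                       n_proteins_list = c(10L, 20L, 30L),
                       n_iterations = 10L, master_seed = 1L,
                       chi2_df = 1L, mi_m = 5L, maxit = 5L,
                       predictor_top_k = NULL, ...) {
  grid <- tidyr::expand_grid(iteration = seq_len(n_iterations),
                             mechanism = mechanisms, rate = rates,
                             n_proteins = n_proteins_list)
  seeds <- derive_seeds(master_seed, nrow(grid))
  purrr::pmap_dfr(
    cbind(grid, seed = seeds),
    function(iteration, mechanism, rate, n_proteins, seed) {
      keep <- withr::with_seed(seed,
                               sample(protein_ids(complete), n_proteins))
      sub <- subset_abundance(complete, proteins = keep)
      true_alpha <- cronbach_alpha(sub)
      spec <- missingness_spec(mechanism, rate, chi2_df = chi2_df,
                               seed = seed)
      inj <- inject_missing(sub, spec)
      purrr::map_dfr(methods, function(method) {
        res <- tryCatch({
          comp <- if (method %in% c("mice_norm", "mice_rf")) {
            mice_impute(inj$masked_matrix, method = method,
                        n_imputations = mi_m, maxit = maxit, seed = seed,
                        predictor_top_k = predictor_top_k)$imputations[[1]]
          } else {
            impute(inj$masked_matrix, method = method, seed = seed, ...)
          }
          ia <- cronbach_alpha(comp)
          tibble::tibble(true_alpha = true_alpha, imputed_alpha = ia,
                         delta_alpha = ia - true_alpha, status = "ok")
        }, lfq_error = function(e) {
          tibble::tibble(true_alpha = true_alpha,
                         imputed_alpha = NA_real_, delta_alpha = NA_real_,
                         status = paste0("failed: ",
                           if (inherits(e, "lfq_singular_error")) "singular"
                           else conditionMessage(e)))
        })
        dplyr::mutate(res, iteration = iteration, mechanism = mechanism,
                      rate = rate, n_proteins = n_proteins, method = method,
                      seed = seed, .before = 1)
      })
    })
}

#' Bonferroni-corrected bias summary of an experiment table
#'
#' Applies [bias_ttest()] to each condition cell of a [regression_bias()]
#' or [alpha_bias()] table; the Bonferroni family size is the number of
#' condition cells tested (recorded in the output).
#'
#' @param results Experiment tibble.
#' @param delta Column to test (`"delta_beta"`, `"delta_p"` or
#'   `"delta_alpha"`).
#' @param alpha_level Nominal level, default 0.05.
#' @return One row per (method, mechanism, rate, n_proteins) cell.
#' @export
summarise_bias <- function(results, delta = "delta_beta",
                           alpha_level = 0.05) {
  ok <- dplyr::filter(results, .data$status == "ok",
                      is.finite(.data[[delta]]))
  cells <- dplyr::group_by(ok, .data$method, .data$mechanism, .data$rate,
                           .data$n_proteins)
  n_tests <- dplyr::n_groups(cells)
  dplyr::reframe(cells, bias_ttest(.data[[delta]],
                                   alpha_level = alpha_level,
                                   n_tests = n_tests))
}

#' Random-forest deep-dive experiment
#'
#' Builds (or accepts) a structured dataset with built-in missingness and
#' runs the leave-one-out structural evaluation with the random-forest
#' imputer, returning the per-cell records and the per-stratum summary.
#'
#' @param structured An [abundance_matrix()] with built-in missingness
#'   (e.g. from [generate_structured_dataset()]).
#' @param n_iter Held-out cells, default 200.
#' @param master_seed Seed.
#' @param method Imputation method, default `"rf"`.
#' @param ... Passed to [impute()].
#' @return List with `records` and `summary` tibbles.
#' @export
rf_deepdive <- function(structured, n_iter = 200L, master_seed = 1L,
                        method = "rf", ...) {
  records <- loo_structural_eval(structured, method = method,
                                 n_iter = n_iter, seed = master_seed, ...)
  list(records = records, summary = summarise_loo(records))
}

#' Run a configured experiment end-to-end
#'
#' Reads an experiment configuration (a list, or a YAML file via
#' [read_experiment_config()]), generates the synthetic dataset, runs the
#' named experiment, and writes `results.tsv`, a summary table where the
#' experiment defines one, and `manifest.json` (configuration plus derived
#' seeds) into `output_dir`. Re-running the same configuration reproduces
#' identical tables.
#'
#' @param config Named list: `experiment` (one of `"accuracy_screen"`,
#'   `"regression_bias"`, `"alpha_bias"`, `"rf_deepdive"`), `synthetic`
#'   (arguments for [synth_config()]), `grid` (arguments for the
#'   experiment function), `master_seed`, `output_dir` (optional; nothing
#'   is written when absent).
#' @return List with `results` (tibble), `summary` (tibble or `NULL`) and
#'   `manifest`.
#' @export
run_experiment <- function(config) {
  exp <- match.arg(config$experiment,
                   c("accuracy_screen", "regression_bias", "alpha_bias",
                     "rf_deepdive"))
  master_seed <- config$master_seed %||% 1L
  scfg <- do.call(synth_config,
                  c(config$synthetic %||% list(),
                    if (is.null(config$synthetic$seed))
                      list(seed = master_seed)))
  grid <- config$grid %||% list()
  if (exp == "rf_deepdive") {
    profile <- missingness_spec(
      mechanism = grid$mechanism %||% "MIX",
      global_rate = grid$builtin_rate %||% 0.3,
      seed = master_seed)
    structured <- generate_structured_dataset(
      scfg, profile, max_protein_missing = grid$max_protein_missing %||% 0.75)
    res <- rf_deepdive(structured, n_iter = grid$n_iter %||% 200L,
                       master_seed = master_seed,
                       method = grid$method %||% "rf")
    results <- res$records
    summary <- res$summary
  } else {
    dat <- generate_complete_dataset(scfg)
    args <- c(list(complete = dat$matrix), grid,
              list(master_seed = master_seed))
    results <- switch(exp,
      accuracy_screen = do.call(accuracy_screen, args),
      regression_bias = do.call(regression_bias,
                                c(args, list(meta = dat$metadata))),
      alpha_bias = do.call(alpha_bias, args))
    summary <- switch(exp,
      accuracy_screen = results |>
        dplyr::group_by(.data$method, .data$mechanism, .data$rate,
                        .data$stratum) |>
        dplyr::summarise(fraction_correct =
                           sum(.data$n_correct) / sum(.data$n_cells),
                         n_cells = sum(.data$n_cells), .groups = "drop"),
      regression_bias = summarise_bias(results, "delta_beta"),
      alpha_bias = summarise_bias(results, "delta_alpha"))
  }
  manifest <- list(experiment = exp, master_seed = master_seed,
                   synthetic = unclass(scfg), grid = grid,
                   package_version = as.character(utils::packageVersion(
                     "lfqimpute")))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(results, file.path(config$output_dir, "results.tsv"))
    if (!is.null(summary)) {
      readr::write_tsv(summary, file.path(config$output_dir, "summary.tsv"))
    }
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(results = results, summary = summary, manifest = manifest)
}

#' Read an experiment configuration file
#'
#' @param path YAML file with the fields described in [run_experiment()].
#' @return A named list.
#' @export
read_experiment_config <- function(path) {
  yaml::read_yaml(path)
}
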