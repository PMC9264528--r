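#' Percent bias of an imputed value
#'
#' The absolute percent difference between an imputed value and the truth:
#' `100 * |imputed - true| / |true|`. Truths with magnitude below `eps`
#' yield `Inf` (percent bias is undefined at a zero truth); callers count
#' and exclude such cells.
#'
#' @param imputed,true Numeric vectors (recycled).
#' @param eps Magnitude below which the truth counts as zero. Default 1e-12.
#' @return Numeric vector of percent biases (>= 0).
#' @export
percent_bias <- function(imputed, true, eps = 1e-12) {
  out <- 100 * abs(imputed - true) / abs(true)
  out[abs(true) < eps] <- Inf
  out
}

#' Fraction of correctly imputed values
#'
#' The proportion of percent biases strictly below `threshold` (default
#' 5%): the "correctly imputed" criterion. Non-finite biases (zero-truth
#' cells) never count as correct.
#'
#' @param biases Numeric vector of percent biases; must be non-empty.
#' @param threshold Percent cutoff, default 5.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_correct <- function(biases, threshold = 5) {
  if (!length(biases)) {
    rlang::abort("fraction_correct of an empty bias set is undefined.",
                 class = "lfq_validation_error")
  }
  mean(is.finite(biases) & biases < threshold)
}

#' Per-protein regression of abundance on a covariate
#'
#' Ordinary least squares of each protein's abundance on age (or another
#' numeric sample covariate), computed on a complete matrix. The slope,
#' its standard error and the two-sided t-test p-value are returned per
#' protein; this is the downstream analysis whose distortion by imputation
#' the bias evaluations measure.
#'
#' @param m A complete [abundance_matrix()].
#' @param meta Sample metadata with `sample_id` and the covariate column.
#' @param covariate Column name, default `"age_years"`.
#' @return A tibble `protein`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `df`.
#' @export
regress_covariate <- function(m, meta, covariate = "age_years") {
  v <- m$values
  if (anyNA(v)) {
    rlang::abort("regression requires a complete (imputed) matrix.",
                 class = "lfq_validation_error")
  }
  if (ncol(v) < 3) {
    rlang::abort("need >= 3 samples for a regression.",
                 class = "lfq_validation_error")
  }
  meta <- check_metadata(m, meta)
  x <- meta[[covariate]]
  if (stats::var(x) == 0) {
    rlang::abort("covariate has zero variance.",
                 class = "lfq_validation_error")
  }
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(v, 1, rowMeans(v))
  beta <- drop(yc %*% xc) / sxx
  resid <- yc - outer(beta, xc)
  df <- n - 2
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(protein = rownames(v), estimate = unname(beta),
                 std_error = unname(se), statistic = unname(tstat),
                 p_value = unname(p), df = df)
}

#' Pooled regression across multiple imputations
#'
#' Runs [regress_covariate()] on each completed dataset of an `mi_result`
#' and pools the per-protein slopes with [pool_rubin()] (Barnard-Rubin df
#' from the complete-data df n - 2).
#'
#' @param mi An `mi_result`.
#' @param meta Sample metadata.
#' @param covariate Covariate column name.
#' @return A tibble like [regress_covariate()]'s, plus `within_var` and
#'   `between_var`.
#' @export
pool_regressions <- function(mi, meta, covariate = "age_years") {
  fits <- lapply(mi$imputations, regress_covariate, meta = meta,
                 covariate = covariate)
  n <- ncol(mi$imputations[[1]]$values)
  purrr::map_dfr(seq_len(nrow(fits[[1]])), function(i) {
    est <- vapply(fits, function(f) f$estimate[i], 0)
    se <- vapply(fits, function(f) f$std_error[i], 0)
    p <- pool_rubin(est, se, df_complete = n - 2)
    tibble::tibble(protein = fits[[1]]$protein[i], estimate = p$estimate,
                   std_error = p$std_error, statistic = p$statistic,
                   p_value = p$p_value, df = p$df,
                   within_var = p$within_var, between_var = p$between_var)
  })
}

#' Compare regression fits on truth versus imputed data
#'
#' Pairs two per-protein fit tables (from [regress_covariate()] or
#' [pool_regressions()]) and records, per protein, the coefficient and
#' p-value shifts induced by imputation (imputed minus true).
#'
#' @param truth_fits,imputed_fits Fit tibbles sharing the same proteins.
#' @return A tibble `protein`, `true_beta`, `imputed_beta`, `delta_beta`,
#'   `true_p`, `imputed_p`, `delta_p`.
#' @export
compare_regressions <- function(truth_fits, imputed_fits) {
  j <- dplyr::inner_join(
    dplyr::select(truth_fits, "protein", true_beta = "estimate",
                  true_p = "p_value"),
    dplyr::select(imputed_fits, "protein", imputed_beta = "estimate",
                  imputed_p = "p_value"),
    by = "protein")
  dplyr::mutate(j, delta_beta = .data$imputed_beta - .data$true_beta,
                delta_p = .data$imputed_p - .data$true_p)
}

#' Cronbach's alpha of a protein set
#'
#' Internal-consistency coefficient with proteins as items and samples as
#' observations:
#' \deqn{\alpha = \frac{k}{k-1}\Bigl(1 -
#'   \frac{\sum_i \mathrm{var}(y_i)}{\mathrm{var}(\sum_i y_i)}\Bigr)}
#' using the sample-variance convention throughout. Because alpha moves
#' with the average inter-item correlation, imputation that inflates or
#' deflates inter-protein correlations shifts alpha away from its
#' complete-data value.
#'
#' @param m A complete [abundance_matrix()] with >= 2 proteins.
#' @return A single numeric (<= 1).
#' @export
cronbach_alpha <- function(m) {
  v <- m$values
  k <- nrow(v)
  if (k < 2) {
    rlang::abort("Cronbach's alpha needs >= 2 proteins.",
                 class = "lfq_validation_error")
  }
  if (anyNA(v)) {
    rlang::abort("Cronbach's alpha requires complete data.",
                 class = "lfq_validation_error")
  }
  item_vars <- apply(v, 1, stats::var)
  total_var <- stats::var(colSums(v))
  if (total_var == 0) {
    rlang::abort("zero total-score variance.", class = "lfq_validation_error")
  }
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' One-sample t-test on imputation-induced deltas
#'
#' Tests whether the mean of a set of differences (imputed minus true
#' coefficients, p-values, or alphas) departs from zero, with Bonferroni
#' adjustment for the experiment-grid family size.
#'
#' @param deltas Numeric vector (>= 2 values).
#' @param alpha_level Nominal level before correction, default 0.05.
#' @param n_tests Bonferroni family size (number of cells in the
#'   experiment grid), default 1.
#' @return One-row tibble: `mean_delta`, `t`, `p_value`,
#'   `p_bonferroni`, `significant` (at `alpha_level`),
#'   `significant_001` (at 0.001), `n`, `n_tests`.
#' @export
bias_ttest <- function(deltas, alpha_level = 0.05, n_tests = 1L) {
  if (length(deltas) < 2) {
    rlang::abort("need >= 2 deltas for a t-test.",
                 class = "lfq_validation_error")
  }
  if (stats::sd(deltas) == 0) {
    p <- if (mean(deltas) == 0) 1 else 0
    tt <- list(statistic = if (p == 1) 0 else Inf * sign(mean(deltas)),
               p.value = p)
  } else {
    tt <- stats::t.test(deltas, mu = 0)
  }
  p_bonf <- min(1, tt$p.value * n_tests)
  tibble::tibble(mean_delta = mean(deltas),
                 t = unname(tt$statistic), p_value = tt$p.value,
                 p_bonferroni = p_bonf,
                 significant = p_bonf < alpha_level,
                 significant_001 = p_bonf < 0.001,
                 n = length(deltas), n_tests = as.integer(n_tests))
}

#' Leave-one-out structural evaluation
#'
#' For a matrix with built-in missingness and a truth layer (from
#' [generate_structured_dataset()]), repeatedly masks one observed cell at
#' a time, imputes the whole matrix (including all genuinely missing
#' cells), records the imputed value against truth along with the
#' protein's missing fraction, and restores the cell. This evaluates an
#' imputer while preserving the exact missingness structure of the data.
#'
#' @param m An [abundance_matrix()] with missing cells; a truth layer is
#'   used when present, otherwise the observed values serve as truth.
#' @param method An [impute()] method name.
#' @param n_iter Number of cells to hold out (without replacement).
#' @param seed Integer seed (cell sampling and stochastic imputers).
#' @param ... Passed to [impute()].
#' @return A tibble: `iteration`, `protein`, `sample`, `true_value`,
#'   `imputed_value`, `pct_bias`, `protein_missing_fraction` (the
#'   fraction missing in that protein once the cell is held out).
#' @export
loo_structural_eval <- function(m, method, n_iter = 10000L, seed = 1L, ...) {
  v <- m$values
  obs <- which(!is.na(v))
  if (n_iter > length(obs)) {
    rlang::abort(sprintf("n_iter (%d) exceeds observed cells (%d).",
                         n_iter, length(obs)),
                 class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  cells <- sample(obs, n_iter)
  p <- nrow(v)
  rows <- (cells - 1L) %% p + 1L
  cols <- (cells - 1L) %/% p + 1L
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    w <- m
    truth <- v[cells[it]]
    w$values[rows[it], cols[it]] <- NA
    imp <- impute(w, method = method,
                  seed = sample.int(.Machine$integer.max, 1L), ...)
    est <- imp$values[rows[it], cols[it]]
    out[[it]] <- tibble::tibble(
      iteration = it, protein = rownames(v)[rows[it]],
      sample = colnames(v)[cols[it]], true_value = truth,
      imputed_value = est, pct_bias = percent_bias(est, truth),
      protein_missing_fraction = mean(is.na(w$values[rows[it], ])))
  }
  dplyr::bind_rows(out)
}

#' Summarise leave-one-out records by protein-missingness stratum
#'
#' @param records Output of [loo_structural_eval()].
#' @param bins Stratum cut points (fractions), default deciles to 80%.
#' @param threshold Percent-bias correctness cutoff, default 5.
#' @return A tibble per stratum: n, mean/median percent bias, fraction
#'   correct.
#' @export
summarise_loo <- function(records, bins = seq(0, 0.8, by = 0.1),
                          threshold = 5) {
  edges <- c(bins, 1 + 1e-9)
  labs <- c(sprintf("[%g%%,%g%%)", 100 * bins[-length(bins)], 100 * bins[-1]),
            sprintf("[%g%%,100%%]", 100 * bins[length(bins)]))
  records |>
    dplyr::mutate(stratum = cut(.data$protein_missing_fraction,
                                breaks = edges, labels = labs,
                                right = FALSE, include.lowest = TRUE)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct_bias = mean(.data$pct_bias[is.finite(.data$pct_bias)]),
      median_pct_bias = stats::median(.data$pct_bias[is.finite(.data$pct_bias)]),
      fraction_correct = fraction_correct(.data$pct_bias, threshold),
      .groups = "drop")
}
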