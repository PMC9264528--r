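#' Specify a missingness injection
#'
#' A mechanism, a target global missing rate, the chi-squared
#' degrees of freedom used for cutpoint draws, and a seed fully determine
#' an injection.
#'
#' Mechanisms follow the standard taxonomy: `MCAR` removes cells uniformly
#' at random; `MAR` removes cells of a "victim" protein in samples where a
#' distinct "driver" protein is high (missingness depends on observed
#' values of another variable); `MNAR` removes a protein's lowest values
#' below a sampled cutpoint (missingness depends on the unobserved value
#' itself, as with below-detection-limit censoring); `MIX` layers MCAR,
#' MAR and MNAR sequentially at equal proportions.
#'
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR"`, `"MIX"`.
#' @param global_rate Target global missing fraction, in `[0, 0.7]`.
#' @param chi2_df Degrees of freedom of the chi-squared cutpoint draw
#'   (default 1). Cutpoints are mapped onto the standardized intensity
#'   scale via the probability integral transform.
#' @param seed Integer seed; the same spec reproduces the same injection.
#' @return A list of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR", "MIX"),
                             global_rate, chi2_df = 1L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(global_rate) || global_rate < 0 || global_rate > 0.7) {
    rlang::abort("`global_rate` must be in [0, 0.7].",
                 class = "lfq_validation_error")
  }
  if (chi2_df < 1) {
    rlang::abort("`chi2_df` must be a positive integer.",
                 class = "lfq_validation_error")
  }
  structure(list(mechanism = mechanism, global_rate = global_rate,
                 chi2_df = as.integer(chi2_df), seed = as.integer(seed)),
            class = "missingness_spec")
}

# Cutpoint on the standardized (z) scale: draw c ~ chi2(df) and map through
# its own CDF to a standard-normal quantile. Scale-free by construction.
draw_cutpoint <- function(df) {
  stats::qnorm(stats::pchisq(stats::rchisq(1L, df), df))
}

new_injection_result <- function(masked, deleted, total_cells) {
  per_protein <- table(factor(deleted$protein, levels = rownames(masked$values)))
  structure(list(
    masked_matrix = masked,
    deleted_cells = deleted,
    realized_global_rate = nrow(deleted) / total_cells,
    per_protein_rates = as.numeric(per_protein) / ncol(masked$values)),
    class = "injection_result")
}

#' @export
print.injection_result <- function(x, ...) {
  cat(sprintf("<injection_result> %d cells deleted (realized rate %.4f)\n",
              nrow(x$deleted_cells), x$realized_global_rate))
  print(table(x$deleted_cells$mechanism))
  invisible(x)
}

# ---- internal workers: operate on a values matrix, RNG already seeded ----

# permutation-walk MCAR honouring a per-protein quota
.mcar_cells <- function(v, n_remove, quota) {
  obs <- which(!is.na(v))
  if (n_remove == 0 || !length(obs)) return(integer(0))
  ord <- sample(obs)
  rows <- (ord - 1L) %% nrow(v) + 1L
  taken <- integer(0)
  used <- integer(nrow(v))
  for (i in seq_along(ord)) {
    r <- rows[i]
    if (used[r] < quota[r]) {
      taken <- c(taken, ord[i])
      used[r] <- used[r] + 1L
      if (length(taken) == n_remove) break
    }
  }
  if (length(taken) < n_remove) {
    rlang::abort("MCAR target rate infeasible under the per-protein cap.",
                 class = "lfq_injection_error")
  }
  taken
}

# MAR: repeated driver/victim pairings; removes victim cells where the
# driver's standardized value exceeds a chi-squared-derived cutpoint.
# Stops once >= n_remove cells are gone (may overshoot; caller records it).
.mar_cells <- function(v, n_remove, quota, chi2_df) {
  p <- nrow(v)
  if (p < 2) {
    rlang::abort("MAR needs at least 2 proteins.",
                 class = "lfq_injection_error")
  }
  removed <- tibble::tibble(cell = integer(0), driver = integer(0),
                            cutpoint = numeric(0), driver_z = numeric(0))
  used <- integer(p)
  attempts <- 0L
  max_attempts <- 200L * p
  cur <- v
  while (nrow(removed) < n_remove && attempts < max_attempts) {
    attempts <- attempts + 1L
    pair <- sample.int(p, 2L)
    drv <- pair[1]; vic <- pair[2]
    c0 <- draw_cutpoint(chi2_df)
    dvals <- cur[drv, ]
    mu <- mean(dvals, na.rm = TRUE); sdv <- stats::sd(dvals, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    z <- (dvals - mu) / sdv
    hit <- which(!is.na(z) & z > c0 & !is.na(cur[vic, ]))
    if (!length(hit)) next
    room <- quota[vic] - used[vic]
    if (room <= 0) next
    if (length(hit) > room) {
      hit <- hit[order(z[hit], decreasing = TRUE)][seq_len(room)]
    }
    cells <- (hit - 1L) * p + vic
    cur[vic, hit] <- NA
    used[vic] <- used[vic] + length(hit)
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      cell = cells, driver = drv, cutpoint = c0, driver_z = z[hit]))
  }
  if (nrow(removed) < n_remove) {
    rlang::abort("MAR target rate not reachable (pairings exhausted).",
                 class = "lfq_injection_error")
  }
  removed
}

# MNAR: random protein order; per protein draw a cutpoint and delete the
# observed values below it (bottom order statistics), truncating the final
# protein so exactly n_remove cells go.
.mnar_cells <- function(v, n_remove, quota, chi2_df) {
  p <- nrow(v)
  taken <- integer(0)
  used <- integer(p)
  cur <- v
  passes <- 0L
  while (length(taken) < n_remove && passes < 100L) {
    passes <- passes + 1L
    progressed <- FALSE
    for (i in sample.int(p)) {
      if (length(taken) >= n_remove) break
      room <- quota[i] - used[i]
      if (room <= 0) next
      vals <- cur[i, ]
      obs <- which(!is.na(vals))
      if (length(obs) < 2) next
      c0 <- draw_cutpoint(chi2_df)
      mu <- mean(vals[obs]); sdv <- stats::sd(vals[obs])
      if (sdv == 0) next
      below <- obs[(vals[obs] - mu) / sdv < c0]
      if (!length(below)) next
      k <- min(length(below), room, n_remove - length(taken))
      pick <- below[order(vals[below])][seq_len(k)]   # smallest first
      cur[i, pick] <- NA
      used[i] <- used[i] + k
      taken <- c(taken, (pick - 1L) * p + i)
      progressed <- TRUE
    }
    if (!progressed && length(taken) < n_remove) {
      rlang::abort("MNAR target rate infeasible (no removable values left).",
                   class = "lfq_injection_error")
    }
  }
  if (length(taken) < n_remove) {
    rlang::abort("MNAR target rate not reached within the pass limit.",
                 class = "lfq_injection_error")
  }
  taken
}

cells_to_tibble <- function(v, cells, mechanism, driver = NA_character_,
                            cutpoint = NA_real_, driver_z = NA_real_) {
  p <- nrow(v)
  rows <- (cells - 1L) %% p + 1L
  cols <- (cells - 1L) %/% p + 1L
  rec <- function(x) if (length(x) == 1) rep(x, length(cells)) else x
  tibble::tibble(protein = rownames(v)[rows], sample = colnames(v)[cols],
                 true_value = v[cells], mechanism = mechanism,
                 driver = rec(driver), cutpoint = rec(cutpoint),
                 driver_z = rec(driver_z))
}

apply_deletion <- function(m, deleted) {
  v <- m$values
  idx <- cbind(match(deleted$protein, rownames(v)),
               match(deleted$sample, colnames(v)))
  v[idx] <- NA
  abundance_matrix(v, scale = m$scale, truth = m$truth)
}

# Deletable cells left per protein under the cap. Injections never remove a
# protein's last two observations: a fully (or all-but-one) deleted protein
# would be discarded by the presence filter in a real pipeline, not imputed.
protein_quota <- function(v, max_protein_missing) {
  d <- ncol(v)
  cap <- min(floor(max_protein_missing * d), d - 2L)
  pmax(0L, cap - rowSums(is.na(v)))
}

# ---- public mechanism functions ----

#' Inject MCAR missingness
#'
#' Removes exactly `round(rate * n_observed)` observed cells uniformly at
#' random without replacement.
#'
#' @param m An [abundance_matrix()].
#' @param rate Fraction of observed cells to remove, in `[0, 1)`.
#' @param seed Integer seed.
#' @param max_protein_missing Per-protein cap on the missing fraction
#'   (default 1: no cap).
#' @return An `injection_result`: the masked matrix, a tibble of deleted
#'   cells with their true values, and realized global / per-protein rates.
#' @export
introduce_mcar <- function(m, rate, seed = 1L, max_protein_missing = 1) {
  if (rate < 0 || rate >= 1) {
    rlang::abort("`rate` must be in [0, 1).", class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  v <- m$values
  n_obs <- sum(!is.na(v))
  cells <- .mcar_cells(v, round(rate * n_obs),
                       protein_quota(v, max_protein_missing))
  deleted <- cells_to_tibble(v, cells, "MCAR")
  new_injection_result(apply_deletion(m, deleted), deleted, length(v))
}

#' Inject MAR missingness
#'
#' Repeatedly pairs a random driver protein with a distinct victim protein
#' and removes the victim's values in samples where the driver's
#' standardized value exceeds a chi-squared-derived cutpoint, until the
#' target global rate is reached. High abundance in one protein thereby
#' causes missingness in another. The last pairing may overshoot the
#' target; the realized rate is recorded, not trimmed.
#'
#' @inheritParams introduce_mcar
#' @param chi2_df Chi-squared degrees of freedom for the cutpoint draw.
#' @export
introduce_mar <- function(m, rate, chi2_df = 1L, seed = 1L,
                          max_protein_missing = 1) {
  if (rate < 0 || rate >= 1) {
    rlang::abort("`rate` must be in [0, 1).", class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  v <- m$values
  if (rate == 0) {
    return(new_injection_result(m, cells_to_tibble(v, integer(0), character(0)),
                                length(v)))
  }
  n_obs <- sum(!is.na(v))
  rem <- .mar_cells(v, round(rate * n_obs),
                    protein_quota(v, max_protein_missing), chi2_df)
  deleted <- cells_to_tibble(v, rem$cell, "MAR", driver = rownames(v)[rem$driver],
                             cutpoint = rem$cutpoint, driver_z = rem$driver_z)
  new_injection_result(apply_deletion(m, deleted), deleted, length(v))
}

#' Inject MNAR missingness
#'
#' Visits proteins in random order; for each, samples a cutpoint from a
#' chi-squared distribution (mapped to the protein's standardized scale)
#' and removes all values below it — i.e. the protein's smallest observed
#' values — stopping exactly at the target global rate (the final
#' protein's removal set is truncated smallest-first, so removals are
#' always bottom order statistics).
#'
#' @inheritParams introduce_mar
#' @export
introduce_mnar <- function(m, rate, chi2_df = 1L, seed = 1L,
                           max_protein_missing = 1) {
  if (rate < 0 || rate >= 1) {
    rlang::abort("`rate` must be in [0, 1).", class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  v <- m$values
  n_obs <- sum(!is.na(v))
  cells <- .mnar_cells(v, round(rate * n_obs),
                       protein_quota(v, max_protein_missing), chi2_df)
  deleted <- cells_to_tibble(v, cells, "MNAR")
  new_injection_result(apply_deletion(m, deleted), deleted, length(v))
}

#' Inject a mixture of MCAR, MAR and MNAR
#'
#' Applies the three mechanisms sequentially (MCAR, then MAR, then MNAR),
#' each contributing one third of the target cell count; the final MNAR
#' round is truncated so the total hits the target exactly (up to MAR's
#' recorded overshoot). Every deleted cell is labelled with the mechanism
#' that removed it.
#'
#' @inheritParams introduce_mar
#' @export
introduce_mixture <- function(m, rate, chi2_df = 1L, seed = 1L,
                              max_protein_missing = 1) {
  if (rate < 0 || rate >= 1) {
    rlang::abort("`rate` must be in [0, 1).", class = "lfq_validation_error")
  }
  withr::local_seed(seed)
  v0 <- m$values
  n_obs <- sum(!is.na(v0))
  target <- round(rate * n_obs)
  q1 <- round(target / 3); q2 <- round(target / 3)

  cur <- m
  cells1 <- .mcar_cells(cur$values, q1,
                        protein_quota(cur$values, max_protein_missing))
  del1 <- cells_to_tibble(cur$values, cells1, "MCAR")
  cur <- apply_deletion(cur, del1)

  del2 <- del1[0, ]
  if (q2 > 0) {
    rem <- .mar_cells(cur$values, q2,
                      protein_quota(cur$values, max_protein_missing), chi2_df)
    del2 <- cells_to_tibble(cur$values, rem$cell, "MAR",
                            driver = rownames(cur$values)[rem$driver],
                            cutpoint = rem$cutpoint, driver_z = rem$driver_z)
    cur <- apply_deletion(cur, del2)
  }

  q3 <- max(0L, target - nrow(del1) - nrow(del2))
  del3 <- del1[0, ]
  if (q3 > 0) {
    cells3 <- .mnar_cells(cur$values, q3,
                          protein_quota(cur$values, max_protein_missing),
                          chi2_df)
    del3 <- cells_to_tibble(cur$values, cells3, "MNAR")
    cur <- apply_deletion(cur, del3)
  }
  deleted <- dplyr::bind_rows(del1, del2, del3)
  new_injection_result(cur, deleted, length(v0))
}

#' Inject missingness per a spec
#'
#' Dispatches on the spec's mechanism; the spec's seed drives all
#' randomness, so the same spec always reproduces the same injection.
#'
#' @param m An [abundance_matrix()].
#' @param spec A [missingness_spec()].
#' @param max_protein_missing Per-protein cap on the missing fraction.
#' @return An `injection_result`.
#' @export
inject_missing <- function(m, spec, max_protein_missing = 1) {
  stopifnot(inherits(spec, "missingness_spec"))
  switch(spec$mechanism,
    MCAR = introduce_mcar(m, spec$global_rate, seed = spec$seed,
                          max_protein_missing = max_protein_missing),
    MAR = introduce_mar(m, spec$global_rate, chi2_df = spec$chi2_df,
                        seed = spec$seed,
                        max_protein_missing = max_protein_missing),
    MNAR = introduce_mnar(m, spec$global_rate, chi2_df = spec$chi2_df,
                          seed = spec$seed,
                          max_protein_missing = max_protein_missing),
    MIX = introduce_mixture(m, spec$global_rate, chi2_df = spec$chi2_df,
                            seed = spec$seed,
                            max_protein_missing = max_protein_missing))
}

#' Stratify proteins by realized missingness
#'
#' Assigns every protein with at least one deleted cell to a half-open
#' missing-fraction bin `[lo, hi)`; fractions at or above the last cut
#' fall in a terminal `[last, 100%]` bin. The default cuts reproduce the
#' usual reporting strata: <5%, 5-10%, 10-20%, 20-30%, and 30%+.
#'
#' @param r An `injection_result`.
#' @param bins Increasing numeric cut points (fractions). Default
#'   `c(0, 0.05, 0.10, 0.20, 0.30)`.
#' @return A tibble `protein`, `missing_fraction`, `bin` (ordered factor).
#' @export
stratify_protein_missingness <- function(r, bins = c(0, .05, .10, .20, .30)) {
  if (is.unsorted(bins, strictly = TRUE)) {
    rlang::abort("`bins` must be strictly increasing.",
                 class = "lfq_validation_error")
  }
  v <- r$masked_matrix$values
  frac <- rowMeans(is.na(v))
  hit <- rownames(v) %in% unique(r$deleted_cells$protein)
  edges <- c(bins, 1 + 1e-9)
  labs <- c(sprintf("[%g%%,%g%%)", 100 * bins[-length(bins)],
                    100 * bins[-1]),
            sprintf("[%g%%,100%%]", 100 * bins[length(bins)]))
  bin <- cut(frac[hit], breaks = edges, labels = labs, right = FALSE,
             include.lowest = TRUE)
  tibble::tibble(protein = rownames(v)[hit],
                 missing_fraction = unname(frac[hit]),
                 bin = factor(as.character(bin), levels = labs,
                              ordered = TRUE))
}
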