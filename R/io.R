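#' Read a protein abundance table
#'
#' Reads a proteins x samples intensity table into an [abundance_matrix()]
#' tagged `raw`. Three dialects are supported:
#'
#' * `generic_tsv` / `generic_csv`: first column protein id, remaining
#'   columns one sample each; empty cells and `NA` are unobserved.
#' * `flashlfq`: a FlashLFQ `QuantifiedProteins.tsv` table; the protein id
#'   comes from the `Protein Groups` column and intensities from the
#'   `Intensity_<sample>` columns. FlashLFQ writes 0 for proteins it could
#'   not quantify in a run, so zeros are unobserved, not measured zeros.
#'
#' @param path File path.
#' @param dialect One of `"generic_tsv"`, `"generic_csv"`, `"flashlfq"`.
#' @return An [abundance_matrix()] with `scale = "raw"`.
#' @export
read_protein_table <- function(path,
                               dialect = c("generic_tsv", "generic_csv",
                                           "flashlfq")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "generic_csv") "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          na = c("", "NA"), progress = FALSE,
                          show_col_types = FALSE)
  if (dialect == "flashlfq") {
    idcol <- "Protein Groups"
    if (!idcol %in% names(df)) {
      rlang::abort("flashlfq dialect requires a `Protein Groups` column.",
                   class = "lfq_parse_error")
    }
    int_cols <- grep("^Intensity_", names(df), value = TRUE)
    if (!length(int_cols)) {
      rlang::abort("flashlfq dialect: no `Intensity_<sample>` columns found.",
                   class = "lfq_parse_error")
    }
    ids <- as.character(df[[idcol]])
    vals <- df[int_cols]
    names(vals) <- sub("^Intensity_", "", int_cols)
  } else {
    ids <- as.character(df[[1]])
    vals <- df[-1]
  }
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate protein id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 class = "lfq_parse_error")
  }
  for (cn in names(vals)) {
    col <- vals[[cn]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        rlang::abort(sprintf("non-numeric cell at protein `%s`, sample `%s`.",
                             ids[bad[1]], cn),
                     class = "lfq_parse_error")
      }
      vals[[cn]] <- num
    }
  }
  m <- as.matrix(vals)
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (dialect == "flashlfq") m[!is.na(m) & m == 0] <- NA_real_
  abundance_matrix(m, scale = "raw")
}

#' Read a sample-metadata table
#'
#' @param path TSV file with columns `sample_id`, `age_years`, `sex`.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "age_years") %in% names(meta))) {
    rlang::abort("metadata needs `sample_id` and `age_years` columns.",
                 class = "lfq_parse_error")
  }
  meta
}

#' Global intensity normalization and log2 transform
#'
#' Rescales every sample column so its observed-intensity total equals the
#' mean column total (total-ion-intensity normalization), then, by default,
#' log2-transforms. Normalization is idempotent: columns that already share
#' a total are unchanged.
#'
#' @param m An [abundance_matrix()] on the `raw` (or `normalized`) scale
#'   with non-negative observed values.
#' @param log2 Apply the log2 transform after rescaling (default `TRUE`).
#'   Set `FALSE` to inspect the pre-log normalized values.
#' @return An [abundance_matrix()] tagged `log` (or `normalized`).
#' @export
global_intensity_normalize <- function(m, log2 = TRUE) {
  if (m$scale == "log") {
    rlang::abort("matrix is already log scale; normalize raw intensities.",
                 class = "lfq_validation_error")
  }
  v <- m$values
  obs <- !is.na(v)
  if (any(v[obs] < 0)) {
    rlang::abort("raw intensities must be >= 0.",
                 class = "lfq_validation_error")
  }
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals == 0)) {
    rlang::abort(sprintf("sample(s) with zero observed total intensity: %s",
                         paste(colnames(v)[totals == 0], collapse = ", ")),
                 class = "lfq_validation_error")
  }
  target <- mean(totals)
  v <- sweep(v, 2, target / totals, `*`)
  if (log2) {
    v[obs & v <= 0] <- NA  # zero intensity carries no quantitative signal
    v <- base::log2(v)
    abundance_matrix(v, scale = "log", truth = NULL)
  } else {
    abundance_matrix(v, scale = "normalized", truth = NULL)
  }
}

#' Presence filter
#'
#' Retains proteins observed in at least `min_fraction` of the samples
#' (inclusive: observed_count / n_samples >= min_fraction), preserving
#' order. The 25% default is the usual LFQ retention rule.
#'
#' @param m An [abundance_matrix()].
#' @param min_fraction Minimum observed fraction, default 0.25.
#' @return A filtered [abundance_matrix()].
#' @export
filter_presence <- function(m, min_fraction = 0.25) {
  keep <- rowMeans(!is.na(m$values)) >= min_fraction
  subset_abundance(m, proteins = keep)
}

#' Complete-data subset
#'
#' Returns the proteins with no missing cells; the usual starting point for
#' injection experiments where truth must be known.
#'
#' @param m An [abundance_matrix()].
#' @return An [abundance_matrix()] with zero missing cells (possibly zero
#'   proteins, with a warning).
#' @export
complete_subset <- function(m) {
  keep <- rowSums(is.na(m$values)) == 0
  if (!any(keep)) {
    rlang::warn("no proteins with complete data; returning empty matrix.")
  }
  subset_abundance(m, proteins = keep)
}
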