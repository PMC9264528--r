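#' Construct an abundance matrix
#'
#' The single data currency of the package: a proteins x samples grid of
#' (usually log2) intensities with `NA` marking unobserved cells, plus a
#' scale tag recording where the values sit in the preprocessing chain.
#'
#' @param values Numeric matrix, rows = proteins, columns = samples.
#'   `NA` entries are unobserved. Row and column names are used as protein
#'   and sample ids; defaults are generated when absent.
#' @param scale One of `"raw"`, `"normalized"`, `"log"`. Raw means
#'   non-negative intensities straight from quantification; normalized means
#'   globally rescaled but not yet log-transformed; log means log2 scale,
#'   ready for imputation.
#' @param truth Optional numeric matrix of the same shape holding the true
#'   (pre-deletion) value of every cell. Carried by synthetic datasets with
#'   built-in missingness so leave-one-out evaluation can compare against
#'   truth without a second file.
#'
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, scale = c("log", "raw", "normalized"),
                             truth = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (proteins x samples).",
                 class = "lfq_validation_error")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    rlang::abort("protein ids must be unique.", class = "lfq_validation_error")
  }
  if (anyDuplicated(colnames(values))) {
    rlang::abort("sample ids must be unique.", class = "lfq_validation_error")
  }
  obs <- values[!is.na(values)]
  if (length(obs) && any(!is.finite(obs))) {
    rlang::abort("observed values must be finite.",
                 class = "lfq_validation_error")
  }
  if (!is.null(truth)) {
    stopifnot(is.matrix(truth), all(dim(truth) == dim(values)))
    dimnames(truth) <- dimnames(values)
  }
  structure(list(values = values, scale = scale, truth = truth),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  nmiss <- sum(is.na(v))
  cat(sprintf(
    "<abundance_matrix> %d proteins x %d samples [%s scale], %d missing (%.1f%%)%s\n",
    nrow(v), ncol(v), x$scale, nmiss, 100 * nmiss / length(v),
    if (!is.null(x$truth)) ", truth layer attached" else ""))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Protein and sample identifiers
#' @param m An `abundance_matrix`.
#' @return Character vector of ids.
#' @export
protein_ids <- function(m) rownames(m$values)

#' @rdname protein_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Number of missing cells
#' @param m An `abundance_matrix`.
#' @export
n_missing <- function(m) sum(is.na(m$values))

#' Per-protein missing fraction
#' @param m An `abundance_matrix`.
#' @return Named numeric vector, one entry per protein.
#' @export
protein_missing_fraction <- function(m) rowMeans(is.na(m$values))

#' Subset an abundance matrix by protein and/or sample
#' @param m An `abundance_matrix`.
#' @param proteins,samples Index, logical or name vectors; `NULL` keeps all.
#' @export
subset_abundance <- function(m, proteins = NULL, samples = NULL) {
  if (is.null(proteins)) proteins <- seq_len(nrow(m$values))
  if (is.null(samples)) samples <- seq_len(ncol(m$values))
  abundance_matrix(m$values[proteins, samples, drop = FALSE], scale = m$scale,
                   truth = if (!is.null(m$truth))
                     m$truth[proteins, samples, drop = FALSE])
}

#' Long-format view of an abundance matrix
#'
#' @param x An `abundance_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `protein`, `sample`, `value` (NA when
#'   missing) and, when a truth layer is attached, `truth`.
#' @importFrom tibble as_tibble
#' @method as_tibble abundance_matrix
#' @export
as_tibble.abundance_matrix <- function(x, ...) {
  out <- tibble::tibble(
    protein = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values))
  if (!is.null(x$truth)) out$truth <- as.vector(x$truth)
  out
}

#' Write an abundance matrix / sample metadata as TSV
#'
#' Rows are proteins, columns samples, first column `protein`; missing cells
#' are written empty.
#'
#' @param m An `abundance_matrix`.
#' @param path Output file path.
#' @export
write_abundance_tsv <- function(m, path) {
  df <- data.frame(protein = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @param meta A sample-metadata tibble (`sample_id`, `age_years`, `sex`).
#' @param path Output file path.
#' @rdname write_abundance_tsv
#' @export
write_metadata_tsv <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

# internal: check metadata matches a matrix
check_metadata <- function(m, meta) {
  if (!all(c("sample_id", "age_years") %in% names(meta))) {
    rlang::abort("metadata needs columns `sample_id` and `age_years`.",
                 class = "lfq_validation_error")
  }
  if (!setequal(meta$sample_id, sample_ids(m)) ||
      nrow(meta) != ncol(m$values)) {
    rlang::abort("metadata rows must match matrix samples 1:1.",
                 class = "lfq_validation_error")
  }
  meta[match(sample_ids(m), meta$sample_id), , drop = FALSE]
}
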