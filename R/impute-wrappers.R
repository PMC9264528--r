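#' Named single-imputation entry points
#'
#' Thin wrappers over [impute()] for the individually documented
#' algorithms; all arguments are forwarded.
#'
#' @param m An [abundance_matrix()].
#' @param ... Passed to [impute()].
#' @return A complete [abundance_matrix()].
#' @name si_wrappers
NULL

#' @rdname si_wrappers
#' @export
rf_impute <- function(m, ...) impute(m, method = "rf", ...)

#' @rdname si_wrappers
#' @export
lls_impute <- function(m, ...) impute(m, method = "lls", ...)

#' @rdname si_wrappers
#' @export
grr_impute <- function(m, ...) impute(m, method = "grr", ...)

#' @rdname si_wrappers
#' @export
bpca_impute <- function(m, ...) impute(m, method = "bpca", ...)

#' @rdname si_wrappers
#' @export
svd_impute <- function(m, ...) impute(m, method = "svd", ...)

#' @rdname si_wrappers
#' @export
knn_impute <- function(m, ...) impute(m, method = "knn", ...)

#' @rdname si_wrappers
#' @export
seqknn_impute <- function(m, ...) impute(m, method = "seqknn", ...)

#' @rdname si_wrappers
#' @export
impseq_impute <- function(m, ...) impute(m, method = "impseq", ...)

#' Registry of available single-imputation methods
#' @return Character vector of method names accepted by [impute()].
#' @export
si_methods <- function() {
  c("zero", "mean", "knn", "seqknn", "svd", "bpca", "lls", "grr", "rf",
    "impseq")
}
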