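#' Plot an accuracy-screen result
#'
#' One point per injection iteration: percentage of correctly imputed
#' values by method, faceted by protein-missingness stratum and coloured
#' by global rate.
#'
#' @param results Tibble from [accuracy_screen()].
#' @param threshold Threshold annotation (percent), default 5.
#' @return A ggplot object.
#' @export
plot_accuracy_screen <- function(results, threshold = 5) {
  df <- dplyr::filter(results, .data$stratum != "overall")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = 100 * .data$fraction_correct,
                                   colour = factor(.data$rate))) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = NULL, colour = "global rate",
                  y = sprintf("%% imputed within %g%% of truth", threshold)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot regression- or alpha-bias deltas
#'
#' Boxplots of the imputation-induced shifts per method, faceted by rate
#' and protein-subset size, with the zero line for reference.
#'
#' @param results Tibble from [regression_bias()] or [alpha_bias()].
#' @param delta Column to plot, e.g. `"delta_beta"`, `"delta_p"`,
#'   `"delta_alpha"`.
#' @return A ggplot object.
#' @export
plot_bias <- function(results, delta = "delta_beta") {
  df <- dplyr::filter(results, .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data[[delta]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_grid(rate ~ n_proteins,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = paste(delta, "(imputed - true)")) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot leave-one-out accuracy by protein-missingness stratum
#'
#' @param records Tibble from [loo_structural_eval()].
#' @param threshold Correctness cutoff (percent), default 5.
#' @return A ggplot object.
#' @export
plot_loo <- function(records, threshold = 5) {
  sm <- summarise_loo(records, threshold = threshold)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$stratum,
                                   y = 100 * .data$fraction_correct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "protein missingness when imputed",
                  y = sprintf("%% within %g%% of truth", threshold)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Autoplot an injection result
#'
#' Histogram of per-protein missing fractions after the injection.
#'
#' @param object An `injection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot injection_result
#' @export
autoplot.injection_result <- function(object, ...) {
  v <- object$masked_matrix$values
  df <- tibble::tibble(missing_fraction = rowMeans(is.na(v)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$missing_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "per-protein missing fraction", y = "proteins") +
    ggplot2::theme_bw()
}
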