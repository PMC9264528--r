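# Small deterministic fixtures built in code.

tiny_matrix <- function(values, scale = "log") {
  abundance_matrix(values, scale = scale)
}

small_complete <- function(n_proteins = 30, n_samples = 20, seed = 1,
                           rho = 0.8, noise_sd = 0.3) {
  generate_complete_dataset(synth_config(
    n_samples = n_samples, n_proteins = n_proteins,
    within_block_correlation = rho, noise_sd = noise_sd, seed = seed))
}

deleted_index <- function(cells, m) {
  cbind(match(cells$protein, rownames(m$values)),
        match(cells$sample, colnames(m$values)))
}

# fraction of deleted cells imputed within `threshold` percent of truth
injected_fraction_correct <- function(inj, imputed, threshold = 5) {
  idx <- deleted_index(inj$deleted_cells, imputed)
  fraction_correct(percent_bias(imputed$values[idx],
                                inj$deleted_cells$true_value), threshold)
}
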