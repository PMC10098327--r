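# Small dataset builders shared across tests.

# compact simulation used where full-size runs would be wasteful
tiny_sim_config <- function(seed, n_genes = 120L, n_cells = 150L,
                            transition_effect = 1, ...) {
  sim_config(n_genes = n_genes,
             n_cells_per_condition = c(sham = n_cells, day1 = n_cells),
             transition_genes = 1:15,
             transition_effect = transition_effect,
             library_size_mean = 4000,
             seed = seed, ...)
}

# cell_dataset from a dense cells x genes matrix with default labels
quick_dataset <- function(counts, genes = NULL, conditions = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(ncol(counts)))
  cell_dataset(counts,
               gene_names = genes,
               cell_barcodes = sprintf("bc%03d", seq_len(nrow(counts))),
               condition = conditions %||% rep("sham", nrow(counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
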