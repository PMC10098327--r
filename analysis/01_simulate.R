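#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates a sham vs post-injury (day1) single-cell experiment: two cell
# types whose signature heterogeneity is five times larger than the planted
# condition effect, with the effect confined to half of the type-1 cells of
# the day1 group; plus paired bulk-RNA and proteomic differential tables
# sharing 44 planted differential genes.

library(stxmicro)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
sim <- simulate_counts(cfg)
write_fixture(sim$dataset, file.path(out, "sim_counts"))

write.table(data.frame(barcode = sim$dataset$cell_barcodes,
                       cell_type = sim$truth$cell_type_labels,
                       affected = sim$truth$affected_cell_mask),
            file.path(out, "sim_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = sim$dataset$gene_names,
                       planted_shift = sim$truth$planted_shift_vector),
            file.path(out, "planted_shift.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tabs <- simulate_paired_omics(n_bulk = 300, n_prot = 200, n_overlap = 44,
                              seed = 2)
write.table(tabs$rna, file.path(out, "bulk_rna_degs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tabs$protein, file.path(out, "proteomic_degs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d cells x %d genes (%d affected cells of type %d, %s)\n",
            nrow(sim$dataset$counts), ncol(sim$dataset$counts),
            sum(sim$truth$affected_cell_mask), cfg$affected_cell_type,
            cfg$affected_condition))
cat(sprintf("paired differential tables: %d bulk rows, %d protein rows, %d planted shared\n",
            nrow(tabs$rna), nrow(tabs$protein), 44))
cat("wrote results/data/\n")
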