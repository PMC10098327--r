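#!/usr/bin/env Rscript
# Stage 2: quality control, normalization, embedding and clustering.
#
# Applies the standard single-cell QC (cells with 200-3000 detected genes
# and at most 10% mitochondrial UMIs; genes in at least 3 cells), log-
# normalizes, selects HVGs, embeds with PCA and clusters the SNN graph.

library(stxmicro)

ds <- read_counts_mtx("results/data/sim_counts",
                      "results/data/sim_counts/conditions.tsv")
cat(sprintf("loaded %d cells x %d genes\n", nrow(ds$counts), ncol(ds$counts)))

qp <- qc_params()
ds <- qc_filter(ds, qp)
cat(sprintf("after QC: %d cells x %d genes\n", nrow(ds$counts), ncol(ds$counts)))

ds <- log_normalize(ds, qp$scale_factor)
ds <- select_hvg(ds, min(qp$n_hvg, ncol(ds$counts)))
ds <- embed_pca(ds, min(qp$n_pcs, min(dim(ds$counts)) - 1L))
ds <- cluster_cells(ds, resolution = qp$resolution, seed = qp$seed)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(barcode = ds$cell_barcodes, condition = ds$condition,
                       n_genes = ds$n_genes_by_cell,
                       mito_fraction = round(ds$mito_fraction, 4),
                       cluster = ds$cluster),
            "results/cell_metadata.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# per-condition composition of the expression-space clusters
ds$cell_type <- as.character(ds$cluster)
comp <- composition_table(ds)
write.table(comp, "results/cluster_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/data/sim_truth.tsv")
truth <- truth[match(ds$cell_barcodes, truth$barcode), ]
cat(sprintf("expression clusters: %d; ARI vs planted cell types: %.3f\n",
            nlevels(droplevels(ds$cluster)),
            adjusted_rand_index(ds$cluster, truth$cell_type)))
cat("wrote results/cell_metadata.tsv, results/cluster_composition.tsv\n")
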