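#' Quality-control and processing parameters
#'
#' Defaults follow the conventional single-cell workflow for mouse brain
#' tissue: cells kept with 200-3000 detected genes (inclusive) and at most
#' 10% mitochondrial UMIs; genes kept when detected in at least 3 retained
#' cells; log-normalization to 1e4 counts; 2000 HVGs; 30 PCs; graph
#' clustering at resolution 1.0.
#'
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param min_cells_per_gene minimum retained cells a gene must appear in.
#' @param max_mito maximum mitochondrial UMI fraction (inclusive).
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param resolution community-detection resolution.
#' @param scale_factor log-normalization scale factor.
#' @param seed community-detection seed.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200L, max_genes = 3000L, min_cells_per_gene = 3L,
                      max_mito = 0.10, n_hvg = 2000L, n_pcs = 30L,
                      resolution = 1.0, scale_factor = 1e4, seed = 0L) {
  p <- list(min_genes = as.integer(min_genes), max_genes = as.integer(max_genes),
            min_cells_per_gene = as.integer(min_cells_per_gene),
            max_mito = max_mito, n_hvg = as.integer(n_hvg),
            n_pcs = as.integer(n_pcs), resolution = resolution,
            scale_factor = scale_factor, seed = as.integer(seed))
  if (p$min_genes >= p$max_genes) stop_named("min_genes must be < max_genes")
  if (p$max_mito <= 0 || p$max_mito > 1) stop_named("max_mito must lie in (0, 1]")
  class(p) <- "qc_params"
  p
}

#' Filter cells and genes on QC criteria
#'
#' Cells are retained when their detected-gene count lies in
#' \[min_genes, max_genes\] and their mitochondrial UMI fraction is at most
#' `max_mito` (removal criteria are strict: fewer than min, more than max,
#' over max_mito). Genes are then retained when detected in at least
#' `min_cells_per_gene` of the retained cells. Cell and gene order is
#' preserved.
#'
#' @param dataset a [cell_dataset] with raw counts.
#' @param params a [qc_params].
#' @return The filtered [cell_dataset].
#' @export
qc_filter <- function(dataset, params = qc_params()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  detected <- as.integer(Matrix::rowSums(dataset$counts > 0))
  tot <- row_totals(dataset$counts)
  mito_genes <- grepl("^mt-", dataset$gene_names, ignore.case = TRUE)
  mito_frac <- numeric(nrow(dataset$counts))
  if (any(mito_genes)) {
    mt <- row_totals(dataset$counts[, mito_genes, drop = FALSE])
    mito_frac[tot > 0] <- mt[tot > 0] / tot[tot > 0]
  }
  keep_cells <- which(detected >= params$min_genes & detected <= params$max_genes &
                        mito_frac <= params$max_mito)
  gene_cells <- Matrix::colSums(dataset$counts[keep_cells, , drop = FALSE] > 0)
  keep_genes <- which(gene_cells >= params$min_cells_per_gene)
  if (!length(keep_cells) || !length(keep_genes))
    warn_named("QC filtering removed all %s", if (!length(keep_cells)) "cells" else "genes")
  subset_cells(dataset, keep_cells, keep_genes)
}

#' Log-normalize counts
#'
#' lognorm\[i, j\] = ln(1 + counts\[i, j\] / total\[i\] * scale_factor).
#' The zero pattern is preserved and the result is invariant to rescaling a
#' cell's counts.
#'
#' @param dataset a [cell_dataset] (normally after [qc_filter()]).
#' @param scale_factor scaling constant (default 1e4).
#' @return The dataset with `lognorm` set.
#' @export
log_normalize <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "cell_dataset"))
  tot <- row_totals(dataset$counts)
  if (any(tot == 0))
    stop_named("cell(s) with zero total counts cannot be normalized: %s",
               paste(utils::head(dataset$cell_barcodes[tot == 0], 5), collapse = ", "))
  ln <- Matrix::Diagonal(x = scale_factor / tot) %*% dataset$counts
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(dataset$counts)
  dataset$lognorm <- methods::as(ln, "CsparseMatrix")
  dataset
}

# per-gene mean and variance of a sparse cells x genes matrix
sparse_gene_moments <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colSums(m^2) / n
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  list(mean = as.numeric(mu), var = pmax(as.numeric(v), 0))
}

#' Select highly variable genes by bin-standardized dispersion
#'
#' Dispersion is variance/mean of the log-normalized values; genes are
#' binned (20 equal-frequency bins) by mean expression and dispersions are
#' z-scored within each bin. The `n_hvg` genes with the highest
#' standardized dispersion are flagged; ties are broken by raw dispersion
#' (descending) then gene name (ascending). Zero-variance genes are never
#' selected while any non-constant gene is available.
#'
#' @param dataset a [cell_dataset] with `lognorm`.
#' @param n_hvg number of genes to flag; must not exceed the gene count.
#' @param n_bins number of mean-expression bins.
#' @return The dataset with `hvg_mask` set.
#' @export
select_hvg <- function(dataset, n_hvg = 2000L, n_bins = 20L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$lognorm)) stop_named("log_normalize must be run before select_hvg")
  G <- ncol(dataset$lognorm)
  if (n_hvg > G) stop_named("n_hvg (%d) exceeds the number of genes (%d)", n_hvg, G)
  mo <- sparse_gene_moments(dataset$lognorm)
  disp <- ifelse(mo$mean > 0, mo$var / mo$mean, 0)
  breaks <- unique(stats::quantile(mo$mean, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) < 2) factor(rep(1L, G))
         else cut(mo$mean, breaks = breaks, include.lowest = TRUE)
  z <- stats::ave(disp, bin, FUN = function(d) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  z[mo$var == 0] <- -Inf
  ord <- order(-z, -disp, dataset$gene_names)
  mask <- logical(G)
  mask[ord[seq_len(n_hvg)]] <- TRUE
  dataset$hvg_mask <- mask
  dataset
}

# z-score columns of a dense matrix, clip at +/- clip; zero-variance -> 0
scale_clip <- function(x, clip = 10) {
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  x <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x
}

# PCA with a deterministic sign convention: the largest-|loading| entry of
# each component is made positive
pca_scores <- function(x, n_pcs) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  list(scores = pc$x, rotation = pc$rotation, sdev = pc$sdev)
}

#' PCA embedding of the scaled HVG matrix
#'
#' The HVG log-normalized submatrix is per-gene z-scored (clipped at +/-10)
#' and decomposed by PCA; the top `n_pcs` scores become the embedding.
#' Component signs follow a fixed convention (largest-|loading| gene
#' positive), making the embedding deterministic.
#'
#' @param dataset a [cell_dataset] with `hvg_mask`.
#' @param n_pcs number of components; must be < min(cells, HVGs).
#' @return The dataset with `embedding` set.
#' @export
embed_pca <- function(dataset, n_pcs = 30L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$hvg_mask)) stop_named("select_hvg must be run before embed_pca")
  x <- as.matrix(dataset$lognorm[, dataset$hvg_mask, drop = FALSE])
  if (n_pcs >= min(nrow(x), ncol(x)))
    stop_named("n_pcs (%d) must be < min(cells, HVGs) = %d", n_pcs, min(dim(x)))
  emb <- pca_scores(scale_clip(x), n_pcs)$scores
  rownames(emb) <- dataset$cell_barcodes
  dataset$embedding <- emb
  dataset
}

#' Cluster cells on the PCA embedding
#'
#' Builds a shared-nearest-neighbor (SNN) graph on the embedding and runs
#' Louvain modularity community detection at the given resolution.
#' Deterministic for a fixed seed.
#'
#' @param dataset a [cell_dataset] with `embedding`.
#' @param resolution community-detection resolution.
#' @param seed integer seed.
#' @param k_neighbors neighborhood size for the SNN graph (capped with a
#'   warning when fewer cells are available).
#' @return The dataset with `cluster` set (factor "c1", "c2", ... in
#'   decreasing cluster size).
#' @export
cluster_cells <- function(dataset, resolution = 1.0, seed = 0L, k_neighbors = 20L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$embedding)) stop_named("embed_pca must be run before cluster_cells")
  dataset$cluster <- snn_louvain(dataset$embedding, resolution = resolution,
                                 seed = seed, k_neighbors = k_neighbors)
  dataset
}

#' Default cell-type marker panels
#'
#' Marker panels for the major mouse brain cell types (microglia panel:
#' Hexb, C1qa, Tmem119, Gpr34, Olfml3; plus endothelial, oligodendrocyte,
#' astrocyte, and further populations).
#'
#' @return Named list of gene vectors.
#' @export
marker_panels <- function() {
  list(
    Astrocyte = c("F3", "Gja1", "Slc1a3", "Gjb6"),
    `B cell` = c("Cd19", "Cd79a"),
    `Choroid plexus` = c("Ttr", "Clic6", "Sostdc1", "Car12", "Prlr", "Htr2c"),
    Endothelial = c("Cldn5", "Ly6c1", "Ly6a", "Itm2a"),
    Ependymal = c("Calml4", "Chchd10", "Clu"),
    Microglia = c("Hexb", "C1qa", "Tmem119", "Gpr34", "Olfml3"),
    Monocyte = c("Cd14", "Cd86"),
    Neuron = c("Rtn1", "Sox4"),
    Neutrophil = c("Trem1", "Mmp8"),
    OPC = c("Olig1", "Olig2", "Pdgfra", "Tnr", "C1ql1", "Matn4"),
    Oligodendrocyte = c("Cldn11", "Mag", "Opalin", "Ermn", "Mog"),
    Pericyte = c("Kcnj8", "Atp13a5", "Anpep", "Abcc9", "Cd248"),
    `T cell` = c("Cd8a", "Klrd1", "Cd4"),
    VSMC = c("Acta2", "Des", "Tpm2", "Filip1l")
  )
}

#' Annotate clusters by marker-panel expression
#'
#' Each cluster is assigned the cell type whose panel attains the highest
#' mean z-scored log-normalized expression within the cluster. Panel genes
#' absent from the data are dropped with a warning; a panel with no genes
#' present is ineligible. Ties are broken alphabetically and flagged.
#'
#' @param dataset a [cell_dataset] with `cluster` and `lognorm`.
#' @param panels named list of marker gene vectors (default
#'   [marker_panels()]).
#' @return The dataset with `cell_type` set and an `annotation_scores`
#'   attribute (cluster x type score matrix, with an `ambiguous` flag).
#' @export
annotate_clusters <- function(dataset, panels = marker_panels()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$cluster)) stop_named("cluster_cells must be run before annotate_clusters")
  if (any(!lengths(panels))) stop_named("every marker panel must be non-empty")
  present <- lapply(panels, function(g) intersect(g, dataset$gene_names))
  missing <- unlist(Map(setdiff, panels, present), use.names = FALSE)
  if (length(missing))
    warn_named("marker gene(s) absent from data: %s",
               paste(utils::head(missing, 8), collapse = ", "))
  eligible <- names(present)[lengths(present) > 0]
  if (!length(eligible)) stop_named("no marker panel has any gene in the data")
  all_genes <- unique(unlist(present[eligible]))
  z <- scale_clip(as.matrix(dataset$lognorm[, all_genes, drop = FALSE]), clip = Inf)
  colnames(z) <- all_genes
  clusters <- sort(unique(as.character(dataset$cluster)))
  scores <- matrix(NA_real_, length(clusters), length(eligible),
                   dimnames = list(clusters, eligible))
  for (cl in clusters) {
    in_cl <- dataset$cluster == cl
    for (ty in eligible)
      scores[cl, ty] <- mean(z[in_cl, present[[ty]], drop = FALSE])
  }
  assigned <- character(length(clusters)); ambiguous <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    best <- max(scores[i, ])
    winners <- sort(eligible[scores[i, ] == best])
    assigned[i] <- winners[1]
    ambiguous[i] <- length(winners) > 1
  }
  names(assigned) <- clusters
  dataset$cell_type <- unname(assigned[as.character(dataset$cluster)])
  attr(dataset, "annotation_scores") <- list(scores = scores, ambiguous = ambiguous)
  dataset
}

#' Per-condition cell-type composition
#'
#' @param dataset an annotated [cell_dataset].
#' @return data.frame (condition, cell_type, n, percent); percentages sum
#'   to 100 within each condition.
#' @export
composition_table <- function(dataset) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$cell_type)) stop_named("annotate_clusters must be run first")
  tab <- as.data.frame(table(condition = dataset$condition,
                             cell_type = dataset$cell_type),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  totals <- stats::ave(tab$n, tab$condition, FUN = sum)
  tab$percent <- 100 * tab$n / totals
  tab[order(tab$condition, tab$cell_type), , drop = FALSE]
}
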