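#' Cell dataset container
#'
#' Lightweight container holding a cells-by-genes UMI count matrix together
#' with per-cell condition labels and the per-cell/per-gene annotations the
#' pipeline accumulates (QC fields, log-normalized values, HVG mask, PCA
#' embedding, cluster and cell-type labels).
#'
#' @param counts cells x genes non-negative integer matrix (dense or sparse);
#'   rows are cells, columns genes.
#' @param gene_names character vector, one per column of `counts`.
#' @param cell_barcodes character vector, one per row of `counts`.
#' @param condition per-cell condition label (e.g. sham/day1/day3/day7).
#'
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(counts, gene_names, cell_barcodes, condition) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) != length(gene_names))
    stop_named("counts has %d columns but %d gene names given", ncol(counts), length(gene_names))
  if (nrow(counts) != length(cell_barcodes))
    stop_named("counts has %d rows but %d barcodes given", nrow(counts), length(cell_barcodes))
  if (length(condition) != length(cell_barcodes))
    stop_named("condition has length %d but there are %d cells", length(condition), length(cell_barcodes))
  if (length(counts@x) && any(counts@x < 0)) stop_named("counts must be non-negative")
  if (length(counts@x) && any(counts@x != round(counts@x))) stop_named("counts must be integers")
  dimnames(counts) <- list(as.character(cell_barcodes), as.character(gene_names))
  mito <- grepl("^mt-", gene_names, ignore.case = TRUE)
  tot <- row_totals(counts)
  mito_frac <- numeric(nrow(counts))
  if (any(mito)) {
    mito_tot <- row_totals(counts[, mito, drop = FALSE])
    mito_frac[tot > 0] <- mito_tot[tot > 0] / tot[tot > 0]
  }
  structure(list(
    counts = counts,
    gene_names = as.character(gene_names),
    cell_barcodes = as.character(cell_barcodes),
    condition = as.character(condition),
    n_genes_by_cell = as.integer(Matrix::rowSums(counts > 0)),
    mito_fraction = mito_frac,
    lognorm = NULL, hvg_mask = NULL, embedding = NULL,
    cluster = NULL, cell_type = NULL
  ), class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s (%d)", names(table(x$condition)), table(x$condition)),
                           collapse = ", "), "\n")
  for (f in c("lognorm", "hvg_mask", "embedding", "cluster", "cell_type"))
    if (!is.null(x[[f]])) cat(sprintf("  %s: set\n", f))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

# subset cells (i) and/or genes (j), keeping annotations aligned
subset_cells <- function(ds, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(ds$counts))
  if (is.null(j)) j <- seq_len(ncol(ds$counts))
  out <- ds
  out$counts <- ds$counts[i, j, drop = FALSE]
  out$gene_names <- ds$gene_names[j]
  out$cell_barcodes <- ds$cell_barcodes[i]
  out$condition <- ds$condition[i]
  out$n_genes_by_cell <- as.integer(Matrix::rowSums(out$counts > 0))
  tot <- row_totals(out$counts)
  mito <- grepl("^mt-", out$gene_names, ignore.case = TRUE)
  mf <- numeric(length(i))
  if (any(mito)) {
    mt <- row_totals(out$counts[, mito, drop = FALSE])
    mf[tot > 0] <- mt[tot > 0] / tot[tot > 0]
  }
  out$mito_fraction <- mf
  if (!is.null(ds$lognorm)) out$lognorm <- ds$lognorm[i, j, drop = FALSE]
  if (!is.null(ds$hvg_mask)) out$hvg_mask <- ds$hvg_mask[j]
  if (!is.null(ds$embedding)) out$embedding <- ds$embedding[i, , drop = FALSE]
  if (!is.null(ds$cluster)) out$cluster <- ds$cluster[i]
  if (!is.null(ds$cell_type)) out$cell_type <- ds$cell_type[i]
  out
}

#' Read a 10x-style MTX triplet plus condition labels
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, genes x cells, 1-based),
#' `genes.tsv` (one gene symbol per line), `barcodes.tsv` and a two-column
#' conditions TSV (barcode TAB condition). Every barcode must have a label.
#'
#' @param directory directory holding matrix.mtx, genes.tsv, barcodes.tsv.
#' @param conditions_file path to the barcode-to-condition TSV.
#' @return A [cell_dataset].
#' @export
read_counts_mtx <- function(directory, conditions_file) {
  paths <- file.path(directory, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  for (p in c(paths, conditions_file))
    if (!file.exists(p)) stop_named("missing input file: %s", p)
  m <- Matrix::readMM(paths[1])            # genes x cells on disk (10x layout)
  if (!methods::is(m, "dsparseMatrix"))    # pattern/logical MTX -> numeric
    m <- methods::as(m * 1, "CsparseMatrix")
  genes <- readLines(paths[2])
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(paths[3])
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(genes))
    stop_named("matrix declares %d genes but genes.tsv has %d", nrow(m), length(genes))
  if (ncol(m) != length(barcodes))
    stop_named("matrix declares %d cells but barcodes.tsv has %d", ncol(m), length(barcodes))
  if (length(m@x) && any(m@x != round(m@x)))
    stop_named("non-integer entries in %s", paths[1])
  cond_tab <- if (length(readLines(conditions_file)) == 0L) {
    data.frame(barcode = character(0), condition = character(0))
  } else {
    utils::read.delim(conditions_file, header = FALSE,
                      col.names = c("barcode", "condition"),
                      colClasses = "character")
  }
  idx <- match(barcodes, cond_tab$barcode)
  if (anyNA(idx))
    stop_named("conditions file is missing barcode(s): %s",
               paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", "))
  cell_dataset(Matrix::t(m), gene_names = genes, cell_barcodes = barcodes,
               condition = cond_tab$condition[idx])
}

#' Write a dataset as an MTX triplet fixture
#'
#' Emits `matrix.mtx` (genes x cells, MatrixMarket coordinate, 1-based),
#' `genes.tsv`, `barcodes.tsv` and `conditions.tsv` so that
#' [read_counts_mtx()] round-trips to an equal dataset.
#'
#' @param dataset a [cell_dataset].
#' @param directory output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop_named("cannot create directory: %s", directory)
  m <- Matrix::t(dataset$counts)           # genes x cells on disk
  files <- file.path(directory, c("matrix.mtx", "genes.tsv", "barcodes.tsv", "conditions.tsv"))
  Matrix::writeMM(m, files[1])
  writeLines(dataset$gene_names, files[2])
  writeLines(dataset$cell_barcodes, files[3])
  utils::write.table(data.frame(dataset$cell_barcodes, dataset$condition),
                     files[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(files)
}
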