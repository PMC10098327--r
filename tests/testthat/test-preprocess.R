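test_that("the MTX reader handles a hand-written triplet and bad inputs", {
  dir <- withr::local_tempdir()
  # 2 genes x 3 cells, 4 nonzero entries, counted by hand
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 4", "1 1 3", "2 1 1", "1 2 2", "2 3 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("GeneA", "GeneB"), file.path(dir, "genes.tsv"))
  writeLines(c("bc1", "bc2", "bc3"), file.path(dir, "barcodes.tsv"))
  writeLines(c("bc1\tsham", "bc2\tday1", "bc3\tday1"), file.path(dir, "conditions.tsv"))
  ds <- read_counts_mtx(dir, file.path(dir, "conditions.tsv"))
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(unname(as.matrix(ds$counts)["bc1", ]), c(3, 1))
  expect_equal(ds$condition, c("sham", "day1", "day1"))

  # conditions file missing a barcode names it
  writeLines(c("bc1\tsham", "bc3\tday1"), file.path(dir, "conditions.tsv"))
  expect_error(read_counts_mtx(dir, file.path(dir, "conditions.tsv")), "bc2")
  expect_error(read_counts_mtx(file.path(dir, "nope"), file.path(dir, "conditions.tsv")),
               "missing input file")
})

test_that("QC keeps cells inside the inclusive gene-count and mito bounds", {
  n_genes <- 3100L
  # a cell expressing exactly `detected` genes (two of them mitochondrial,
  # carrying `mito_umis` UMIs between them; the rest one UMI each), so
  # mito fraction = mito_umis / (mito_umis + detected - 2)
  make_cell <- function(detected, mito_umis) {
    v <- numeric(n_genes)
    v[3:detected] <- 1
    v[1:2] <- c(mito_umis - 1, 1)
    v
  }
  cells <- rbind(
    make_cell(199, 10),    # removed: fewer than 200 genes
    make_cell(200, 22),    # kept: exactly 200 genes, mito 22/220 = 10.0%
    make_cell(3000, 10),   # kept: exactly 3000 genes
    make_cell(3001, 10),   # removed: more than 3000 genes
    make_cell(893, 100),   # removed: mito 100/991 = 10.09% (over 10%)
    make_cell(902, 100)    # kept: mito 100/1000 = 10.0% exactly
  )
  genes <- c("mt-Nd1", "mt-Nd2", sprintf("G%04d", seq_len(n_genes - 2)))
  ds <- quick_dataset(cells, genes = genes)
  expect_equal(ds$n_genes_by_cell, c(199L, 200L, 3000L, 3001L, 893L, 902L))
  expect_equal(ds$mito_fraction[c(2, 6)], c(0.1, 0.1), tolerance = 1e-12)
  expect_gt(ds$mito_fraction[5], 0.1)
  kept <- qc_filter(ds, qc_params(min_cells_per_gene = 1L))
  expect_equal(kept$cell_barcodes, ds$cell_barcodes[c(2, 3, 6)])
})

test_that("genes detected in fewer than 3 retained cells are removed", {
  counts <- matrix(0, nrow = 4, ncol = 4)
  counts[, 1] <- c(1, 1, 1, 1)   # in 4 cells: kept
  counts[, 2] <- c(1, 1, 1, 0)   # in 3 cells: kept
  counts[, 3] <- c(1, 1, 0, 0)   # in 2 cells: removed
  counts[, 4] <- c(1, 0, 0, 0)   # in 1 cell: removed
  ds <- quick_dataset(counts)
  kept <- qc_filter(ds, qc_params(min_genes = 1L, max_genes = 100L))
  expect_equal(kept$gene_names, c("G001", "G002"))
  # idempotence
  again <- qc_filter(kept, qc_params(min_genes = 1L, max_genes = 100L))
  expect_equal(as.matrix(again$counts), as.matrix(kept$counts))
})

test_that("log-normalization has the closed form and its invariances", {
  counts <- rbind(c(5, 0, 0), c(2, 2, 0), c(0, 0, 7))
  ds <- log_normalize(quick_dataset(counts))
  ln <- as.matrix(ds$lognorm)
  # zeros preserved
  expect_equal(ln == 0, counts == 0, ignore_attr = TRUE)
  # a cell with one expressed gene maps it to ln(1 + 1e4)
  expect_equal(ln[1, 1], log(1 + 1e4), tolerance = 1e-12)
  expect_equal(ln[3, 3], log(1 + 1e4), tolerance = 1e-12)
  # doubling a cell's counts leaves its normalized row unchanged
  ds2 <- log_normalize(quick_dataset(2 * counts))
  expect_equal(as.matrix(ds2$lognorm), ln, tolerance = 1e-12)
  # zero-total cell errors
  expect_error(log_normalize(quick_dataset(rbind(c(1, 1, 1), c(0, 0, 0)))),
               "zero total")
})

test_that("HVG selection ranks by dispersion with saturation and tie rules", {
  # three genes with hand-computed dispersions 5.0, 1.0, 0.1 on injected values
  ds <- quick_dataset(matrix(1, nrow = 6, ncol = 3))
  build_col <- function(target_disp, mean_val) {
    # values with variance = target_disp * mean_val around mean_val
    unit <- c(-1, 1, -1, 1, -1, 1)
    mean_val + sqrt(target_disp * mean_val) * unit / stats::sd(unit)
  }
  ln <- cbind(build_col(5, 2), build_col(1, 2), build_col(0.1, 2))
  ds$lognorm <- Matrix::Matrix(ln, sparse = TRUE)
  disp <- apply(ln, 2, stats::var) / colMeans(ln)
  expect_equal(disp, c(5, 1, 0.1), tolerance = 1e-9)
  out <- select_hvg(ds, 2L)
  expect_equal(out$hvg_mask, c(TRUE, TRUE, FALSE))
  # saturation: n_hvg = n_genes flags everything
  expect_true(all(select_hvg(ds, 3L)$hvg_mask))
  expect_error(select_hvg(ds, 4L), "exceeds")
  # a constant gene is never picked while non-constant genes remain
  ds$lognorm[, 3] <- 1
  expect_equal(select_hvg(ds, 2L)$hvg_mask, c(TRUE, TRUE, FALSE))
})

test_that("PCA embedding matches a brute-force eigendecomposition", {
  set.seed(42)
  x <- matrix(rnorm(4 * 6), nrow = 4)
  ds <- quick_dataset(matrix(rpois(24, 5), nrow = 4, ncol = 6))
  ds$lognorm <- Matrix::Matrix(x, sparse = TRUE)
  ds$hvg_mask <- rep(TRUE, 6)
  out <- embed_pca(ds, 3L)
  emb <- out$embedding
  # oracle: dense eigendecomposition of the covariance of the scaled matrix
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  ev <- eigen(stats::cov(xs))
  oracle <- xs %*% ev$vectors[, 1:3]
  for (k in 1:3)
    expect_lt(min(max(abs(emb[, k] - oracle[, k])),
                  max(abs(emb[, k] + oracle[, k]))), 1e-8)
  # scores are orthogonal
  gram <- crossprod(emb)
  expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
  expect_error(embed_pca(ds, 6L), "n_pcs")
})

test_that("a rank-1 expression matrix loads on a single component", {
  u <- rnorm(12); v <- abs(rnorm(8)) + 1
  ds <- quick_dataset(matrix(1, 12, 8))
  ds$lognorm <- Matrix::Matrix(outer(u, v), sparse = TRUE)
  ds$hvg_mask <- rep(TRUE, 8)
  out <- embed_pca(ds, 3L)
  vars <- apply(out$embedding, 2, stats::var)
  expect_gte(vars[1] / sum(vars), 0.999)
})

test_that("graph clustering separates well-separated blobs deterministically", {
  set.seed(7)
  emb <- rbind(matrix(rnorm(100 * 5), ncol = 5),
               matrix(rnorm(100 * 5, mean = 10), ncol = 5))
  ds <- quick_dataset(matrix(1, 200, 3))
  ds$embedding <- emb
  out <- cluster_cells(ds, resolution = 0.1, seed = 0)
  expect_equal(nlevels(droplevels(out$cluster)), 2L)
  expect_equal(adjusted_rand_index(out$cluster, rep(1:2, each = 100)), 1.0)
  # same seed twice: identical labels
  out2 <- cluster_cells(ds, resolution = 0.1, seed = 0)
  expect_identical(out$cluster, out2$cluster)
  # resolution -> 0 on connected data: one cluster
  ds3 <- quick_dataset(matrix(1, 150, 3))
  ds3$embedding <- matrix(rnorm(150 * 4), ncol = 4)
  expect_equal(nlevels(droplevels(cluster_cells(ds3, resolution = 0.01, seed = 0)$cluster)), 1L)
})

test_that("marker-panel annotation labels constructed types perfectly", {
  panels <- list(Microglia = c("Hexb", "C1qa", "Tmem119"),
                 Astrocyte = c("Gja1", "Slc1a3"))
  genes <- c(panels$Microglia, panels$Astrocyte, "Gfiller")
  n <- 60
  counts <- matrix(rpois(n * 6, 1), n, 6)
  type <- rep(c("Microglia", "Astrocyte"), each = n / 2)
  counts[type == "Microglia", 1:3] <- matrix(rpois(3 * n / 2, 30), ncol = 3)
  counts[type == "Astrocyte", 4:5] <- matrix(rpois(2 * n / 2, 30), ncol = 2)
  counts <- cbind(counts[, 1:5], rpois(n, 5))
  ds <- quick_dataset(counts, genes = genes)
  ds <- log_normalize(ds)
  ds$cluster <- factor(rep(c("c1", "c2"), each = n / 2))
  out <- annotate_clusters(ds, panels)
  expect_equal(out$cell_type, type)
  # a panel gene absent from the data warns but does not break
  panels$Microglia <- c(panels$Microglia, "NotAGene")
  expect_warning(annotate_clusters(ds, panels), "NotAGene")
  # identical scores tie-break alphabetically and are flagged
  ds$lognorm <- Matrix::Matrix(
    matrix(1, n, 6, dimnames = list(ds$cell_barcodes, genes)), sparse = TRUE)
  tie <- suppressWarnings(annotate_clusters(ds, list(Bcd = "Hexb", Abc = "Hexb")))
  expect_true(all(tie$cell_type == "Abc"))
  expect_true(all(attr(tie, "annotation_scores")$ambiguous))
})

test_that("composition percentages sum to 100 within each condition", {
  set.seed(2)
  ds <- quick_dataset(matrix(rpois(500 * 3, 3), 500, 3),
                      conditions = rep(c("sham", "day1"), c(400, 100)))
  ds$cell_type <- sample(c("Microglia", "Neuron"), 500, replace = TRUE)
  tab <- composition_table(ds)
  sums <- tapply(tab$percent, tab$condition, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # hand-counted case: 40 microglia of 400 sham cells is 10%
  ds$cell_type <- c(rep("Microglia", 40), rep("Neuron", 360), rep("Microglia", 100))
  tab2 <- composition_table(ds)
  expect_equal(tab2$percent[tab2$condition == "sham" & tab2$cell_type == "Microglia"], 10)
  # single type: 100% everywhere
  ds$cell_type <- rep("Microglia", 500)
  expect_true(all(composition_table(ds)$percent == 100))
})
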