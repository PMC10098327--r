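# Shared-nearest-neighbor graph + Louvain community detection.
# This is the single clustering contract used both for expression-space
# clustering (preprocess) and transition-space clustering (scstar).

# k-nearest-neighbor index matrix (self excluded) by exact search
knn_index <- function(emb, k) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# SNN graph with Jaccard edge weights over the kNN neighborhoods
# (neighborhoods include the cell itself); edges pruned below `prune`.
snn_graph <- function(emb, k_neighbors = 20L, prune = 1 / 15) {
  n <- nrow(emb)
  if (n < 3L) stop_named("at least 3 cells are required for clustering")
  k <- k_neighbors
  if (k > n - 1L) {
    warn_named("k_neighbors (%d) exceeds n-1; using %d", k, n - 1L)
    k <- n - 1L
  }
  nn <- knn_index(emb, k)
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                            j = as.integer(t(cbind(seq_len(n), nn))),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)          # counts of shared neighbors
  cand <- (a + Matrix::t(a)) > 0           # pairs adjacent in the kNN graph
  sh <- shared * cand
  sh <- methods::as(methods::as(sh, "generalMatrix"), "TsparseMatrix")
  keep <- sh@i < sh@j
  i <- sh@i[keep] + 1L; j <- sh@j[keep] + 1L
  jac <- sh@x[keep] / (2 * (k + 1L) - sh@x[keep])
  ok <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g
}

# Louvain labels on the SNN graph, returned as factor "c1","c2",... ordered
# by decreasing cluster size; deterministic for a fixed seed.
snn_louvain <- function(emb, resolution = 1.0, seed = 0L, k_neighbors = 20L) {
  g <- snn_graph(emb, k_neighbors)
  set.seed(as.integer(seed))
  memb <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  memb <- memb[order(as.integer(names(memb)))]
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  factor(paste0("c", relabel[as.character(memb)]),
         levels = paste0("c", seq_along(sizes)))
}

# Adjusted Rand index between two labelings (used by tests and reports)
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same cells, corrected for
#' chance; 1 means identical partitions, 0 the expected value under
#' independent random labelings.
#'
#' @param a,b two label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
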