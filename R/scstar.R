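#' State-transition analysis parameters
#'
#' @param n_components PLS latent components (capped at the data rank).
#' @param pairing_k nearest neighbors used to build pseudo-partners.
#' @param gene_filter_min_cv multiplier on the mean-CV-trend baseline in
#'   [filter_genes_adaptive()]; genes with CV above `min_cv * baseline` are
#'   kept. 0 keeps every non-constant gene.
#' @param assign_alpha hypergeometric significance level for assigning
#'   transition clusters to conditions.
#' @param cluster_resolution resolution for transition-space clustering;
#'   the default (0.3) targets the coarse separation between transitioning
#'   and stable cell states rather than fine substructure.
#' @param n_pcs components for the joint and transition-space PCA.
#' @param seed integer seed for the clustering stage.
#' @return list of class `scstar_params`.
#' @export
scstar_params <- function(n_components = 10L, pairing_k = 5L,
                          gene_filter_min_cv = 0.8, assign_alpha = 0.05,
                          cluster_resolution = 0.3, n_pcs = 30L, seed = 0L) {
  p <- list(n_components = as.integer(n_components), pairing_k = as.integer(pairing_k),
            gene_filter_min_cv = gene_filter_min_cv, assign_alpha = assign_alpha,
            cluster_resolution = cluster_resolution, n_pcs = as.integer(n_pcs),
            seed = as.integer(seed))
  if (p$n_components < 1L) stop_named("n_components must be >= 1")
  if (p$assign_alpha <= 0 || p$assign_alpha >= 1) stop_named("assign_alpha must lie in (0,1)")
  if (p$pairing_k < 1L) stop_named("pairing_k must be >= 1")
  class(p) <- "scstar_params"
  p
}

#' Adaptive coefficient-of-variation gene filter
#'
#' Keeps genes whose coefficient of variation (sd/mean of the normalized
#' values) exceeds `min_cv` times a baseline fitted on the mean-CV trend
#' (median CV within 20 equal-frequency mean-expression bins). Constant
#' genes are always removed; `min_cv = 0` keeps every non-constant gene.
#' Deterministic.
#'
#' @param lognorm cells x genes normalized matrix.
#' @param params an [scstar_params] (uses `gene_filter_min_cv`).
#' @param n_bins number of mean-expression bins for the trend.
#' @return Logical per-gene mask.
#' @export
filter_genes_adaptive <- function(lognorm, params = scstar_params(), n_bins = 20L) {
  mo <- sparse_gene_moments(Matrix::Matrix(lognorm, sparse = TRUE))
  cv <- ifelse(mo$mean > 0 & mo$var > 0, sqrt(mo$var) / mo$mean, 0)
  breaks <- unique(stats::quantile(mo$mean, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) < 2) factor(rep(1L, length(cv)))
         else cut(mo$mean, breaks = breaks, include.lowest = TRUE)
  baseline <- stats::ave(cv, bin, FUN = stats::median)
  mask <- cv > params$gene_filter_min_cv * baseline & cv > 0
  if (!any(mask))
    stop_named("the adaptive filter removed every gene; relax gene_filter_min_cv")
  mask
}

#' Build real-virtual pseudo-pairs across two condition groups
#'
#' Cells of the two conditions are unpaired; each A cell is coupled with a
#' pseudo-partner profile equal to the mean of its `pairing_k` nearest B
#' cells in a joint PCA embedding of both groups (and symmetrically for B
#' cells). With `pairing_k = |B|` every A cell is paired with the B
#' centroid.
#'
#' @param group_a,group_b cells x genes matrices on a shared gene space.
#' @param pairing_k nearest-neighbor count (capped at the partner group
#'   size with a warning).
#' @param n_pcs dimensionality of the joint PCA used for matching.
#' @return list with `a` and `b`, each holding `x` (real profiles) and `y`
#'   (pseudo-partner profiles in the other condition's space).
#' @export
build_pseudo_pairs <- function(group_a, group_b, pairing_k = 5L, n_pcs = 30L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (!nrow(group_a) || !nrow(group_b)) stop_named("both groups must be non-empty")
  if (ncol(group_a) != ncol(group_b)) stop_named("groups must share one gene space")
  k <- pairing_k
  if (k > min(nrow(group_a), nrow(group_b))) {
    k <- min(nrow(group_a), nrow(group_b))
    warn_named("pairing_k capped at the smaller group size (%d)", k)
  }
  joint <- rbind(group_a, group_b)
  d <- min(n_pcs, dim(joint) - 1L)
  emb <- pca_scores(joint, max(1L, d))$scores
  ea <- emb[seq_len(nrow(group_a)), , drop = FALSE]
  eb <- emb[nrow(group_a) + seq_len(nrow(group_b)), , drop = FALSE]
  partner_means <- function(from_emb, to_emb, to_profiles) {
    cross <- outer(rowSums(from_emb^2), rowSums(to_emb^2), "+") -
      2 * tcrossprod(from_emb, to_emb)
    t(apply(cross, 1, function(r) {
      nn <- order(r)[seq_len(k)]
      colMeans(to_profiles[nn, , drop = FALSE])
    }))
  }
  list(a = list(x = group_a, y = partner_means(ea, eb, group_b)),
       b = list(x = group_b, y = partner_means(eb, ea, group_a)),
       pairing_k = k)
}

#' Compute per-cell state-transition profiles between two conditions
#'
#' Builds pseudo-pairs, fits the dual PLS model, projects every cell into
#' the counterpart condition's space and returns the real-virtual
#' differences. A cells contribute virtual minus real (A to B direction);
#' B cells contribute real minus virtual, so both groups express the same
#' A-to-B direction. Variation shared by both groups (e.g. cell-type
#' structure) cancels in these differences, which is what lets a small
#' condition effect emerge from under much larger cell-type heterogeneity.
#'
#' @param group_a,group_b cells x genes matrices (filtered gene space),
#'   with rownames used as cell identifiers.
#' @param params an [scstar_params].
#' @return An object of class `state_transition_set`: `cells`,
#'   `transition` (cells x genes), `condition_of_origin`, `model`.
#' @export
state_transition_matrix <- function(group_a, group_b, params = scstar_params()) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  pairs <- build_pseudo_pairs(group_a, group_b, params$pairing_k, params$n_pcs)
  model <- fit_dual_pls(pairs, params)
  virt_a <- project_virtual(group_a, model, "ab")
  virt_b <- project_virtual(group_b, model, "ba")
  trans <- rbind(virt_a - group_a, group_b - virt_b)
  cells <- c(rownames(group_a) %||% paste0("a", seq_len(nrow(group_a))),
             rownames(group_b) %||% paste0("b", seq_len(nrow(group_b))))
  rownames(trans) <- cells
  virt <- rbind(virt_a, virt_b)
  rownames(virt) <- cells
  structure(list(
    cells = cells,
    transition = trans,
    real = rbind(group_a, group_b),
    virtual = virt,
    condition_of_origin = rep(c("A", "B"), c(nrow(group_a), nrow(group_b))),
    transition_cluster = NULL, assignment = NULL, marker_genes = NULL,
    model = model
  ), class = "state_transition_set")
}

#' @export
print.state_transition_set <- function(x, ...) {
  cat(sprintf("state_transition_set: %d cells x %d genes\n",
              nrow(x$transition), ncol(x$transition)))
  if (!is.null(x$transition_cluster))
    cat("clusters:", paste(levels(x$transition_cluster), collapse = ", "), "\n")
  if (!is.null(x$assignment)) {
    lab <- attr(x$assignment, "cluster_labels")
    for (cl in names(lab)) cat(sprintf("  %s -> %s\n", cl, lab[[cl]]))
  }
  invisible(x)
}

#' Cluster cells on their state-transition profiles
#'
#' Applies the same SNN + Louvain contract as [cluster_cells()] to the PCA
#' embedding of the transition matrix.
#'
#' @param st a [state_transition_matrix()] result.
#' @param resolution community-detection resolution.
#' @param seed integer seed.
#' @param n_pcs embedding dimensionality.
#' @param k_neighbors SNN neighborhood size.
#' @return The set with `transition_cluster` set.
#' @export
cluster_transitions <- function(st, resolution = 0.3, seed = 0L, n_pcs = 30L,
                                k_neighbors = 20L) {
  stopifnot(inherits(st, "state_transition_set"))
  d <- max(1L, min(n_pcs, dim(st$transition) - 1L))
  emb <- pca_scores(st$transition, d)$scores
  st$transition_cluster <- snn_louvain(emb, resolution = resolution, seed = seed,
                                       k_neighbors = k_neighbors)
  st
}

#' Assign transition clusters to conditions by hypergeometric test
#'
#' For cluster k and condition c with x cells of c inside k, N cells in
#' total, K cells of c and n cells in k, the enrichment p-value is
#' P(X >= x) for X ~ Hypergeometric(N, K, n). A cluster is assigned every
#' condition with p < alpha; a cluster significant for no condition is
#' labelled "stable".
#'
#' @param st a clustered [state_transition_matrix()] result.
#' @param alpha significance level (default 0.05).
#' @return The set with `assignment` (data.frame: cluster, condition, x,
#'   n, K, N, p, assigned) and per-cluster labels in
#'   `attr(assignment, "cluster_labels")`.
#' @export
assign_clusters_to_conditions <- function(st, alpha = 0.05) {
  stopifnot(inherits(st, "state_transition_set"))
  if (is.null(st$transition_cluster)) stop_named("cluster_transitions must be run first")
  cl <- as.character(st$transition_cluster)
  cond <- as.character(st$condition_of_origin)
  N <- length(cl)
  rows <- expand.grid(cluster = sort(unique(cl)), condition = sort(unique(cond)),
                      stringsAsFactors = FALSE)
  rows$x <- mapply(function(k, c) sum(cl == k & cond == c), rows$cluster, rows$condition)
  rows$n <- vapply(rows$cluster, function(k) sum(cl == k), numeric(1))
  rows$K <- vapply(rows$condition, function(c) sum(cond == c), numeric(1))
  rows$N <- N
  rows$p <- hypergeom_upper_tail(rows$x, rows$N, rows$K, rows$n)
  rows$assigned <- rows$p < alpha
  labels <- lapply(split(rows, rows$cluster), function(d) {
    if (any(d$assigned)) d$condition[d$assigned] else "stable"
  })
  attr(rows, "cluster_labels") <- labels
  st$assignment <- rows
  st
}

#' Upper-tail hypergeometric probability P(X >= x)
#'
#' X ~ Hypergeometric(N, K, n): x successes drawn in n draws from a
#' population of N with K successes.
#'
#' @param x observed overlap (vectorized).
#' @param N population size.
#' @param K successes in the population.
#' @param n draws.
#' @return P(X >= x).
#' @export
hypergeom_upper_tail <- function(x, N, K, n) {
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-gene log fold change of a cell group's state transition
#'
#' Summarizes a set of cells' real-virtual pairs as a natural-log fold
#' change on the (de-logged) normalized-count scale: for each gene,
#' log of the mean inverse-log1p expression across the later-condition
#' profiles minus the same for the earlier-condition profiles, oriented in
#' the A-to-B direction. Unlike the raw mean of log1p-scale transition
#' values, this is expressed in the same units as a log-scale shift in
#' expected counts, so a planted log-e shift of 1 is recovered as 1
#' regardless of a gene's expression level.
#'
#' @param st a [state_transition_matrix()] result.
#' @param cells logical or index vector selecting the cells to summarize
#'   (default all).
#' @param eps pseudo-value guarding the log for genes with near-zero mean.
#' @return Named numeric vector, one log-e fold change per gene.
#' @export
transition_log_foldchange <- function(st, cells = NULL, eps = 0.05) {
  stopifnot(inherits(st, "state_transition_set"))
  if (is.null(cells)) cells <- seq_along(st$cells)
  real <- st$real[cells, , drop = FALSE]
  virt <- st$virtual[cells, , drop = FALSE]
  is_a <- (st$condition_of_origin == st$condition_of_origin[1])[cells]
  # orient every pair A -> B: for A cells the virtual profile is the later
  # state, for B cells the real profile is
  later <- rbind(virt[is_a, , drop = FALSE], real[!is_a, , drop = FALSE])
  earlier <- rbind(real[is_a, , drop = FALSE], virt[!is_a, , drop = FALSE])
  m_later <- pmax(colMeans(expm1(later)), 0)
  m_earlier <- pmax(colMeans(expm1(earlier)), 0)
  lfc <- log(m_later + eps) - log(m_earlier + eps)
  names(lfc) <- colnames(st$transition)
  lfc
}

#' Rank cluster marker genes by Wilcoxon rank-sum test
#'
#' Each gene is tested two-sided (in-cluster values vs all other cells);
#' p-values are Bonferroni-adjusted over the genes tested and the
#' significant set is adjusted p < 0.05. Rows are ranked by effect (mean
#' in-cluster minus mean rest, descending) then p then gene name.
#'
#' @param values cells x genes matrix (log-normalized expression or
#'   transition profiles).
#' @param clusters per-cell cluster labels.
#' @param cluster the cluster to characterize (size >= 2 required).
#' @return data.frame: gene, effect, p, p_adj, significant.
#' @export
find_cluster_markers <- function(values, clusters, cluster) {
  values <- as.matrix(values)
  in_cl <- as.character(clusters) == as.character(cluster)
  if (sum(in_cl) < 2L) stop_named("cluster '%s' has fewer than 2 cells", cluster)
  if (sum(!in_cl) < 2L) stop_named("fewer than 2 cells outside cluster '%s'", cluster)
  genes <- colnames(values) %||% paste0("g", seq_len(ncol(values)))
  p <- vapply(seq_len(ncol(values)), function(j) {
    a <- values[in_cl, j]; b <- values[!in_cl, j]
    if (max(values[, j]) == min(values[, j])) return(1)
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
  }, numeric(1))
  effect <- colMeans(values[in_cl, , drop = FALSE]) -
    colMeans(values[!in_cl, , drop = FALSE])
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(gene = genes, effect = unname(effect), p = p, p_adj = p_adj,
                    significant = p_adj < 0.05, stringsAsFactors = FALSE)
  out[order(-out$effect, out$p, out$gene), , drop = FALSE]
}

#' Run the full state-transition analysis for one condition pair
#'
#' Subsets the dataset to the two conditions, applies the adaptive CV gene
#' filter, computes the dual-PLS state-transition matrix, clusters the
#' transition profiles, assigns clusters to conditions and ranks marker
#' genes per cluster.
#'
#' @param dataset a log-normalized [cell_dataset].
#' @param condition_a,condition_b the two condition labels (A is the
#'   reference; transitions express the A-to-B direction).
#' @param params an [scstar_params].
#' @return A [state_transition_matrix()] set with clusters, assignments
#'   and `marker_genes` filled in.
#' @export
run_scstar <- function(dataset, condition_a, condition_b, params = scstar_params()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(dataset$lognorm)) stop_named("log_normalize must be run before run_scstar")
  for (cc in c(condition_a, condition_b))
    if (!cc %in% dataset$condition) stop_named("condition '%s' has no cells", cc)
  sel <- dataset$condition %in% c(condition_a, condition_b)
  sub <- subset_cells(dataset, which(sel))
  mask <- filter_genes_adaptive(sub$lognorm, params)
  m <- as.matrix(sub$lognorm[, mask, drop = FALSE])
  is_a <- sub$condition == condition_a
  st <- state_transition_matrix(m[is_a, , drop = FALSE], m[!is_a, , drop = FALSE], params)
  st$condition_of_origin <- ifelse(c(rep(TRUE, sum(is_a)), rep(FALSE, sum(!is_a))),
                                   condition_a, condition_b)
  st <- cluster_transitions(st, resolution = params$cluster_resolution,
                            seed = params$seed, n_pcs = params$n_pcs)
  st <- assign_clusters_to_conditions(st, alpha = params$assign_alpha)
  st$marker_genes <- lapply(
    stats::setNames(nm = levels(st$transition_cluster)),
    function(cl) {
      n_in <- sum(st$transition_cluster == cl)
      if (n_in < 2L || nrow(st$transition) - n_in < 2L) return(NULL)
      find_cluster_markers(st$transition, st$transition_cluster, cl)
    })
  st$gene_mask <- mask
  st
}

#' Rerun the transition analysis with groups defined by a gene's expression
#'
#' Cells are split into gene-positive (raw count > 0) and gene-negative
#' groups; the transition analysis is rerun between the two groups and the
#' cluster-versus-positivity and cluster-versus-condition contingency
#' matrices are attached.
#'
#' @param dataset a log-normalized [cell_dataset].
#' @param gene gene symbol defining positivity.
#' @param params an [scstar_params].
#' @return A state-transition set with `contingency` (list of two
#'   matrices: `positivity`, `condition`).
#' @export
gene_partition_run <- function(dataset, gene, params = scstar_params()) {
  stopifnot(inherits(dataset, "cell_dataset"))
  j <- match(gene, dataset$gene_names)
  if (is.na(j)) stop_named("gene '%s' is absent from the dataset", gene)
  positive <- as.numeric(dataset$counts[, j]) > 0
  if (!any(positive)) stop_named("gene '%s' is expressed in zero cells", gene)
  if (all(positive)) stop_named("gene '%s' is expressed in every cell; no negative group", gene)
  if (is.null(dataset$lognorm)) stop_named("log_normalize must be run before gene_partition_run")
  mask <- filter_genes_adaptive(dataset$lognorm, params)
  m <- as.matrix(dataset$lognorm[, mask, drop = FALSE])
  st <- state_transition_matrix(m[!positive, , drop = FALSE],
                                m[positive, , drop = FALSE], params)
  neg_lab <- paste0(gene, "-"); pos_lab <- paste0(gene, "+")
  st$condition_of_origin <- c(rep(neg_lab, sum(!positive)), rep(pos_lab, sum(positive)))
  st <- cluster_transitions(st, resolution = params$cluster_resolution,
                            seed = params$seed, n_pcs = params$n_pcs)
  st <- assign_clusters_to_conditions(st, alpha = params$assign_alpha)
  ord <- c(which(!positive), which(positive))
  st$contingency <- list(
    positivity = table(cluster = st$transition_cluster,
                       positivity = st$condition_of_origin),
    condition = table(cluster = st$transition_cluster,
                      condition = dataset$condition[ord]))
  st
}
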