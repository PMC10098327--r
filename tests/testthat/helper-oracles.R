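# Independent brute-force oracles used across the suite. These never call
# the package's own code paths for the quantity they check.

# exact hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_upper <- function(x, N, K, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- max(0, x):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# all-pairs shortest-path distances and path counts by dynamic programming
# on an adjacency matrix (no igraph)
oracle_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (t in which(d[s, ] == dist)) {
        pred <- which(adj[, t] == 1 & d[s, ] == dist - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  list(d = d, sigma = sigma)
}

# normalized degree, betweenness and component-corrected closeness by
# exhaustive shortest-path accounting
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  sp <- oracle_paths(adj)
  deg <- rowSums(adj) / (n - 1)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(sp$d[s, t]) || sp$sigma[s, t] == 0) next
      if (sp$d[s, v] + sp$d[v, t] == sp$d[s, t])
        tot <- tot + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
    }
    btw[v] <- if (n > 2) tot / ((n - 1) * (n - 2) / 2) else 0
  }
  clo <- vapply(seq_len(n), function(v) {
    fin <- sp$d[v, is.finite(sp$d[v, ])]
    reach <- length(fin)
    if (reach < 2) return(0)
    ((reach - 1) / (n - 1)) * ((reach - 1) / sum(fin))
  }, numeric(1))
  data.frame(degree_c = deg, betweenness_c = btw, closeness_c = clo)
}

# exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled values into the two groups (distinct values assumed)
oracle_wilcox_two_sided <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# igraph from a 0/1 adjacency matrix with letter names
graph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}
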