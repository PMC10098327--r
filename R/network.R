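#' Read a STRING-style edge list into a PPI graph
#'
#' Accepts a TSV with two node columns and a combined-score column on the
#' STRING 0-1000 scale (header auto-detected: columns named like node1,
#' node2, combined_score are used when present, otherwise the first two
#' and the last column). Edges with score >= `min_combined_score` are
#' kept (inclusive, matching the "medium confidence 0.4" convention);
#' duplicate pairs are collapsed keeping the maximum score and self-loops
#' are dropped.
#'
#' @param path TSV path.
#' @param min_combined_score score threshold on the 0-1000 scale
#'   (default 400).
#' @return An undirected [igraph::igraph] with edge attribute `score`.
#' @export
read_edge_list <- function(path, min_combined_score = 400) {
  if (min_combined_score < 0 || min_combined_score > 1000)
    stop_named("min_combined_score must lie in [0, 1000]")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn_named("empty edge file: %s", path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[length(first)])))
  idx <- c(1L, 2L, length(first))
  if (has_header) {
    known <- match(c("node1", "node2", "combined_score"), tolower(trimws(first)))
    if (!anyNA(known)) idx <- known
    fields <- fields[-1]
  }
  start_line <- if (has_header) 2L else 1L
  edges <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    score <- suppressWarnings(as.numeric(f[idx[3]]))
    if (length(f) < max(idx) || is.na(score))
      stop_named("malformed row at line %d of %s", i + start_line - 1L, path)
    edges[[i]] <- data.frame(from = trimws(f[idx[1]]), to = trimws(f[idx[2]]),
                             score = score, stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edges)
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  if (nrow(ed)) {
    key <- ifelse(ed$from < ed$to, paste(ed$from, ed$to, sep = "\r"),
                  paste(ed$to, ed$from, sep = "\r"))
    ed <- do.call(rbind, lapply(split(ed, key), function(d) d[which.max(d$score), ]))
  }
  ed <- ed[ed$score >= min_combined_score, , drop = FALSE]
  if (!nrow(ed)) {
    warn_named("no edges at or above score %g in %s", min_combined_score, path)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(ed, directed = FALSE)
}

#' Remove degree-zero nodes
#'
#' @param g an undirected igraph.
#' @return The graph without isolated vertices; edges unchanged.
#' @export
prune_isolated <- function(g) {
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Normalized node centralities
#'
#' Computes, per node and on unweighted shortest paths: degree centrality
#' deg/(N-1); pair-normalized betweenness; and Wasserman-Faust
#' component-corrected closeness ((r-1)/(N-1) * (r-1)/sum(d) over the r
#' reachable nodes), so all three lie in \[0, 1\] even on disconnected
#' graphs.
#'
#' @param g an undirected igraph with at least 2 nodes.
#' @return data.frame: gene, degree_c, betweenness_c, closeness_c.
#' @export
centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop_named("centralities require at least 2 nodes")
  deg <- igraph::degree(g) / (n - 1)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  d <- igraph::distances(g, weights = NA)
  clo <- apply(d, 1, function(r) {
    fin <- r[is.finite(r)]
    reach <- length(fin)          # includes the node itself (distance 0)
    if (reach < 2) return(0)
    ((reach - 1) / (n - 1)) * ((reach - 1) / sum(fin))
  })
  data.frame(gene = igraph::V(g)$name %||% as.character(seq_len(n)),
             degree_c = unname(deg), betweenness_c = unname(btw),
             closeness_c = unname(clo), stringsAsFactors = FALSE)
}

#' Hub-gene ranking by median of centralities
#'
#' Each node's hub score is the median of its normalized degree,
#' betweenness and closeness centralities; nodes are ranked by score
#' (descending) with alphabetical tie-break.
#'
#' @param g an undirected igraph (>= 2 nodes, normally pruned).
#' @return data.frame: gene, degree_c, betweenness_c, closeness_c,
#'   hub_score, rank.
#' @export
hub_score_table <- function(g) {
  ct <- centralities(g)
  ct$hub_score <- apply(ct[, c("degree_c", "betweenness_c", "closeness_c")], 1,
                        stats::median)
  ct <- ct[order(-ct$hub_score, ct$gene), , drop = FALSE]
  ct$rank <- seq_len(nrow(ct))
  rownames(ct) <- NULL
  ct
}

# density of an undirected simple graph
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE node weight: coreness k of the highest k-core of the closed
# neighborhood, times that core's density
mcode_node_weights <- function(g, degree_cutoff = 2L) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == k))
    w[v] <- k * graph_density(core_sub)
  }
  w
}

#' MCODE-style dense-complex detection
#'
#' Nodes are weighted by the density of the highest k-core of their closed
#' neighborhood (times its coreness); complexes grow greedily from
#' unvisited local weight maxima, admitting neighbors whose weight is
#' within `node_score_cutoff` of the seed weight; each complex is then
#' reduced to its `k_core` and to the connected component containing the
#' seed. Complexes are vertex-disjoint and ranked by density times size.
#'
#' @param g an undirected igraph (normally pruned).
#' @param degree_cutoff nodes below this degree are never seeds and carry
#'   zero weight (default 2).
#' @param node_score_cutoff admission band relative to the seed weight
#'   (default 0.2).
#' @param k_core minimum internal degree of a reported complex (default 2).
#' @return list of complexes, each a list with `members` (gene names),
#'   `density`, `score` (density x size), ordered by decreasing score.
#' @export
mcode_complexes <- function(g, degree_cutoff = 2L, node_score_cutoff = 0.2,
                            k_core = 2L) {
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  names_v <- igraph::V(g)$name %||% as.character(seq_len(n))
  w <- mcode_node_weights(g, degree_cutoff)
  visited <- logical(n)
  complexes <- list()
  for (seed in order(-w, names_v)) {
    if (visited[seed] || w[seed] <= 0) next
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    thr <- w[seed] * (1 - node_score_cutoff)
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    keep <- which(core >= k_core)
    if (!length(keep)) next
    sub2 <- igraph::induced_subgraph(sub, keep)
    comp <- igraph::components(sub2)
    seed_name <- names_v[seed]
    seed_pos <- match(seed_name, igraph::V(sub2)$name)
    comp_id <- if (!is.na(seed_pos)) comp$membership[seed_pos] else which.max(comp$csize)
    final <- igraph::induced_subgraph(sub2, which(comp$membership == comp_id))
    if (igraph::vcount(final) < 2) next
    complexes[[length(complexes) + 1L]] <- list(
      members = sort(igraph::V(final)$name),
      density = graph_density(final),
      score = graph_density(final) * igraph::vcount(final))
  }
  complexes[order(-vapply(complexes, `[[`, numeric(1), "score"))]
}
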