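#' Gene-set collection
#'
#' Named gene sets (with optional descriptions) plus a symbol universe,
#' used for local over-representation analysis in place of web enrichment
#' services. Symbols are matched case-insensitively.
#'
#' @param sets named list of character vectors (duplicates within a set
#'   collapsed; empty sets rejected).
#' @param descriptions optional character vector parallel to `sets`.
#' @param universe optional symbol universe; defaults to the union of all
#'   set members.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_named("sets must be a non-empty named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(!lengths(sets))) stop_named("gene sets must be non-empty")
  structure(list(sets = sets,
                 descriptions = descriptions %||% stats::setNames(rep("", length(sets)), names(sets)),
                 universe = unique(as.character(universe %||% unlist(sets, use.names = FALSE)))),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, fields name TAB description TAB gene...
#' Lines with fewer than three fields are an error (reported with the line
#' number); duplicate genes within a set are collapsed.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  line_no <- which(keep)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_named("GMT line %d has fewer than 3 fields", line_no[bad[1]])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), names(sets))
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Multiple-testing correction
#'
#' `bonferroni`: min(1, m * p); `bh`: Benjamini-Hochberg step-up with
#' monotonicity enforcement. Output order matches input order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method "bonferroni" or "bh".
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_named("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Hypergeometric over-representation analysis
#'
#' For each set: k = |query intersect set|, n = |query|, K = |set|, N =
#' |universe|, all after harmonization to the universe; p = P(X >= k) for
#' X ~ Hypergeometric(N, K, n). Query genes outside the universe are
#' dropped with a warning. Rows are ranked by p (ties by set name).
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection].
#' @param universe optional universe override.
#' @param method multiple-testing correction ("bonferroni" or "bh").
#' @return data.frame of class `enrichment_result`: set, k, n, K, N, p,
#'   p_adj, overlap (semicolon-joined gene symbols).
#' @export
ora_hypergeometric <- function(query, collection, universe = NULL,
                               method = c("bonferroni", "bh")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  method <- match.arg(method)
  uni <- normalize_symbols(unique(universe %||% collection$universe))
  q <- unique(normalize_symbols(query))
  outside <- setdiff(q, uni)
  if (length(outside))
    warn_named("%d query gene(s) outside the universe dropped (e.g. %s)",
               length(outside), utils::head(outside, 3)[1])
  q <- intersect(q, uni)
  if (!length(q)) stop_named("no query genes remain inside the universe")
  N <- length(uni); n <- length(q)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(normalize_symbols(collection$sets[[nm]]), uni)
    ov <- intersect(q, s)
    data.frame(set = nm, k = length(ov), n = n, K = length(s), N = N,
               p = hypergeom_upper_tail(length(ov), N, length(s), n),
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, method)
  out <- out[order(out$p, out$set), c("set", "k", "n", "K", "N", "p", "p_adj", "overlap")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Per-complex enrichment report for MCODE complexes
#'
#' Runs over-representation analysis for each complex's member list
#' (optionally with one extra anchor gene added, e.g. Itgb2, mirroring
#' pathway analysis of complexes together with a hub gene of interest) and
#' reports the top terms by p-value with an FDR < 0.05 flag.
#'
#' @param complexes list from [mcode_complexes()].
#' @param collection a [gene_set_collection].
#' @param anchor_gene optional gene symbol added to every query (adding it
#'   is idempotent when already present).
#' @param universe optional universe override.
#' @param top number of top terms reported per complex (default 3).
#' @param method multiple-testing correction (default "bh", an FDR).
#' @return Named list (complex_1, complex_2, ...) of
#'   [ora_hypergeometric()] tables truncated to `top` rows; complexes with
#'   no genes in the universe are skipped with a warning.
#' @export
mcode_term_report <- function(complexes, collection, anchor_gene = NULL,
                              universe = NULL, top = 3L,
                              method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  uni <- normalize_symbols(unique(universe %||% collection$universe))
  out <- list()
  for (i in seq_along(complexes)) {
    query <- complexes[[i]]$members
    if (!is.null(anchor_gene)) query <- union(query, anchor_gene)
    if (!length(intersect(normalize_symbols(query), uni))) {
      warn_named("complex %d has no genes in the universe; skipped", i)
      next
    }
    res <- suppressWarnings(
      ora_hypergeometric(query, collection, universe = universe, method = method))
    res$significant <- res$p_adj < 0.05
    out[[paste0("complex_", i)]] <- utils::head(res, top)
  }
  out
}
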