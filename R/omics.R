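#' Differential table
#'
#' A data.frame of gene-level differential statistics with columns `gene`,
#' `log2fc` and `p`, tagged with its source assay (`rna` or `protein`).
#' Gene symbols must be unique within a table and p-values must lie in
#' \[0, 1\].
#'
#' @param df data.frame with columns gene, log2fc, p (extra columns kept).
#' @param source assay label, `"rna"` or `"protein"`.
#' @return The data.frame with class `diff_table` and a `source` attribute.
#' @export
diff_table <- function(df, source = c("rna", "protein")) {
  source <- match.arg(source)
  missing_cols <- setdiff(c("gene", "log2fc", "p"), names(df))
  if (length(missing_cols))
    stop_named("diff_table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(normalize_symbols(df$gene)))
    stop_named("duplicate gene symbols in diff_table")
  if (any(df$p < 0 | df$p > 1, na.rm = TRUE))
    stop_named("p-values must lie in [0, 1]")
  structure(df, class = c("diff_table", "data.frame"), source = source)
}

#' Read a differential table from TSV
#'
#' @param path TSV with header columns gene, log2fc, p (a `p_col` can remap
#'   an adjusted-p column onto `p`).
#' @param source assay label.
#' @param p_col name of the column to use as the p-value (default "p").
#' @return A [diff_table].
#' @export
read_diff_table <- function(path, source = c("rna", "protein"), p_col = "p") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (p_col != "p") {
    if (!p_col %in% names(df)) stop_named("column '%s' not found in %s", p_col, path)
    df$p <- df[[p_col]]
  }
  diff_table(df, source = match.arg(source))
}

#' Filter a differential table on effect size and significance
#'
#' Retains rows with |log2FC| >= `min_abs_lfc` (inclusive) and p <
#' `max_p` (strict), preserving row order. Idempotent.
#'
#' @param table a [diff_table].
#' @param min_abs_lfc minimum absolute log2 fold change (default 1).
#' @param max_p strict p-value cutoff (default 0.05).
#' @return The filtered [diff_table].
#' @export
filter_degs <- function(table, min_abs_lfc = 1, max_p = 0.05) {
  stopifnot(inherits(table, "diff_table"))
  keep <- abs(table$log2fc) >= min_abs_lfc & table$p < max_p
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  structure(out, class = class(table), source = attr(table, "source"))
}

#' Intersect two (filtered) differential tables
#'
#' Gene symbols are matched case-insensitively after whitespace stripping
#' (mouse gene symbols and protein accessions often differ in case); an
#' optional alias map is applied first. Output rows are in deterministic
#' alphabetical order of the matched symbol and carry both tables'
#' statistics.
#'
#' @param a,b two [diff_table] objects (normally already through
#'   [filter_degs()]).
#' @param aliases optional named character vector mapping alternative
#'   symbols to canonical ones.
#' @return data.frame with columns gene, log2fc_a, p_a, log2fc_b, p_b.
#' @export
intersect_degs <- function(a, b, aliases = NULL) {
  stopifnot(inherits(a, "diff_table"), inherits(b, "diff_table"))
  canon <- function(x) {
    x <- normalize_symbols(x)
    if (!is.null(aliases)) {
      m <- match(x, normalize_symbols(names(aliases)))
      x[!is.na(m)] <- normalize_symbols(aliases)[m[!is.na(m)]]
    }
    x
  }
  ka <- canon(a$gene); kb <- canon(b$gene)
  shared <- sort(intersect(ka, kb))
  ia <- match(shared, ka); ib <- match(shared, kb)
  data.frame(gene = a$gene[ia],
             log2fc_a = a$log2fc[ia], p_a = a$p[ia],
             log2fc_b = b$log2fc[ib], p_b = b$p[ib],
             stringsAsFactors = FALSE)
}
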