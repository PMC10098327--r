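#' Simulation configuration
#'
#' Parameters of the synthetic single-cell generator. The generator plants a
#' condition-driven expression shift inside one cell subpopulation of a
#' multi-cell-type mixture, so that the shift is masked by the (much larger)
#' cell-type heterogeneity — the scenario the state-transition analysis is
#' designed to resolve.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_condition named integer vector, cells per condition;
#'   the first name is treated as the reference (sham-like) condition.
#' @param n_cell_types number of cell types mixed into every condition.
#' @param cell_type_effect_scale magnitude (natural-log scale) of the sparse
#'   per-type signature shifts; the default is five times `transition_effect`
#'   so that type heterogeneity dominates the planted condition effect.
#' @param transition_genes integer indices (1-based) of the genes carrying
#'   the planted condition shift.
#' @param transition_effect natural-log shift added on `transition_genes` in
#'   affected cells.
#' @param affected_fraction fraction of cells of the designated (condition,
#'   cell type) pair that carry the shift.
#' @param affected_condition condition receiving the shift; default the
#'   second condition listed.
#' @param affected_cell_type index of the cell type receiving the shift.
#' @param mito_gene_fraction fraction of genes labelled mitochondrial
#'   (symbols get an "mt-" prefix); their total abundance is calibrated so
#'   the expected per-cell mitochondrial UMI fraction equals this value.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param library_size_mean mean per-cell library size (UMIs); per-cell
#'   sizes are log-normal around it.
#' @param seed integer seed; identical config + seed gives identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       n_cells_per_condition = c(sham = 1000L, day1 = 1000L),
                       n_cell_types = 2L,
                       cell_type_effect_scale = 5,
                       transition_genes = 1:40,
                       transition_effect = 1,
                       affected_fraction = 0.5,
                       affected_condition = NULL,
                       affected_cell_type = 1L,
                       mito_gene_fraction = 0.05,
                       nb_dispersion = 0.2,
                       library_size_mean = 10000,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_condition = n_cells_per_condition,
              n_cell_types = as.integer(n_cell_types),
              cell_type_effect_scale = cell_type_effect_scale,
              transition_genes = as.integer(transition_genes),
              transition_effect = transition_effect,
              affected_fraction = affected_fraction,
              affected_condition = affected_condition %||% names(n_cells_per_condition)[2],
              affected_cell_type = as.integer(affected_cell_type),
              mito_gene_fraction = mito_gene_fraction,
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_cell_types < 1L || any(cfg$n_cells_per_condition < 1L))
    stop_named("all counts in the simulation config must be >= 1")
  if (is.null(names(cfg$n_cells_per_condition)) || any(!nzchar(names(cfg$n_cells_per_condition))))
    stop_named("n_cells_per_condition must be a named vector of conditions")
  if (cfg$affected_fraction < 0 || cfg$affected_fraction > 1)
    stop_named("affected_fraction must lie in [0,1]")
  if (cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction > 1)
    stop_named("mito_gene_fraction must lie in [0,1]")
  if (length(cfg$transition_genes) &&
      (min(cfg$transition_genes) < 1L || max(cfg$transition_genes) > cfg$n_genes))
    stop_named("transition_genes indices must lie in [1, n_genes]")
  if (!length(cfg$transition_genes) && cfg$transition_effect != 0)
    stop_named("transition_effect != 0 requires a non-empty transition_genes set")
  if (cfg$nb_dispersion <= 0 || cfg$library_size_mean <= 0 || cfg$cell_type_effect_scale < 0)
    stop_named("dispersion, library size and effect scale must be positive")
  if (!cfg$affected_condition %in% names(cfg$n_cells_per_condition))
    stop_named("affected_condition '%s' is not a listed condition", cfg$affected_condition)
  if (cfg$affected_cell_type < 1L || cfg$affected_cell_type > cfg$n_cell_types)
    stop_named("affected_cell_type out of range")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-condition single-cell UMI counts with a planted transition
#'
#' Counts are negative binomial around a per-cell mean built from (i) a
#' log-normal gene abundance baseline, (ii) a sparse cell-type signature of
#' scale `cell_type_effect_scale`, (iii) the planted shift
#' `transition_effect` on `transition_genes` for affected cells, and (iv) a
#' log-normal per-cell library-size factor. Mitochondrial genes (symbols
#' "mt-*") are calibrated so their expected UMI share equals
#' `mito_gene_fraction`. The planted shift is an exact natural-log change in
#' expected counts, so log mean-count differences between affected cells and
#' matched unaffected cells of the same type converge to the shift.
#'
#' @param config a [sim_config].
#' @return list with `dataset` (a [cell_dataset]) and `truth` (list:
#'   `cell_type_labels`, `affected_cell_mask`, `planted_shift_vector`,
#'   `affected_condition`, `affected_cell_type`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  n_mito <- floor(config$mito_gene_fraction * G)
  mito_idx <- if (n_mito > 0) seq.int(G - n_mito + 1L, G) else integer(0)
  gene_names <- sprintf("G%04d", seq_len(G))
  gene_names[mito_idx] <- sprintf("mt-G%04d", mito_idx)

  mu <- stats::rnorm(G, 0, 1)

  # sparse per-type signatures; never on mitochondrial genes (keeps the
  # mito-fraction calibration valid across types) and never on transition
  # genes (a signature on a shifted gene would inflate affected cells'
  # expected library size, leaking the planted effect into every gene's
  # relative expression instead of keeping it confined to transition_genes)
  sig <- matrix(0, nrow = config$n_cell_types, ncol = G)
  eligible <- setdiff(seq_len(G), c(mito_idx, config$transition_genes))
  n_sig <- max(1L, floor(0.2 * length(eligible)))
  for (t in seq_len(config$n_cell_types)) {
    gs <- sample(eligible, n_sig)
    sig[t, gs] <- sample(c(-1, 1), n_sig, replace = TRUE) *
      stats::runif(n_sig, 0.5, 1) * config$cell_type_effect_scale
  }

  if (n_mito > 0) {
    # calibrate mitochondrial abundance so the expected mitochondrial UMI
    # share (averaged over cell types, signatures included) matches the
    # requested fraction
    other <- mean(vapply(seq_len(config$n_cell_types), function(t)
      sum(exp((mu + sig[t, ])[-mito_idx])), numeric(1)))
    target <- config$mito_gene_fraction / (1 - config$mito_gene_fraction) * other
    mu[mito_idx] <- mu[mito_idx] + log(target / sum(exp(mu[mito_idx])))
  }

  shift <- numeric(G)
  shift[config$transition_genes] <- config$transition_effect

  conds <- names(config$n_cells_per_condition)
  condition <- rep(conds, times = config$n_cells_per_condition)
  n_cells <- length(condition)
  cell_type <- unlist(lapply(config$n_cells_per_condition, function(n)
    sample(rep_len(seq_len(config$n_cell_types), n))), use.names = FALSE)

  affected <- rep(FALSE, n_cells)
  pool <- which(condition == config$affected_condition &
                  cell_type == config$affected_cell_type)
  if (length(pool) && config$affected_fraction > 0 && config$transition_effect != 0) {
    n_aff <- round(config$affected_fraction * length(pool))
    affected[sample(pool, n_aff)] <- TRUE
  }

  size_factor <- stats::rlnorm(n_cells, meanlog = log(config$library_size_mean) - 0.3^2 / 2,
                               sdlog = 0.3)
  counts <- matrix(0L, nrow = n_cells, ncol = G)
  # normalizing constant per type uses the unshifted signature so the planted
  # shift stays an exact log change in expected counts
  type_norm <- vapply(seq_len(config$n_cell_types),
                      function(t) sum(exp(mu + sig[t, ])), numeric(1))
  for (i in seq_len(n_cells)) {
    lm <- mu + sig[cell_type[i], ]
    if (affected[i]) lm <- lm + shift
    lambda <- size_factor[i] * exp(lm) / type_norm[cell_type[i]]
    counts[i, ] <- stats::rnbinom(G, mu = lambda, size = 1 / config$nb_dispersion)
  }

  barcodes <- sprintf("cell%05d-%s", seq_len(n_cells), condition)
  ds <- cell_dataset(counts, gene_names, barcodes, condition)
  truth <- list(cell_type_labels = paste0("type", cell_type),
                affected_cell_mask = affected,
                planted_shift_vector = shift,
                affected_condition = config$affected_condition,
                affected_cell_type = config$affected_cell_type)
  list(dataset = ds, truth = truth)
}

#' Simulate paired bulk RNA-seq and proteomic differential tables
#'
#' Generates two differential tables (gene, log2fc, p) in which exactly
#' `n_overlap` shared genes pass |log2FC| >= 1 and p < 0.05 in both tables;
#' every other gene fails at least one of the two filters in at least one
#' table where it appears.
#'
#' @param n_bulk,n_prot number of rows in each table.
#' @param n_overlap number of genes passing both filters in both tables;
#'   must not exceed `min(n_bulk, n_prot)`.
#' @param effect_range length-2 numeric, |log2FC| range for passing genes
#'   (lower bound clamped to 1).
#' @param seed integer seed.
#' @return list of two `diff_table` data.frames named `rna` and `protein`.
#' @export
simulate_paired_omics <- function(n_bulk, n_prot, n_overlap,
                                  effect_range = c(1, 3), seed = 1L) {
  if (n_bulk < 0 || n_prot < 0 || n_overlap < 0)
    stop_named("counts must be non-negative")
  if (n_overlap > min(n_bulk, n_prot))
    stop_named("n_overlap (%d) exceeds min(n_bulk, n_prot) = %d",
               n_overlap, min(n_bulk, n_prot))
  set.seed(as.integer(seed))
  lo <- max(1, min(effect_range))
  hi <- max(effect_range)

  pass_lfc <- function(n) sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, lo, hi)
  pass_p <- function(n) stats::runif(n, 1e-6, 0.049)
  fail_row <- function(n) {
    # fail the fold-change filter, the p filter, or both
    mode <- sample(1:3, n, replace = TRUE)
    lfc <- ifelse(mode %in% c(1, 3), stats::runif(n, 0, 0.99), pass_lfc(n))
    p <- ifelse(mode %in% c(2, 3), stats::runif(n, 0.06, 1), pass_p(n))
    data.frame(log2fc = lfc, p = p)
  }

  shared_pass <- sprintf("Shared%04d", seq_len(n_overlap))
  rest_b <- n_bulk - n_overlap
  rest_p <- n_prot - n_overlap
  n_shared_fail <- min(rest_b, rest_p) %/% 2
  shared_fail <- sprintf("Bothfail%04d", seq_len(n_shared_fail))
  uniq_b <- sprintf("Rnaonly%04d", seq_len(rest_b - n_shared_fail))
  uniq_p <- sprintf("Protonly%04d", seq_len(rest_p - n_shared_fail))

  build <- function(src) {
    genes <- c(shared_pass, shared_fail,
               if (src == "rna") uniq_b else uniq_p)
    n_fail <- length(genes) - n_overlap
    fr <- if (n_fail > 0) fail_row(n_fail) else data.frame(log2fc = numeric(0), p = numeric(0))
    df <- data.frame(gene = genes,
                     log2fc = c(pass_lfc(n_overlap), fr$log2fc),
                     p = c(pass_p(n_overlap), fr$p),
                     stringsAsFactors = FALSE)
    diff_table(df, source = src)
  }
  list(rna = build("rna"), protein = build("protein"))
}
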