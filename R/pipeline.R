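default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "stxmicro_out",
    stages = c("simulate", "preprocess", "scstar", "omics", "network", "enrichment"),
    sim = list(n_genes = 500L, n_cells_per_condition = list(sham = 1000L, day1 = 1000L),
               n_cell_types = 2L, cell_type_effect_scale = 5, transition_genes = 1:40,
               transition_effect = 1, affected_fraction = 0.5,
               mito_gene_fraction = 0.05, nb_dispersion = 0.2, library_size_mean = 10000),
    qc = list(min_genes = 200L, max_genes = 3000L, min_cells_per_gene = 3L,
              max_mito = 0.10, n_hvg = 2000L, n_pcs = 30L, resolution = 1.0,
              scale_factor = 1e4),
    scstar = list(n_components = 10L, pairing_k = 5L, gene_filter_min_cv = 0.8,
                  assign_alpha = 0.05, cluster_resolution = 0.3, n_pcs = 30L,
                  reference_condition = NULL, partition_gene = NULL),
    omics = list(rna_file = NULL, prot_file = NULL, n_bulk = 300L, n_prot = 200L,
                 n_overlap = 44L, min_abs_lfc = 1, max_p = 0.05),
    network = list(edges_file = NULL, min_combined_score = 400),
    enrichment = list(gmt_file = NULL, method = "bh")
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with sections `sim`, `qc`, `scstar`, `omics`,
#' `network`, `enrichment` plus top-level `seed`, `out_dir` and `stages`.
#' Missing keys take the documented defaults; unknown keys are rejected
#' by name. An empty file yields the full default configuration
#' (min_genes 200, 2000 HVGs, 30 PCs, resolution 1.0, ...).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path) %||% list()
  merge_section <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop_named("unknown config key '%s' in section '%s'", unknown[1], where)
    base[names(upd)] <- upd
    base
  }
  top_unknown <- setdiff(names(user), names(cfg))
  if (length(top_unknown)) stop_named("unknown top-level config key '%s'", top_unknown[1])
  for (sec in intersect(names(user), c("sim", "qc", "scstar", "omics", "network", "enrichment")))
    cfg[[sec]] <- merge_section(cfg[[sec]], user[[sec]], sec)
  for (key in intersect(names(user), c("seed", "out_dir", "stages")))
    cfg[[key]] <- user[[key]]
  bad_stage <- setdiff(cfg$stages, default_pipeline_config()$stages)
  if (length(bad_stage)) stop_named("unknown stage '%s'", bad_stage[1])
  # validate by constructing each stage's parameter object
  sim_args <- cfg$sim[setdiff(names(cfg$sim), "n_cells_per_condition")]
  sim_args$n_cells_per_condition <- unlist(cfg$sim$n_cells_per_condition)
  sim_args$seed <- cfg$seed
  do.call(sim_config, sim_args)
  do.call(qc_params, cfg$qc)
  do.call(scstar_params, cfg$scstar[setdiff(names(cfg$scstar),
                                            c("reference_condition", "partition_gene"))])
  for (f in c(cfg$omics$rna_file, cfg$omics$prot_file, cfg$network$edges_file,
              cfg$enrichment$gmt_file))
    if (!is.null(f) && !file.exists(f)) stop_named("referenced file does not exist: %s", f)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save a pipeline configuration as YAML
#'
#' @param config a [load_config()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, scstar,
#' omics, network, enrichment), writing each stage's tables plus a
#' parameter log under `out_dir`, and returns a manifest of every artifact
#' with its MD5 hash. Per-stage seeds are derived deterministically from
#' the global seed, so identical config + seed reproduces identical
#' artifacts. A stage failure halts the run with the stage named; earlier
#' outputs are retained.
#'
#' @param config a [load_config()] result.
#' @return data.frame manifest: stage, artifact, path, md5.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         path = character(0), md5 = character(0))
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  cat(sprintf("stxmicro pipeline | seed %d | %s\n", config$seed,
              format(Sys.time())), file = log_path)
  note <- function(stage, artifact, path) {
    cat(sprintf("[%s] wrote %s\n", stage, path), file = log_path, append = TRUE)
    manifest <<- rbind(manifest, data.frame(stage = stage, artifact = artifact,
                                            path = path,
                                            md5 = unname(tools::md5sum(path))))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    cat(sprintf("[%s] params: %s\n", stage,
                paste(utils::capture.output(utils::str(config[[stage]] %||% list())),
                      collapse = " ")), file = log_path, append = TRUE)
    tryCatch(fn(), error = function(e)
      stop_named("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  env <- new.env()

  run_stage("simulate", function() {
    cfg <- do.call(sim_config, c(
      config$sim[setdiff(names(config$sim), "n_cells_per_condition")],
      list(n_cells_per_condition = unlist(config$sim$n_cells_per_condition),
           seed = derive_seed(config$seed, "simulate"))))
    sim <- simulate_counts(cfg)
    env$sim <- sim
    dir <- file.path(config$out_dir, "sim_counts")
    files <- write_fixture(sim$dataset, dir)
    for (f in files) note("simulate", basename(f), f)
    truth_path <- write_tsv(data.frame(barcode = sim$dataset$cell_barcodes,
                                       cell_type = sim$truth$cell_type_labels,
                                       affected = sim$truth$affected_cell_mask),
                            file.path(config$out_dir, "sim_truth.tsv"))
    note("simulate", "sim_truth.tsv", truth_path)
  })

  run_stage("preprocess", function() {
    if (is.null(env$sim)) stop_named("no dataset available (enable the simulate stage)")
    qp <- do.call(qc_params, c(config$qc, list(seed = derive_seed(config$seed, "cluster"))))
    ds <- qc_filter(env$sim$dataset, qp)
    ds <- log_normalize(ds, qp$scale_factor)
    ds <- select_hvg(ds, min(qp$n_hvg, ncol(ds$counts)))
    ds <- embed_pca(ds, min(qp$n_pcs, min(dim(ds$counts)) - 1L))
    ds <- cluster_cells(ds, resolution = qp$resolution, seed = qp$seed)
    env$dataset <- ds
    note("preprocess", "qc_summary.tsv", write_tsv(
      data.frame(barcode = ds$cell_barcodes, condition = ds$condition,
                 n_genes = ds$n_genes_by_cell, mito_fraction = ds$mito_fraction,
                 cluster = ds$cluster),
      file.path(config$out_dir, "qc_summary.tsv")))
  })

  run_stage("scstar", function() {
    if (is.null(env$dataset)) stop_named("preprocess stage must run before scstar")
    sp <- do.call(scstar_params, c(
      config$scstar[setdiff(names(config$scstar), c("reference_condition", "partition_gene"))],
      list(seed = derive_seed(config$seed, "scstar"))))
    conds <- unique(env$dataset$condition)
    ref <- config$scstar$reference_condition %||% conds[1]
    for (other in setdiff(conds, ref)) {
      st <- run_scstar(env$dataset, ref, other, sp)
      env$st <- st
      tag <- paste0(ref, "_vs_", other)
      note("scstar", paste0("assignment_", tag, ".tsv"), write_tsv(
        st$assignment, file.path(config$out_dir, paste0("assignment_", tag, ".tsv"))))
      note("scstar", paste0("transition_clusters_", tag, ".tsv"), write_tsv(
        data.frame(cell = st$cells, condition = st$condition_of_origin,
                   cluster = st$transition_cluster),
        file.path(config$out_dir, paste0("transition_clusters_", tag, ".tsv"))))
    }
    if (!is.null(config$scstar$partition_gene)) {
      pg <- gene_partition_run(env$dataset, config$scstar$partition_gene, sp)
      note("scstar", "partition_contingency.tsv", write_tsv(
        as.data.frame(pg$contingency$positivity),
        file.path(config$out_dir, "partition_contingency.tsv")))
    }
  })

  run_stage("omics", function() {
    tabs <- if (!is.null(config$omics$rna_file)) {
      list(rna = read_diff_table(config$omics$rna_file, "rna"),
           protein = read_diff_table(config$omics$prot_file, "protein"))
    } else {
      simulate_paired_omics(config$omics$n_bulk, config$omics$n_prot,
                            config$omics$n_overlap,
                            seed = derive_seed(config$seed, "omics"))
    }
    shared <- intersect_degs(filter_degs(tabs$rna, config$omics$min_abs_lfc, config$omics$max_p),
                             filter_degs(tabs$protein, config$omics$min_abs_lfc, config$omics$max_p))
    env$shared_degs <- shared
    note("omics", "shared_degs.tsv",
         write_tsv(shared, file.path(config$out_dir, "shared_degs.tsv")))
  })

  run_stage("network", function() {
    if (is.null(config$network$edges_file)) return(invisible(NULL))
    g <- read_edge_list(config$network$edges_file, config$network$min_combined_score)
    g <- prune_isolated(g)
    if (igraph::vcount(g) < 2) stop_named("pruned network has fewer than 2 nodes")
    hubs <- hub_score_table(g)
    env$network <- g
    env$complexes <- mcode_complexes(g)
    note("network", "hub_scores.tsv",
         write_tsv(hubs, file.path(config$out_dir, "hub_scores.tsv")))
    if (length(env$complexes)) {
      memb <- do.call(rbind, lapply(seq_along(env$complexes), function(i)
        data.frame(complex = i, gene = env$complexes[[i]]$members,
                   score = env$complexes[[i]]$score)))
      note("network", "mcode_complexes.tsv",
           write_tsv(memb, file.path(config$out_dir, "mcode_complexes.tsv")))
    }
  })

  run_stage("enrichment", function() {
    if (is.null(config$enrichment$gmt_file)) return(invisible(NULL))
    coll <- read_gmt(config$enrichment$gmt_file)
    queries <- list()
    if (!is.null(env$st) && !is.null(env$st$marker_genes))
      queries <- lapply(env$st$marker_genes, function(m)
        if (!is.null(m)) m$gene[m$significant] else character(0))
    if (!is.null(env$complexes))
      for (i in seq_along(env$complexes))
        queries[[paste0("complex_", i)]] <- env$complexes[[i]]$members
    for (nm in names(queries)) {
      q <- queries[[nm]]
      if (length(intersect(normalize_symbols(q), normalize_symbols(coll$universe))) == 0) next
      res <- suppressWarnings(
        ora_hypergeometric(q, coll, method = config$enrichment$method))
      note("enrichment", paste0("enrichment_", nm, ".tsv"), write_tsv(
        utils::head(res, 20), file.path(config$out_dir, paste0("enrichment_", nm, ".tsv"))))
    }
  })

  manifest
}
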