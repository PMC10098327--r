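test_that("the adaptive CV filter removes constants and respects the zero limit", {
  set.seed(1)
  m <- cbind(matrix(rexp(50 * 8), 50, 8), const = 2)
  colnames(m) <- paste0("g", 1:9)
  mask <- filter_genes_adaptive(m, scstar_params(gene_filter_min_cv = 0))
  expect_false(mask[9])                    # constant gene always removed
  expect_true(all(mask[1:8]))              # threshold 0 keeps all non-constant
  expect_error(filter_genes_adaptive(matrix(1, 10, 4), scstar_params()),
               "relax")
})

test_that("planted high-variance genes survive the adaptive filter", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_counts(sim_config(seed = 300 + s))
    ds <- log_normalize(sim$dataset)
    mask <- filter_genes_adaptive(ds$lognorm, scstar_params())
    mean(mask[1:40])                       # the default transition genes
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pseudo-pairing matches translated copies and degenerates to centroids", {
  set.seed(9)
  # cells spread along the all-ones direction; the group shift is orthogonal
  # to that spread so each translated cell stays its own nearest partner
  a <- matrix(rnorm(12 * 6, sd = 0.01), 12, 6) +
    10 * matrix(rep(1:12, 6), 12, 6) / 12
  delta <- rep(c(2, -2), 3)
  b <- sweep(a, 2, -delta)
  pr <- build_pseudo_pairs(a, b, pairing_k = 1)
  expect_equal(pr$a$y, b, tolerance = 1e-12, ignore_attr = TRUE)
  # identical groups: each cell pairs with itself
  pr2 <- build_pseudo_pairs(a, a, pairing_k = 1)
  expect_equal(pr2$a$y, a, tolerance = 1e-12, ignore_attr = TRUE)
  # k = |B|: every A cell pairs with the B centroid
  pr3 <- build_pseudo_pairs(a, b, pairing_k = nrow(b))
  expect_equal(pr3$a$y, matrix(colMeans(b), 12, 6, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(build_pseudo_pairs(a, b, pairing_k = 50), "capped")
})

test_that("dual PLS reproduces identity and pure-shift mappings exactly", {
  set.seed(4)
  x <- matrix(rnorm(30 * 5), 30, 5)
  colnames(x) <- paste0("g", 1:5)
  prs <- list(a = list(x = x, y = x), b = list(x = x, y = x))
  model <- fit_dual_pls(prs, scstar_params(n_components = 5))
  expect_lt(max(abs(project_virtual(x, model, "ab") - x)), 1e-6)
  delta <- rnorm(5)
  y <- sweep(x, 2, -delta)
  model2 <- fit_dual_pls(list(a = list(x = x, y = y), b = list(x = y, y = x)),
                         scstar_params(n_components = 5))
  expect_lt(max(abs(project_virtual(x, model2, "ab") - y)), 1e-6)
  # held-out cells under the shift-only model
  xnew <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("g", 1:5)))
  pred <- project_virtual(xnew, model2, "ab")
  expect_lt(max(abs(pred - sweep(xnew, 2, -delta))), 1e-6)
  # captured covariance is non-increasing across components
  expect_true(all(diff(model2$ab$explained_cov) <= 1e-8))
  expect_error(project_virtual(xnew[, 1:4], model2, "ab"), "gene")
})

test_that("single-component PLS on rank-1 data matches least squares", {
  set.seed(6)
  t_score <- rnorm(25)
  px <- rnorm(4); py <- rnorm(3)
  x <- outer(t_score, px); y <- outer(t_score, py)
  model <- stxmicro:::fit_pls2(x, y, ncomp = 1)
  pred <- stxmicro:::predict_pls2(model, x)
  # OLS oracle on the latent score
  ols <- vapply(1:3, function(j) {
    fit <- stats::lm.fit(cbind(1, t_score), y[, j])
    cbind(1, t_score) %*% fit$coefficients
  }, numeric(25))
  expect_lt(max(abs(pred - ols)), 1e-8)
})

test_that("mixOmics agrees with the hand-rolled PLS predictions", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("x", 1:8)))
  b_op <- matrix(rnorm(8 * 8, sd = 0.4), 8, 8)
  y <- x %*% b_op + matrix(rnorm(40 * 8, sd = 0.05), 40, 8)
  colnames(y) <- paste0("y", 1:8)
  ours <- stxmicro:::fit_pls2(x, y, ncomp = 3)
  ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, x)$predict[, , 3]
  pred_ours <- stxmicro:::predict_pls2(ours, x)
  expect_lt(max(abs(pred_ours - pred_ref)), 1e-6)
})

test_that("identical groups yield a near-zero transition matrix", {
  set.seed(5)
  x <- matrix(rnorm(20 * 6), 20, 6)
  colnames(x) <- paste0("g", 1:6)
  rownames(x) <- paste0("cell", 1:20)
  st <- state_transition_matrix(x, x, scstar_params(n_components = 6, pairing_k = 1))
  expect_lt(max(abs(st$transition)), 1e-5)
  expect_equal(nrow(st$transition), 40L)
})

test_that("planted transitions are recovered and concentrated in affected cells", {
  sim <- simulate_counts(sim_config(
    n_genes = 300L, n_cells_per_condition = c(sham = 300L, day1 = 300L),
    transition_genes = 1:30, library_size_mean = 6000, seed = 21))
  ds <- log_normalize(sim$dataset)
  st <- run_scstar(ds, "sham", "day1", scstar_params(seed = 2))
  is_a <- ds$condition == "sham"
  aff <- sim$truth$affected_cell_mask[c(which(is_a), which(!is_a))]
  shift <- sim$truth$planted_shift_vector[match(colnames(st$transition),
                                                ds$gene_names)]
  r <- stats::cor(colMeans(st$transition[aff, , drop = FALSE]), shift)
  expect_gte(r, 0.7)
  # affected cells move further than unaffected cells
  norms <- sqrt(rowSums(st$transition^2))
  p <- stats::wilcox.test(norms[aff], norms[!aff], alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # clustering recovers the affected mask and assigns it to day1
  expect_gte(adjusted_rand_index(st$transition_cluster, aff), 0.8)
  aff_cl <- names(which.max(table(st$transition_cluster[aff])))
  expect_true("day1" %in% attr(st$assignment, "cluster_labels")[[aff_cl]])
})

test_that("transition clustering is deterministic for a fixed seed", {
  set.seed(3)
  x <- matrix(rnorm(60 * 8), 60, 8)
  y <- matrix(rnorm(60 * 8, mean = 0.3), 60, 8)
  colnames(x) <- colnames(y) <- paste0("g", 1:8)
  st <- state_transition_matrix(x, y, scstar_params(n_components = 4))
  a <- cluster_transitions(st, resolution = 0.5, seed = 7)
  b <- cluster_transitions(st, resolution = 0.5, seed = 7)
  expect_identical(a$transition_cluster, b$transition_cluster)
})

test_that("hypergeometric assignment matches exact enumeration", {
  # worked case: N=10, K=5, n=5, x=3 -> 126/252 = 0.5
  expect_equal(hypergeom_upper_tail(3, 10, 5, 5), 0.5, tolerance = 1e-12)
  expect_equal(oracle_hyper_upper(3, 10, 5, 5), 0.5, tolerance = 1e-12)
  # x = n = K: p = 1 / C(N, n)
  expect_equal(hypergeom_upper_tail(4, 9, 4, 4), 1 / choose(9, 4), tolerance = 1e-12)
  # x = 0: never assigned
  expect_equal(hypergeom_upper_tail(0, 12, 6, 3), 1)
  # sweep small populations against the enumeration oracle
  for (N in c(5, 11, 17)) for (K in c(1, N %/% 2)) for (n in c(1, N %/% 3 + 1))
    for (x in 0:min(K, n))
      expect_equal(hypergeom_upper_tail(x, N, K, n),
                   oracle_hyper_upper(x, N, K, n), tolerance = 1e-12)
})

test_that("cluster-condition assignment labels follow the test outcomes", {
  st <- structure(list(
    cells = paste0("c", 1:40),
    transition = matrix(0, 40, 2),
    condition_of_origin = rep(c("sham", "day1"), each = 20),
    transition_cluster = factor(rep(c("c1", "c2"), times = c(22, 18)))
  ), class = "state_transition_set")
  # c2: 18 cells, all day1 -> strongly day1; c1 mixed
  st$transition_cluster <- factor(c(rep("c1", 20), rep("c1", 2), rep("c2", 18)))
  out <- assign_clusters_to_conditions(st, alpha = 0.05)
  labs <- attr(out$assignment, "cluster_labels")
  expect_true("day1" %in% labs$c2)
  expect_true("sham" %in% labs$c1)
  expect_true(all(out$assignment$p >= 0 & out$assignment$p <= 1))
  # balanced cluster on balanced data is stable
  st$transition_cluster <- factor(rep(c("c1", "c2"), times = 20))
  out2 <- assign_clusters_to_conditions(st, alpha = 0.05)
  expect_equal(attr(out2$assignment, "cluster_labels")$c1, "stable")
})

test_that("Wilcoxon marker ranking matches the permutation oracle", {
  vals <- matrix(c(5, 6, 7, 1, 2, 3), ncol = 1,
                 dimnames = list(paste0("c", 1:6), "gA"))
  cl <- rep(c("in", "out"), each = 3)
  tab <- find_cluster_markers(vals, cl, "in")
  expect_equal(tab$p, 0.1, tolerance = 1e-12)
  expect_equal(tab$p, oracle_wilcox_two_sided(c(5, 6, 7), c(1, 2, 3)),
               tolerance = 1e-12)
  expect_equal(tab$effect, 4)
  # Bonferroni arithmetic: raw 0.01 with 10 genes tested -> 0.1
  expect_equal(adjust_pvalues(rep(0.01, 10), "bonferroni")[1], 0.1)
  # constant gene: p = 1, never significant
  vals2 <- cbind(vals, gB = rep(2, 6))
  tab2 <- find_cluster_markers(vals2, cl, "in")
  expect_equal(tab2$p[tab2$gene == "gB"], 1)
  expect_false(tab2$significant[tab2$gene == "gB"])
  expect_error(find_cluster_markers(vals, c("in", rep("out", 5)), "in"),
               "fewer than 2")
})

test_that("gene-partition analysis reports coherent contingency tables", {
  sim <- simulate_counts(sim_config(
    n_genes = 200L, n_cells_per_condition = c(sham = 150L, day1 = 150L),
    n_cell_types = 1L, transition_genes = 1:20, library_size_mean = 5000,
    seed = 31))
  ds <- log_normalize(sim$dataset)
  # plant a marker expressed exactly in the affected cells
  marker_col <- match("G0150", ds$gene_names)
  ds$counts[, marker_col] <- ifelse(sim$truth$affected_cell_mask, 3L, 0L)
  out <- gene_partition_run(ds, "G0150", scstar_params(seed = 4))
  # bookkeeping: every cell appears once; row sums equal cluster sizes
  expect_equal(sum(out$contingency$positivity), length(ds$cell_barcodes))
  expect_equal(unname(rowSums(out$contingency$positivity)),
               unname(as.vector(table(out$transition_cluster))))
  expect_equal(sum(out$contingency$positivity[, "G0150+"]),
               sum(sim$truth$affected_cell_mask))
  # all positive cells come from the affected condition
  expect_equal(sum(out$contingency$condition[, "day1"] >=
                     out$contingency$positivity[, "G0150+"]),
               nrow(out$contingency$condition))
  expect_error(gene_partition_run(ds, "NotAGene"), "absent")
  ds$counts[, marker_col] <- 0L
  expect_error(gene_partition_run(ds, "G0150"), "zero cells")
})
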