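# stxmicro

Condition-driven cell-state transitions in multi-condition single-cell
RNA-seq, with the full analysis chain around them. The motivating setting
is a mouse cerebral ischemia–reperfusion study (sham and days 1/3/7 after
transient middle cerebral artery occlusion), where microglial state
changes are masked by the far larger cell-type heterogeneity — but every
stage runs on any multi-condition dataset, and a synthetic generator with
planted effects makes the whole chain testable offline.

## What it computes

The core is a **dual-PLS real–virtual cell-pair analysis**. For two
condition groups $A$ and $B$ on a CV-filtered gene space:

1. each cell is pseudo-paired with the mean of its $k$ nearest
   other-condition cells in a joint PCA embedding;
2. two NIPALS PLS2 regressions ($A \to B$, $B \to A$) learn the shared
   structure and project every real cell to a *virtual counterpart* in the
   other condition, $\hat y = \bar y + (x - \bar x) B_{PLS}$;
3. the per-cell transition profile $t(x) = \hat y - x$ (sign-harmonized to
   the $A \to B$ direction) cancels cell-type structure and keeps the
   condition effect;
4. transition profiles are clustered (SNN + Louvain) and each cluster is
   assigned to conditions by a one-sided hypergeometric test
   ($p < 0.05$; clusters with no significant condition are "stable"),
   with Wilcoxon + Bonferroni marker genes per cluster.

Around the core: standard QC (cells kept with 200–3000 detected genes and
≤ 10% mitochondrial UMIs; genes in ≥ 3 cells), log-normalization, 2000
HVGs, 30 PCs, resolution-1.0 clustering and marker-panel annotation;
intersection of bulk RNA-seq and proteomic differential tables at
|log2FC| ≥ 1, p < 0.05; PPI networks from STRING-style TSV exports
(combined score ≥ 400) with hub scores = median of normalized degree,
betweenness and closeness centralities, and MCODE-style dense complexes;
and local hypergeometric over-representation analysis against GMT gene-set
collections (Bonferroni / Benjamini–Hochberg).

## Worked example

```r
library(stxmicro)

# a synthetic two-condition experiment: 2 x 1000 cells, 500 genes, a log-e
# shift of 1 on 40 genes planted in half of the day1 type-1 cells, under
# 5x larger cell-type heterogeneity
sim <- simulate_counts(sim_config(seed = 42))
ds  <- log_normalize(qc_filter(sim$dataset))

st <- run_scstar(ds, "sham", "day1", scstar_params(seed = 1))
table(st$transition_cluster)
#>   c1   c2
#> 1750  250
attr(st$assignment, "cluster_labels")
#> $c1: "sham"   $c2: "day1"
```

The 250 cells of cluster `c2` are exactly the planted affected
subpopulation (ARI 1.0 against the ground-truth mask over this seed), and
the hypergeometric test assigns that cluster to day1. Correlating the
affected cells' mean transition profile with the planted shift gives
r ≈ 0.87 for a single replicate and 0.96-0.98 when pooled over ten
replicates. The per-cell resolution is the point: a gene-level test between
conditions can flag the shifted genes, but only the transition profiles say
*which* cells carry the change — here recovering the planted subpopulation
essentially exactly despite signature shifts five times larger.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate → preprocess → state transitions → omics/network →
enrichment), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_state_transition.R
Rscript analysis/04_omics_network.R
Rscript analysis/05_enrichment.R
```

`run_pipeline(load_config(system.file("extdata/pipeline_example.yaml",
package = "stxmicro")))` does the same in one call
with per-stage seeds derived from one global seed and an artifact manifest
with file hashes.

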