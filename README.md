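# snconcord

Droplet-level QC, cell-type annotation, and concordance statistics for
paired **single-cell** (scRNA-seq) and **single-nucleus** (snRNA-seq)
RNA-seq of the same tissue — built for the situation where you need to ask:
*does sequencing nuclei instead of whole cells recover the same cell types
and the same genes?*

The package implements the complete computational workflow downstream of a
count matrix:

- **Droplet QC** — per-droplet metrics; empty-droplet calling by a Gaussian
  mixture on ln total UMI (droplets with posterior > 0.5 in the low-count
  component are empty); ambient-RNA fraction estimation by maximum
  likelihood under the mixture `(1 − ρ)·π_type + ρ·π_ambient`; doublet
  flagging with an artificial-doublet kNN score; and the filter cascade —
  genes detected in ≥ 3 cells, droplets with ≥ 200 detected genes, removal
  above 20% mitochondrial UMI, and for xenograft nuclei ≥ 1000 UMI, ≥ 500
  genes and ≤ 25% mouse UMI followed by removal of all mouse genes.
- **Typing** — ln(1+count) normalization, PCA (25 components) →
  shared-nearest-neighbour graph → Louvain clustering, annotation of each
  cluster by Pearson correlation against reference cell-type centroids, and
  per-cluster Wilcoxon rank-sum marker detection.
- **Concordance** — detected-gene-set overlap (Jaccard and
  percent-of-smaller); per-cell-type regression of mean ln counts reporting
  *R²* (the square of the Pearson correlation); fractional overlap of the
  top *N* ∈ {100, 200, 500, 1000} genes per type; and per-gene
  detection-rate enrichment (fold-change > 1.5 with BH-adjusted
  two-proportion tests) with the gene-biotype breakdown that exposes the
  nuclear retention of lncRNAs such as *NEAT1* and *MEG3*.
- **Simulation** — a synthetic droplet-count generator
  (`sim_config()`, `simulate_paired_experiment()`) that produces paired
  whole-cell / nucleus / xenograft-nucleus bundles from shared cell-type
  expression programs, with per-droplet ambient fractions, doublets, empty
  droplets, bimodal mouse contamination, and full ground-truth labels, so
  every stage is testable without any download.

Everything is tidyverse-native: count bundles live in a light
`droplet_matrix` container; every analysis step returns a tibble; reports
have `tidy()` / `glance()` methods and ggplot2 `autoplot()` /
`plot_*()` companions.

## Worked example

Simulate a paired islet-like experiment (six cell types: alpha, beta,
delta, PP, ductal, other), QC both modalities, annotate, and compare:

```r
library(snconcord)

cfg <- sim_config(seed = 42)
sim <- simulate_paired_experiment(cfg)

qc_sc <- run_droplet_qc(sim$whole_cell$matrix, seed = 1)
qc_sn <- run_droplet_qc(sim$nucleus$matrix,    seed = 2)
glance(qc_sn)
#> # A tibble: 1 × 10
#>   n_droplets_in n_droplets_out n_genes_out removed_empty removed_doublet
#> 1          1200            950        1950           200              50
#> # … removed_droplet_thresholds, median_umi, median_genes, …

sc <- annotate_dataset(qc_sc$matrix, sim$profiles, analysis_params(seed = 3))
sn <- annotate_dataset(qc_sn$matrix, sim$profiles, analysis_params(seed = 4))

rep <- concordance_report(qc_sn$matrix, qc_sc$matrix, sn$labels, sc$labels)
rep
#> <concordance_report> nucleus vs whole_cell
#>   detected genes: 1950 vs 1963, 99.8% of smaller set shared (Jaccard 0.989)
#>   matched-type R^2: ductal=0.98, beta=0.98, delta=0.98, PP=0.97, alpha=0.98, other=0.97
#>   enriched genes (fold > 1.5, q <= 0.05): 264
```

Reading the report: the two modalities detect nearly the same gene set
(99.8% of the smaller set is shared); the expression profile of each cell
type in nuclei correlates with the *same* type in whole cells at *R²* ≈
0.97–0.98, far above any mismatched-type pair (`glance(rep)` gives the mean
mismatched *R²* ≈ 0.77); and 264 genes are detected significantly more
often in nuclei — with the simulated 3-fold nuclear lncRNA retention, those
are the lncRNAs. `autoplot(rep)` draws the type-by-type *R²* heatmap and
`plot_top_overlap(rep)` the top-*N* overlap bars.

The whole chain, including TSV/JSON output and a run manifest, is also
available as one call:

```r
res <- run_pipeline(pipeline_config(simulation = cfg, out_dir = "out",
                                    seed = 42))
```

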