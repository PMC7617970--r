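# tamtempo

Temporal, trajectory and spatial analysis of tumour-associated
macrophages (TAMs) in photoconvertible-label experiments.

## The problem

In Kaede-transgenic mice, violet light photoconverts every cell inside a
tumour from green to red fluorescence. Cells harvested later therefore
split into **newly infiltrating (Kaede-green)** and **resident since
labelling (Kaede-red)** fractions — a per-cell *dwell-time* stamp that
ordinary single-cell snapshots lack. Monocyte-derived TAMs (mdTAMs) turn
over within days, differentiate down two fate branches distinguished by
MHC class II, and lose inflammatory gene expression as they dwell;
checkpoint blockade (anti-PD-L1) perturbs all three processes. Analysing
such data requires statistics that respect cell non-independence and
label-derived time, which is what this package provides:

* **Bootstrap pseudo-bulk differential expression.** Cells of each group
  are randomly sorted into artificial replicates, raw counts are summed,
  normalized by **median-of-ratios** size factors
  (`s_j = median_g k_gj / geomean_g`), and tested per gene with a
  negative-binomial log-link **Wald test**
  (`W = LFC / SE`, log2 scale, fixed method-of-moments dispersion). The
  procedure repeats over ≥ 10 random partitions and ranks genes by the
  **averaged Wald statistic** — a rank metric robust to any single
  arbitrary partition.
* **Pre-ranked GSEA.** Classic weighted Kolmogorov–Smirnov running sum
  (hits add `|w|^p / Σ|w|^p`, misses subtract `1/(N − N_set)`, `p = 1`),
  gene-label permutation p-values, same-sign NES normalization, and
  leading-edge genes.
* **Trajectory stage.** kNN transition graph with adaptive Gaussian
  kernels, diffusion pseudotime rooted in the Kaede-green–dominant
  monocyte cluster, absorption ("branch") probabilities from an
  absorbing Markov chain, and the probability cut-offs used downstream
  (assignment > 0.5, high confidence > 0.7), plus loess smoothing of
  scores over pseudotime.
* **Label kinetics.** Kaede-red fractions with Wilson intervals and an
  exponential replacement fit `f(t) = f0 · exp(−k t)` giving a net
  replacement rate and half-life per population; calliper tumour volume
  `V = 0.5·a·b²`.
* **Spatial analysis.** 10-pixel (~5 µm) grid averaging of
  immunofluorescence intensities, intensity-weighted KDE, the
  F4/80:CD11b ratio versus distance-to-edge (Spearman), Visium-like spot
  QC, marker scoring, and CD68⁺CD14⁺ × TRAC⁺CD4⁺ spot co-localization
  with the CXCL9/CXCL10-positive fraction.
* **A synthetic-data generator** producing all of the above inputs with
  known ground truth (branches, pseudotime, dwell times, replacement
  rates, co-localization indicators), so every stage is testable without
  downloads.

## Worked example

Simulate a labelled experiment, QC it, test Kaede-red vs Kaede-green
expression, and run GSEA on the averaged-Wald rank metric:

```r
library(tamtempo)

sim <- simulate_cell_matrix(sim_config(n_cells = 1000, n_genes = 500, seed = 42))
x <- qc_filter(sim$matrix, min_genes = 100, max_genes = 500)
x
#> <cell_matrix> 500 genes x 991 cells
#> metadata columns: barcode, kaede_label, time_since_label_h, condition, cluster, mito_fraction

design <- pseudobulk_design(x$cell_metadata$kaede_label,
                            n_replicates_per_group = 3,
                            n_iterations = 11, seed = 42)
de <- bootstrap_de(x, design)
head(de$table[order(de$table$wald_mean), c("gene", "lfc_mean", "wald_mean", "p_median")], 5)
#>        gene lfc_mean wald_mean p_median
#> 99 infl_049   -0.759     -15.3 9.96e-42
#> 95 infl_045   -0.829     -15.2 1.78e-33
#> 56 infl_006   -0.740     -14.8 2.21e-26
#> 54 infl_004   -0.669     -14.7 5.14e-37
#> 51 infl_001   -0.826     -14.0 4.97e-39

sets <- list(
  inflammatory = gene_set("inflammatory", grep("^infl", x$gene_ids, value = TRUE)),
  mhc2         = gene_set("mhc2",         grep("^mhc2", x$gene_ids, value = TRUE))
)
run_gsea(rank_metric(de), sets, n_perm = 1000, seed = 42)[, c("set", "size", "es", "nes", "p")]
#>            set size     es   nes       p
#> 1 inflammatory   50 -0.998 -2.51 0.00152
#> 2         mhc2   50  1.000  2.70 0.00274
```

Inflammatory program genes are strongly *down* in Kaede-red (resident)
macrophages — the dwell-dependent silencing the generator encodes — and
the set-level enrichment is decisively negative (ES ≈ −1, permutation
p ≈ 0.002), while the MHC-II program is enriched in the red fraction.

Replacement kinetics from simulated flow-cytometry counts:

```r
tb <- simulate_turnover(c(mdTAM = log(2) / 24, TIL = log(2) / 150),
                        c(5, 24, 48, 72), 500, efficiency = 0.98, seed = 42)
fit_replacement(tb)
#>   population k_per_h    f0 half_life_h n_points residual_ss
#> 1      mdTAM 0.03108 0.999        22.3        4       0.648
#> 2        TIL 0.00512 0.989       135.3        4       3.099
```

The mdTAM pool's fitted half-life (~22 h vs the simulated 24 h) captures
its rapid replacement by circulating monocytes; lymphocytes turn over an
order of magnitude more slowly.

A thin CLI wraps the same functions (`inst/scripts/tamtempo`):
`simulate`, `qc`, `de`, `gsea`, `traj`, `turnover`, `spots`.

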