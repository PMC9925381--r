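# chicdyn

Downstream analysis of **single-cell sortChIC** data: sparse per-cell
genomic cut-site counts for one histone modification (H3K4me1, H3K4me3,
H3K27me3 or H3K9me3), obtained by antibody-tethered MNase cleavage with
FACS index sorting. The package takes cut tables or region × cell count
matrices and carries them through quality control, dimensionality
reduction, differential chromatin testing, transcription-factor activity
inference, deconvolution of doubly-stained cells, cell typing and
chromatin velocity — with a seeded synthetic-data generator so that every
stage is testable against known ground truth, without any sequencing
data.

It is written for computational biologists analysing single-cell
chromatin profiling experiments (sortChIC, CUT&RUN/CUT&Tag-style assays)
in R.

## Models at the core

* **Quantification & QC** — 50 kb genome bins and TSS ±5 kb windows
  (0-based half-open), fraction of reads in peaks, Gini coefficient,
  signal enrichment, cell filtering, and automatic above-background bin
  calling from the bimodal log10 bin-sum distribution.
* **Topic model** — counts Y are a hierarchical multinomial (LDA):
  topics φ are distributions over regions, cells θ are mixtures over
  topics; fitted by collapsed Gibbs sampling (C++). The reconstruction
  Ỹ = log(φᵀθᵀ) is the imputed signal used downstream. Latent-space
  batch correction removes cell-type-specific plate effects while
  preserving cluster means exactly.
* **Differential chromatin** — per region, Poisson regressions
  `log E[Y] = μ + offset` (null) vs `log E[Y] = μ + γ_celltype + offset`
  (full) compared by deviance (χ², df = #types − 1), with log total cuts
  as offset, BH q-values, mark-specific dynamic-bin thresholds
  (q < 1e−50 active marks and H3K27me3, q < 1e−9 H3K9me3), fold changes
  vs a reference population, and fate-independence classification.
* **Motif activities (MARA-style)** — ridge regression
  Ỹ_g,c = Σ_m N_g,m A_m,c + ε with an 80/20 cross-validated penalty
  shared across cells and z-score filtering (z > 0.7).
* **Double-incubation deconvolution** — a doubly-stained cell's counts
  are Multinomial(N, w·p_c + (1−w)·q_l); concave profile likelihood in
  w, model selection over (cell type, lineage) pairs.
* **Cell typing** — multinomial likelihood against pseudocounted
  FACS-labelled reference profiles, posterior in log space.
* **Trajectories & velocity** — k = 10 nearest-neighbour FACS marker
  imputation, ternary Sca1–cKit–Lin coordinates, rank-based pseudotime
  from two selected PCs, cubic-spline fits along pseudotime and their
  forward-difference derivative at Δ = 0.01, projected into PC space.

## Worked example

Simulate a three-type experiment, fit the topic model, cluster, and test
for dynamic bins:

```r
library(chicdyn)

cfg <- sim_config(n_region = 300, n_type = 3, n_cell_per_type = 50,
                  depth_median = 2000, frac_dynamic = 0.15,
                  fold_spec = c(1, 3, 0.4), seed = 101)
truth <- simulate_profiles(cfg)
cells <- simulate_cells(truth, cfg)

fit <- fit_topics(cells$counts, K = 3, n_iter = 300, seed = 102)
#> Multinomial topic model: 150 cells, 300 regions, K = 3
#>   300 Gibbs sweeps (last 50 averaged), alpha = 16.7, beta = 0.1

table(cluster_cells(fit$theta, k = 3, seed = 103), cells$cell_labels)
#>    type1 type2 type3
#>  1     0     0    50
#>  2    50     0     0
#>  3     0    50     0

res <- diff_mark_test(cells$counts, cells$cell_labels, reference = "type1")
res <- call_dynamic(res, "H3K9me3")
sum(res$dynamic)
#> [1] 63
head(res[order(res$q), c("region", "dev_diff", "q",
                         "log2fc_type2", "log2fc_type3")], 3)
#>        region dev_diff             q log2fc_type2 log2fc_type3
#> 264 region264 1596.727  0.000000e+00     1.296677    -1.097530
#> 265 region265 2047.378  0.000000e+00     1.210322    -1.342354
#> 211 region211 1118.394 1.392743e-241     1.315523    -1.411879
```

The clustering separates the three simulated types perfectly; 63 bins
pass the H3K9me3 dynamic threshold (45 were planted — renormalising a
compositional profile after planting folds also shifts the remaining
regions slightly, which a well-calibrated test detects at this depth).
The top dynamic bins show the planted pattern: enriched in type2
(log2FC ≈ +1.3 ≈ log2 3 relative to the common depth shift) and depleted
in type3.

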