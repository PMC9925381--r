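---
title: "Models and methods behind chicdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chicdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chicdyn)
```

chicdyn implements the downstream statistical analysis of single-cell
sortChIC data: sparse per-cell counts of antibody-tethered MNase cut sites
for one histone modification (H3K4me1, H3K4me3, H3K27me3 or H3K9me3),
quantified over genomic regions. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the methodology left genuine choices open. Every empirical claim made here
is one that the package's own test suite or acceptance script computes.

## The count model and quantification

All coordinates are 0-based half-open, the native BED convention: a cut at
position $p$ belongs to region $[s, e)$ iff $s \le p < e$. Default
features are genome-wide 50 kb non-overlapping bins (`make_bins()`) or
±5 kb windows around transcription start sites (`make_tss_windows()`),
matching the feature sets used for genome-wide chromatin profiling and
promoter-centric marker-gene analysis respectively.

QC follows the specificity/sensitivity metrics standard for single-cell
chromatin assays:

* **FRiP** (`fraction_in_peaks()`): in-peak cut events over total events.
* **Gini coefficient** (`gini()`): mean absolute pairwise difference over
  twice the mean, computed by the sorted-cumulative formula; 0 for
  perfectly even coverage, scale-invariant.
* **Signal enrichment** (`signal_enrichment()`): in-mark cut fraction
  divided by the genomic fraction the marked territory covers.

**Above-background bins.** Summed per-bin counts of real data are bimodal
in log10 space (a background mode and a marked mode). The published
analyses placed this cutoff by eye, per mark; for reproducibility
`bins_above_background()` automates it as the minimum-density valley
between the two largest modes of a kernel density estimate of the log10
bin sums, with `manual_cutoff` as an override. When the density has no
valley (unimodal or degenerate input) all bins are kept and a warning is
raised rather than guessing.

## Topic model (hierarchical multinomial / LDA)

Counts $Y_{g,c}$ are modelled as a hierarchical multinomial: topic $k$ is
a distribution $\phi_k$ over regions, cell $c$ a mixture $\theta_c$ over
topics, and each cut is drawn from $\sum_k \theta_{c,k}\,\phi_{k,g}$.
This is a discrete analogue of probabilistic PCA, appropriate where
Gaussian factor models are not (deep cells and near-empty cells live on
the same simplex).

Inference is collapsed Gibbs sampling (`fit_topics()`), written in C++
for throughput, with symmetric Dirichlet priors. Defaults: $\alpha = 50/K$,
$\beta = 0.1$, 500 sweeps, point estimate averaged over the final 50
sweeps. $K$ defaults to 30 and is deliberately configurable: there is no
canonical $K$ for chromatin data, and the tests use $K$ equal to the
number of planted types. The sampler consumes R's RNG, so a seed fixes
the fit exactly.

The **imputed signal** (`impute_signal()`) is
$\tilde Y = \log(\phi^\top \theta^\top)$ — each cell's reconstructed
multinomial probability vector, in natural log. It is the smoothed
per-cell profile consumed by motif inference and velocity;
`exp()` of each column sums to 1.

**Batch correction** (`correct_batch()`) fits, per latent dimension, the
linear model `value ~ cluster + cluster:batch` and subtracts the
cell-type-specific batch terms, measured against the cell-weighted
cluster mean — so cluster means are preserved exactly (to machine
precision) while between-plate differences within a cluster vanish.
A cluster confined to one plate has no estimable batch term and is
skipped with a warning, never silently "corrected". The correction is
applied to whatever cell × dimension matrix the caller supplies; the
package default workflow corrects the latent topic weights.

Clustering is seeded k-means on $\theta$ (`cluster_cells()`). Graph-based
community detection and nonlinear embeddings are out of scope here;
embeddings are a plotting concern, not an inference step.

## Differential histone-mark levels (Poisson deviance)

For each region, `fit_region_glm()` compares two Poisson regressions of
the per-cell counts, fitted with `stats::glm()`:

$$\text{null: } \log E[Y_c] = \mu + o_c, \qquad
  \text{full: } \log E[Y_c] = \mu + \gamma_{t(c)} + o_c,$$

with the reference cell type's $\gamma$ constrained to 0. The deviance
difference is $\chi^2$ with (#types − 1) degrees of freedom under the
null. The offset $o_c$ is the log total cut count of the cell — the
model statement leaves the offset open, but without depth normalisation
sequencing depth masquerades as cell-type signal, so the offset is the
package's default (callers may supply their own). Log2 fold changes
versus the reference are $\gamma_t / \ln 2$; they agree with
depth-normalised pseudobulk log-ratios at high counts (tested).

Multiplicity is controlled by Benjamini–Hochberg (`adjust_q()`); the
source analyses report q-values without naming a procedure, and BH is
the field default. Dynamic bins are called at mark-specific thresholds
(`call_dynamic()`): $q < 10^{-50}$ for H3K4me1, H3K4me3 and H3K27me3 and
$q < 10^{-9}$ for H3K9me3, whose broad heterochromatic signal yields
weaker per-bin statistics. All-zero regions are kept with $p = 1$ and
zero folds rather than dropped, so region registries stay aligned.

**Fate-independence.** A dynamic region "changes" in type $t$ with
direction $d$ iff $\mathrm{sign}(\log_2\mathrm{FC}_t) = d$ and
$|\log_2\mathrm{FC}_t| >$ `min_effect` (default 0). It changes
*fate-independently* iff it changes with the same direction in every
non-reference type; the per-(type, direction) summary divides the
fate-independent count by the count changing in that type and direction.
`select_top_depleted()` returns the k = 150 most negative folds (ties
broken lexicographically by region id), the set size used to define
cluster-specific heterochromatin regions.

## Motif activities (ridge regression, MARA-style)

The imputed, batch-corrected signal is modelled as a linear combination
of transcription-factor binding sites:
$\tilde Y_{g,c} = \sum_m N_{g,m} A_{m,c} + \varepsilon$, with
$N$ the region × motif site-count matrix and $A$ the motif × cell
activities, fitted by ridge regression (`fit_activities()`). One penalty
$\lambda$ is shared across cells — per-cell penalties would make
activities incomparable between cells — and is chosen by an 80/20
region holdout over a 13-point grid log-spaced $10^{-3}..10^{3}$ times
the mean diagonal of $N^\top N$.

Two conventions are the package's own, as the source method states
neither: $\tilde Y$ is centred per region across cells (otherwise the
mean chromatin profile is absorbed into every motif's activity) and the
columns of $N$ are scaled to unit variance, with coefficients reported
back on the original site-count scale. Both are exposed as arguments
(`center`, `standardize`) so uncentred fits remain available.

Significance (`motif_zscores()`): per motif,
$z_m = \sqrt{\tfrac1C\sum_c (A_{m,c}/\mathrm{se}_{m,c})^2}$, the root
mean square of the activity-to-standard-error ratio across cells, with
standard errors from the ridge sandwich variance
$\sigma_c^2\,(N^\top N+\lambda I)^{-1} N^\top N\,(N^\top N+\lambda I)^{-1}$
and per-cell residual variance $\sigma_c^2$. This expresses the MARA
notion of significance — consistently nonzero activity — with the
default threshold $z > 0.7$. The exact z-score formula is not canonical;
it is a package choice documented here.

## Deconvolution of double-incubated cells

A cell stained for both H3K4me1 and H3K9me3 draws its $N$ cuts from a
mixture of two multinomials:
$\vec y \mid c, l, w \sim \mathrm{Multinomial}(N,\; w\,\vec p_c + (1-w)\,\vec q_l)$,
where $\vec p_c$ is an active-mark cell-type profile, $\vec q_l$ a
repressive-mark lineage profile and $w$ the active-mark fraction of the
mix. Profiles come from single-incubated pseudobulks with pseudocount 1
(`build_reference()`), guaranteeing finite likelihoods.

The log-likelihood $\ell(w) = \sum_i y_i \log(w p_i + (1-w) q_i)$ is
concave in $w$ (each summand is a log of an affine function), so
`fit_w()` finds the global maximiser by golden-section search
(`stats::optimize`, tolerance $10^{-4}$); when $p = q$ elementwise the
likelihood is flat and 0.5 is returned with a flag. `assign_pair()`
profiles $\ell$ over every (cell type, lineage) pair — maximising over
$w$ per pair, or at a caller-fixed $w$, since one mixing chemistry per
experiment plausibly implies one shared $w$; both modes are exposed —
and selects the argmax, with a softmax posterior under a uniform pair
prior and lexicographic tie-breaking.

## Reference-based cell typing

`build_typing_reference()` pools counts per FACS-defined type
(pseudocount 1, uniform prior by default; neither is prescribed by the
source method) and `classify_cells()` scores query cells by multinomial
log-likelihood, softmax-normalised with max-subtraction so depths up to
$10^7$ cuts cannot overflow. Zero-count cells receive the prior back,
flagged.

## Trajectories, FACS imputation and chromatin velocity

Cells with exactly one missing (Sca1, cKit, Lin) marker are completed by
averaging the k = 10 nearest neighbours (Euclidean, in a caller-supplied
latent embedding) among cells where that marker was measured
(`impute_missing_marker()`). `ternary_coords()` normalises the triple to
the unit simplex for the stem→progenitor→mature ternary projection.

**Pseudotime** (`pseudotime_from_pcs()`): trajectory cells are projected
onto the first principal axis of a selected two-PC subspace and
rank-transformed to [0, 1] — monotone, deterministic, and invariant
under monotone rescaling of the scores; the axis is oriented so the
starting population's mean pseudotime is below 0.5. PC selection is
config-driven (the published analysis selected PCs per trajectory by
inspection).

**Velocity** (`fit_trajectory_spline()`, `chromatin_velocity()`): per
region and trajectory, a least-squares cubic B-spline (df = 6 basis
functions, internal knots at pseudotime quantiles) is fitted to signal
against pseudotime, and the velocity is the forward difference of the
spline prediction between $t$ and $t + \Delta$, $\Delta = 0.01$, divided
by $\Delta$. At the trajectory end $t + \Delta$ is clipped to 1 and the
difference taken one-sided over the same width. Because projection is
linear, projecting velocities through PCA loadings
(`project_velocity()`) commutes with differencing the projected signal
(tested to $10^{-8}$).

## The synthetic-data generator

`sim_config()` + `simulate_*()` generate every input with known ground
truth: multinomial cut profiles per type over regions, log-normal
per-cell depths (median 3,000 cuts, the sparsity regime of single-cell
active-mark data; depth distributions of the real data are not published,
so depths are regime-matched, not calibrated), planted dynamic regions
with per-type folds, per-plate batch shifts, double-incubated mixtures,
Poisson motif-site designs with planted activities and exact-zero null
motifs, and FACS trajectories with exact-count masking (the number of
masked cells is `round(missing_frac * n)` by permutation, so tests are
deterministic in count).

Two profile regimes are provided. `profile_mode = "planted"` perturbs a
shared baseline by per-type folds at the dynamic regions — the regime
for differential testing. Note a compositional consequence: renormalising
after planting folds shifts *all* regions' relative mass, so even
"non-dynamic" regions differ slightly between types; calibration and FDR
experiments therefore use direct Poisson simulation with explicit rates.
`profile_mode = "distinct"` draws an independent sparse profile per type,
the well-separated regime that typing and deconvolution references
assume. Batch effects are region-wise Gaussian shifts in log-profile
space shared within a plate — an additive constant would cancel under
renormalisation, so a flat per-plate offset cannot represent a plate
effect in composition space.

What the generator does *not* emulate: genomic sequence context and cut
motifs, fragment-level structure, overdispersion beyond multinomial
sampling, doublets, and cell-cycle covariates. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
laws, not robustness to every artefact of real sortChIC data.

## Problem sizes and numerical choices

The test and acceptance experiments use deliberately desk-scale sizes
chosen to make the statistical properties sharp: 200 double-incubated
cells at 5,000 reads over 8 × 4 cluster pairs; 2,000 regions × 20 motifs
× 300 cells with noise at 0.1 × signal sd; 1,000 null plus 200 planted
regions at 200 cells and mean 5 counts; two-type corpora of 100 cells at
depth 3,000; 8-type typing at depth 1,000 with 400 held-out cells. These
are the package's standard study conditions, fixed before interpreting
any run and reused identically by `scripts/acceptance.R`.

Numerical conventions worth knowing: probability vectors are validated
to 1e-12; posteriors are computed in log space with max-subtraction;
deviances are floored at 0 where floating point would produce tiny
negatives; all-zero regions test as $p = 1$; k-means and the Gibbs
sampler take explicit seeds and the generator derives independent
substreams from one master seed, so every pipeline run is bit-identical
under a fixed configuration (checked via md5 manifests).

## Known limitations

* The automatic background cutoff is a stand-in for the per-mark manual
  cutoffs used on the deposited data; equivalence is not claimed.
* No negative-binomial overdispersion in the differential model; real
  data with biological replicates of pseudobulks may be overdispersed.
* Reference profiles for deconvolution are taken as given; the mixture
  model does not re-estimate them from double-incubated data (an EM
  extension would).
* Pseudotime is a rank transform of a linear projection: adequate for
  single unbranched trajectories, not a branching-trajectory method.
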