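---
title: "Estimating cell-type fractions from bulk ATAC-Seq: model and methods"
author: "atacdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-type fractions from bulk ATAC-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdeconv)
```

## The deconvolution model

A bulk ATAC-Seq sample measures chromatin accessibility of a cell mixture.
After TPM-like normalization (counts divided by peak length, each sample
rescaled to a column sum of $10^6$), the bulk signal $b_j$ at peak $j$ is
modeled as a linear mixture of reference cell-type profiles $R_{ji}$:

$$ b_j \;=\; \sum_{i=1}^{k} R_{ji}\, p_i \;+\; u_j\, p_u, $$

where $p_i \ge 0$ is the fraction of reference cell type $i$, $p_u \ge 0$
the fraction of *uncharacterized* cells (cell types absent from the
reference — chiefly malignant cells in tumor samples), and $u_j$ their
unknown accessibility. The model becomes identifiable by restricting the
fit to **marker peaks**: peaks accessible specifically in one reference
cell type and, by construction of the marker filters, inaccessible in other
human cell types — so $u_j \approx 0$ on the fit features. The fractions
are then estimated per sample by weighted constrained least squares

$$ \hat p \;=\; \arg\min_{p \ge 0,\; \sum_i p_i \le 1}
   \sum_{j \in \text{markers}} w_j \Big(b_j - \sum_i R_{ji} p_i\Big)^2,
   \qquad \hat p_u = 1 - \sum_i \hat p_i , $$

a convex quadratic program solved exactly by the dual active-set method
(`quadprog`). The weights $w_j = 1/(\bar v_j + \varepsilon)$ down-weight
variable reference features, where $\bar v_j$ is the cell-type-averaged
interquartile range (IQR) of the normalized accessibility at peak $j$ and
$\varepsilon = 10^{-2}\,\mathrm{median}(\bar v_j > 0)$ keeps the weights
finite ($\varepsilon = 1$ when all $\bar v$ are zero). Because ATAC-Seq
measures signal at the DNA level, per-cell signal content is comparable
across cell types; the per-cell-type signal-content factors therefore
default to 1 and the final renormalization only rescales
$(\hat p, \hat p_u)$ to sum exactly to 1.

Two consequences worth noting:

* **Scale invariance.** Multiplying a sample's raw counts by any constant
  leaves its fractions unchanged (the TPM-like transform removes depth).
* **Dilution linearity.** If the cell-type signal is diluted by a factor
  $\alpha$ (replaced by signal from cells silent at the markers), the fit
  returns $\hat p_u \approx 1 - \alpha$.

## Building the reference: consensus peaks, markers, profiles

**Consensus peaks.** Per-sample peak calls are merged by iterative overlap
collapse: repeatedly keep the highest-scoring remaining peak and discard
everything overlapping it by $\ge 1$ bp (ties broken by coordinate, so the
result is deterministic; coordinates are never averaged). The collapse runs
at two levels: within each study, keeping peaks detected in at least half
of the samples — `ceiling(n/2)`, and both samples when $n = 2$ — and then
across studies within each cell type, keeping peaks detected in every
study. The final set is the collapsed union over cell types, with
chromosome Y excluded. "Detected" means $\ge 1$ bp overlap with an original
call, mirroring the collapse rule. The ceiling reading of "at least half"
is the stricter consistent choice for odd $n$.

**Differential accessibility.** Marker discovery runs on TMM-normalized
log-CPM values: effective library sizes by the trimmed mean of M-values
(trim fractions 0.3 on log-ratios, 0.05 on average intensities; reference
sample chosen by the upper-quartile rule; factors rescaled to geometric
mean 1), then $\log_2((c + 0.5)/(\text{lib} \cdot f + 1) \times 10^6)$. A
one-way group-means model is fitted across all cell types (plus any
external-tissue groups), pooling the residual variance with
$d = n - g$ degrees of freedom. Per-peak variances are moderated by
empirical Bayes: the prior $(d_0, s_0^2)$ of the scaled-F model is
estimated by moment matching on $\log s^2$ (digamma/trigamma equations,
monotone root finding), and posteriors
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ feed moderated t-statistics
with $d + d_0$ degrees of freedom per pairwise contrast, BH-adjusted
within each contrast. Per-observation precision weights from a
mean–variance trend (as in voom) are deliberately not implemented: the
marker selection consumes only the log2 fold change and the adjusted
p-value, and the moderated-t core captures the statistical essence at far
lower complexity. Users comparing against a full limma-voom analysis
should expect small differences in borderline peaks.

**Marker selection.** Samples are split into ten cell-type-stratified
folds; each fold's analysis set is the complement (leave-one-fold-out), so
every analysis run keeps all cell types represented. Within a run, a
candidate marker for cell type $i$ must show $\log_2$ fold change $> 0.2$
in favor of $i$ in *every* contrast involving $i$ (the recurrent reading;
a switch allows "any contrast"); candidates are ranked by their maximum
BH-adjusted p across those contrasts and truncated to the top 200. Markers
recurring in at least 3 of the 10 folds are retained. Note that with the
all-contrasts requirement, marker lists are automatically disjoint across
cell types (a peak cannot be up in two types in their mutual contrast).

**Chromatin-module veto.** Markers overlapping universal open-chromatin
modules (regions accessible across essentially all human tissues), or
tissue-class modules not exempted for the marker's cell type, are removed.
Default exemptions: immune cell types keep immune-class overlaps,
endothelial cells keep endothelial-class, fibroblasts keep stromal-class.
This is the step that removes peaks that look cell-type specific within
the sorted collection but are broadly accessible in other human tissues.

**Correlation refinement (tumor marker sets only).** Across tumor bulk
samples, genuine markers of a cell type co-vary (they all track that
type's abundance). Per cell type, the pairwise Pearson correlation matrix
of the markers across bulk samples is computed; the cutoff is the 90th
percentile of the upper-triangle values (linear interpolation); scanning
pairs in column-major order, each pair above the cutoff flags its member
with the larger mean absolute correlation (skipping already-flagged
members; ties flag the lower index). The *flagged* — most
inter-correlated — markers are retained (`prune_mode = "keep_correlated"`;
the conventional redundancy-removal reading is available as
`"drop_correlated"`). If no pair exceeds the cutoff the set is kept
unpruned with a warning rather than silently emptied. This refinement is
applied only when a tumor bulk matrix is supplied; marker sets intended
for non-tumor samples (e.g. PBMC-style references) skip it.

**Profiles.** Reference profiles are the per-cell-type median and IQR of
the TPM-like accessibility across sorted samples, computed with quantile
type 7 (linear interpolation between order statistics — stated explicitly
because the IQR feeds the fit weights). Profiles serialize to a gzipped
TSV with a three-line header (format version, genome build, cell types).

## Matching bulk data to the reference

Bulk features are matched to reference peaks by genomic overlap: each bulk
peak maps to its nearest reference peak when they overlap by $\ge 1$ bp
(among several overlapping candidates the leftmost wins — deterministic);
counts of multiple bulk peaks mapping to one reference peak are summed.
The TPM-like transform is applied *after* aggregation, using reference
peak lengths (a switch normalizes the full bulk feature set first). Builds
are matched by exact tag comparison; hg19 data lift onto hg38 through a
chain file with conservative semantics: a region lifts only if its start
and last base fall inside the same aligned block of the single
highest-scoring overlapping chain — so lengths are always preserved —
and regions spanning gaps, split across chains, or colliding on identical
destination coordinates are dropped with a reason (`unmapped`,
`no_chain`, `duplicate_target`). This is intentionally stricter than
split/partial mapping lifters; peaks are short relative to chain blocks,
so the loss is negligible and the behavior is easy to reason about.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lfc_min` | 0.2 | minimum log2 fold change toward the target type, required in every contrast |
| `top_n` | 200 | candidates kept per fold and cell type |
| `n_folds` / `min_folds` | 10 / 3 | stability design: folds and minimum recurrence |
| `corr_percentile` | 90 | percentile of pairwise correlations defining the pruning cutoff |
| `prune_mode` | keep_correlated | retain co-varying markers (or drop them) |
| TMM trims | 0.3 / 0.05 | canonical published trim fractions (M, A) |
| `prior_count` | 0.5 | log-CPM offset |
| weight $\varepsilon$ | 1e-2 × median positive $\bar v$ | floor preventing infinite weights |

## What the synthetic generator emulates

`sim_config()` / `simulate_reference_truth()` build a ground-truth peak
universe of planted markers (high accessibility in exactly one cell type,
near-zero elsewhere), log-normal background peaks shared by all types, and
*module decoys* — peaks that behave like markers of one cell type within
the sorted collection but sit inside universal chromatin modules, so only
the module veto (not the differential analysis) can remove them. The
uncharacterized profile equals the background at background peaks and is
exactly zero at every marker (a `leaky_markers` option relaxes this for
robustness studies). Sorted samples draw negative-binomial counts
(dispersion $\phi = 0.2$, i.e. ~45% biological CV, the realistic order for
human samples; $\phi \to 0$ gives Poisson) around length-weighted expected
rates scaled to a configured depth, with multiplicative log-normal study
batch effects (sd 0.2) shared within (study, peak-block) pairs. Bulk
mixtures draw Dirichlet($\alpha$) fractions, optionally reserving a
uniform uncharacterized fraction, and NB counts around the mixed profile.
Everything is deterministic under the config seed; generators snapshot and
restore the caller's RNG state.

What the generator does *not* model: fragment-level artifacts (Tn5
insertion bias, duplicates, GC effects), single-cell sparsity, and —
importantly — per-peak dispersion heterogeneity. Passing tests on this
substrate demonstrate the estimator's correctness and noise behavior, not
performance on real tissue.

## Validation design and problem sizes

The test-suite and `scripts/acceptance.R` recompute, at modest problem
sizes chosen to keep a complete run in minutes on one core:

* **Noiseless identifiability** — 7 cell types, 40 markers each, 20
  mixtures with uncharacterized fractions up to 0.6: recovered fractions
  match the truth to better than $10^{-4}$ (in practice machine
  precision).
* **Optimizer cross-check** — on 100 random 3-cell-type problems the QP
  objective is compared with an exhaustive 0.005-step simplex grid search;
  the fit is never worse than the grid and the grid never beats it by more
  than one grid cell.
* **Stochastic recovery** — 100 NB pseudobulks (depth $10^6$,
  $\phi = 0.2$, Dirichlet $\alpha = 1$, uncharacterized included) against
  a reference built from simulated sorted samples. Batch effects are off
  in this run so that reference and bulk describe the same population and
  count noise is the only error source; batch distortion of reference
  building is exercised separately by the marker-recovery run. Typical
  results: pooled $r \approx 0.99$, RMSE $\approx 0.02$, uncharacterized
  MAE $\approx 0.02$, stable across seeds.
* **Planted-marker recovery** — the full marker pipeline on the default
  generator (5 types × 3 studies × 4 samples, 100 planted markers/type,
  module decoys, batch sd 0.2): recall is 1.0 per cell type and every
  decoy is removed by the module veto.
* **Statistical-engine oracles** — BH against a naive $O(m^2)$
  min-over-tails computation; TMM against a from-scratch trim-and-weight
  evaluation; moderated-t limits ($d_0 = 0$: pooled t; $d_0 = \infty$:
  prior-variance normal); prior recovery $(d_0 = 4, s_0^2 = 1)$ from a
  $10^4$-peak scaled-F simulation; the correlation scan against an
  independent step-through; interval and liftover queries against brute
  force and per-base chain mapping.

### A known precision ceiling of the planted-marker contract

Under the default generator, marker *precision* plateaus near 0.5 even
though recall is perfect. This is structural, and worth understanding
before interpreting precision numbers on any comparable design: with only
100 planted markers per type and `top_n = 200`, ranks 101–200 of each
per-fold list must be filled by the best-ranking background peaks whenever
enough of them qualify. At $\phi = 0.2$ a null peak's group-mean log2
difference has a standard error of ~0.27 with 12 samples per type, so a
few percent of the background passes `lfc > 0.2` toward a given type in
all of its contrasts — far more than the 100 junk slots — and the
stability filter cannot remove them because leave-one-fold-out analysis
sets share 90% of their samples, making per-fold selections nearly
identical. Real reference collections sidestep this because cell types
carry many more than `top_n` genuinely differential peaks, so the top-200
never reaches into noise. For the generator, precision approaches 1 only
when planted markers outnumber `top_n` or dispersion is an order of
magnitude smaller; neither is the default, and the shipped defaults
report the plateau honestly rather than adjusting the substrate to hide
it.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED) everywhere, including
  `"chrom:start-end"` ids; chromosome names match by exact string equality.
* Quantiles (profile medians/IQRs, correlation cutoffs) use type 7.
* Score ties in the consensus collapse break by (chrom, start); nearest /
  overlap ties break to the lowest index — all outputs deterministic.
* `s^2 = 0` peaks are excluded from the prior-moment estimation but still
  shrunk; if the moments imply non-positive excess variance, $d_0 = \infty$
  and all posteriors equal $s_0^2$.
* A rank-deficient reference matrix is ridged ($10^{-10} \times$ trace)
  and the sample flagged `non_unique` instead of failing.
* Zero-variance vectors yield `NA` correlations (reported, never imputed);
  all-zero samples, empty feature intersections and mismatched genome
  builds raise errors naming the offending sample/file/build.
* Solver slack never leaks: $\hat p_u = \max(0, 1 - \sum \hat p)$ and the
  final renormalization makes fractions sum to exactly 1.

## Limitations

* No confidence intervals on fractions; samples are fitted independently.
* Closely related cell types (e.g. T-cell subtypes) share accessibility
  and are intrinsically harder to separate; expect lower per-type
  correlations for low-abundance or related types.
* The liftover is deliberately minimal (single best chain, same-block
  endpoints); it is not a replacement for a full lifter on complex
  rearrangements.
* RNA-Seq deconvolution, gene-activity aggregation and comparisons with
  third-party tools are out of scope.
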