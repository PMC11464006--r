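# atacdeconv

Cell-type deconvolution of bulk ATAC-Seq data against reference
chromatin-accessibility profiles, including the fraction of
**uncharacterized** cells — cell types absent from the reference, chiefly
malignant cells in tumor samples.

## The problem and who this is for

Bulk ATAC-Seq measures chromatin accessibility of a cell mixture. For
tumor and immune-profiling studies the question is *what fraction of each
cell type* — B cells, T cells, NK, myeloid, fibroblasts, endothelial
cells, and the cancer cells themselves — makes up each sample. This
package estimates those fractions from a peaks × samples fragment-count
matrix, and also provides the full upstream pipeline that builds the
required reference from sorted-cell ATAC-Seq samples:

1. **Consensus peaks** — two-level iterative overlap merging of per-sample
   peak calls (within-study reproducibility at half the samples, then
   detection in every study per cell type; chrY excluded).
2. **Marker discovery** — pairwise differential accessibility on
   TMM-normalized log-CPM with empirical-Bayes moderated t-tests
   (log2FC > 0.2 in every contrast, top 200 per fold by worst adjusted p,
   recurrence in ≥ 3 of 10 stratified folds), followed by a
   chromatin-module veto (universal/tissue open-chromatin modules, with
   per-cell-class exemptions) and optional correlation-based refinement on
   tumor bulk samples.
3. **Reference profiles** — per-cell-type median and IQR of the TPM-like
   accessibility.
4. **Deconvolution** — for each bulk sample, weighted constrained least
   squares on the marker peaks:

   minimize Σⱼ wⱼ (bⱼ − Σᵢ Rⱼᵢ pᵢ)²  subject to  pᵢ ≥ 0, Σᵢ pᵢ ≤ 1,

   with weights wⱼ = 1/(v̄ⱼ + ε) from the reference IQRs, solved exactly as
   a convex quadratic program; the uncharacterized fraction is the simplex
   deficit p_u = 1 − Σᵢ pᵢ, identifiable because markers are selected to be
   silent in cell types outside the reference.

A seeded synthetic-data generator (planted markers, module decoys,
negative-binomial noise, study batch effects, Dirichlet mixtures) and
Pearson/RMSE scoring close the loop for validation. See the vignette in
`vignettes/atac-deconvolution.Rmd` for the model, parameter meanings and
design decisions.

## Worked example

Simulate a small cohort, build a reference from sorted samples, and
deconvolve 20 bulk mixtures with known composition:

```r
library(atacdeconv)

cfg     <- sim_config(n_cell_types = 5, seed = 42, batch_sdlog = 0)
truth   <- simulate_reference_truth(cfg)
sorted  <- simulate_sorted_samples(truth, cfg)
profile <- build_profile(tpm_like(sorted))
profile <- set_profile_markers(profile, truth$marker_truth)

bulk <- simulate_bulk(truth, 20, cfg)
res  <- deconvolve(bulk$counts, profile)
head(as.data.frame(res)[, 1:7], 3)
#>   sample_id Bcells CD4_Tcells CD8_Tcells Monocytes     NK uncharacterized
#> 1     bulk1  0.472     0.1995     0.0538   0.03773 0.0254           0.211
#> 2     bulk2  0.109     0.2871     0.1769   0.00816 0.0721           0.347
#> 3     bulk3  0.112     0.0831     0.1035   0.08496 0.0468           0.569

metrics_table(res, bulk$proportions)
#>         cell_type     r    rmse   n
#> 1          Bcells 0.999 0.01506  20
#> 2      CD4_Tcells 0.998 0.00656  20
#> 3      CD8_Tcells 0.997 0.00946  20
#> 4       Monocytes 0.999 0.01662  20
#> 5              NK 0.998 0.00696  20
#> 6 uncharacterized 0.997 0.03304  20
#> 7          pooled 0.993 0.01720 120
```

Each row of the result is one bulk sample; the cell-type columns and
`uncharacterized` are fractions summing to 1. Under negative-binomial
count noise at depth 10⁶ the estimates track the true mixing proportions
with pooled Pearson r ≈ 0.99 and RMSE ≈ 0.02; the uncharacterized column
recovers the planted "cancer" fraction without any profile for it.

Real data enter through the same types: `read_counts_tsv()` /
`read_counts_mtx()` for bulk matrices (row ids `chr:start-end`),
`parse_bed()` for peak calls, `read_profile()` for serialized references,
and `read_chain()` + `deconvolve(..., chains = )` to lift hg19 bulk data
onto an hg38 reference. A command-line wrapper with subcommands
`consensus`, `markers`, `deconvolve`, `simulate`, `evaluate` is installed
at `system.file("exec", "atacdeconv", package = "atacdeconv")`.

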