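# cellvar

Differential cell-to-cell expression variability for two-condition
single-cell RNA-seq.

Most single-cell comparisons ask whether a perturbation changes a gene's
*mean* expression. cellvar asks whether it changes a gene's *variability*
across cells — the expression noise — and provides the full supporting
pipeline: quality filters, TPM normalisation, noise estimation,
variation-gene classification, overlap enrichment with expression-changed
genes, PCA separation diagnostics, and regulatory-peak counting near
transcription start sites. A negative-binomial simulator with known ground
truth makes every stage testable without external data. It is written for
computational biologists analysing plate- or microfluidics-based (full
length) scRNA-seq of a control and a perturbed population.

## The statistic

For each gene and condition, on linear TPM with the n−1 denominator:

- expression noise **η² = σ²/μ²**, the squared coefficient of variation
  (for negative-binomial counts, η² ≈ 1/μ + φ: sampling noise at low
  expression, a plateau at the biological overdispersion φ above it);
- **CV = σ/μ**, and the classifier statistic **ΔCV = CV_KD − CV_WT**.

After removing low-expressed genes (pooled mean log2(TPM+1) ≤ 1, where the
1/μ term dominates), genes are labelled by the mean ± SD rule on ΔCV with
strict inequalities:

- increased: ΔCV > mean(ΔCV) + sd(ΔCV)
- decreased: ΔCV < mean(ΔCV) − sd(ΔCV)
- unchanged: otherwise.

Overlap between variation-changed and expression-changed gene sets is
tested with a Pearson χ² on the 2×2 membership table (Fisher exact as the
cross-check), over the universe of genes carrying variation labels.

## Worked example

The one-command demo simulates a 96-cell, 10,000-gene two-condition
experiment in which 80% of dispersion-increased genes are also
mean-decreased, then runs the whole pipeline:

```r
library(cellvar)
cfg <- pipeline_config(sim_config(seed = 1, coupling = 0.8))
report <- run_pipeline(cfg)
print(report)
#> <pipeline_report>
#>   cells: 96 -> 96 after QC; genes: 10000 -> 9978 after prevalence, 8762 past low-expression cutoff
#>   variation: 946 increased / 739 decreased / 7077 unchanged
#>   DE: 255 up / 1016 down (alpha = 0.05)
#>   down & increased overlap: a = 724, chi2 p = 0
#>   PC1 condition separation p = 4.04e-131
#>   peak proximity: computed
```

Reading the report: all 96 simulated cells pass the 3000-detected-gene
filter; 9978 genes survive the prevalence filter and 8762 the
low-expression cutoff; the mean ± SD rule labels 946 genes
variation-increased and 739 variation-decreased. Because the simulation
couples mean decrease with dispersion increase, 724 of the 1016
down-regulated genes fall in the increased class — a χ² p-value at floating
point zero — and the two conditions separate completely on PC1. Individual
stage results live in `report$objects` and are tibbles throughout
(`glance(report$objects$vcs)`, `tidy(report$objects$pca, "scores")`,
`autoplot(report$objects$vcs)`).

The same stages run on real data from files:

```r
cfg <- pipeline_config(input = list(
  counts = "counts.mtx", cells = "cells.tsv", lengths = "lengths.tsv",
  de_table = "edger_results.tsv",   # optional external DE calls
  peaks = "peaks.bed", tss = "tss.tsv"
))
report <- run_pipeline(cfg)
```

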