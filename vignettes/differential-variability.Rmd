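---
title: "Quantifying differential cell-to-cell expression variability with cellvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential cell-to-cell expression variability with cellvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellvar)
library(dplyr)
```

## The question

Two cell populations — a reference (here labelled WT) and a perturbed
condition (KD, e.g. a transcription-factor knockdown) — can differ not only
in *how much* each gene is expressed on average but in *how variable* each
gene's expression is from cell to cell. cellvar implements a complete
pipeline for the second question on single-cell RNA-seq count matrices:
quality filtering, TPM normalisation, per-gene expression-noise estimation,
classification of variation-increased and variation-decreased genes, and the
downstream analyses that relate variability changes to expression changes
(overlap enrichment), to global structure (PCA separation), and to
regulatory-site density near transcription start sites.

## The noise model and the classifier

For a gene with across-cell mean $\mu$ and standard deviation $\sigma$
(computed on linear TPM with the $n-1$ denominator), expression noise is the
squared coefficient of variation,

$$\eta^2 = \frac{\sigma^2}{\mu^2} = \mathrm{CV}^2 .$$

For counts drawn from a negative binomial with variance
$\mu + \phi\,\mu^2$, the expectation is

$$\eta^2 \approx \frac{1}{\mu} + \phi :$$

a $1/\mu$ sampling-noise regime at low expression and a plateau at the
biological overdispersion $\phi$ at high expression. This two-regime shape
is why the pipeline removes low-expressed genes (pooled mean
$\log_2(\mathrm{TPM}+1) \le 1$) before comparing variability: below that
cutoff, measured noise mostly reflects sampling depth, not biology.
`noise_vs_expression_profile()` exposes the empirical curve so the cutoff
can be judged per dataset.

The classifier statistic is the per-gene change in coefficient of
variation, $\Delta CV = CV_{KD} - CV_{WT}$, over the genes passing the
low-expression cutoff. With $m$ and $s$ the sample mean and standard
deviation of $\Delta CV$ over those genes, a gene is

* **increased** when $\Delta CV > m + s$,
* **decreased** when $\Delta CV < m - s$,
* **unchanged** otherwise.

The inequalities are strict, so a degenerate spread ($s = 0$) labels
nothing. Genes with zero mean in either condition have no defined CV; they
are excluded before $m$ and $s$ are computed and their count is recorded on
the result. `normality_check()` reports the skewness, excess kurtosis and a
goodness-of-fit test of $\Delta CV$ against a fitted normal — descriptively,
because the rule itself makes no distributional assumption, but the familiar
"roughly 16% per tail" intuition only holds when $\Delta CV$ is close to
normal (see *Limitations*).

## Parameters and defaults

| Parameter | Default | Where | Why |
|---|---|---|---|
| `min_genes` | 3000 detected genes/cell | `filter_cells_by_detected_genes()` | standard cell-quality bar for full-length libraries; detection = raw count > 0, threshold inclusive |
| `level`, `min_cells` | $\log_2(\mathrm{TPM}+1) > 1$ in $\ge 2$ cells | `filter_genes_by_prevalence()` | removes genes never reliably observed; strict `>` at the level |
| `cutoff` | pooled mean $\log_2(\mathrm{TPM}+1) > 1$ | `low_expression_filter()` | excludes the $1/\mu$ sampling-noise regime before classification |
| `cv_on` | `"tpm"` | `gene_noise_stats()` | $\sigma/\mu$ on log-transformed values is not a conventional CV; a `"log"` option exists for sensitivity analyses |
| `alpha` | 0.05 | `simple_de_test()`, `import_de_results()` | conventional FDR level on BH-adjusted q |
| `window` | 20,000 bases | `count_peaks_near_tss()` | regulatory neighbourhood of a TSS; closed window, any-overlap rule |
| `n_pcs` | 10 | `pca_embed()` | enough components for separation and single-gene correlation diagnostics |

Choices the data do not dictate, decided once and exposed as flags:

* **CV scale.** Linear TPM (default), because CV is a ratio statistic of the
  linear mean; computing it on $\log_2(\mathrm{TPM}+1)$ compresses exactly
  the spread being measured.
* **Pooling for the cutoff.** The low-expression cutoff uses the mean over
  *all* retained cells rather than per-condition means, so the classified
  gene set does not depend on which condition is noisier.
* **TPM lengths.** TPM needs effective gene lengths. When none are given
  the pipeline falls back to counts-per-million (all lengths 1) and records
  the fallback in the filter log. Per-gene statistics downstream (CV,
  noise, gene-centred PCA) are unaffected because length cancels within a
  gene.
* **PCA.** Gene-centred, not unit-scaled (scaling is available by flag);
  computed on all retained genes rather than a highly-variable subset; PC
  signs fixed by making the largest-magnitude loading positive so results
  are reproducible across platforms.
* **Separation test.** Classical equal-variance two-sample t-test on a PC
  coordinate (Welch by flag), with groups ordered alphabetically so the
  sign of the statistic is deterministic.
* **Overlap universe.** The 2×2 overlap test between expression-changed and
  variation-changed genes uses, as its universe, the genes on which
  variation labels exist (those passing the low-expression cutoff); DE
  calls outside that universe are dropped and counted.
* **Chi-square.** Pearson, 1 df, no Yates correction by default (tables here
  are large); `fisher_exact()` is the exact cross-check and the advised
  fallback when a margin is empty.
* **TSS policy.** One TSS per gene; `most_upstream` (5'-most in the
  direction of transcription) by default, `longest_transcript` by flag.
  GTF coordinates (1-based, inclusive) are converted to 0-based positions;
  BED peaks are 0-based half-open. A peak is counted when it overlaps any
  part of the closed window $[\mathrm{tss}-w, \mathrm{tss}+w]$; a
  peak-midpoint rule is available by flag.
* **Wilcoxon.** Exact enumeration when the combined sample is at most 12
  with no ties, otherwise the tie-corrected normal approximation with
  continuity correction. The per-gene DE stand-in uses the same
  approximation, vectorised across genes, and is checked in the test suite
  for exact agreement with the reference implementation.

## The synthetic-data generator

`simulate_counts()` draws a two-condition, two-batch experiment mimicking a
microfluidics full-length protocol: by default 24 cells per condition per
batch (96 cells), 10,000 genes, log-normal baseline expected counts
(median 5, `sdlog` 1.8 — a realistic spread of expression across four
orders of magnitude at a depth of a few hundred thousand reads per cell),
and negative-binomial counts with baseline dispersion $\phi_0 = 0.3$.
Ground truth is returned alongside the counts:

* a `fraction_de` share of genes (5%) receives a 4-fold mean change, half
  up, half down;
* a `fraction_disp` share (10%) has dispersion multiplied by 4 in KD (true
  variation-increased genes) and a symmetric `fraction_disp_down` share
  divided by 4;
* the `coupling` fraction of the dispersion-increased genes is additionally
  mean-decreased — the mechanism whose downstream signature is an overlap
  between down-regulated and variation-increased genes;
* dropout is off by default (full-length chemistry is far less
  zero-inflated than droplet data) but available as a logistic thinning on
  gene mean; batch multipliers default to 1.

`simulate_annotation()` lays the genes along one synthetic chromosome with
non-overlapping TSS windows and scatters Poisson-distributed peaks at a
higher rate over true variation-increased genes, so the peak-proximity
stage has a recoverable signal.

What the generator does **not** emulate: transcript-level coverage bias,
UMI deduplication, cell-cycle or lineage structure, correlated gene
modules, and empirical dropout patterns. Passing the recovery tests
therefore demonstrates correctness of the statistical machinery under a
clean count model, not robustness to every artefact of real data.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: the
classifier against a brute-force reimplementation on random instances; the
chi-square and BH adjustment against the reference implementations in base
R; the interval counter against an $O(nm)$ double loop; the vectorised
rank-sum against per-gene `wilcox.test()` calls; NB moments against the
closed form $CV^2 = 1/\mu + \phi$. Distributional checks use 5000 cells
per condition (noise scaling), 20 replicates of 5000 genes at 24 cells per
condition (null calibration), and 20 seeded replicates of the full 96-cell,
10,000-gene pipeline per coupling setting (overlap direction). These sizes
were chosen so each property is measured with comfortable Monte-Carlo
margin while the whole suite stays quick on a laptop.

## Limitations

* **Mean changes move the CV.** Because $\eta^2 \approx 1/\mu + \phi$, a
  gene whose mean drops fourfold gains CV through the sampling term even if
  its biological overdispersion $\phi$ is untouched. Down-regulated genes
  therefore drift toward the variation-increased class (and up-regulated
  genes toward variation-decreased) on count data *by construction*, at any
  realistic sequencing depth. The overlap between expression-changed and
  variation-changed gene sets should be read with this in mind: the 2×2
  chi-square is well calibrated for independent gene sets (verified in the
  test suite on random sets), but "down-regulated ∩ variation-increased"
  enrichment conflates genuine dispersion coupling with this mechanical
  effect. The low-expression filter reduces, but cannot eliminate, the
  $1/\mu$ contribution.
* **Rank tests detect dispersion, not only location.** The built-in DE
  stand-in compares full distributions; a pure dispersion increase at fixed
  mean lowers the NB median and can be called significant. Mean-focused DE
  from a dedicated count-model tool, imported via `import_de_results()`, is
  the better input when the goal is to separate mean effects from
  variability effects.
* **Tail fractions under the null.** At 24 cells per condition, $\Delta CV$
  is a scale mixture across expression levels and hence heavier-tailed than
  normal; the mean ± SD rule then labels closer to 11–12% per side than the
  15.9% a normal reference suggests. `normality_check()` makes this visible
  per dataset.
* The classifier emits labels, not per-gene significance: the mean ± SD
  rule is a population-relative threshold, and a gene's label depends on
  the whole gene set under analysis.
* Spike-in-based technical-noise decomposition, batch correction, and
  clustering are out of scope; inputs are assumed to start from a count
  matrix.
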