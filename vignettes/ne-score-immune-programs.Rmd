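---
title: "Scoring neuroendocrine identity and its anti-correlated immune programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neuroendocrine identity and its anti-correlated immune programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nescore)
```

## The model

Small cell lung cancer (SCLC) spans a phenotypic axis from *classic*
neuroendocrine (NE) tumors, driven by the lineage factor ASCL1, to *variant*
tumors with depleted NE features and YAP1/POU2F3-associated programs. The
package quantifies where a transcriptome sits on that axis with a two-centroid
signature score: a 50-gene reference panel carries one expression prototype
for NE cell lines and one for non-NE cell lines, both on log2 scale, and a
test profile is scored as

$$\mathrm{NE\ score} = \frac{r_{\mathrm{NE}} - r_{\mathrm{non\text{-}NE}}}{2},$$

where $r_{\mathrm{NE}}$ and $r_{\mathrm{non\text{-}NE}}$ are Pearson
correlations between the profile and the two centroids over the signature
genes shared with the profile. Because each correlation lies in $[-1, 1]$,
the score lies in $[-1, 1]$; a positive score calls the sample NE, a negative
score non-NE, and an exact zero is reported as indeterminate rather than
silently binned. Pearson correlation is invariant to positive-slope affine
transforms of the profile, so per-sample standardization (or any rescaling)
leaves the score unchanged — a property the tests exercise directly.

The biological use of the score is relational: genes and gene programs are
characterized by how they co-vary with it. In SCLC cohorts, REST-target genes
track the score positively while interferon-stimulated genes (ISGs), MHC
class I genes and immune-infiltration signatures track it negatively — low-NE
"variant" samples carry the active immune programs. The package provides the
full chain used to establish such patterns: correlation screens, pre-ranked
GSEA, single-sample GSEA, and a categorical sign-proportion test.

## Scoring parameters

* `min_genes` (default 40 of 50, i.e. 80%): the minimum number of signature
  genes that must be measured in a profile. Platforms missing many signature
  genes produce unstable correlations; the threshold is a package decision
  (no published policy exists), is configurable, and the genes actually used
  are always reported as `n_genes_used`. `NA` values in a profile drop that
  gene pairwise and decrement the count.
* Scale: scoring assumes log2 expression, since the signature centroids are
  log2-scale. `score_matrix()` consults the matrix's scale tag and
  log2(x+1)-transforms linear input with a warning rather than scoring raw
  intensities.
* Centroids are taken as given from the signature file; the package does not
  re-derive them from cell-line cohorts.

## Preprocessing

`quantile_normalize()` forces all samples onto the common distribution given
by the row means of the column-sorted matrix. Tied values within a column
receive the mean of the reference values at their tied ranks — the
conventional tie policy of the widely used implementation; the function is
idempotent and preserves each column's rank order. `log2_transform()` uses a
configurable pseudocount (default 1.0; no published offset exists, so the
default is declared, not inferred). `library_size_normalize()` rescales each
single-cell library to the median of the observed totals (a fixed target can
be supplied). `zscore_standardize()` uses the sample (n−1) standard
deviation everywhere and maps constant vectors to zeros with a warning.
`cluster_average_minmax()` builds the pseudobulk view used for cell-type
panels: clusters under 10 cells are dropped (the cutoff used for the
single-cell analyses it mirrors), cluster means are computed per gene, then
min–max scaled to [0, 1] across clusters; genes flat across clusters become
zeros with a warning.

## Pre-ranked GSEA

Genes are ranked by their Pearson correlation with the NE score (descending;
metric ties break by gene id so the ranking is deterministic). The
enrichment score is the classic weighted Kolmogorov–Smirnov statistic:
walking the ranking, in-set genes add $|r|^p / \sum_{\mathrm{hits}} |r|^p$
and out-of-set genes subtract $1/(N - N_\mathrm{hit})$; the ES is the
running sum's extreme of larger absolute value. Numerical choices worth
stating:

* Weight exponent `p` defaults to 1 (the classic weighted statistic),
  configurable; `p = 0` gives the unweighted KS form.
* When the positive and negative extremes tie in absolute value, the
  positive one is reported; the comparison carries a `1e-12` slack so the
  choice cannot flip with floating-point summation order. The brute-force
  oracle in the test suite applies the same rule.
* If every in-set metric is exactly zero (possible with `p > 0`), hit
  weights fall back to equal weights so the statistic stays defined.
* The leading edge is the set members at or before the maximum (at or after
  the minimum for negative ES).

The null distribution comes from **gene-label permutation**: size-matched
random sets drawn from the ranked genes, one shared null per distinct set
size, fully determined by the `seed` argument. The p-value is
$(1 + \#\{\text{same-sign null ES at least as extreme}\}) /
(1 + \#\{\text{same-sign null ES}\})$, so it is floored at
$1/(n_\mathrm{perm}+1)$ and never zero; NES divides the ES by the mean
absolute same-sign null ES. NES conventions differ across tools, so this
estimator is stated explicitly. Benjamini–Hochberg adjustment is applied
within the tested collection (one library at a time), matching per-library
reporting practice.

A **sample-label permutation** mode (`gsea_sample_permutation()`) is
provided for synthetic cohorts: it permutes the score vector, recomputes the
correlation ranking and re-evaluates each set. On strongly co-expressed
planted modules this null is deliberately conservative — the module's genes
stay mutually correlated under any score permutation, cluster somewhere in
every permuted ranking, and keep the null |ES| high. The tests therefore
assert orientation and determinism for this mode, not significance;
gene-label permutation is the mode the package's quantitative guarantees
rest on.

## Single-sample GSEA

`ssgsea()` scores one sample at a time: genes are ranked by expression
(descending; average ranks for ties, tie order fixed by gene id), and the
score is the sum over ranking positions of the difference between the
weighted empirical CDF of in-set genes and the unweighted ECDF of the
out-of-set genes. The in-set weight of the gene at descending position $i$
is its rank-from-the-bottom $(N - i + 1)^\alpha$, normalized within the set,
so the most expressed genes weigh most; with $\alpha = 0$ the statistic
reduces to the plain ECDF difference, which the tests check against a
closed-form small case. Defaults are $\alpha = 0.25$ and range
normalization (dividing the whole score matrix by its global max − min) —
the conventions of the tool this methodology popularized — and both are
recorded as attributes on the output.

## Association statistics

Correlation screens report Pearson r with two-sided p-values from the exact
t transform with $n-2$ degrees of freedom, pairwise-complete observations,
and BH adjustment over the tested genes. Group comparisons default to
Welch's unequal-variance t-test (a pooled-variance flag exists); only
"t-test" is conventionally specified, and Welch is the safer default. The
sign-proportion test asks whether a gene category (e.g. innate immune
genes) is negatively associated with the NE score more often than the
background: a 2×2 table of (in-set vs background) × (negative vs
nonnegative r), Pearson's chi-squared without continuity correction, 1 df.
The sign of r is the default association criterion, with a flag to restrict
to BH-significant genes first; the choice of test statistic for this
category comparison is a package decision.

## Quantification arithmetic

The IHC H-score is $3 p_\mathrm{strong} + 2 p_\mathrm{moderate} +
1 p_\mathrm{weak}$ over intensity-extent percentages, range 0–300;
percentages must be nonnegative and sum to at most 100 (the remainder is
intensity 0). T-cell infiltration is summarized as cells per mm² of
analysed tissue. qPCR relative expression summarizes target and control
(PPIA) Ct values by the median over replicates, normalizes as
$2^{\mathrm{Ct}_\mathrm{control} - \mathrm{Ct}_\mathrm{target}}$, and
divides by the median of the parental samples' normalized values. The
published wording is ambiguous about whether the median is taken per gene
over Ct or per replicate over ΔCt; the default takes per-gene Ct medians
(reading "the median was taken from triplicates" as per-measurement), and a
`median_dct` mode provides the alternative.

## The synthetic-data generator

Real SCLC cohorts require controlled-access or external downloads, so the
package ships a seeded generator reproducing the statistical structure the
analysis assumes, with truth labels for recovery tests:

* each sample has a latent NE state $s \sim U(-1, 1)$ (or a two-group
  mixture);
* the 50 signature genes follow the convex centroid blend
  $\tfrac{1+s}{2}\,\mathrm{ne} + \tfrac{1-s}{2}\,\mathrm{non\text{-}ne}$,
  with centroids rejection-sampled to non-positive correlation (an exact
  mirror option forces correlation −1 for adversarial bound checks);
* 100 immune-program genes couple to $s$ with slope −2 log2 units, 100
  REST-target genes with slope +2, over per-gene baselines drawn once;
* 800 background genes are neutral, giving quantile normalization realistic
  heterogeneity and the enrichment null a large pool;
* everything gets i.i.d. Gaussian noise (sd 1) and all randomness flows
  from one explicit seed, leaving the session RNG untouched.

These defaults — 200 samples, ±2 slopes against noise 1 — describe a
desk-scale cohort in which per-gene score correlations for program genes
are strong but not saturated (|r| ≈ 0.7), comparable to the clearer
program genes in real cohorts. The convex blend makes the noise-free score
*strictly increasing* in $s$, but not linear in it: rank agreement with the
latent state is exact in the noise-free limit while the Pearson correlation
plateaus near 0.99, and the tests assert exactly that. Planted sets
(`IMMUNE_PROGRAM`, `REST_TARGETS`, and a size-matched `RANDOM_K` draw of
background genes) support enrichment recovery: at defaults, the immune set
recovers a negative NES with adjusted p < 0.05 and the random set does not,
in at least 9 of 10 seeded replicates.

The generator deliberately omits count-level noise (negative binomial
dispersion, dropout), batch effects, and correlated backgrounds. Passing
recovery tests therefore demonstrates that the pipeline's statistics behave
as designed under their own assumptions — not that those assumptions hold
in any particular real cohort.

## Problem sizes and runtime choices

The test suite runs the oracle comparisons exhaustively at small N (all
proper subsets of rankings up to 8 genes; all 2×2 tables with cells 1–8),
uses 10,000 random profiles for the score-bound check, 150 null sets × 999
permutations for p-value calibration, and 10 seeded replicates of the
200-sample default cohort with 500 permutations each for program recovery.
These sizes make the whole suite complete in about a minute on one core
while keeping every Monte-Carlo check comfortably powered.

## Known limitations

* NES values from cohort-scale sample-permutation GSEA on the original data
  sets are not reproducible without those cohorts and are out of scope.
* The signature is an input; the package does not derive or update it, and
  does not perform multi-class transcription-factor subtype calling.
* ssGSEA scores are reported on the conventional range-normalized scale;
  absolute values are not comparable across gene-set collections run
  separately.
* GCT support targets version 1.2; sparse single-cell formats are out of
  scope for the I/O layer.
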