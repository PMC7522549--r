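---
title: "Methods: integrated transcriptome-proteome hub-gene analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated transcriptome-proteome hub-gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasomics)
```

## The analysis problem

pasomics implements an integrated analysis of paired bulk transcriptome
(mRNA read counts) and proteome (intensity) profiles from a small
case-control cohort — the motivating setting is placenta accreta spectrum
(PAS), with placental tissue from 5 affected and 5 unaffected pregnancies,
17,860 quantified mRNAs, and 4,800 quantified proteins forming a subset of
the mRNA universe. The scientific question is which genes are *hub genes*:
differentially expressed in both omics layers with the same direction of
change, and therefore the strongest candidates for driving the phenotype.
Around that core the package classifies candidate lncRNA regulators of the
hub genes by genomic position, and tests gene-structure variation (SNP
presence, splice-event expression, gene fusions) for association with case
status.

## Differential expression

Both layers are called at the same joint thresholds: Benjamini–Hochberg
FDR < 0.05 and fold change > 1.5, applied symmetrically
(`|log2FC| >= log2(1.5)`). The fold-change cut matters as much as the FDR
cut in a 5-vs-5 design, where tiny shifts can reach small p-values for
high-abundance genes.

**Count layer.** Counts are tested with a conditional negative-binomial
exact test: for each gene, given the two group sums and their total `s`,
the case-group sum under the null of a common per-sample mean follows the
conditional law of one NB variable given an NB sum, and the two-sided
p-value sums the probabilities of all splits no more likely than the
observed one (point-probability rule, computed in log space over a support
window carrying all but ~1e-14 of the mass). A single common dispersion is
estimated across genes by method of moments — ten samples cannot support
per-gene dispersion estimation, and a pooled ratio estimator
`sum(s2 - mu) / sum(mu^2)` over well-expressed genes is stable at this
scale.

Before testing, samples are equalized with **median-of-ratios size
factors** (the ratio of each sample to the gene-wise geometric-mean
reference, median over everywhere-expressed genes) rather than raw column
totals. The reason is composition bias: a modest number of strongly
up-regulated, abundant genes inflates a group's library totals, and
total-count scaling then makes every unchanged gene look shifted the other
way. The median ratio tracks the unchanged majority and is robust to this.
The exported `normalize_counts()` remains plain CPM for reporting and
plotting; the differential step uses the robust factors internally for
both the test and the fold changes. TMM-style trimmed weighting and
empirical-Bayes dispersion shrinkage are deliberately out of scope — the
downstream hub-gene logic is threshold-driven, not engine-driven.

**Intensity layer.** Protein intensities are tested with a Welch
(unequal-variance) t-test on `log2(x + 0.5)` values. Intensities are
continuous and approximately log-normal; zero-variance rows return p = 1
rather than NaN.

## Cross-omics integration

**Per-gene correlation.** For every gene quantified in both layers, the
Pearson correlation between its log2 mRNA and log2 protein values across
the matched samples. Genes with zero variance in either layer are flagged
degenerate (with a reason, not silently set to 0) and excluded from the
positive-fraction denominator. The fraction of positively correlated genes
is the headline summary; typical paired designs put it around 60%.

**Hub selection.** The co-differential set is the exact intersection of
the two significant gene lists (order-stabilized by gene id). The trend
filter partitions it by sign agreement of the two log2 fold changes; a
zero fold change — possible only through pseudocounts — is classified
inconsistent and flagged, since a gene with no estimated direction cannot
support a consistency claim.

**Overlap null.** Whether the intersection is larger than chance is tested
by simulation: each replicate draws the two differential sets uniformly at
random (728 of 17,860; 439 of the 4,800-gene subset) and counts the
intersection; the p-value is the plain fraction of replicates with overlap
at least the observed 31 (the add-one variant is available by flag, but
the plain proportion is the primary definition so that the reported value
is an unbiased tail estimate). Because the protein draw is uniform within
a fixed subset of the mRNA universe, the null intersection is exactly
hypergeometric — `X ~ Hypergeom(N = 17860, K = 439, n = 728)`, the subset
size cancelling — and `overlap_hypergeometric_tail()` reports this closed
form alongside every permutation estimate as an internal oracle. At the
default 10,000 replicates the Monte-Carlo standard error at p ≈ 0.002 is
about 0.00045.

**Fold-change correlation.** The Pearson correlation between the two
layers' log2 fold changes over the co-differential genes, with a two-sided
test. Whether such a summary should use fold changes or another expression
summary of the same genes is genuinely ambiguous in practice; this package
computes it on fold-change pairs and documents that choice.

## Preranked enrichment on the correlation ranking

Genes ranked by their mRNA–protein correlation are scored against
user-supplied gene sets (GMT format) with the weighted Kolmogorov–Smirnov
running sum: hits advance by `|score|^weight` normalized by the set total,
misses retreat by `1/(N - n_hits)`, and the enrichment score is the
extremum of the running sum (which returns to zero by construction).
Weight defaults to 1; ties in scores are broken lexicographically by gene
id so rankings are reproducible.

The null is built by **gene-label permutation** — set membership redrawn
uniformly over the ranked list, size-preserving. There is no phenotype to
permute here: the ranking metric is itself a per-gene statistic, so label
permutation is the appropriate (and standard) preranked convention. NES
divides the ES by the mean absolute null ES of matching sign; p-values are
sign-matched tail proportions floored at `1/n_perm`; FDR q follows the
sign-stratified NES-null ratio scheme. No pathway database content ships
with the package: enrichment runs on user-supplied sets only.

## lncRNA target rules

Positional cis classes follow the three-window vocabulary: `cis_up10k`
(lncRNA within 10 kb upstream), `cis_dw20k` (within 20 kb downstream),
`cis_overlap` (sharing at least one base, distance 0). Distances are
edge-to-edge coordinate gaps (gene start minus lncRNA end on the
lower-coordinate side), the least-assumption reading when no anchor point
(TSS vs gene edge) is specified; the windows are configurable. Up- and
downstream are strand-aware — for a minus-strand gene the 5' side is the
higher-coordinate side — and genes of unknown strand are refused rather
than silently misclassified. Pairs with no cis relation are called `trans`
when either |Pearson r| or |Spearman rho| across samples reaches 0.9, a
deliberately strict default for n = 10, where the null probability of
|r| ≥ 0.9 is far below 1%; everything else is `none`. Cis precedence over
trans is total: position is structural evidence, correlation only
supporting.

Intervals are handled 1-based inclusive internally (GTF convention);
BED input is converted at the boundary by the rtracklayer importer.

## Gene-structure association

Exact tests are used throughout because every unit is a 5-vs-5
comparison:

* **Variants** (per gene × effect class, six-class vocabulary with
  `other` as catch-all): presence/absence vs case status in a 2×2 table,
  Fisher's exact test with the **point-probability two-sided rule** (sum
  of tables no more probable than observed, 1e-7 relative tie tolerance).
  The canonical 4-of-5-cases vs 0-of-5-controls table gives p = 0.0476
  (printed as 0.048). Only classes observed in at least one sample are
  tested.
* **Splice events** (seven-type vocabulary AE/TSS/TTS/IR/MIR/SKIP/MSKIP):
  exact Mann–Whitney on case vs control expression. The exact two-sided
  p is `2·min(tails)` from the full dynamic-programming U distribution
  when there are no ties and n + m ≤ 20; otherwise a tie- and
  continuity-corrected normal approximation, flagged `approximate`.
  Complete separation at 5 vs 5 gives 2/252 ≈ 0.0079; U = 2 gives
  8/252 ≈ 0.032. The exact form is the right choice at this scale — the
  corrected normal approximation gives 0.037 for U = 2 and would not
  reproduce small-sample results. Because the test is rank-based, the
  unit of the expression values (count, FPKM, ratio) does not affect
  p-values.
* **Fusions:** carrier counts per group are the primary readout; a Fisher
  p is computed only on request, since 3-of-5 vs 0-of-5 (p = 1/6) shows
  how little power presence counts have at this n.

Association p-values are reported raw by default, matching small-cohort
screening practice for a 23-gene candidate panel; a BH flag is available
for reuse in larger screens.

## The synthetic-data generator

`generate_paired_omics()` produces datasets with the statistical structure
the analysis assumes, so the whole pipeline is testable without external
data. Defaults are fixed at the study design: 5 + 5 samples, 17,860
mRNAs, a 4,800-gene protein subset, 728/439 planted differential genes,
23 + 8 planted co-differential genes (consistent/inconsistent), |log2FC|
uniform on [1.0, 6.7].

The model, per gene *g* and sample *j*:

* baseline abundance `B_g ~ LogNormal(log 100, 1.3)` (a moderate-depth
  bulk library of ~4M counts); library-size factors log-normal with
  CV 20% so normalization is exercised;
* a latent factor `f_gj ~ N(0,1)` shared between layers; biological
  log-deviations `b_m = sigma·(sqrt(rho)·f + sqrt(1-rho)·u)` and
  `b_p = tau·(sqrt(rho)·f + sqrt(1-rho)·v)` with independent `u, v`, so
  the two layers' biological components correlate at exactly `rho`;
* mRNA counts Poisson around `B_g · 2^{L_g·case} · exp(b_m - sigma²/2)`
  with `sigma² = log(1 + dispersion)`: marginally the counts match a
  negative binomial with the configured dispersion (default 0.1), and —
  importantly — the shared latent is *inside* that dispersion, not on top
  of it, so the moments-estimated dispersion sees the full biological
  variance and the exact test stays calibrated;
* protein intensities log-normal with CV 0.2 (`tau² = log(1 + cv²)`),
  shifted by the planted protein-layer log2 fold change.

`rho` (latent_correlation_strength) defaults to **0.13**, chosen
analytically: Poisson noise attenuates the observed log-log correlation to
roughly `0.9·rho` at typical abundances, and by the Fisher-z argument the
fraction of genes with positive sample correlation at n = 10 is about
`Phi(atanh(0.9·rho)·sqrt(7)) ≈ 0.62`, the fraction reported for paired
placental profiling. At `rho = 0` the fraction centers on 0.5, which the
tests verify.

Hub genes are planted with controlled cross-layer signs (consistent ones
matching, inconsistent ones opposite) because the trend filter must be
exercised in both directions; the 8 inconsistent genes are planted
explicitly since only the consistent 23 are ever listed in practice. The
planted differential sets are constructed so their intersection is exactly
the hub set, making ground-truth recovery unambiguous.

What the generator does **not** emulate: batch effects, sample swaps,
missing protein quantifications, count-level technical artifacts
(GC/length bias), or any real placental biology. Passing recovery tests
therefore shows the pipeline is correct under its own model assumptions —
not that the biological findings of any particular cohort are
reproducible from raw data.

The structure-table generator plants three variant units at 4-of-5 cases
vs 0 controls (reproducing the canonical 0.048), two splice events with a
2.5-log2 case shift, one fusion in 3 of 5 cases, and background units with
no group association (presence probability 0.3 in both groups; background
splice events share one distribution).

## Numerical choices and degenerate inputs

* Exact-test p-values are computed in log space; sums within 1e-9 of 1
  (the symmetric degenerate case) snap to exactly 1.
* Missing expression values are rejected at the boundary, not imputed —
  the intended inputs quantify every reported gene in every sample.
* Empty 2×2 margins return p = 1 flagged degenerate; constant correlation
  vectors return NA with a degenerate flag.
* Pseudocount 0.5 on group means for fold changes (configurable); with
  both means zero the fold change is 0.
* The permutation p-value is the plain proportion by default; the
  conservative (b+1)/(m+1) variant is a flag.
* One global pipeline seed deterministically derives per-stage seeds by
  stage-name hashing, so stages re-run independently and reproducibly.

## Problem sizes used by the test suite

Unit and property tests run on reduced universes (2,000–5,000 genes,
400–1,200 proteins) chosen so every property that matters at full scale —
type-I calibration, hub recovery, correlation-fraction bands — is already
stable there; the study-scale checks (17,860/4,800 universes, 10,000
overlap replicates, three full-scale recovery runs) run in the dedicated
acceptance tests. Full-scale differential calling takes a few seconds per
layer; the complete suite runs in about a minute.

## Known limitations

* The differential engine is a deliberate, documented substitute for
  shrinkage-based DE packages; with 5 + 5 samples its common-dispersion
  exact test is well calibrated, but it will not match any specific
  published tool gene-for-gene, and exact reproduction of any cohort's
  printed DE counts from raw reads is out of scope.
* The cis windows are measured edge-to-edge; pipelines measuring from the
  TSS will classify borderline pairs differently. Both the anchor
  convention and the windows are configurable for that reason.
* The trans rule is a correlation threshold, not a mechanism claim; at
  n = 10 even |r| = 0.9 is only suggestive.
* Raw (unadjusted) association p-values are the default in the
  structure-variation module by design; users screening many units should
  enable the BH flag.
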