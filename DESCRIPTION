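Package: pasomics
Title: Integrated Transcriptome-Proteome Hub-Gene Analysis for Placenta
    Accreta Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multi-omics analysis pipeline for small paired
    case-control designs, developed around placenta accreta spectrum (PAS)
    placental profiling. Calls differentially expressed genes in an mRNA
    count layer (conditional negative-binomial exact test) and a protein
    intensity layer (Welch t on log2 intensities) at joint FDR and
    fold-change thresholds; computes per-gene mRNA-protein correlations and
    preranked gene-set enrichment on the correlation ranking (weighted
    Kolmogorov-Smirnov statistic with a gene-label permutation null);
    selects trend-consistent hub genes from the cross-layer intersection
    and tests the intersection size against a permutation overlap null with
    an analytic hypergeometric oracle; classifies lncRNA-gene regulatory
    relations by strand-aware positional cis windows and correlation-based
    trans calls; and associates per-sample variant, splice-event, and gene
    fusion tables with case status using exact Fisher and Mann-Whitney
    tests implemented from first principles. A synthetic paired-omics
    generator reproduces the study design (5 cases vs 5 controls, 17,860
    mRNAs, 4,800 proteins) with planted ground truth so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
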