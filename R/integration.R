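#' @importFrom stats cor cor.test phyper
NULL

#' Per-gene cross-omics correlation
#'
#' For every gene quantified in both layers, the Pearson correlation
#' between its mRNA and protein values across the matched samples, plus
#' the fraction of non-degenerate genes with positive correlation. Genes
#' with zero variance in either layer are flagged degenerate and excluded
#' from the positive-fraction denominator.
#'
#' @param mrna,protein `expr_matrix` objects sharing the same design.
#' @param log_transform Correlate on `log2(x + 0.5)` values (default TRUE;
#'   abundance distributions in both layers are heavily right-skewed).
#' @return A list with `correlations` (data frame: `gene_id`, `pearson_r`,
#'   `n_samples`, `degenerate`), `fraction_positive`, and `n_degenerate`.
#' @export
per_gene_correlation <- function(mrna, protein, log_transform = TRUE) {
  stopifnot(inherits(mrna, "expr_matrix"), inherits(protein, "expr_matrix"))
  samples <- intersect(mrna$design$sample_id, protein$design$sample_id)
  if (length(samples) < 3) stop("need at least 3 shared samples")
  shared <- intersect(rownames(mrna$values), rownames(protein$values))
  if (length(shared) == 0) stop("no genes shared between the two layers")
  a <- mrna$values[shared, samples, drop = FALSE]
  b <- protein$values[shared, samples, drop = FALSE]
  if (log_transform) {
    a <- log2(a + 0.5)
    b <- log2(b + 0.5)
  }
  sda <- apply(a, 1, sd)
  sdb <- apply(b, 1, sd)
  degenerate <- sda == 0 | sdb == 0
  r <- rep(NA_real_, length(shared))
  ok <- !degenerate
  if (any(ok)) {
    # row-wise Pearson without a per-gene loop
    az <- (a[ok, , drop = FALSE] - rowMeans(a[ok, , drop = FALSE]))
    bz <- (b[ok, , drop = FALSE] - rowMeans(b[ok, , drop = FALSE]))
    r[ok] <- rowSums(az * bz) /
      sqrt(rowSums(az^2) * rowSums(bz^2))
  }
  correlations <- data.frame(gene_id = shared, pearson_r = r,
                             n_samples = length(samples),
                             degenerate = degenerate,
                             stringsAsFactors = FALSE)
  list(correlations = correlations,
       fraction_positive = mean(r[ok] > 0),
       n_degenerate = sum(degenerate))
}

#' Intersection of two significant gene sets
#'
#' Exact set intersection of the differentially expressed gene ids from
#' two layers, returned sorted by gene id for order stability.
#'
#' @param de_mrna,de_protein Character vectors of gene ids, or
#'   `differential_result` data frames (significant rows are used).
#' @return Character vector of co-differentially expressed gene ids.
#' @export
co_de_intersection <- function(de_mrna, de_protein) {
  pick <- function(x) {
    if (inherits(x, "data.frame")) x$gene_id[x$significant] else as.character(x)
  }
  sort(intersect(pick(de_mrna), pick(de_protein)))
}

#' Trend-consistency filter for co-differential hub candidates
#'
#' Partitions co-differentially expressed genes by whether their log2 fold
#' change has the same sign in the transcriptome and the proteome. A zero
#' fold change in either layer (possible only through pseudocounts) is
#' classified inconsistent and flagged.
#'
#' @param candidates Data frame with columns `gene_id`, `log2fc_mrna`,
#'   `log2fc_protein` (extra columns, e.g. FDRs, are carried through).
#' @return A list with data frames `consistent` and `inconsistent`, each
#'   with an added logical `trend_consistent` column; partition is
#'   exhaustive, exclusive, and invariant to input row order.
#' @export
trend_filter <- function(candidates) {
  need <- c("gene_id", "log2fc_mrna", "log2fc_protein")
  if (!all(need %in% names(candidates))) {
    stop("candidates need columns: ", paste(need, collapse = ", "))
  }
  candidates <- candidates[order(candidates$gene_id), , drop = FALSE]
  zero <- candidates$log2fc_mrna == 0 | candidates$log2fc_protein == 0
  if (any(zero)) {
    warning(sum(zero), " candidate(s) with zero log2 fold change ",
            "classified inconsistent")
  }
  consistent <- !zero &
    sign(candidates$log2fc_mrna) == sign(candidates$log2fc_protein)
  candidates$trend_consistent <- consistent
  rownames(candidates) <- NULL
  list(consistent = candidates[consistent, , drop = FALSE],
       inconsistent = candidates[!consistent, , drop = FALSE])
}

#' Permutation null for the overlap of two differential gene sets
#'
#' Tests whether the observed number of co-differentially expressed genes
#' could arise by chance: each replicate draws `n_de_mrna` labels uniformly
#' without replacement from the mRNA universe and `n_de_protein` labels
#' from the protein universe (a fixed subset of the mRNA universe) and
#' counts the intersection. The p-value is the plain fraction of
#' replicates with overlap at least as large as observed (set
#' `conservative = TRUE` for the (b+1)/(m+1) variant). The analytic
#' hypergeometric tail is reported alongside as an oracle.
#'
#' @param universe_mrna,universe_protein Universe sizes; the protein
#'   universe must be contained in the mRNA universe.
#' @param n_de_mrna,n_de_protein Sizes of the differential sets drawn.
#' @param observed Observed overlap.
#' @param replicates Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed (required for reproducibility).
#' @param conservative Use the add-one permutation p-value.
#' @return An `overlap_test` list: universe sizes, draw sizes, `observed`,
#'   `expected_overlap` (`n_de_mrna * n_de_protein / universe_mrna`),
#'   `p_permutation`, `p_hypergeometric`, `replicate_overlaps`,
#'   `replicates`, `seed`.
#' @export
overlap_permutation_test <- function(universe_mrna, universe_protein,
                                     n_de_mrna, n_de_protein, observed,
                                     replicates = 10000, seed,
                                     conservative = FALSE) {
  stopifnot(universe_protein <= universe_mrna,
            n_de_mrna <= universe_mrna,
            n_de_protein <= universe_protein,
            observed >= 0, observed <= min(n_de_mrna, n_de_protein),
            replicates >= 1)
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))
  # protein universe fixed as the first universe_protein mRNA labels; the
  # overlap distribution depends only on the subset relation, not which
  # labels are in it
  overlaps <- integer(replicates)
  for (i in seq_len(replicates)) {
    de_m <- sample.int(universe_mrna, n_de_mrna)
    de_p <- sample.int(universe_protein, n_de_protein)
    hit <- logical(universe_protein)
    hit[de_p] <- TRUE
    in_sub <- de_m[de_m <= universe_protein]
    overlaps[i] <- sum(hit[in_sub])
  }
  b <- sum(overlaps >= observed)
  p_perm <- if (conservative) (b + 1) / (replicates + 1) else b / replicates
  structure(list(
    universe_mrna = universe_mrna,
    universe_protein = universe_protein,
    n_de_mrna = n_de_mrna,
    n_de_protein = n_de_protein,
    observed = observed,
    expected_overlap = n_de_mrna * n_de_protein / universe_mrna,
    p_permutation = p_perm,
    p_hypergeometric = overlap_hypergeometric_tail(
      universe_mrna, n_de_mrna, n_de_protein, observed),
    replicate_overlaps = overlaps,
    replicates = replicates,
    seed = as.integer(seed)
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap test: observed %d (expected %.2f) | P(overlap >= %d): permutation %.4g (%d reps), hypergeometric %.4g\n",
    x$observed, x$expected_overlap, x$observed, x$p_permutation,
    x$replicates, x$p_hypergeometric))
  invisible(x)
}

#' Analytic tail probability for the overlap null
#'
#' Closed form for the permutation null of [overlap_permutation_test()]:
#' because the protein draw is uniform within a fixed subset of the mRNA
#' universe, the intersection size is hypergeometric with population
#' `universe_mrna`, `n_de_protein` "successes" and `n_de_mrna` draws — the
#' protein universe size cancels. Returns `P(X >= observed)`.
#'
#' @inheritParams overlap_permutation_test
#' @return Upper-tail probability in (0, 1].
#' @export
overlap_hypergeometric_tail <- function(universe_mrna, n_de_mrna,
                                        n_de_protein, observed) {
  stopifnot(n_de_mrna <= universe_mrna, n_de_protein <= universe_mrna,
            observed >= 0)
  if (observed == 0) return(1)
  phyper(observed - 1, n_de_protein, universe_mrna - n_de_protein,
         n_de_mrna, lower.tail = FALSE)
}

#' Cross-omics fold-change correlation of hub candidates
#'
#' Pearson correlation, with a two-sided test, between the transcriptome
#' and proteome log2 fold changes of the co-differential genes.
#'
#' @param candidates Data frame with `log2fc_mrna` and `log2fc_protein`.
#' @return List with `r`, `p_value`, `n`.
#' @export
cross_omics_fc_correlation <- function(candidates) {
  stopifnot(all(c("log2fc_mrna", "log2fc_protein") %in% names(candidates)))
  if (nrow(candidates) < 3) stop("need at least 3 gene pairs")
  ct <- cor.test(candidates$log2fc_mrna, candidates$log2fc_protein,
                 method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(candidates))
}

#' Assemble hub-gene table from two differential results
#'
#' Joins the per-layer differential results on the co-differential
#' intersection and applies the trend filter.
#'
#' @param de_mrna,de_protein `differential_result` data frames.
#' @return A list with `candidates` (all co-differential genes),
#'   `consistent`, and `inconsistent` data frames, each carrying both
#'   layers' log2 fold changes and FDRs.
#' @export
select_hub_genes <- function(de_mrna, de_protein) {
  co <- co_de_intersection(de_mrna, de_protein)
  m <- de_mrna[match(co, de_mrna$gene_id), ]
  p <- de_protein[match(co, de_protein$gene_id), ]
  candidates <- data.frame(gene_id = co,
                           log2fc_mrna = m$log2fc, fdr_mrna = m$fdr,
                           log2fc_protein = p$log2fc, fdr_protein = p$fdr,
                           stringsAsFactors = FALSE)
  parts <- trend_filter(candidates)
  c(list(candidates = candidates), parts)
}
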