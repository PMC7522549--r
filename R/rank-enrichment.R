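#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member gene ids,
#' tab-separated. Duplicated members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (names are set ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line needs id, description, >= 1 member")
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  if (anyDuplicated(names(sets))) stop("duplicate set id in GMT")
  sets
}

#' Build a ranked gene list
#'
#' Orders genes by descending score; ties are broken by gene id
#' (lexicographic) so the ranking is deterministic.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param scores Numeric scores (e.g. per-gene mRNA-protein Pearson
#'   correlations).
#' @return A data frame (`gene_id`, `score`) in ranking order.
#' @export
ranked_list <- function(gene_ids, scores) {
  gene_ids <- as.character(gene_ids)
  stopifnot(length(gene_ids) == length(scores), !anyNA(scores))
  if (anyDuplicated(gene_ids)) stop("duplicate gene id in ranked list")
  ord <- order(-scores, gene_ids)
  data.frame(gene_id = gene_ids[ord], score = as.numeric(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight` (normalized by the
#' set's total) at set members and subtracting `1/(N - n_hits)` at
#' non-members; the enrichment score is the running-sum value of maximal
#' absolute deviation from zero. The running sum ends at zero by
#' construction. `weight = 0` gives the classic unweighted KS statistic.
#'
#' @param ranked A data frame from [ranked_list()].
#' @param gene_set Character vector of member gene ids.
#' @param weight Non-negative exponent on the scores (default 1).
#' @return List with `es`, `running` (the full profile), and
#'   `leading_edge` (members up to / from the extremum, by ES sign).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(weight >= 0)
  hits <- ranked$gene_id %in% gene_set
  n <- nrow(ranked)
  n_hit <- sum(hits)
  if (n_hit == 0) stop("gene set has no member in the ranked list")
  if (n_hit == n) stop("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight
  hit_mass <- w * hits
  denom <- sum(hit_mass)
  if (denom == 0) {
    # all member scores are exactly zero: fall back to equal hit mass so
    # the statistic stays defined
    hit_mass <- as.numeric(hits)
    denom <- n_hit
  }
  steps <- hit_mass / denom - (!hits) / (n - n_hit)
  running <- cumsum(steps)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) {
    ranked$gene_id[seq_len(i_max)][hits[seq_len(i_max)]]
  } else {
    idx <- seq(i_max + 1L, n)
    ranked$gene_id[idx][hits[idx]]
  }
  list(es = es, running = running, leading_edge = leading)
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' For each gene set (filtered to `min_size` members present in the list),
#' computes the weighted KS enrichment score, then builds a null by
#' redrawing the set's membership uniformly over the ranked list
#' (size-preserving) `n_perm` times. The permutation p-value is the
#' sign-matched tail proportion with a floor of `1/n_perm`; NES divides
#' the ES by the mean absolute null ES of matching sign, and FDR q-values
#' follow the sign-stratified NES-null ratio scheme.
#'
#' @param ranked A data frame from [ranked_list()].
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm Permutations per set (default 1000).
#' @param weight Score exponent, see [enrichment_score()].
#' @param min_size Minimum members present in the list (default 5).
#' @param seed Integer seed (required).
#' @return Data frame with one row per retained set: `set_id`, `size`,
#'   `es`, `nes`, `p_perm`, `fdr_q`, `leading_edge`
#'   (comma-separated).
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000, weight = 1,
                           min_size = 5, seed) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(as.integer(seed))
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene_id %in% s),
                  integer(1))
  keep <- sizes >= min_size & sizes < nrow(ranked)
  if (!any(keep)) stop("no gene set passes min_size after intersection")
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]

  es_obs <- numeric(length(gene_sets))
  leading <- character(length(gene_sets))
  null_es <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    sc <- enrichment_score(ranked, gene_sets[[i]], weight = weight)
    es_obs[i] <- sc$es
    leading[i] <- paste(sc$leading_edge, collapse = ",")
    null_es[[i]] <- vapply(seq_len(n_perm), function(b) {
      members <- ranked$gene_id[sample.int(nrow(ranked), sizes[i])]
      enrichment_score(ranked, members, weight = weight)$es
    }, numeric(1))
  }

  nes <- numeric(length(gene_sets))
  p_perm <- numeric(length(gene_sets))
  nes_null <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    nul <- null_es[[i]]
    same <- if (es_obs[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    if (length(same) == 0) {
      p_perm[i] <- 1 / n_perm
      nes[i] <- sign(es_obs[i]) * Inf
    } else {
      p_perm[i] <- max(mean(abs(same) >= abs(es_obs[i])), 1 / n_perm)
      nes[i] <- es_obs[i] / mean(abs(same))
    }
    # normalize the whole null for the FDR step
    pos_mean <- mean(nul[nul >= 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    nn <- nul
    nn[nul >= 0] <- if (is.finite(pos_mean) && pos_mean > 0)
      nul[nul >= 0] / pos_mean else 0
    nn[nul < 0] <- if (is.finite(neg_mean) && neg_mean > 0)
      nul[nul < 0] / neg_mean else 0
    nes_null[[i]] <- nn
  }

  all_null <- unlist(nes_null)
  fdr_q <- vapply(seq_along(gene_sets), function(i) {
    if (!is.finite(nes[i])) return(0)
    if (nes[i] >= 0) {
      num_den <- mean(all_null[all_null >= 0] >= nes[i])
      obs_den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num_den <- mean(all_null[all_null < 0] <= nes[i])
      obs_den <- mean(nes[nes < 0] <= nes[i])
    }
    if (is.nan(num_den)) num_den <- 0
    min(1, num_den / max(obs_den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set_id = names(gene_sets), size = sizes, es = es_obs,
             nes = nes, p_perm = p_perm, fdr_q = fdr_q,
             leading_edge = leading, row.names = NULL,
             stringsAsFactors = FALSE)
}
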