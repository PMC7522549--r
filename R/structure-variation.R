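#' @importFrom stats pnorm
NULL

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table (rows
#' = case/control, columns = event present/absent). With both margins
#' fixed, the first cell follows a hypergeometric law; the two-sided
#' p-value is the point-probability (minimum-likelihood) definition — the
#' sum of the probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table (within a
#' 1e-7 relative tie tolerance). Computed in log space.
#'
#' @param a,b,c,d Cell counts: `a` cases with the event, `b` cases
#'   without, `c` controls with, `d` controls without. A 2x2 matrix can be
#'   passed as `a` instead.
#' @return List with `p_value`, `odds_ratio` (sample OR, may be Inf/NaN),
#'   and `degenerate` (TRUE when a margin is empty; then `p_value = 1`).
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  or <- (a * d) / (b * c)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(p_value = 1, odds_ratio = or, degenerate = TRUE))
  }
  n <- r1 + r2
  # support of the first cell given fixed margins
  x <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  lp_obs <- lp[x == a]
  p <- sum(exp(lp[lp <= lp_obs + log1p(1e-7)]))
  list(p_value = min(1, p), odds_ratio = or, degenerate = FALSE)
}

# Exact null distribution of the Mann-Whitney U statistic for sample
# sizes (n, m) without ties, via the rank-sum subset-sum count: the
# number of size-n subsets of ranks {1..n+m} with a given sum, built by
# dynamic programming. U = W - n(n+1)/2; returns counts for u = 0..n*m.
u_count_table <- function(n, m) {
  N <- n + m
  maxw <- sum((m + 1):N)            # largest possible rank sum for n x's
  ways <- matrix(0, n + 1, maxw + 1)
  ways[1, 1] <- 1
  for (k in seq_len(N)) {
    for (i in min(k, n):1) {
      idx <- (k + 1):(maxw + 1)
      ways[i + 1, idx] <- ways[i + 1, idx] + ways[i, idx - k]
    }
  }
  offset <- n * (n + 1) / 2
  ways[n + 1, (offset + 1):(offset + n * m + 1)]
}

#' Exact two-sided Mann-Whitney U test
#'
#' U is computed by rank summation with midranks for ties. Without ties
#' and with `n_x + n_y <= exact_limit` the two-sided p-value is exact:
#' `2 * min(P(U <= u), P(U >= u))` capped at 1, from the full
#' dynamic-programming enumeration of the U distribution. With ties or
#' larger samples, a normal approximation with tie correction and
#' continuity correction is used and flagged `approximate`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_limit Maximum `n_x + n_y` for the exact path (default 20).
#' @return List with `U` (for the `x` group), `p_value`, `approximate`.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))           # midranks for ties
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n + m <= exact_limit) {
    counts <- u_count_table(n, m)
    total <- sum(counts)               # choose(n + m, n)
    lower <- sum(counts[seq_len(U + 1)]) / total      # P(U <= u)
    upper <- sum(counts[(U + 1):(n * m + 1)]) / total # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    return(list(U = U, p_value = p, approximate = FALSE))
  }
  # normal approximation with tie and continuity correction
  mu <- n * m / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = U, p_value = 1, approximate = TRUE))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p_value = min(1, 2 * pnorm(z, lower.tail = FALSE)),
       approximate = TRUE)
}

#' Associate variant presence with case status
#'
#' For every (gene, effect class) unit with at least one present sample,
#' builds the 2x2 presence table against case status and applies
#' [fisher_exact_two_sided()]. P-values are reported raw by default
#' (matching small-cohort practice for these per-gene screens); set
#' `adjust = TRUE` for BH adjustment across units.
#'
#' @param variants A variant table (see [read_variant_table()]).
#' @param design A [sample_design()].
#' @param adjust Add a BH-adjusted `fdr` column.
#' @return Data frame sorted by p-value: `gene_id`, `effect_class`,
#'   `case_present`, `control_present`, `p_value` (+ `fdr` if requested).
#' @export
variant_association <- function(variants, design, adjust = FALSE) {
  variants <- validate_variant_table(variants)
  if (!all(variants$sample_id %in% design$sample_id)) {
    stop("variant table contains samples not in the design")
  }
  cases <- design_samples(design, "case")
  ctrls <- design_samples(design, "control")
  present <- variants[variants$present, , drop = FALSE]
  units <- unique(present[, c("gene_id", "effect_class")])
  if (nrow(units) == 0) {
    return(data.frame(gene_id = character(), effect_class = character(),
                      case_present = integer(), control_present = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(units)), function(i) {
    sel <- present$gene_id == units$gene_id[i] &
      present$effect_class == units$effect_class[i]
    samp <- present$sample_id[sel]
    a <- sum(samp %in% cases)
    c_ <- sum(samp %in% ctrls)
    ft <- fisher_exact_two_sided(a, length(cases) - a,
                                 c_, length(ctrls) - c_)
    data.frame(gene_id = units$gene_id[i],
               effect_class = units$effect_class[i],
               case_present = a, control_present = c_,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate splice-event expression with case status
#'
#' Per splice event, an exact Mann-Whitney test of the case vs control
#' expression vectors.
#'
#' @param events A splice table (see [read_splice_table()]).
#' @param design A [sample_design()].
#' @param adjust Add a BH-adjusted `fdr` column.
#' @return Data frame sorted by p-value: `event_type`, `gene_id`, `chrom`,
#'   `start`, `end`, `U`, `p_value`, `approximate` (+ `fdr` if requested).
#' @export
splice_association <- function(events, design, adjust = FALSE) {
  events <- validate_splice_table(events)
  cases <- design_samples(design, "case")
  ctrls <- design_samples(design, "control")
  if (!all(c(cases, ctrls) %in% names(events))) {
    stop("splice table lacks expression columns for some design samples")
  }
  rows <- lapply(seq_len(nrow(events)), function(i) {
    mw <- mann_whitney_exact(as.numeric(events[i, cases]),
                             as.numeric(events[i, ctrls]))
    data.frame(event_type = events$event_type[i],
               gene_id = events$gene_id[i], chrom = events$chrom[i],
               start = events$start[i], end = events$end[i],
               U = mw$U, p_value = mw$p_value,
               approximate = mw$approximate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize gene fusions by group
#'
#' Per fusion partner pair: the number of case and control samples in
#' which the fusion was detected. Fusions absent from every sample are
#' excluded. A Fisher exact p-value is added only on request — presence
#' counts are the primary readout.
#'
#' @param fusions A fusion table (see [read_fusion_table()]).
#' @param design A [sample_design()].
#' @param test Add `p_value` from [fisher_exact_two_sided()].
#' @return Data frame: `gene_a`, `gene_b`, `chrom`, `case_count`,
#'   `control_count` (+ `p_value` if requested).
#' @export
summarize_fusions <- function(fusions, design, test = FALSE) {
  fusions <- validate_fusion_table(fusions)
  cases <- design_samples(design, "case")
  ctrls <- design_samples(design, "control")
  present <- fusions[fusions$present, , drop = FALSE]
  if (nrow(present) == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      chrom = character(), case_count = integer(),
                      control_count = integer(), stringsAsFactors = FALSE)
    if (test) out$p_value <- numeric()
    return(out)
  }
  units <- unique(present[, c("gene_a", "gene_b", "chrom")])
  rows <- lapply(seq_len(nrow(units)), function(i) {
    sel <- present$gene_a == units$gene_a[i] &
      present$gene_b == units$gene_b[i]
    samp <- present$sample_id[sel]
    a <- sum(samp %in% cases)
    c_ <- sum(samp %in% ctrls)
    r <- data.frame(units[i, ], case_count = a, control_count = c_,
                    stringsAsFactors = FALSE)
    if (test) {
      r$p_value <- fisher_exact_two_sided(a, length(cases) - a,
                                          c_, length(ctrls) - c_)$p_value
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
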