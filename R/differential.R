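#' @importFrom stats p.adjust pt dnbinom qnbinom dbinom var
NULL

#' Library-size normalization to counts per million
#'
#' Scales each sample column of a count matrix by its column total so that
#' every column sums to one million. Columns with zero total are rejected
#' rather than silently propagated.
#'
#' @param x An `expr_matrix` with layer `"mrna_counts"`.
#' @return An `expr_matrix` of CPM values (same layer tag and design).
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "mrna_counts") stop("normalize_counts expects a counts layer")
  totals <- colSums(x$values)
  if (any(totals == 0)) {
    stop("all-zero sample column: ",
         paste(colnames(x$values)[totals == 0], collapse = ", "))
  }
  out <- x
  out$values <- sweep(x$values, 2, totals, "/") * 1e6
  out
}

#' Per-gene log2 fold change (case vs control)
#'
#' `log2((mean_case + pseudocount) / (mean_control + pseudocount))` on the
#' supplied (normalized) values. The pseudocount keeps the ratio defined
#' when one group mean is zero; with both means zero the fold change is 0.
#'
#' @param x An `expr_matrix` (normalized values for the counts layer).
#' @param pseudocount Non-negative value added to both group means
#'   (default 0.5).
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
log2_fold_change <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "expr_matrix"), pseudocount >= 0)
  case <- design_samples(x$design, "case")
  ctrl <- design_samples(x$design, "control")
  m_case <- rowMeans(x$values[, case, drop = FALSE])
  m_ctrl <- rowMeans(x$values[, ctrl, drop = FALSE])
  log2((m_case + pseudocount) / (m_ctrl + pseudocount))
}

#' Median-of-ratios size factors for a count matrix
#'
#' Per-sample scaling factors computed as the median across genes of the
#' ratio of each sample's counts to the gene-wise geometric-mean
#' reference, using genes expressed in every sample. Robust to
#' composition bias: a handful of strongly regulated abundant genes can
#' dominate column totals and make every unchanged gene look shifted,
#' whereas the median ratio tracks the unchanged majority. Factors are
#' normalized to geometric mean 1. Falls back to relative column totals
#' when fewer than 50 genes are everywhere-positive.
#'
#' @param values Count matrix (genes x samples).
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(values) {
  pos <- rowSums(values > 0) == ncol(values)
  if (sum(pos) < 50) {
    sf <- colSums(values)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lref <- rowMeans(log(values[pos, , drop = FALSE]))
  sf <- apply(log(values[pos, , drop = FALSE]) - lref, 2,
              function(lr) exp(median(lr)))
  sf / exp(mean(log(sf)))
}

# Method-of-moments common dispersion across genes. For NB counts with
# per-gene mean mu_g, E[s2_g] = mu_g + phi * mu_g^2 within a group; phi is
# estimated by pooling (s2 - mu) / mu^2 over genes with informative means
# in each group and averaging, floored at 0.
estimate_common_dispersion <- function(values, design) {
  phis <- c()
  for (g in c("case", "control")) {
    cols <- design_samples(design, g)
    v <- values[, cols, drop = FALSE]
    mu <- rowMeans(v)
    s2 <- apply(v, 1, var)
    keep <- mu > 1
    if (sum(keep) >= 10) {
      # pooled ratio estimator: robust to low-mean genes dominating
      phis <- c(phis, sum(s2[keep] - mu[keep]) / sum(mu[keep]^2))
    }
  }
  if (length(phis) == 0) return(0.01)
  max(mean(phis), 1e-4)
}

# Exact conditional NB test for one gene: given group library-size-adjusted
# counts summing to s in groups of n1 and n2 samples, the case-group sum Y1
# given Y1 + Y2 = s has P(y) proportional to
#   dnbinom(y, size = n1/phi, mu = n1 mu) * dnbinom(s - y, n2/phi, n2 mu)
# under the null of a common per-sample mean mu = s / (n1 + n2). The
# two-sided p sums the probabilities of all splits no more likely than the
# observed one (point-probability method). Enumeration is restricted to a
# support window holding all but ~1e-14 of the unconditional mass.
nb_exact_test_one <- function(y1, s, n1, n2, dispersion) {
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  if (dispersion <= 1e-8) {
    # dispersion -> 0 limit: conditional law is Binomial(s, n1/(n1+n2))
    pr <- dbinom(0:s, s, n1 / (n1 + n2))
    obs <- pr[y1 + 1]
    return(clamp_p(sum(pr[pr <= obs * (1 + 1e-7)])))
  }
  size1 <- n1 / dispersion
  size2 <- n2 / dispersion
  lo <- qnbinom(1e-14, size = size1, mu = n1 * mu)
  hi <- qnbinom(1e-14, size = size1, mu = n1 * mu, lower.tail = FALSE)
  lo <- max(0, min(lo, s, y1))
  hi <- min(s, max(hi, y1))
  y <- lo:hi
  lp <- dnbinom(y, size = size1, mu = n1 * mu, log = TRUE) +
    dnbinom(s - y, size = size2, mu = n2 * mu, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[y1 - lo + 1]
  clamp_p(sum(pr[pr <= obs * (1 + 1e-7)]))
}

# keep exact-test p-values in [0, 1]; sums within float error of 1 (the
# symmetric degenerate case where every split qualifies) snap to 1
clamp_p <- function(p) {
  if (p >= 1 - 1e-9) 1 else max(p, 0)
}

#' Per-gene differential test
#'
#' For the mRNA count layer: a conditional negative-binomial exact test of
#' the case-group sum given the gene's two-group total, with a common
#' dispersion estimated across genes by method of moments; counts are first
#' scaled to a common library size and rounded, so unequal sequencing depth
#' does not masquerade as differential expression. For the protein
#' intensity layer: a Welch (unequal-variance) two-sample t-test on log2
#' intensities.
#'
#' @param x An `expr_matrix` (raw counts for `"mrna_counts"`, raw
#'   intensities for `"protein_intensity"`).
#' @param dispersion Optional fixed NB dispersion; estimated from the data
#'   when `NULL` (counts layer only).
#' @return Named numeric vector of raw two-sided p-values, one per gene.
#' @export
de_test <- function(x, dispersion = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  design <- x$design
  n1 <- sum(design$group == "case")
  n2 <- sum(design$group == "control")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  case <- design_samples(design, "case")
  ctrl <- design_samples(design, "control")

  if (x$layer == "mrna_counts") {
    # equalize effective library sizes (median-of-ratios, robust to
    # composition bias), keep integer counts for the exact test
    totals <- colSums(x$values)
    if (any(totals == 0)) stop("all-zero sample column")
    v <- round(sweep(x$values, 2, size_factors(x$values), "/"))
    if (is.null(dispersion)) {
      dispersion <- estimate_common_dispersion(v, design)
    }
    y1 <- rowSums(v[, case, drop = FALSE])
    s <- y1 + rowSums(v[, ctrl, drop = FALSE])
    p <- vapply(seq_along(s), function(i) {
      nb_exact_test_one(y1[i], s[i], n1, n2, dispersion)
    }, numeric(1))
    names(p) <- rownames(x$values)
    return(p)
  }

  # protein layer: Welch t on log2 intensities (pseudocount guards zeros)
  lv <- log2(x$values + 0.5)
  a <- lv[, case, drop = FALSE]
  b <- lv[, ctrl, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var) / n1
  vb <- apply(b, 1, var) / n2
  se2 <- va + vb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (n1 - 1) + vb^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1  # zero-variance degenerate rows
  names(p) <- rownames(x$values)
  p
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; rejects inputs
#' outside \[0, 1\].
#'
#' @param p Numeric vector of raw p-values.
#' @return Numeric vector of FDR values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at joint thresholds
#'
#' A gene is significant when its FDR falls below `fdr_threshold` and its
#' absolute fold change reaches `fc_threshold` (i.e. `|log2fc| >=
#' log2(fc_threshold)`), the same cut applied symmetrically to up- and
#' down-regulation. Defaults reproduce the FDR < 0.05, fold change > 1.5
#' convention for small-cohort placental profiling.
#'
#' @param log2fc Named vector of log2 fold changes.
#' @param fdr Named vector of FDR values, aligned with `log2fc`.
#' @param p_raw Optional named vector of raw p-values carried through.
#' @param fdr_threshold,fc_threshold Positive thresholds.
#' @return A `differential_result` data frame with columns `gene_id`,
#'   `log2fc`, `p_raw`, `fdr`, `direction` (`"up"`/`"down"`),
#'   `significant`.
#' @export
call_differential <- function(log2fc, fdr, p_raw = NULL,
                              fdr_threshold = 0.05, fc_threshold = 1.5) {
  if (fdr_threshold <= 0 || fc_threshold <= 0) stop("thresholds must be > 0")
  stopifnot(length(log2fc) == length(fdr))
  ids <- names(log2fc)
  if (is.null(ids)) ids <- as.character(seq_along(log2fc))
  if (!is.null(names(fdr)) && !identical(names(fdr), ids)) {
    fdr <- fdr[ids]
  }
  if (is.null(p_raw)) p_raw <- rep(NA_real_, length(log2fc))
  out <- data.frame(
    gene_id = ids,
    log2fc = unname(log2fc),
    p_raw = unname(p_raw),
    fdr = unname(fdr),
    direction = ifelse(log2fc >= 0, "up", "down"),
    significant = unname(fdr < fdr_threshold &
                           abs(log2fc) >= log2(fc_threshold)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("differential_result", "data.frame")
  out
}

#' One-call differential analysis of an expression layer
#'
#' Convenience wrapper: normalization (counts layer), log2 fold change,
#' layer-appropriate test, BH adjustment, and threshold calling.
#'
#' @inheritParams de_test
#' @inheritParams call_differential
#' @param pseudocount Passed to [log2_fold_change()].
#' @return A `differential_result` data frame (see [call_differential()]).
#' @export
run_differential <- function(x, fdr_threshold = 0.05, fc_threshold = 1.5,
                             pseudocount = 0.5, dispersion = NULL) {
  norm <- x
  if (x$layer == "mrna_counts") {
    # median-of-ratios scaling for fold changes, matching the test's
    # internal equalization (see size_factors for why not column totals)
    norm$values <- sweep(x$values, 2, size_factors(x$values), "/")
  }
  lfc <- log2_fold_change(norm, pseudocount = pseudocount)
  p <- de_test(x, dispersion = dispersion)
  call_differential(lfc, bh_adjust(p), p_raw = p,
                    fdr_threshold = fdr_threshold,
                    fc_threshold = fc_threshold)
}
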