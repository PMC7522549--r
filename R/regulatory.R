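#' @importFrom stats cor
NULL

CIS_RELATIONS <- c("cis_up10k", "cis_dw20k", "cis_overlap", "trans", "none")

#' Positional cis classification of an lncRNA relative to a gene
#'
#' Applies the positional candidate-regulator rules: an lncRNA sharing at
#' least one base with the gene is `cis_overlap` (distance 0); otherwise
#' the gap between the nearest interval edges (coordinate difference,
#' e.g. gene start minus lncRNA end for an lncRNA on the lower-coordinate
#' side) is measured, and the lncRNA is `cis_up10k` when it lies on the
#' gene's 5' side within `up_window`, `cis_dw20k` on the 3' side within
#' `dw_window`. Upstream/downstream are strand-aware: for a minus-strand
#' gene the 5' side is the higher-coordinate side. Different chromosomes
#' or gaps beyond both windows give `"none"`. Genes of unknown strand are
#' refused (silent misclassification would be worse).
#'
#' @param lncrna,gene Lists or one-row data frames with `chrom`, `start`,
#'   `end`, and (for `gene`) `strand`.
#' @param up_window,dw_window Window sizes in bp (defaults 10000, 20000).
#' @return List with `relation` (one of `cis_up10k`, `cis_dw20k`,
#'   `cis_overlap`, `none`) and `distance` (0 for overlap, the edge gap
#'   for cis calls, NA otherwise).
#' @export
classify_cis <- function(lncrna, gene, up_window = 10000, dw_window = 20000) {
  if (is.null(gene$strand) || !gene$strand %in% c("+", "-")) {
    stop("gene strand must be '+' or '-' for cis classification")
  }
  if (lncrna$chrom != gene$chrom) {
    return(list(relation = "none", distance = NA_real_))
  }
  if (max(lncrna$start, gene$start) <= min(lncrna$end, gene$end)) {
    return(list(relation = "cis_overlap", distance = 0))
  }
  if (lncrna$end < gene$start) {       # lncRNA on the lower-coordinate side
    gap <- as.numeric(gene$start - lncrna$end)
    side <- if (gene$strand == "+") "up" else "dw"
  } else {                              # higher-coordinate side
    gap <- as.numeric(lncrna$start - gene$end)
    side <- if (gene$strand == "+") "dw" else "up"
  }
  if (side == "up" && gap <= up_window) {
    list(relation = "cis_up10k", distance = gap)
  } else if (side == "dw" && gap <= dw_window) {
    list(relation = "cis_dw20k", distance = gap)
  } else {
    list(relation = "none", distance = NA_real_)
  }
}

#' Pearson and Spearman correlation between an lncRNA and a gene
#'
#' @param lncrna_expr,gene_expr Numeric vectors of matched per-sample
#'   expression (at least 3 samples).
#' @return List with `pearson_r`, `spearman_rho`, and `degenerate` (TRUE
#'   when either vector is constant, in which case both coefficients are
#'   NA).
#' @export
correlate_lncrna_gene <- function(lncrna_expr, gene_expr) {
  stopifnot(length(lncrna_expr) == length(gene_expr))
  if (length(lncrna_expr) < 3) stop("need at least 3 matched samples")
  if (sd(lncrna_expr) == 0 || sd(gene_expr) == 0) {
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                degenerate = TRUE))
  }
  list(pearson_r = cor(lncrna_expr, gene_expr, method = "pearson"),
       spearman_rho = cor(lncrna_expr, gene_expr, method = "spearman"),
       degenerate = FALSE)
}

#' Call lncRNA regulatory targets among hub genes
#'
#' Every (lncRNA, hub gene) pair receives exactly one relation: positional
#' cis calls take precedence (overlap > up10k > dw20k, assigned regardless
#' of correlation); pairs with no cis relation are called `trans` when the
#' larger of |Pearson r| and |Spearman rho| reaches `trans_abs_r`, and
#' `none` otherwise. Hub genes without an annotation row are skipped with
#' a warning.
#'
#' @param annotations A `gene_annotation` data frame holding both the
#'   lncRNA loci (`biotype == "lncrna"`) and gene loci (`biotype ==
#'   "mrna"`).
#' @param lncrna_expr Matrix of lncRNA expression (rownames = lncRNA ids),
#'   columns matching `gene_expr` columns.
#' @param gene_expr Matrix of gene expression (rownames = gene ids).
#' @param hub_genes Character vector of hub gene ids to classify against.
#' @param trans_abs_r Absolute-correlation threshold for trans calls
#'   (default 0.9).
#' @param up_window,dw_window Passed to [classify_cis()].
#' @return Data frame with one row per (lncRNA, hub gene) pair:
#'   `lncrna_id`, `gene_id`, `relation`, `distance`, `pearson_r`,
#'   `spearman_rho`.
#' @export
call_targets <- function(annotations, lncrna_expr, gene_expr, hub_genes,
                         trans_abs_r = 0.9,
                         up_window = 10000, dw_window = 20000) {
  stopifnot(inherits(annotations, "gene_annotation"))
  lnc_ann <- annotations[annotations$biotype == "lncrna", , drop = FALSE]
  gene_ann <- annotations[annotations$biotype == "mrna", , drop = FALSE]
  missing_ann <- setdiff(hub_genes, gene_ann$gene_id)
  if (length(missing_ann)) {
    warning("hub gene(s) without annotation skipped: ",
            paste(missing_ann, collapse = ", "))
    hub_genes <- setdiff(hub_genes, missing_ann)
  }
  rows <- list()
  for (li in seq_len(nrow(lnc_ann))) {
    lnc <- lnc_ann[li, ]
    for (g in hub_genes) {
      gene <- gene_ann[gene_ann$gene_id == g, ]
      cls <- classify_cis(lnc, gene, up_window = up_window,
                          dw_window = dw_window)
      r <- rho <- NA_real_
      if (lnc$gene_id %in% rownames(lncrna_expr) &&
          g %in% rownames(gene_expr)) {
        cc <- correlate_lncrna_gene(lncrna_expr[lnc$gene_id, ],
                                    gene_expr[g, ])
        r <- cc$pearson_r
        rho <- cc$spearman_rho
      }
      relation <- cls$relation
      if (relation == "none" && !is.na(r) && !is.na(rho) &&
          max(abs(r), abs(rho)) >= trans_abs_r) {
        relation <- "trans"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lnc$gene_id, gene_id = g, relation = relation,
        distance = cls$distance, pearson_r = r, spearman_rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
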