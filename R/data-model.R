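#' @importFrom stats rbinom rnorm rpois runif sd setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

# Controlled vocabularies shared across the package.
VARIANT_EFFECT_CLASSES <- c("intron", "intergenic", "synonymous", "missense",
                            "utr", "other")
SPLICE_EVENT_TYPES <- c("AE", "TSS", "TTS", "IR", "MIR", "SKIP", "MSKIP")
EXPRESSION_LAYERS <- c("mrna_counts", "protein_intensity")

#' Two-group sample design
#'
#' Describes the case/control assignment of the profiled samples. Both
#' groups must be non-empty and sample labels unique; this is the design
#' every expression matrix and per-sample table is validated against.
#'
#' @param sample_ids Character vector of unique sample labels, in the column
#'   order expression matrices are expected to follow.
#' @param group Character vector, one of `"case"` or `"control"` per sample.
#' @return A `sample_design` object (a data frame with columns `sample_id`
#'   and `group`).
#' @examples
#' sample_design(c(paste0("PAS", 1:5), paste0("NPAS", 1:5)),
#'               rep(c("case", "control"), each = 5))
#' @export
sample_design <- function(sample_ids, group) {
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (length(sample_ids) != length(group)) {
    stop("`sample_ids` and `group` must have the same length")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% group)) {
    stop("both groups must be non-empty")
  }
  out <- data.frame(sample_id = sample_ids, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d samples (%d case, %d control)\n",
              nrow(x), sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

design_samples <- function(design, group) {
  design$sample_id[design$group == group]
}

#' Expression matrix with layer tag and design
#'
#' Container for a genes-by-samples table of non-negative values, tagged
#' with the omics layer it comes from (`"mrna_counts"` or
#' `"protein_intensity"`) and carrying its [sample_design()]. Columns are
#' stored in design order; values must be finite and non-negative and gene
#' ids unique.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param layer `"mrna_counts"` or `"protein_intensity"`.
#' @param design A [sample_design()].
#' @return An `expr_matrix` object: a list with elements `values`, `layer`,
#'   `design`.
#' @export
expression_matrix <- function(values, layer = EXPRESSION_LAYERS,
                              design) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("gene ids (rownames) required")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (is.null(colnames(values))) stop("sample ids (colnames) required")
  if (!setequal(colnames(values), design$sample_id) ||
      ncol(values) != nrow(design)) {
    stop("sample mismatch between matrix columns and design")
  }
  # enforce design column order
  values <- values[, design$sample_id, drop = FALSE]
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing or non-finite expression values are not accepted")
  }
  if (any(values < 0)) stop("negative expression value")
  structure(list(values = values, layer = layer, design = design),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table from delimited text
#'
#' Expects a TSV whose first column holds gene ids and whose remaining
#' columns are the samples named in `design` (any order; columns are
#' reordered to design order). Values must be complete, finite and
#' non-negative.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param layer Omics layer tag, see [expression_matrix()].
#' @param design A [sample_design()].
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path, layer = EXPRESSION_LAYERS, design) {
  layer <- match.arg(layer)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a gene column plus samples")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  expression_matrix(mat, layer = layer, design = design)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, one
#' column per sample in design order.
#'
#' @param x An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene/lncRNA annotation table
#'
#' Builds the annotation data frame used by the positional regulatory
#' rules: one row per gene with biotype and a stranded 1-based inclusive
#' locus.
#'
#' @param gene_id Character vector, unique within each biotype.
#' @param biotype `"mrna"` or `"lncrna"` per gene.
#' @param chrom Chromosome label per gene.
#' @param start,end 1-based inclusive positions, `1 <= start <= end`.
#' @param strand `"+"`, `"-"`, or `"*"` (unknown).
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene_id, biotype, chrom, start, end, strand) {
  out <- data.frame(gene_id = as.character(gene_id),
                    biotype = as.character(biotype),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (!all(out$biotype %in% c("mrna", "lncrna"))) {
    stop("biotype must be 'mrna' or 'lncrna'")
  }
  if (!all(out$strand %in% c("+", "-", "*"))) {
    stop("strand must be '+', '-' or '*'")
  }
  if (any(out$start < 1L) || any(out$start > out$end)) {
    stop("invalid interval: need 1 <= start <= end")
  }
  for (bt in unique(out$biotype)) {
    ids <- out$gene_id[out$biotype == bt]
    if (anyDuplicated(ids)) {
      stop("duplicate gene id within biotype '", bt, "'")
    }
  }
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Read gene annotations from BED or GTF
#'
#' Delegates parsing to `rtracklayer::import()` and normalizes every
#' interval to the package's internal 1-based inclusive convention (BED's
#' 0-based half-open intervals are converted at the boundary; GTF is
#' already 1-based inclusive). Zero-length BED features are rejected.
#'
#' @param path Path to a BED6 or GTF/GFF2 file.
#' @param dialect `"bed"` or `"gtf"`.
#' @param biotype Biotype assigned to all records (`"mrna"` default), or a
#'   vector recycled across records. GTF records with a `gene_biotype`
#'   attribute of `"lncRNA"`/`"lincRNA"` are tagged `"lncrna"` regardless.
#' @return A `gene_annotation` data frame.
#' @export
read_annotation <- function(path, dialect = c("bed", "gtf"),
                            biotype = "mrna") {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (length(gr) == 0) stop("no records in ", path)
  # rtracklayer returns 1-based inclusive GRanges for both dialects; a
  # zero-length BED feature (start == end in BED coordinates) surfaces as
  # width 0 and is invalid here.
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("zero-length feature after coordinate normalization")
  }
  meta <- S4Vectors::mcols(gr)
  ids <- if (dialect == "bed") {
    as.character(meta$name)
  } else if (!is.null(meta$gene_id)) {
    as.character(meta$gene_id)
  } else {
    as.character(meta$name)
  }
  if (is.null(ids) || anyNA(ids)) stop("annotation records lack gene ids")
  bt <- rep_len(biotype, length(gr))
  if (dialect == "gtf" && !is.null(meta$gene_biotype)) {
    lnc <- !is.na(meta$gene_biotype) &
      tolower(meta$gene_biotype) %in% c("lncrna", "lincrna")
    bt[lnc] <- "lncrna"
  }
  strand <- as.character(GenomicRanges::strand(gr))
  gene_annotation(ids, bt,
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = strand)
}

#' Read or write per-sample variant presence records
#'
#' Variant tables record, per gene and variant effect class, which samples
#' carry at least one variant of that class. Effect classes are restricted
#' to the vocabulary `intron, intergenic, synonymous, missense, utr,
#' other`; `(gene, class, sample)` triples must be unique.
#'
#' @param path TSV path with columns `gene_id`, `effect_class`,
#'   `sample_id`, `present` (logical or 0/1).
#' @return A data frame of the validated records.
#' @export
read_variant_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_variant_table(tab)
}

validate_variant_table <- function(tab) {
  need <- c("gene_id", "effect_class", "sample_id", "present")
  if (!all(need %in% names(tab))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tab$effect_class), VARIANT_EFFECT_CLASSES)
  if (length(bad)) {
    stop("unknown effect_class '", bad[1], "'; valid classes: ",
         paste(VARIANT_EFFECT_CLASSES, collapse = ", "))
  }
  key <- paste(tab$gene_id, tab$effect_class, tab$sample_id)
  if (anyDuplicated(key)) stop("duplicate (gene, class, sample) record")
  tab$present <- as.logical(tab$present)
  if (anyNA(tab$present)) stop("`present` must be logical or 0/1")
  tab
}

#' @rdname read_variant_table
#' @param tab A variant table data frame.
#' @export
write_variant_table <- function(tab, path) {
  tab <- validate_variant_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write splice-event expression tables
#'
#' Splice events carry a type from the seven-class vocabulary
#' `AE, TSS, TTS, IR, MIR, SKIP, MSKIP` (alternative exon ends,
#' alternative 5' first exon, alternative 3' last exon, intron retention,
#' multi-IR, skipped exon, multi-exon skip), a locus, and one non-negative
#' expression value per sample.
#'
#' @param path TSV path with columns `event_type`, `gene_id`, `chrom`,
#'   `start`, `end`, then one column per sample.
#' @return A data frame of the validated records.
#' @export
read_splice_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_splice_table(tab)
}

validate_splice_table <- function(tab) {
  need <- c("event_type", "gene_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("splice table needs columns: ", paste(need, collapse = ", "),
         ", plus one expression column per sample")
  }
  bad <- setdiff(unique(tab$event_type), SPLICE_EVENT_TYPES)
  if (length(bad)) {
    stop("unknown event_type '", bad[1], "'; valid types: ",
         paste(SPLICE_EVENT_TYPES, collapse = ", "))
  }
  expr_cols <- setdiff(names(tab), need)
  if (length(expr_cols) == 0) stop("no per-sample expression columns")
  expr <- as.matrix(tab[, expr_cols, drop = FALSE])
  if (anyNA(expr) || any(!is.finite(expr)) || any(expr < 0)) {
    stop("splice-event expression must be finite and non-negative")
  }
  tab
}

#' @rdname read_splice_table
#' @param tab A splice table data frame.
#' @export
write_splice_table <- function(tab, path) {
  tab <- validate_splice_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write gene-fusion presence tables
#'
#' One record per (fusion partner pair, sample); partners must differ.
#'
#' @param path TSV path with columns `gene_a`, `gene_b`, `chrom`,
#'   `sample_id`, `present`.
#' @return A data frame of the validated records.
#' @export
read_fusion_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_fusion_table(tab)
}

validate_fusion_table <- function(tab) {
  need <- c("gene_a", "gene_b", "chrom", "sample_id", "present")
  if (!all(need %in% names(tab))) {
    stop("fusion table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$gene_a == tab$gene_b)) stop("fusion partners must differ")
  tab$present <- as.logical(tab$present)
  if (anyNA(tab$present)) stop("`present` must be logical or 0/1")
  tab
}

#' @rdname read_fusion_table
#' @param tab A fusion table data frame.
#' @export
write_fusion_table <- function(tab, path) {
  tab <- validate_fusion_table(tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report directory for a set of analysis results
#'
#' Emits one TSV per named result table plus `manifest.json` recording the
#' parameters, seed, package version, and per-table row counts.
#'
#' @param results Named list of data frames (one per analysis stage).
#' @param out_dir Output directory, created if needed.
#' @param params Named list echoed into the manifest (must include `seed`
#'   when any stage was stochastic).
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(results, out_dir, params = list()) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (nm in names(results)) {
    tab <- as.data.frame(results[[nm]])
    write.table(tab, file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts[[nm]] <- nrow(tab)
  }
  manifest <- list(
    package = "pasomics",
    version = as.character(packageVersion("pasomics")),
    params = params,
    record_counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Load the bundled hub-gene expression reference table
#'
#' Returns the 23-gene reference set of placental hub genes with their
#' transcriptome and proteome log2 fold changes and FDR values, as used in
#' worked examples and the trend-consistency checks. FDR entries recorded
#' as a bound (`<0.001`) are parsed as that bound.
#'
#' @return A data frame with columns `gene_id`, `log2fc_mrna`, `fdr_mrna`,
#'   `log2fc_protein`, `fdr_protein`.
#' @export
load_hub_gene_reference <- function() {
  path <- system.file("extdata", "hub_genes_expression.tsv",
                      package = "pasomics", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  parse_fdr <- function(x) {
    bounded <- grepl("^<", x)
    out <- as.numeric(sub("^<", "", x))
    attr(out, "is_bound") <- bounded
    out
  }
  data.frame(gene_id = tab$gene_id,
             log2fc_mrna = as.numeric(tab$log2fc_mrna),
             fdr_mrna = parse_fdr(tab$fdr_mrna),
             log2fc_protein = as.numeric(tab$log2fc_protein),
             fdr_protein = parse_fdr(tab$fdr_protein),
             stringsAsFactors = FALSE)
}
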