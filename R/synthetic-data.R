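#' Configuration for the paired-omics simulator
#'
#' Defaults emulate the study design the package was built around: 5 cases
#' vs 5 controls, 17,860 quantified mRNAs of which a 4,800-gene subset is
#' also quantified at the protein level, 728 differential mRNAs and 439
#' differential proteins, 31 co-differential genes of which 23 are
#' trend-consistent, and planted log2 fold changes spanning 1.0–6.7.
#'
#' @param n_mrna,n_protein Universe sizes (protein universe is a subset of
#'   the mRNA universe).
#' @param n_case,n_control Samples per group.
#' @param n_de_mrna,n_de_protein Planted differential genes per layer.
#' @param n_hub_consistent,n_hub_inconsistent Planted co-differential
#'   genes with matching / opposite fold-change signs across layers.
#' @param log2fc_range Range the planted |log2 fold changes| are drawn
#'   from, uniformly.
#' @param mrna_dispersion Negative-binomial dispersion of the count layer
#'   (squared biological CV; default 0.1, conventional for human tissue
#'   cohorts).
#' @param protein_cv Coefficient of variation of protein intensities
#'   (default 0.2, typical for DIA quantification).
#' @param latent_correlation_strength Correlation between the mRNA and
#'   protein biological log-deviations of a gene (default 0.13, chosen so
#'   that with 10 samples roughly 62% of genes show a positive sample
#'   correlation between layers).
#' @param base_log_mean,base_log_sd Log-normal baseline of per-gene mean
#'   counts (defaults log(100) and 1.3, a moderate-depth bulk library).
#' @param library_size_cv CV of the per-sample library-size factors
#'   (default 0.2).
#' @param variant_k Cases carrying each planted variant unit (default 4 of
#'   5, with 0 controls).
#' @param fusion_cases Cases carrying the planted fusion (default 3).
#' @param splice_shift_log2 Case-group log2 shift of planted splice-event
#'   expression (default 2.5).
#' @param n_background_variants,n_background_splice Background units with
#'   no group association.
#' @param seed Integer seed; required by the generators.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_mrna = 17860, n_protein = 4800,
                              n_case = 5, n_control = 5,
                              n_de_mrna = 728, n_de_protein = 439,
                              n_hub_consistent = 23,
                              n_hub_inconsistent = 8,
                              log2fc_range = c(1.0, 6.7),
                              mrna_dispersion = 0.1, protein_cv = 0.2,
                              latent_correlation_strength = 0.13,
                              base_log_mean = log(100), base_log_sd = 1.3,
                              library_size_cv = 0.2,
                              variant_k = 4, fusion_cases = 3,
                              splice_shift_log2 = 2.5,
                              n_background_variants = 50,
                              n_background_splice = 20,
                              seed = NULL) {
  cfg <- list(n_mrna = n_mrna, n_protein = n_protein, n_case = n_case,
              n_control = n_control, n_de_mrna = n_de_mrna,
              n_de_protein = n_de_protein,
              n_hub_consistent = n_hub_consistent,
              n_hub_inconsistent = n_hub_inconsistent,
              log2fc_range = log2fc_range,
              mrna_dispersion = mrna_dispersion, protein_cv = protein_cv,
              latent_correlation_strength = latent_correlation_strength,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              library_size_cv = library_size_cv,
              variant_k = variant_k, fusion_cases = fusion_cases,
              splice_shift_log2 = splice_shift_log2,
              n_background_variants = n_background_variants,
              n_background_splice = n_background_splice,
              seed = seed)
  n_hub <- n_hub_consistent + n_hub_inconsistent
  if (n_protein > n_mrna) stop("n_protein must be <= n_mrna")
  if (n_de_mrna > n_mrna || n_de_protein > n_protein) {
    stop("differential counts exceed their universes")
  }
  if (n_hub > min(n_de_mrna, n_de_protein)) {
    stop("hub genes cannot exceed the smaller differential set")
  }
  if (length(log2fc_range) != 2 || any(log2fc_range < 0) ||
      log2fc_range[1] > log2fc_range[2]) {
    stop("log2fc_range must be an ordered non-negative pair")
  }
  if (latent_correlation_strength < 0 || latent_correlation_strength > 1) {
    stop("latent_correlation_strength must lie in [0, 1]")
  }
  if (n_case < 2 || n_control < 2) stop("need >= 2 samples per group")
  if (variant_k > n_case || fusion_cases > n_case) {
    stop("planted event counts exceed the case group size")
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_design <- function(config) {
  sample_design(
    c(paste0("PAS", seq_len(config$n_case)),
      paste0("NPAS", seq_len(config$n_control))),
    rep(c("case", "control"), c(config$n_case, config$n_control)))
}

draw_lfc <- function(n, range) {
  mag <- runif(n, range[1], range[2])
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a paired mRNA/protein dataset with planted ground truth
#'
#' Simulates the two omics layers of a small case-control cohort. Per-gene
#' baseline abundances are log-normal; mRNA counts are Poisson draws around
#' a log-normal biological factor whose variance equals the configured NB
#' dispersion (so marginally the counts are NB-like and the dispersion is
#' recoverable by moments), and protein intensities are log-normal with the
#' configured CV. A per-gene, per-sample latent factor is shared between
#' the two layers' biological deviations with correlation
#' `latent_correlation_strength`, inducing the mostly-positive per-gene
#' mRNA-protein correlations seen in paired designs. Differential genes
#' receive a group mean shift of |log2FC| drawn from `log2fc_range` with
#' random sign; hub genes are planted in both layers with controlled
#' cross-layer sign agreement. Deterministic under `config$seed`.
#'
#' @param config A [simulation_config()] with a non-NULL `seed`.
#' @return List with `mrna` and `protein` (`expr_matrix` objects) and
#'   `truth`, a list holding the per-gene truth table (`genes`), the
#'   config, and the design.
#' @export
generate_paired_omics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) stop("config$seed is required")
  set.seed(as.integer(config$seed))
  design <- sim_design(config)
  n_s <- nrow(design)
  is_case <- design$group == "case"
  gene_ids <- sprintf("G%05d", seq_len(config$n_mrna))

  protein_genes <- sort(sample(gene_ids, config$n_protein))
  n_hub <- config$n_hub_consistent + config$n_hub_inconsistent
  hubs <- sample(protein_genes, n_hub)
  hub_consistent <- hubs[seq_len(config$n_hub_consistent)]
  hub_inconsistent <- setdiff(hubs, hub_consistent)
  extra_p <- sample(setdiff(protein_genes, hubs),
                    config$n_de_protein - n_hub)
  de_protein <- c(hubs, extra_p)
  extra_m <- sample(setdiff(gene_ids, de_protein),
                    config$n_de_mrna - n_hub)
  de_mrna <- c(hubs, extra_m)

  lfc_m <- setNames(numeric(config$n_mrna), gene_ids)
  lfc_m[de_mrna] <- draw_lfc(length(de_mrna), config$log2fc_range)
  lfc_p <- setNames(numeric(config$n_mrna), gene_ids)
  lfc_p[de_protein] <- draw_lfc(length(de_protein), config$log2fc_range)
  # controlled cross-layer sign relation for the planted hubs
  lfc_p[hub_consistent] <- abs(lfc_p[hub_consistent]) *
    sign(lfc_m[hub_consistent])
  lfc_p[hub_inconsistent] <- -abs(lfc_p[hub_inconsistent]) *
    sign(lfc_m[hub_inconsistent])

  base_m <- exp(rnorm(config$n_mrna, config$base_log_mean,
                      config$base_log_sd))
  lib <- exp(rnorm(n_s, 0, sqrt(log(1 + config$library_size_cv^2))))

  rho <- config$latent_correlation_strength
  sigma_m <- sqrt(log(1 + config$mrna_dispersion))
  tau_p <- sqrt(log(1 + config$protein_cv^2))
  f <- matrix(rnorm(config$n_mrna * n_s), config$n_mrna, n_s)
  u <- matrix(rnorm(config$n_mrna * n_s), config$n_mrna, n_s)
  b_m <- sigma_m * (sqrt(rho) * f + sqrt(1 - rho) * u)
  shift_m <- outer(lfc_m, as.numeric(is_case)) * log(2)
  log_mu <- log(base_m) + shift_m + b_m - sigma_m^2 / 2 +
    matrix(log(lib), config$n_mrna, n_s, byrow = TRUE)
  counts <- matrix(rpois(config$n_mrna * n_s, exp(log_mu)),
                   config$n_mrna, n_s,
                   dimnames = list(gene_ids, design$sample_id))

  pidx <- match(protein_genes, gene_ids)
  v <- matrix(rnorm(config$n_protein * n_s), config$n_protein, n_s)
  b_p <- tau_p * (sqrt(rho) * f[pidx, , drop = FALSE] + sqrt(1 - rho) * v)
  base_p <- exp(rnorm(config$n_protein, log(1e5), 1))
  shift_p <- outer(lfc_p[protein_genes], as.numeric(is_case)) * log(2)
  intens <- exp(log(base_p) + shift_p + b_p - tau_p^2 / 2)
  dimnames(intens) <- list(protein_genes, design$sample_id)

  genes <- data.frame(
    gene_id = gene_ids,
    in_protein = gene_ids %in% protein_genes,
    de_in_mrna = gene_ids %in% de_mrna,
    de_in_protein = gene_ids %in% de_protein,
    hub = gene_ids %in% hubs,
    trend_consistent = gene_ids %in% hub_consistent,
    true_log2fc_mrna = unname(lfc_m),
    true_log2fc_protein = unname(lfc_p),
    stringsAsFactors = FALSE)
  stopifnot(all(!genes$hub | (genes$de_in_mrna & genes$de_in_protein)),
            all(!genes$trend_consistent | genes$hub))

  list(mrna = expression_matrix(counts, "mrna_counts", design),
       protein = expression_matrix(intens, "protein_intensity", design),
       truth = list(genes = genes, config = config, design = design))
}

#' Generate gene and lncRNA annotations with requested cis/trans geometry
#'
#' For each requested relation, emits one mRNA locus and one lncRNA locus
#' whose positions satisfy exactly that relation: `up10k` places the
#' lncRNA within 10 kb of the gene's 5' edge, `dw20k` within 20 kb of the
#' 3' edge (both strand-aware), `overlap` shares at least one base, and
#' `trans` puts the lncRNA on a different chromosome. Gene strands are
#' assigned randomly.
#'
#' @param requests Data frame with columns `lncrna_id`, `gene_id`,
#'   `relation` (from `up10k`, `dw20k`, `overlap`, `trans`), or a
#'   character vector of relations (ids auto-generated).
#' @param seed Integer seed.
#' @return A `gene_annotation` data frame with the mRNA and lncRNA rows.
#' @export
generate_annotations <- function(requests, seed) {
  if (is.character(requests)) {
    requests <- data.frame(
      lncrna_id = sprintf("LNC%03d", seq_along(requests)),
      gene_id = sprintf("TGT%03d", seq_along(requests)),
      relation = requests, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("lncrna_id", "gene_id", "relation") %in% names(requests)))
  bad <- setdiff(requests$relation, c("up10k", "dw20k", "overlap", "trans"))
  if (length(bad)) stop("unknown relation request: ", bad[1])
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_len(nrow(requests))) {
    gs <- 2e6 * i                      # spaced gene loci, chr1
    glen <- sample(5000:50000, 1)
    ge <- gs + glen - 1
    strand <- sample(c("+", "-"), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = requests$gene_id[i], biotype = "mrna", chrom = "chr1",
      start = gs, end = ge, strand = strand, stringsAsFactors = FALSE)
    llen <- sample(200:3000, 1)
    rel <- requests$relation[i]
    if (rel == "overlap") {
      ls <- sample(gs:ge, 1)
      le <- ls + llen - 1
      lchrom <- "chr1"
    } else if (rel == "trans") {
      ls <- sample.int(49000000L, 1) + 1000000L
      le <- ls + llen - 1
      lchrom <- "chr9"
    } else {
      gap <- if (rel == "up10k") sample(1:10000, 1) else sample(1:20000, 1)
      upstream_low_side <- (strand == "+") == (rel == "up10k")
      if (upstream_low_side) {         # lncRNA on the lower-coordinate side
        le <- gs - gap
        ls <- le - llen + 1
      } else {
        ls <- ge + gap
        le <- ls + llen - 1
      }
      lchrom <- "chr1"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = requests$lncrna_id[i], biotype = "lncrna", chrom = lchrom,
      start = ls, end = le, strand = sample(c("+", "-"), 1),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  gene_annotation(ann$gene_id, ann$biotype, ann$chrom, ann$start, ann$end,
                  ann$strand)
}

#' Generate variant, splice-event, and fusion tables with planted signals
#'
#' Builds the three gene-structure tables the association stage consumes.
#' Planted variant units are present in `variant_k` of the cases and no
#' controls; background units are present with equal probability (0.3) in
#' both groups. Planted splice events get a `splice_shift_log2` case-group
#' expression shift; background events share one distribution. One fusion
#' is planted in `fusion_cases` cases and no controls.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element of [generate_paired_omics()] output
#'   (planted units attach to its hub genes).
#' @return List with `variants`, `splice`, `fusions` (validated tables)
#'   and `planted` (the planted unit descriptors, for recovery checks).
#' @export
generate_structure_tables <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) stop("config$seed is required")
  set.seed(as.integer(config$seed) + 1L)
  design <- truth$design
  cases <- design_samples(design, "case")
  ctrls <- design_samples(design, "control")
  genes <- truth$genes
  hub_ids <- genes$gene_id[genes$hub]
  if (length(hub_ids) < 3) stop("need at least 3 hub genes to plant events")

  # --- variants: 3 planted (gene, class) units + background
  planted_v <- data.frame(
    gene_id = hub_ids[1:3],
    effect_class = c("intron", "intergenic", "synonymous"),
    stringsAsFactors = FALSE)
  v_rows <- list()
  for (i in 1:3) {
    carriers <- sample(cases, config$variant_k)
    v_rows[[i]] <- data.frame(
      gene_id = planted_v$gene_id[i],
      effect_class = planted_v$effect_class[i],
      sample_id = design$sample_id,
      present = design$sample_id %in% carriers,
      stringsAsFactors = FALSE)
  }
  bg_genes <- sample(genes$gene_id, config$n_background_variants)
  for (i in seq_len(config$n_background_variants)) {
    cls <- sample(VARIANT_EFFECT_CLASSES, 1)
    v_rows[[3 + i]] <- data.frame(
      gene_id = bg_genes[i], effect_class = cls,
      sample_id = design$sample_id,
      present = runif(nrow(design)) < 0.3,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, v_rows)
  variants <- variants[!duplicated(
    variants[, c("gene_id", "effect_class", "sample_id")]), ]

  # --- splice events: 2 planted shifted events + background
  mk_event <- function(type, gene, shift) {
    base <- exp(rnorm(1, log(50), 0.5))
    expr <- base * exp(rnorm(nrow(design), 0, 0.35))
    expr[design$group == "case"] <- expr[design$group == "case"] * 2^shift
    pos <- sample.int(199000000L, 1) + 1000000L
    row <- data.frame(event_type = type, gene_id = gene, chrom = "chr2",
                      start = pos, end = pos + sample(100:3000, 1),
                      stringsAsFactors = FALSE)
    row[design$sample_id] <- as.list(round(expr, 3))
    row
  }
  planted_s <- rbind(mk_event("TSS", hub_ids[1], config$splice_shift_log2),
                     mk_event("TTS", hub_ids[2], config$splice_shift_log2))
  bg_s <- do.call(rbind, lapply(seq_len(config$n_background_splice),
    function(i) mk_event(sample(SPLICE_EVENT_TYPES, 1),
                         sample(genes$gene_id, 1), 0)))
  splice <- rbind(planted_s, bg_s)

  # --- fusion: one planted pair in fusion_cases cases, absent elsewhere
  fusion_pair <- c(hub_ids[1], hub_ids[2])
  carriers <- sample(cases, config$fusion_cases)
  fusions <- data.frame(gene_a = fusion_pair[1], gene_b = fusion_pair[2],
                        chrom = "chr2", sample_id = design$sample_id,
                        present = design$sample_id %in% carriers,
                        stringsAsFactors = FALSE)

  list(variants = validate_variant_table(variants),
       splice = validate_splice_table(splice),
       fusions = validate_fusion_table(fusions),
       planted = list(variants = planted_v,
                      splice = planted_s[, c("event_type", "gene_id")],
                      fusion = fusion_pair))
}
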