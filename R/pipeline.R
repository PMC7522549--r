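#' Derive a per-stage seed from the global pipeline seed
#'
#' Stage seeds are a deterministic hash of the global seed and the stage
#' name, so any stage can be re-run independently with the same stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the integrated multi-omics pipeline end to end
#'
#' Orchestrates the stages on either simulated or user-supplied inputs:
#' differential calling in both layers, cross-omics correlation, hub-gene
#' selection with the permutation overlap null, optional preranked
#' enrichment, lncRNA target classification, and gene-structure
#' association. Every stage writes a TSV into `out_dir` and is recorded in
#' `manifest.json`; identical config and seed give identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed (required).
#' @param sim_config A [simulation_config()] to generate the inputs, or
#'   `NULL` to use `inputs`.
#' @param inputs When not simulating: a list with `mrna` and `protein`
#'   (`expr_matrix` objects), optionally `annotations`
#'   (`gene_annotation`), `lncrna_expr` (matrix), `variants`, `splice`,
#'   `fusions` (validated tables).
#' @param gene_sets Optional named list of gene sets for the enrichment
#'   stage (skipped when `NULL`).
#' @param fdr_threshold,fc_threshold Differential-calling thresholds.
#' @param trans_abs_r,up_window,dw_window lncRNA target parameters.
#' @param replicates Overlap-null Monte-Carlo replicates.
#' @return Invisibly, a list with all stage results plus the manifest.
#' @export
run_pipeline <- function(out_dir, seed, sim_config = NULL, inputs = NULL,
                         gene_sets = NULL,
                         fdr_threshold = 0.05, fc_threshold = 1.5,
                         trans_abs_r = 0.9,
                         up_window = 10000, dw_window = 20000,
                         replicates = 10000) {
  if (missing(seed)) stop("`seed` is required")
  if (is.null(sim_config) == is.null(inputs)) {
    stop("provide exactly one of `sim_config` or `inputs`")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  timing <- list()
  seeds_used <- list(global = as.integer(seed))
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- stage: simulate (or load) ------------------------------------
  if (!is.null(sim_config)) {
    sim_config$seed <- stage_seed(seed, "simulate")
    seeds_used$simulate <- sim_config$seed
    sim <- tick("simulate", {
      omics <- generate_paired_omics(sim_config)
      struct <- generate_structure_tables(sim_config, omics$truth)
      # annotations + lncRNA expression over the first four planted
      # consistent hubs, one request per relation class
      hub_ids <- omics$truth$genes$gene_id[omics$truth$genes$trend_consistent]
      req <- data.frame(
        lncrna_id = sprintf("LNC%03d", 1:4),
        gene_id = hub_ids[1:4],
        relation = c("up10k", "dw20k", "overlap", "trans"),
        stringsAsFactors = FALSE)
      ann <- generate_annotations(req, seed = stage_seed(seed, "annotate"))
      # the mRNA loci for the requested hubs keep their hub gene ids, so
      # classification round-trips with expression
      gexpr <- normalize_counts(omics$mrna)$values
      set.seed(stage_seed(seed, "lncexpr"))
      lnc_expr <- matrix(exp(rnorm(4 * ncol(gexpr), log(20), 0.5)),
                         4, ncol(gexpr),
                         dimnames = list(req$lncrna_id, colnames(gexpr)))
      # trans request: expression tracks its target gene
      lnc_expr["LNC004", ] <- gexpr[req$gene_id[4], ] *
        exp(rnorm(ncol(gexpr), 0, 0.05))
      list(omics = omics, struct = struct, annotations = ann,
           lncrna_expr = lnc_expr, lnc_requests = req)
    })
    mrna <- sim$omics$mrna
    protein <- sim$omics$protein
    annotations <- sim$annotations
    lncrna_expr <- sim$lncrna_expr
    variants <- sim$struct$variants
    splice <- sim$struct$splice
    fusions <- sim$struct$fusions
    stages$ground_truth <- sim$omics$truth$genes
  } else {
    mrna <- inputs$mrna
    protein <- inputs$protein
    annotations <- inputs$annotations
    lncrna_expr <- inputs$lncrna_expr
    variants <- inputs$variants
    splice <- inputs$splice
    fusions <- inputs$fusions
  }

  # --- stage: differential (both layers) ----------------------------
  de_mrna <- tick("de_mrna", run_differential(
    mrna, fdr_threshold = fdr_threshold, fc_threshold = fc_threshold))
  de_protein <- tick("de_protein", run_differential(
    protein, fdr_threshold = fdr_threshold, fc_threshold = fc_threshold))
  stages$de_mrna <- de_mrna
  stages$de_protein <- de_protein

  # --- stage: integrate ---------------------------------------------
  seeds_used$integrate <- stage_seed(seed, "integrate")
  integ <- tick("integrate", {
    corr <- per_gene_correlation(mrna, protein)
    hubs <- select_hub_genes(de_mrna, de_protein)
    ov <- overlap_permutation_test(
      universe_mrna = nrow(mrna$values),
      universe_protein = nrow(protein$values),
      n_de_mrna = sum(de_mrna$significant),
      n_de_protein = sum(de_protein$significant),
      observed = nrow(hubs$candidates),
      replicates = replicates, seed = seeds_used$integrate)
    fc_corr <- if (nrow(hubs$candidates) >= 3) {
      cross_omics_fc_correlation(hubs$candidates)
    } else NULL
    list(corr = corr, hubs = hubs, overlap = ov, fc_corr = fc_corr)
  })
  stages$correlation <- integ$corr$correlations
  stages$hub_genes <- integ$hubs$consistent
  stages$hub_inconsistent <- integ$hubs$inconsistent
  stages$overlap_test <- data.frame(
    universe_mrna = integ$overlap$universe_mrna,
    universe_protein = integ$overlap$universe_protein,
    n_de_mrna = integ$overlap$n_de_mrna,
    n_de_protein = integ$overlap$n_de_protein,
    observed = integ$overlap$observed,
    expected_overlap = integ$overlap$expected_overlap,
    p_permutation = integ$overlap$p_permutation,
    p_hypergeometric = integ$overlap$p_hypergeometric,
    replicates = integ$overlap$replicates,
    seed = integ$overlap$seed)

  # --- stage: enrichment (optional) ----------------------------------
  if (!is.null(gene_sets)) {
    seeds_used$gsea <- stage_seed(seed, "gsea")
    ok <- !integ$corr$correlations$degenerate
    ranked <- ranked_list(integ$corr$correlations$gene_id[ok],
                          integ$corr$correlations$pearson_r[ok])
    stages$enrichment <- tick("gsea", gsea_preranked(
      ranked, gene_sets, seed = seeds_used$gsea))
  }

  # --- stage: lncRNA targets -----------------------------------------
  if (!is.null(annotations) && !is.null(lncrna_expr)) {
    hub_ids <- stages$hub_genes$gene_id
    gexpr <- if (mrna$layer == "mrna_counts") {
      normalize_counts(mrna)$values
    } else mrna$values
    stages$lncrna_targets <- tick("lncrna", suppressWarnings(call_targets(
      annotations, lncrna_expr, gexpr, hub_ids,
      trans_abs_r = trans_abs_r,
      up_window = up_window, dw_window = dw_window)))
  }

  # --- stage: structure variation ------------------------------------
  if (!is.null(variants)) {
    stages$variant_association <- tick("structvar_snp",
                                       variant_association(variants,
                                                           mrna$design))
  }
  if (!is.null(splice)) {
    stages$splice_association <- tick("structvar_splice",
                                      splice_association(splice,
                                                         mrna$design))
  }
  if (!is.null(fusions)) {
    stages$fusions <- tick("structvar_fusion",
                           summarize_fusions(fusions, mrna$design))
  }

  params <- list(seed = as.integer(seed),
                 fdr_threshold = fdr_threshold,
                 fc_threshold = fc_threshold,
                 trans_abs_r = trans_abs_r,
                 up_window = up_window, dw_window = dw_window,
                 replicates = replicates,
                 simulated = !is.null(sim_config),
                 gsea = if (is.null(gene_sets)) "skipped: no gene sets"
                        else "run",
                 stage_seeds = seeds_used,
                 timing_s = timing)
  manifest <- write_report(stages, out_dir, params = params)
  invisible(c(stages, list(manifest = manifest,
                           overlap = integ$overlap,
                           fc_corr = integ$fc_corr)))
}
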