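test_that("per-gene correlation recovers exact and degenerate cases", {
  d <- make_design()
  set.seed(2)
  base <- matrix(exp(rnorm(30, 3, 1)), 3, 10,
                 dimnames = list(c("g1", "g2", "g3"), d$sample_id))
  mrna <- expression_matrix(base, "mrna_counts", d)
  prot_vals <- base
  # g2 is a decreasing transform of the mRNA row; g3 constant
  prot_vals["g2", ] <- max(base["g2", ]) + 1 - base["g2", ]
  prot_vals["g3", ] <- 7
  protein <- expression_matrix(prot_vals, "protein_intensity", d)
  pc <- per_gene_correlation(mrna, protein, log_transform = FALSE)
  r <- setNames(pc$correlations$pearson_r, pc$correlations$gene_id)
  expect_equal(unname(r["g1"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["g2"]), -1, tolerance = 1e-12)
  expect_true(is.na(r["g3"]))
  expect_identical(pc$n_degenerate, 1L)
  expect_equal(pc$fraction_positive, 0.5)   # 1 of 2 non-degenerate
})

test_that("per-gene correlation rejects unusable inputs", {
  d <- make_design(1, 1)
  m <- matrix(1:2, 1, 2, dimnames = list("g", d$sample_id))
  x <- expression_matrix(m, "mrna_counts", d)
  expect_error(per_gene_correlation(x, x), "3 shared samples")
  d10 <- make_design()
  a <- tiny_matrix(d10)
  b_vals <- a$values
  rownames(b_vals) <- paste0("other", 1:3)
  b <- expression_matrix(b_vals, "protein_intensity", d10)
  expect_error(per_gene_correlation(a, b), "no genes shared")
})

test_that("co-differential intersection is exact and order-stable", {
  expect_identical(co_de_intersection(c("a", "b"), c("c", "d")), character(0))
  expect_identical(co_de_intersection(c("b", "a"), c("a", "b")), c("a", "b"))
  sim <- generate_paired_omics(
    simulation_config(n_mrna = 2000, n_protein = 600, n_de_mrna = 80,
                      n_de_protein = 50, n_hub_consistent = 10,
                      n_hub_inconsistent = 4, seed = 8))
  de_m <- run_differential(sim$mrna)
  de_p <- run_differential(sim$protein)
  co <- co_de_intersection(de_m, de_p)
  g <- sim$truth$genes
  detected_hubs <- g$gene_id[g$hub &
                               g$gene_id %in% de_m$gene_id[de_m$significant] &
                               g$gene_id %in% de_p$gene_id[de_p$significant]]
  expect_true(all(detected_hubs %in% co))
})

test_that("trend filter partitions by sign agreement, invariant to row order", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc_mrna = c(2, 2, -1, -3),
                    log2fc_protein = c(1, -1, -0.1, 2))
  parts <- trend_filter(tab)
  expect_setequal(parts$consistent$gene_id, c("a", "c"))
  expect_setequal(parts$inconsistent$gene_id, c("b", "d"))
  # exhaustive + exclusive
  expect_identical(nrow(parts$consistent) + nrow(parts$inconsistent), 4L)
  shuffled <- tab[c(3, 1, 4, 2), ]
  expect_identical(trend_filter(shuffled), parts)
  # zero fold change is inconsistent, with a warning
  tab0 <- data.frame(gene_id = "z", log2fc_mrna = 0, log2fc_protein = 1)
  expect_warning(p0 <- trend_filter(tab0), "zero")
  expect_identical(nrow(p0$inconsistent), 1L)
})

test_that("the bundled hub reference is fully trend-consistent", {
  tab <- load_hub_gene_reference()
  parts <- trend_filter(tab)
  expect_identical(nrow(parts$consistent), 23L)
  expect_identical(nrow(parts$inconsistent), 0L)
})

test_that("hypergeometric overlap tail matches brute-force enumeration", {
  # N = 10 universe, 4 and 3 drawn, observed 2 -> exactly 1/3
  expect_equal(overlap_hypergeometric_tail(10, 4, 3, 2),
               overlap_tail_oracle(10, 4, 3, 2), tolerance = 1e-12)
  expect_equal(overlap_hypergeometric_tail(10, 4, 3, 2), 1 / 3,
               tolerance = 1e-12)
  expect_identical(overlap_hypergeometric_tail(10, 4, 3, 0), 1)
  # a second instance against the enumeration oracle
  expect_equal(overlap_hypergeometric_tail(12, 5, 4, 3),
               overlap_tail_oracle(12, 5, 4, 3), tolerance = 1e-12)
})

test_that("permutation overlap test converges to the analytic tail", {
  ov <- overlap_permutation_test(10, 6, 4, 3, 2, replicates = 100000,
                                 seed = 17)
  p_exact <- overlap_hypergeometric_tail(10, 4, 3, 2)
  se <- sqrt(p_exact * (1 - p_exact) / ov$replicates)
  expect_lt(abs(ov$p_permutation - p_exact), 4 * se)
  # expected overlap matches the replicate mean within 3 SEs
  se_mean <- sd(ov$replicate_overlaps) / sqrt(ov$replicates)
  expect_lt(abs(mean(ov$replicate_overlaps) - ov$expected_overlap),
            3 * se_mean)
  # p is a multiple of 1/replicates
  expect_equal(ov$p_permutation * ov$replicates,
               round(ov$p_permutation * ov$replicates), tolerance = 1e-9)
})

test_that("permutation overlap test handles edge cases and seeds", {
  ov0 <- overlap_permutation_test(10, 6, 4, 3, 0, replicates = 500, seed = 1)
  expect_identical(ov0$p_permutation, 1)
  a <- overlap_permutation_test(50, 20, 10, 8, 3, replicates = 2000, seed = 2)
  b <- overlap_permutation_test(50, 20, 10, 8, 3, replicates = 2000, seed = 2)
  expect_identical(a$p_permutation, b$p_permutation)
  cons <- overlap_permutation_test(50, 20, 10, 8, 3, replicates = 2000,
                                   seed = 2, conservative = TRUE)
  expect_equal(cons$p_permutation,
               (sum(a$replicate_overlaps >= 3) + 1) / 2001)
  expect_error(overlap_permutation_test(10, 20, 4, 3, 2, seed = 1),
               "universe_protein")
})

test_that("cross-omics fold-change correlation behaves on exact inputs", {
  line <- data.frame(log2fc_mrna = 1:5, log2fc_protein = 2 * (1:5) + 1)
  expect_equal(cross_omics_fc_correlation(line)$r, 1, tolerance = 1e-12)
  anti <- data.frame(log2fc_mrna = c(1, 2, 3), log2fc_protein = -c(1, 2, 3))
  expect_equal(cross_omics_fc_correlation(anti)$r, -1, tolerance = 1e-12)
  expect_error(cross_omics_fc_correlation(anti[1:2, ]), "3 gene pairs")
  # the bundled 23 trend-consistent pairs correlate strongly positively
  tab <- load_hub_gene_reference()
  res <- cross_omics_fc_correlation(tab)
  expect_gt(res$r, 0.5)
  expect_lt(res$p_value, 0.01)
})

test_that("default-scale synthetic data lands in the observed correlation band", {
  fracs <- vapply(c(101, 102, 103), function(seed) {
    cfg <- simulation_config(seed = seed)
    sim <- generate_paired_omics(cfg)
    per_gene_correlation(sim$mrna, sim$protein)$fraction_positive
  }, numeric(1))
  expect_gt(mean(fracs), 0.55)
  expect_lt(mean(fracs), 0.75)
})
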