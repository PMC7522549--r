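test_that("Fisher exact test reproduces canonical small-cohort tables", {
  # 4-of-5 cases vs 0-of-5 controls: the printed 0.048
  expect_equal(fisher_exact_two_sided(4, 1, 0, 5)$p_value, 0.04761905,
               tolerance = 1e-7)
  expect_equal(round(fisher_exact_two_sided(4, 1, 0, 5)$p_value, 3), 0.048)
  # symmetric table
  expect_equal(fisher_exact_two_sided(2, 3, 2, 3)$p_value, 1)
  # complete separation at 5 vs 5: 2 / C(10,5)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5)$p_value, 2 / 252,
               tolerance = 1e-12)
  # degenerate margin
  deg <- fisher_exact_two_sided(0, 5, 0, 5)
  expect_identical(deg$p_value, 1)
  expect_true(deg$degenerate)
  # matrix input
  expect_equal(fisher_exact_two_sided(matrix(c(4, 0, 1, 5), 2))$p_value,
               0.04761905, tolerance = 1e-7)
})

test_that("Fisher exact matches enumeration and fisher.test for all small tables", {
  for (rep in 1:40) {
    set.seed(rep)
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    ours <- fisher_exact_two_sided(a, b, c_, d)$p_value
    expect_equal(ours, fisher_oracle(a, b, c_, d), tolerance = 1e-10,
                 info = sprintf("table %d %d %d %d", a, b, c_, d))
    # independent reference implementation (same two-sided convention)
    ref <- fisher.test(matrix(c(a, c_, b, d), 2))$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }
})

test_that("Fisher exact is invariant to group-label swap", {
  for (tab in list(c(4, 1, 0, 5), c(3, 2, 1, 4), c(5, 0, 2, 3))) {
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])$p_value,
                 fisher_exact_two_sided(tab[3], tab[4], tab[1], tab[2])$p_value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact reproduces the canonical 5-vs-5 p-values", {
  # complete separation: U = 0, p = 2/252
  mw <- mann_whitney_exact(1:5, 6:10 + 0.5)
  expect_identical(mw$U, 0)
  expect_equal(mw$p_value, 2 / 252, tolerance = 1e-12)
  expect_false(mw$approximate)
  # U = 2: the printed 0.032
  mw2 <- mann_whitney_exact(c(1, 2, 3, 4, 6.5), c(5, 6, 7, 8, 9))
  expect_identical(mw2$U, 2)
  expect_equal(mw2$p_value, 8 / 252, tolerance = 1e-12)
  expect_equal(round(mw2$p_value, 3), 0.032)
})

test_that("Mann-Whitney exact matches enumeration and the U-distribution", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    vals <- sample(seq(0.1, 100, by = 0.1), n + m)   # no ties
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    ours <- mann_whitney_exact(x, y)
    expect_equal(ours$p_value, mw_oracle(x, y), tolerance = 1e-10)
    # cross-check against the base U distribution
    lower <- pwilcox(ours$U, n, m)
    upper <- 1 - pwilcox(ours$U - 1, n, m)
    expect_equal(ours$p_value, min(1, 2 * min(lower, upper)),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney respects symmetry and monotone invariance", {
  x <- c(3.2, 1.1, 7.8, 0.4, 5.5)
  y <- c(2.2, 9.1, 6.3, 8.8, 4.4)
  a <- mann_whitney_exact(x, y)
  b <- mann_whitney_exact(y, x)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(b$U, length(x) * length(y) - a$U)
  # strictly monotone transform leaves the rank test unchanged
  tr <- mann_whitney_exact(exp(x), exp(y))
  expect_identical(tr$U, a$U)
  expect_equal(tr$p_value, a$p_value, tolerance = 1e-12)
})

test_that("ties and large samples fall back to the flagged approximation", {
  tied <- mann_whitney_exact(rep(2, 5), rep(2, 5))
  expect_true(tied$approximate)
  expect_identical(tied$p_value, 1)
  big <- mann_whitney_exact(rnorm(15), rnorm(15))
  expect_true(big$approximate)
  expect_gte(big$p_value, 0)
  expect_lte(big$p_value, 1)
})

test_that("variant association builds the right tables per unit", {
  d <- make_design()
  rows <- expand.grid(gene_id = "FSTL3", effect_class = "intergenic",
                      sample_id = d$sample_id, stringsAsFactors = FALSE)
  rows$present <- rows$sample_id %in% paste0("PAS", 1:4)
  everywhere <- expand.grid(gene_id = "HK2", effect_class = "intron",
                            sample_id = d$sample_id, stringsAsFactors = FALSE)
  everywhere$present <- TRUE
  nowhere <- expand.grid(gene_id = "INHA", effect_class = "utr",
                         sample_id = d$sample_id, stringsAsFactors = FALSE)
  nowhere$present <- FALSE
  va <- variant_association(rbind(rows, everywhere, nowhere), d)
  # zero-presence units are skipped entirely
  expect_identical(sort(va$gene_id), c("FSTL3", "HK2"))
  expect_equal(va$p_value[va$gene_id == "FSTL3"], 0.04761905,
               tolerance = 1e-7)
  # all-samples unit is degenerate: p = 1
  expect_identical(va$p_value[va$gene_id == "HK2"], 1)
  stray <- rows
  stray$sample_id[1] <- "GHOST"
  expect_error(variant_association(stray, d), "not in the design")
})

test_that("splice association reports exact p-values per event", {
  d <- make_design()
  mk <- function(type, gene, case_vals, ctrl_vals) {
    row <- data.frame(event_type = type, gene_id = gene, chrom = "chr1",
                      start = 100L, end = 200L, check.names = FALSE)
    row[d$sample_id] <- as.list(c(case_vals, ctrl_vals))
    row
  }
  events <- rbind(
    mk("TSS", "LAMB3", c(10, 11, 12, 13, 14), c(1, 2, 3, 4, 5)),
    mk("TTS", "HK2", c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5)))
  sa <- splice_association(events, d)
  sep <- sa[sa$gene_id == "LAMB3", ]
  expect_equal(sep$p_value, 2 / 252, tolerance = 1e-12)
  expect_false(sep$approximate)
  flat <- sa[sa$gene_id == "HK2", ]
  expect_identical(flat$p_value, 1)
  expect_true(flat$approximate)
  expect_true(all(sa$event_type %in%
                    c("AE", "TSS", "TTS", "IR", "MIR", "SKIP", "MSKIP")))
})

test_that("fusion summaries count carriers per group", {
  d <- make_design()
  fus <- data.frame(gene_a = "INHA", gene_b = "STK11IP", chrom = "chr2",
                    sample_id = d$sample_id,
                    present = d$sample_id %in% c("PAS1", "PAS2", "PAS5"))
  out <- summarize_fusions(fus, d)
  expect_identical(out$case_count, 3L)
  expect_identical(out$control_count, 0L)
  expect_false("p_value" %in% names(out))
  # optional exact test: 3/5 vs 0/5 -> 1/6
  tested <- summarize_fusions(fus, d, test = TRUE)
  expect_equal(tested$p_value, 1 / 6, tolerance = 1e-10)
  # absent-everywhere fusions are excluded
  none <- transform(fus, present = FALSE)
  expect_identical(nrow(summarize_fusions(none, d)), 0L)
})
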