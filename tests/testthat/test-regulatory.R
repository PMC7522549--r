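iv <- function(chrom, start, end, strand = NULL) {
  out <- list(chrom = chrom, start = start, end = end)
  if (!is.null(strand)) out$strand <- strand
  out
}

test_that("cis classification follows the strand-aware window rules", {
  gene_plus <- iv("chr1", 100000, 110000, "+")
  gene_minus <- iv("chr1", 100000, 110000, "-")
  lnc <- iv("chr1", 95000, 98000)

  up <- classify_cis(lnc, gene_plus)
  expect_identical(up$relation, "cis_up10k")
  expect_identical(up$distance, 2000)

  # same geometry, minus-strand gene: the low-coordinate side is now 3'
  dw <- classify_cis(lnc, gene_minus)
  expect_identical(dw$relation, "cis_dw20k")
  expect_identical(dw$distance, 2000)

  # one shared base is an overlap at distance 0
  touch <- classify_cis(iv("chr1", 90000, 100000), gene_plus)
  expect_identical(touch$relation, "cis_overlap")
  expect_identical(touch$distance, 0)

  # high-coordinate side of a plus-strand gene within 20 kb: downstream
  right <- classify_cis(iv("chr1", 125000, 126000), gene_plus)
  expect_identical(right$relation, "cis_dw20k")
  expect_identical(right$distance, 15000)
  # but upstream of the minus-strand gene at the same gap
  right_minus <- classify_cis(iv("chr1", 115000, 116000), gene_minus)
  expect_identical(right_minus$relation, "cis_up10k")
  expect_identical(right_minus$distance, 5000)

  # beyond both windows, or another chromosome: none
  expect_identical(classify_cis(iv("chr1", 10000, 12000), gene_plus)$relation,
                   "none")
  expect_identical(classify_cis(iv("chr2", 95000, 98000), gene_plus)$relation,
                   "none")
  expect_error(classify_cis(lnc, iv("chr1", 1, 10, "*")), "strand")
})

test_that("cis calls are symmetric under strand flip plus reflection", {
  # reflecting all coordinates about a point and flipping strand must
  # preserve the relation (relabeling invariance)
  set.seed(14)
  for (rep in 1:25) {
    gs <- sample(50000:200000, 1); ge <- gs + sample(1000:20000, 1)
    ls <- sample(30000:250000, 1); le <- ls + sample(200:5000, 1)
    strand <- sample(c("+", "-"), 1)
    a <- classify_cis(iv("c", ls, le), iv("c", gs, ge, strand))
    M <- 400000
    flip <- function(s, e) c(M - e, M - s)
    g2 <- flip(gs, ge); l2 <- flip(ls, le)
    b <- classify_cis(iv("c", l2[1], l2[2]),
                      iv("c", g2[1], g2[2], if (strand == "+") "-" else "+"))
    expect_identical(a$relation, b$relation)
    expect_identical(a$distance, b$distance)
  }
})

test_that("cis distances stay within their windows whenever defined", {
  set.seed(15)
  for (rep in 1:50) {
    gs <- sample(100000:200000, 1); ge <- gs + sample(1000:30000, 1)
    ls <- sample(50000:300000, 1); le <- ls + sample(200:3000, 1)
    r <- classify_cis(iv("c", ls, le), iv("c", gs, ge,
                                          sample(c("+", "-"), 1)))
    if (r$relation == "cis_up10k") expect_lte(r$distance, 10000)
    if (r$relation == "cis_dw20k") expect_lte(r$distance, 20000)
    if (!is.na(r$distance)) expect_gte(r$distance, 0)
  }
})

test_that("lncRNA-gene correlation handles rank and degenerate structure", {
  x <- c(1, 3, 2, 8, 5, 7, 4, 6, 9, 10)
  same <- correlate_lncrna_gene(x, x)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$spearman_rho, 1)
  # strictly monotone nonlinear transform: rho stays 1, r drops below
  tr <- correlate_lncrna_gene(x, exp(x))
  expect_equal(tr$spearman_rho, 1)
  expect_lt(tr$pearson_r, 1)
  # strictly decreasing transform
  dec <- correlate_lncrna_gene(x, -x^3)
  expect_equal(dec$spearman_rho, -1)
  expect_lt(dec$pearson_r, 0)
  expect_true(correlate_lncrna_gene(x, rep(1, 10))$degenerate)
  expect_error(correlate_lncrna_gene(1:2, 1:2), "3 matched")
})

test_that("call_targets round-trips generator geometry and expression", {
  d <- make_design()
  req <- data.frame(lncrna_id = paste0("L", 1:4),
                    gene_id = paste0("G", 1:4),
                    relation = c("up10k", "dw20k", "overlap", "trans"))
  ann <- generate_annotations(req, seed = 30)
  set.seed(31)
  gexpr <- matrix(exp(rnorm(40, 4, 1)), 4, 10,
                  dimnames = list(req$gene_id, d$sample_id))
  lexpr <- matrix(exp(rnorm(40, 2, 1)), 4, 10,
                  dimnames = list(req$lncrna_id, d$sample_id))
  # the trans pair shares a latent profile (|r| >= 0.95)
  lexpr["L4", ] <- gexpr["G4", ] * exp(rnorm(10, 0, 0.01))
  calls <- call_targets(ann, lexpr, gexpr, req$gene_id)
  expect_identical(nrow(calls), 16L)  # every (lncRNA, gene) pair
  pick <- function(l, g) calls$relation[calls$lncrna_id == l &
                                          calls$gene_id == g]
  expect_identical(pick("L1", "G1"), "cis_up10k")
  expect_identical(pick("L2", "G2"), "cis_dw20k")
  expect_identical(pick("L3", "G3"), "cis_overlap")
  expect_identical(pick("L4", "G4"), "trans")
  # distant pairs with independent noise stay unclassified
  expect_identical(pick("L4", "G1"), "none")
  # exactly one relation per pair
  expect_true(all(calls$relation %in%
                    c("cis_up10k", "cis_dw20k", "cis_overlap",
                      "trans", "none")))
})

test_that("call_targets warns on and skips unannotated hub genes", {
  req <- data.frame(lncrna_id = "L1", gene_id = "G1", relation = "up10k")
  ann <- generate_annotations(req, seed = 3)
  d <- make_design()
  gexpr <- matrix(1:10, 1, 10, dimnames = list("G1", d$sample_id))
  lexpr <- matrix(10:1, 1, 10, dimnames = list("L1", d$sample_id))
  expect_warning(calls <- call_targets(ann, lexpr, gexpr, c("G1", "GHOST")),
                 "GHOST")
  expect_identical(nrow(calls), 1L)
})

test_that("independent noise pairs are called none at the default threshold", {
  # null-correlation tail at |r| >= 0.9 with n = 10 is far below 1%
  req <- data.frame(lncrna_id = "L1", gene_id = "G1", relation = "trans")
  ann <- generate_annotations(req, seed = 4)
  d <- make_design()
  set.seed(44)
  n_none <- 0
  for (rep in 1:50) {
    gexpr <- matrix(exp(rnorm(10, 4, 1)), 1, 10,
                    dimnames = list("G1", d$sample_id))
    lexpr <- matrix(exp(rnorm(10, 2, 1)), 1, 10,
                    dimnames = list("L1", d$sample_id))
    calls <- call_targets(ann, lexpr, gexpr, "G1")
    n_none <- n_none + (calls$relation == "none")
  }
  expect_gte(n_none, 49)
})
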