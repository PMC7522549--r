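# Shared fixtures and independent brute-force oracles. The oracles here
# are deliberately naive (full enumeration) and never share code with the
# implementation they check.

make_design <- function(n_case = 5, n_control = 5) {
  sample_design(c(paste0("PAS", seq_len(n_case)),
                  paste0("NPAS", seq_len(n_control))),
                rep(c("case", "control"), c(n_case, n_control)))
}

tiny_matrix <- function(design = make_design(), n_genes = 3, seed = 1,
                        layer = "mrna_counts") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * nrow(design), 50), n_genes, nrow(design),
              dimnames = list(paste0("g", seq_len(n_genes)),
                              design$sample_id))
  expression_matrix(m, layer, design)
}

# Exhaustive two-sided Fisher p: enumerate all 2x2 tables with the
# observed margins, point-probability rule.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, numeric(1))
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exhaustive Mann-Whitney: enumerate every assignment of n ranks out of
# n + m, compute U, take the two-sided doubled tail.
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  U_all <- apply(combos, 2, function(idx) sum(idx) - n * (n + 1) / 2)
  lower <- mean(U_all <= U_obs)
  upper <- mean(U_all >= U_obs)
  min(1, 2 * min(lower, upper))
}

# Exhaustive overlap-null tail: enumerate every draw of n_de_mrna labels
# from the universe against a fixed protein-subset differential set.
overlap_tail_oracle <- function(universe, n_de_mrna, n_de_protein, observed) {
  de_p <- seq_len(n_de_protein)        # fixed wlog by symmetry
  combos <- utils::combn(universe, n_de_mrna)
  mean(apply(combos, 2, function(s) sum(s %in% de_p)) >= observed)
}

# Exhaustive conditional NB tail for one gene: enumerate all splits of
# the total s, point-probability rule.
nb_oracle <- function(y1, s, n1, n2, phi) {
  mu <- s / (n1 + n2)
  pr <- vapply(0:s, function(y) {
    dnbinom(y, size = n1 / phi, mu = n1 * mu) *
      dnbinom(s - y, size = n2 / phi, mu = n2 * mu)
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[y1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Independent weighted-KS running sum (loop form, no cumsum).
es_oracle <- function(ids, scores, set, weight) {
  hits <- ids %in% set
  nr <- sum(abs(scores[hits])^weight)
  miss_step <- 1 / (length(ids) - sum(hits))
  running <- numeric(length(ids))
  acc <- 0
  for (i in seq_along(ids)) {
    acc <- if (hits[i]) acc + abs(scores[i])^weight / nr else acc - miss_step
    running[i] <- acc
  }
  running[which.max(abs(running))]
}
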