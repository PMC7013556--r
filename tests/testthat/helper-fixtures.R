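# Shared fixtures and independent oracles for the test suite.

# Tiny expression matrix from a list day -> replicate values (same gene
# values recycled per gene row if a matrix is not supplied).
make_expr <- function(gene_rows, days, reps) {
  cn <- sprintf("day%d_rep%d", rep(days, each = reps),
                rep(seq_len(reps), length(days)))
  m <- do.call(rbind, gene_rows)
  dimnames(m) <- list(names(gene_rows), cn)
  m
}

# Brute-force Fisher p oracle: enumerate all tables with the observed
# margins using exact choose() ratios (independent of dhyper/fisher.test).
fisher_p_oracle <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c; n2 <- b + d; k <- a + b; N <- m + n2
  xs <- max(0, k - n2):min(k, m)
  pr <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  obs <- pr[xs == a]
  if (alternative == "two.sided") sum(pr[pr <= obs * (1 + 1e-7)])
  else if (alternative == "greater") sum(pr[xs >= a])
  else sum(pr[xs <= a])
}

# Five shape-distinct planted modules covering all genes (no background),
# used for module-recovery benchmarks.
recovery_config <- function(seed, n_genes = 2000, rep_sigma = 0.3) {
  sizes <- round(n_genes * c(0.30, 0.25, 0.20, 0.15, 0.10))
  sizes[1] <- n_genes - sum(sizes[-1])
  synthetic_config(
    n_genes = n_genes, rep_sigma = rep_sigma, seed = seed,
    module_spec = list(
      module_entry("immediate_transient",  sizes[1]),
      module_entry("immediate_persistent", sizes[2], sign = "mixed"),
      module_entry("mid_transient",        sizes[3]),
      module_entry("slow_persistent",      sizes[4], sign = "mixed"),
      module_entry("late_transient",       sizes[5])))
}

# Printed module-table counts used as inputs: per module, total genes and
# flagged-gene counts within a 1937-gene universe carrying 91 PPE, 212 PE
# and 220 TR flags.
module_table_counts <- list(
  universe = 1937, n_ppe = 91, n_pe = 212, n_tr = 220,
  rows = data.frame(
    module = c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8", "M9"),
    n      = c(256, 45, 42, 726, 378, 176, 72, 182, 60),
    ppe    = c(17, 10, 3, 26, 11, 7, 9, 7, 1),
    pe     = c(37, 5, 4, 79, 43, 12, 7, 19, 6),
    tr     = c(27, 3, 3, 108, 37, 21, 8, 12, 1),
    or_ppe = c(1.54, 6.39, 1.58, 0.65, 0.55, 0.83, 3.11, 0.80, 0.34),
    or_pe  = c(1.45, 1.02, 0.85, 0.99, 1.06, 0.57, 0.87, 0.94, 0.90),
    or_tr  = c(0.91, 0.55, 0.59, 1.71, 0.82, 1.06, 0.97, 0.53, 0.13)))

# Simple acyclicity check by repeated removal of sink-free nodes.
is_acyclic <- function(edges) {
  nodes <- union(edges$source, edges$target)
  repeat {
    if (nrow(edges) == 0) return(TRUE)
    sinks <- setdiff(nodes, edges$source)
    drop <- edges$target %in% sinks
    if (!any(drop)) return(FALSE)
    edges <- edges[!drop, , drop = FALSE]
  }
}
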