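# Shared fixtures and independent oracles, built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# chain root <- A <- B
chain_dag <- function() {
  ontology_dag(
    tibble::tibble(
      term_id = c("T:root", "T:A", "T:B"),
      name = c("root", "a", "b"),
      namespace = "biological_process"
    ),
    list("T:A" = "T:root", "T:B" = "T:A")
  )
}

# diamond: root <- {L, R} <- X
diamond_dag <- function() {
  ontology_dag(
    tibble::tibble(
      term_id = c("T:root", "T:L", "T:R", "T:X"),
      name = c("root", "left", "right", "leaf"),
      namespace = "biological_process"
    ),
    list("T:L" = "T:root", "T:R" = "T:root", "T:X" = c("T:L", "T:R"))
  )
}

# Independent ancestor closure (naive recursion, no memoisation) used as
# the oracle for propagation and rollup checks.
naive_ancestors <- function(dag, id) {
  ps <- dag$parents[[id]]
  out <- id
  for (p in ps) out <- union(out, naive_ancestors(dag, p))
  sort(out)
}

# Spearman oracle: Pearson product-moment formula applied to average ranks,
# computed from first principles.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Hypergeometric overlap null for equal shared universes: A of size n_a and
# B of size n_b drawn from N distinct terms.
hyper_overlap_mean <- function(N, n_a, n_b) n_a * n_b / N
hyper_overlap_sd <- function(N, n_a, n_b) {
  sqrt(n_a * n_b * (N - n_a) * (N - n_b) / (N^2 * (N - 1)))
}

# Exact upper hypergeometric tail by direct pmf summation (oracle for the
# Fisher enrichment p-value).
hyper_tail_sum <- function(q, K, N, n) {
  ks <- q:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

make_cgmap_line <- function(seq_id = "st1", nuc = "C", pos = 1, ctx3 = "CG",
                            dinuc = "CG", level = 0, mc = 0, cov = 10) {
  paste(seq_id, nuc, pos, ctx3, dinuc, level, mc, cov, sep = "\t")
}
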