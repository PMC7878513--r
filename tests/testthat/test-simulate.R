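test_that("generators are pure functions of their seed", {
  a <- simulate_methylome(methylome_sim_params(n_transcripts = 20, seed = 4))
  b <- simulate_methylome(methylome_sim_params(n_transcripts = 20, seed = 4))
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$cgmap, b$cgmap)
  expect_identical(a$truth, b$truth)
  c <- simulate_methylome(methylome_sim_params(n_transcripts = 20, seed = 5))
  expect_false(identical(a$fasta$sequence, c$fasta$sequence))

  d1 <- simulate_de_pair(overlap_sim_params(seed = 2))
  d2 <- simulate_de_pair(overlap_sim_params(seed = 2))
  expect_identical(d1$de_a, d2$de_a)

  o1 <- simulate_orthogroup_matrix(ortho_sim_params(seed = 3))
  o2 <- simulate_orthogroup_matrix(ortho_sim_params(seed = 3))
  expect_identical(o1$matrix$counts, o2$matrix$counts)

  g1 <- simulate_ontology(ontology_sim_params(seed = 6))
  g2 <- simulate_ontology(ontology_sim_params(seed = 6))
  expect_identical(g1$study, g2$study)
})

test_that("null methylome emits only unmethylated calls", {
  p <- methylome_sim_params(n_transcripts = 10,
    p_meth = c(CG = 0, CW = 0, CC = 0), seed = 2)
  sim <- simulate_methylome(p)
  expect_true(all(sim$cgmap$mc_count == 0L))
  expect_true(all(sim$cgmap$level == 0))
  expect_equal(sum(sim$truth$n_meth), 0L)
})

test_that("degenerate context mix puts every C site in CG", {
  p <- methylome_sim_params(n_transcripts = 10,
    context_mix = c(CG = 1, CA = 0, CC = 0, CT = 0), seed = 2)
  sim <- simulate_methylome(p)
  cen <- context_census(sim$fasta)
  expect_equal(cen$proportion[cen$dinucleotide == "CG"], 1)
  expect_true(all(sim$cgmap$dinucleotide == "CG"))
})

test_that("CGmap output is consistent with the FASTA dinucleotides", {
  sim <- simulate_methylome(methylome_sim_params(n_transcripts = 8, seed = 9))
  seqs <- setNames(sim$fasta$sequence, sim$fasta$seq_id)
  x <- sim$cgmap[sample.int(nrow(sim$cgmap), 300), ]
  for (i in seq_len(nrow(x))) {
    s <- seqs[[x$seq_id[[i]]]]
    pos <- x$position[[i]]
    base <- substr(s, pos, pos)
    expect_equal(base, x$nucleotide[[i]])
    if (x$nucleotide[[i]] == "C") {
      expect_equal(paste0("C", substr(s, pos + 1L, pos + 1L)),
        x$dinucleotide[[i]])
    } else {
      prev <- substr(s, pos - 1L, pos - 1L)
      expect_equal(paste0("C", chartr("ACGT", "TGCA", prev)),
        x$dinucleotide[[i]])
    }
  }
  # truth table and census agree on per-class site totals
  cen <- context_census(sim$fasta)
  cls <- census_by_class(cen)
  expect_equal(cls$n[cls$class == "CG"], sum(sim$truth$n_cg))
  expect_equal(cls$n[cls$class == "CW"], sum(sim$truth$n_cw))
  expect_equal(cls$n[cls$class == "CC"], sum(sim$truth$n_cc))
})

test_that("realized census tracks the context mix at multinomial scale", {
  sim <- simulate_methylome(methylome_sim_params(n_transcripts = 200, seed = 12))
  cen <- context_census(sim$fasta)
  n <- attr(cen, "n_sites")
  p <- sim$params$context_mix[["CG"]]
  lo <- qbinom(0.005, n, p) / n
  hi <- qbinom(0.995, n, p) / n
  cg <- cen$proportion[cen$dinucleotide == "CG"]
  expect_gte(cg, lo - 200 / n)  # slack for the per-transcript pair rounding
  expect_lte(cg, hi + 200 / n)
})

test_that("planted DE overlap is exact, including the boundary cases", {
  # k = 0: nothing shared
  s0 <- simulate_de_pair(overlap_sim_params(k = 0L,
    concordant = c(nurse = 0L, forager = 0L), seed = 3))
  r0 <- overlap_random_test(
    normalize_terms(s0$de_a$annotation), normalize_terms(s0$de_b$annotation),
    normalize_terms(s0$universe_a), normalize_terms(s0$universe_b),
    reps = 150, seed = 1)
  expect_equal(r0$observed, 0L)

  # complete overlap: n_a = n_b = k over a fully shared universe
  sm <- simulate_de_pair(overlap_sim_params(
    universe_a = 60L, universe_b = 60L, shared_universe = 60L,
    de_a = 25L, de_b = 25L, k = 25L,
    concordant = c(nurse = 15L, forager = 10L), seed = 4))
  rm <- overlap_random_test(
    normalize_terms(sm$de_a$annotation), normalize_terms(sm$de_b$annotation),
    normalize_terms(sm$universe_a), normalize_terms(sm$universe_b),
    reps = 150, seed = 1)
  expect_equal(rm$observed, 25L)

  # hypergeometric location of the null under a shared universe
  sh <- simulate_de_pair(overlap_sim_params(
    universe_a = 1000L, universe_b = 1000L, shared_universe = 1000L,
    de_a = 100L, de_b = 50L, k = 30L,
    concordant = c(nurse = 20L, forager = 10L), seed = 5))
  rh <- overlap_random_test(
    normalize_terms(sh$de_a$annotation), normalize_terms(sh$de_b$annotation),
    normalize_terms(sh$universe_a), normalize_terms(sh$universe_b),
    reps = 4000, seed = 2, universe_mode = "shared")
  expect_equal(rh$observed, 30L)
  mu <- hyper_overlap_mean(1000, 100, 50)
  expect_lt(abs(rh$expected_mean - mu),
    4 * hyper_overlap_sd(1000, 100, 50) / sqrt(4000) + 1e-9)

  expect_error(overlap_sim_params(de_a = 10, de_b = 10, k = 11),
    class = "beecaste_param_error")
})

test_that("orthogroup simulation satisfies its planted classes by construction", {
  sim <- simulate_orthogroup_matrix(ortho_sim_params(seed = 17))
  # apinae rows are present everywhere
  api <- sim$truth$orthogroup[sim$truth$category == "apinae"]
  expect_true(all(sim$matrix$counts[api, ] > 0L))
  # species-specific rows are present in exactly one dataset
  ss <- sim$truth$orthogroup[sim$truth$category == "species_specific"]
  expect_true(all(rowSums(sim$matrix$counts[ss, ] > 0L) == 1L))
  # classifier recovers every planted label
  asn <- classify_orthogroup(sim$matrix)
  expect_equal(asn$category, sim$truth$category)
  # unassigned lists have the requested sizes
  expect_equal(lengths(sim$matrix$unassigned[c(
    "B_terrestris_trans", "T_angustula_trans")]),
    c(B_terrestris_trans = 60L, T_angustula_trans = 40L))
})

test_that("ontology simulation plants a recoverable enrichment", {
  sim <- simulate_ontology(ontology_sim_params(odds_ratio = 8, seed = 23))
  ann <- propagate_annotations(sim$annotation, sim$dag)
  enr <- fisher_enrichment(sim$study, sim$background, ann, alpha = 0.01)
  p_planted <- enr$p_value[enr$term_id == sim$truth$planted_term]
  expect_lt(p_planted, 0.01)

  # rollup of any planted-term carrier hits the planted level-3 term
  roll <- rollup_level(
    tibble::tibble(gene_id = sim$study, log_fc = 1), ann, sim$dag, level = 3L)
  carriers_in_study <- intersect(sim$study, sim$truth$carriers)
  expect_equal(
    roll$n_genes[roll$term_id == sim$truth$planted_term],
    length(carriers_in_study)
  )

  expect_error(ontology_sim_params(n_levels = 2),
    class = "beecaste_param_error")
})
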