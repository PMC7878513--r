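test_that("propagation closes annotations over chains and diamonds", {
  dag <- chain_dag()
  ann <- tibble::tibble(gene_id = "g1", term_id = "T:B")
  prop <- propagate_annotations(ann, dag)
  expect_setequal(prop$term_id, c("T:B", "T:A", "T:root"))

  # root annotation is a fixpoint
  ann_root <- tibble::tibble(gene_id = "g1", term_id = "T:root")
  expect_equal(propagate_annotations(ann_root, dag)$term_id, "T:root")

  # diamond: both parents once (set semantics)
  d <- diamond_dag()
  prop_d <- propagate_annotations(
    tibble::tibble(gene_id = "g1", term_id = "T:X"), d)
  expect_setequal(prop_d$term_id, c("T:X", "T:L", "T:R", "T:root"))
  expect_equal(nrow(prop_d), 4L)

  # idempotence
  expect_equal(propagate_annotations(prop_d, d), prop_d)

  expect_error(
    propagate_annotations(tibble::tibble(gene_id = "g", term_id = "T:none"), d),
    class = "beecaste_validation_error"
  )
})

test_that("Fisher enrichment equals the brute-force hypergeometric tail", {
  # the worked 2x2: study 10 genes (5 with term), background 100 (10 with term)
  genes <- sprintf("g%03d", 1:100)
  with_term <- genes[1:10]
  study <- c(genes[1:5], genes[50:54])
  dag <- chain_dag()
  ann <- tibble::tibble(gene_id = with_term, term_id = "T:root")
  res <- fisher_enrichment(study, genes, ann)
  expect_equal(res$study_count, 5L)
  oracle <- hyper_tail_sum(5, 10, 100, 10)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.62e-4, tolerance = 1e-2)
  expect_true(res$enriched)

  # randomised small tables against the summation oracle
  set.seed(8)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    bg <- sprintf("b%03d", 1:N)
    st <- sample(bg, n)
    ann_i <- tibble::tibble(gene_id = bg[1:K], term_id = "T:root")
    ri <- fisher_enrichment(st, bg, ann_i, alpha = 0.01)
    q <- ri$study_count
    expect_equal(ri$p_value, hyper_tail_sum(q, K, N, n), tolerance = 1e-12)
  }

  # uninformative term annotating everything: p = 1
  ann_all <- tibble::tibble(gene_id = genes, term_id = "T:root")
  expect_equal(fisher_enrichment(study, genes, ann_all)$p_value, 1)

  # study = background: p = 1 for every term
  expect_true(all(fisher_enrichment(genes, genes, ann)$p_value == 1))

  expect_error(fisher_enrichment(c("zzz"), genes, ann),
    class = "beecaste_validation_error")
})

test_that("term depth counts shortest (or longest) paths from the root", {
  dag <- chain_dag()
  d <- term_depth(dag)
  expect_equal(unname(d[c("T:root", "T:A", "T:B")]), c(1L, 2L, 3L))

  # diamond with a long and a short route
  terms <- tibble::tibble(
    term_id = c("R", "M", "X"),
    name = c("r", "m", "x"), namespace = "bp"
  )
  dag2 <- ontology_dag(terms, list(M = "R", X = c("R", "M")))
  expect_equal(unname(term_depth(dag2)["X"]), 2L)
  expect_equal(unname(term_depth(dag2, "longest")["X"]), 3L)
})

test_that("level rollup aggregates genes and mean logFC at the target depth", {
  dag <- chain_dag()
  ann <- propagate_annotations(
    tibble::tibble(gene_id = c("g1", "g2"), term_id = c("T:B", "T:B")), dag)
  de <- tibble::tibble(gene_id = c("g1", "g2"), log_fc = c(2, -2))
  roll <- rollup_level(de, ann, dag, level = 3L)
  expect_equal(roll$term_id, "T:B")
  expect_equal(roll$n_genes, 2L)
  expect_equal(roll$mean_log_fc, 0)

  roll1 <- rollup_level(de[1, ], ann, dag, level = 3L)
  expect_equal(roll1$mean_log_fc, 2)

  expect_warning(empty <- rollup_level(de, ann, dag, level = 9L), "no ontology terms")
  expect_equal(nrow(empty), 0L)
})

test_that("rollup counts on a simulated ontology match an independent closure", {
  sim <- simulate_ontology(ontology_sim_params(seed = 77))
  ann <- propagate_annotations(sim$annotation, sim$dag)
  de <- tibble::tibble(gene_id = sim$study, log_fc = seq_along(sim$study))
  roll <- rollup_level(de, ann, sim$dag, level = 3L)

  level3 <- names(sim$truth$depths)[sim$truth$depths == 3L]
  direct <- split(sim$annotation$term_id, sim$annotation$gene_id)
  for (tid in roll$term_id) {
    hits <- vapply(sim$study, function(g) {
      any(vapply(direct[[g]], function(t) tid %in% naive_ancestors(sim$dag, t),
        logical(1)))
    }, logical(1))
    expect_equal(roll$n_genes[roll$term_id == tid], sum(hits))
  }
  expect_true(all(roll$term_id %in% level3))
})

test_that("induced subgraphs are ancestor-closed and stable under re-induction", {
  dag <- chain_dag()
  sg <- induced_subgraph("T:B", dag)
  expect_setequal(sg$nodes$term_id, c("T:root", "T:A", "T:B"))

  expect_equal(induced_subgraph("T:root", dag)$nodes$term_id, "T:root")

  # two leaves sharing one parent: Y shape with 4 nodes
  terms <- tibble::tibble(
    term_id = c("R", "P", "L1", "L2"),
    name = letters[1:4], namespace = "bp"
  )
  dagy <- ontology_dag(terms, list(P = "R", L1 = "P", L2 = "P"))
  sgy <- induced_subgraph(c("L1", "L2"), dagy)
  expect_equal(nrow(sgy$nodes), 4L)
  expect_equal(nrow(sgy$edges), 3L)

  # closure stability: re-inducing on the node set reproduces the subgraph
  sg2 <- induced_subgraph(sgy$nodes$term_id, dagy)
  expect_equal(sg2$nodes$term_id, sgy$nodes$term_id)
  expect_equal(sg2$edges, sgy$edges)

  expect_error(induced_subgraph("nope", dagy),
    class = "beecaste_validation_error")
})

test_that("top-k selection feeds the subgraph from an enrichment table", {
  sim <- simulate_ontology(ontology_sim_params(seed = 5))
  ann <- propagate_annotations(sim$annotation, sim$dag)
  enr <- fisher_enrichment(sim$study, sim$background, ann)
  sg <- induced_subgraph(enr, sim$dag, top_k = 3L)
  top3 <- head(dplyr::arrange(enr, p_value)$term_id, 3L)
  expect_true(all(top3 %in% sg$nodes$term_id))
  expect_true(all(sg$nodes$term_id[sg$nodes$seed] %in% top3))
})
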