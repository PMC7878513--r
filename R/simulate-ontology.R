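#' Parameters for the toy-ontology generator
#'
#' Builds a rooted `is_a` tree with a fixed branching factor, annotates
#' genes to its terms, and plants one enriched term: genes carrying the
#' planted term enter the study set with the stated odds ratio relative to
#' non-carriers. At least three levels are required so that a "third
#' hierarchical level" exists for rollups.
#'
#' @param n_levels Tree depth (root = level 1; >= 3).
#' @param branching Children per internal term.
#' @param n_genes Number of annotated genes.
#' @param n_study Study-set size.
#' @param planted_level Depth of the planted term (default 3).
#' @param carrier_rate Background probability that a gene carries the
#'   planted term.
#' @param odds_ratio Planted enrichment odds ratio (1 = no enrichment).
#' @param extra_terms_per_gene How many additional random deepest-level
#'   terms each gene is annotated to.
#' @param seed Integer seed.
#' @return A list of class `ontology_sim_params`.
#' @export
ontology_sim_params <- function(n_levels = 4L, branching = 3L,
                                n_genes = 300L, n_study = 40L,
                                planted_level = 3L, carrier_rate = 0.15,
                                odds_ratio = 6, extra_terms_per_gene = 2L,
                                seed = 1L) {
  if (n_levels < 3L) param_error("n_levels must be >= 3")
  if (planted_level > n_levels) param_error("planted_level exceeds n_levels")
  if (odds_ratio <= 0) param_error("odds_ratio must be positive")
  structure(
    list(
      n_levels = as.integer(n_levels), branching = as.integer(branching),
      n_genes = as.integer(n_genes), n_study = as.integer(n_study),
      planted_level = as.integer(planted_level),
      carrier_rate = carrier_rate, odds_ratio = odds_ratio,
      extra_terms_per_gene = as.integer(extra_terms_per_gene),
      seed = check_seed(seed)
    ),
    class = "ontology_sim_params"
  )
}

#' Simulate an ontology, annotations and an enriched study set
#'
#' @param params An [ontology_sim_params()] object.
#' @return A list with `dag` (an [ontology_dag()]), `annotation` (direct
#'   gene -> term tibble), `study` (character), `background` (character)
#'   and `truth` (list: `planted_term`, `carriers`, `odds_ratio`,
#'   `depths`).
#' @export
simulate_ontology <- function(params = ontology_sim_params()) {
  stopifnot(inherits(params, "ontology_sim_params"))
  set.seed(params$seed)
  p <- params

  # breadth-first tree construction
  ids <- "GO:0000001"
  level_of <- c(1L)
  parents <- list("GO:0000001" = character())
  frontier <- "GO:0000001"
  counter <- 1L
  for (lvl in seq(2L, p$n_levels)) {
    nxt <- character()
    for (parent in frontier) {
      for (b in seq_len(p$branching)) {
        counter <- counter + 1L
        id <- sprintf("GO:%07d", counter)
        ids <- c(ids, id)
        level_of <- c(level_of, lvl)
        parents[[id]] <- parent
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  terms <- tibble(
    term_id = ids,
    name = paste0("process ", seq_along(ids)),
    namespace = "biological_process"
  )
  dag <- ontology_dag(terms, parents)

  at_planted <- ids[level_of == p$planted_level]
  planted <- at_planted[[1L]]
  deepest <- ids[level_of == p$n_levels]

  genes <- sprintf("gene%04d", seq_len(p$n_genes))
  carriers <- genes[runif(p$n_genes) < p$carrier_rate]
  # direct annotations: carriers get the planted term (or one of its
  # descendants' side remains free); everyone gets random deep terms
  ann <- list(tibble(
    gene_id = carriers, term_id = planted
  ))
  others <- setdiff(deepest, descendants_of(dag, planted))
  for (e in seq_len(p$extra_terms_per_gene)) {
    ann[[e + 1L]] <- tibble(
      gene_id = genes,
      term_id = sample(others, p$n_genes, replace = TRUE)
    )
  }
  annotation <- distinct(bind_rows(ann), .data$gene_id, .data$term_id)

  w <- ifelse(genes %in% carriers, p$odds_ratio, 1)
  study <- sample(genes, p$n_study, prob = w)

  list(
    dag = dag, annotation = annotation, study = study, background = genes,
    truth = list(
      planted_term = planted, carriers = carriers,
      odds_ratio = p$odds_ratio,
      depths = setNames(level_of, ids)
    ),
    params = params
  )
}

# all terms whose ancestor closure contains `term` (term itself included)
descendants_of <- function(dag, term) {
  anc <- ancestor_closure(dag)
  names(anc)[vapply(anc, function(a) term %in% a, logical(1))]
}
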