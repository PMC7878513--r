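#' Propagate gene annotations up the ontology
#'
#' Replaces each gene's direct term set by its ancestor closure under the
#' `is_a` relation (true-path rule): a gene annotated to a term is
#' implicitly annotated to every ancestor up to and including the root.
#' Propagation is idempotent.
#'
#' @param annotation Tibble with columns `gene_id`, `term_id` (direct
#'   annotations).
#' @param dag An [ontology_dag()]. All annotated terms must exist in it.
#' @return Tibble `gene_id`/`term_id` with the closure, distinct rows,
#'   carrying attribute `propagated = TRUE`.
#' @export
propagate_annotations <- function(annotation, dag) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  unknown <- setdiff(unique(annotation$term_id), dag$terms$term_id)
  if (length(unknown) > 0L) {
    validation_error(paste0(
      "annotation uses term(s) absent from ontology: ",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  anc <- ancestor_closure(dag)
  out <- annotation %>%
    distinct(.data$gene_id, .data$term_id) %>%
    mutate(term_id = purrr::map(.data$term_id, ~ anc[[.x]])) %>%
    tidyr::unnest("term_id") %>%
    distinct(.data$gene_id, .data$term_id) %>%
    arrange(.data$gene_id, .data$term_id)
  attr(out, "propagated") <- TRUE
  out
}

# term id -> character vector of itself plus all is_a ancestors (memoised
# over a topological-ish recursion)
ancestor_closure <- function(dag) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- id
    for (p in dag$parents[[id]]) res <- union(res, get_anc(p))
    memo[[id]] <- res
    res
  }
  setNames(lapply(dag$terms$term_id, get_anc), dag$terms$term_id)
}

#' Fisher enrichment of ontology terms in a study set
#'
#' Classic one-sided Fisher's exact test per term: is the term
#' over-represented among the study genes relative to the background (the
#' full annotated transcriptome)? The p-value is the upper hypergeometric
#' tail of the 2x2 table. No multiplicity correction is applied by default,
#' matching the raw `p < alpha` reporting convention; set
#' `correct = "BH"` for Benjamini-Hochberg adjusted values in an extra
#' column.
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param annotation Propagated annotation tibble (see
#'   [propagate_annotations()]).
#' @param alpha Significance threshold for the `enriched` flag (default
#'   0.01).
#' @param correct `"none"` (default) or `"BH"`.
#' @return Tibble sorted by p-value: `term_id`, `study_count`,
#'   `study_size`, `background_count`, `background_size`, `p_value`,
#'   `enriched` (and `p_adjusted` if requested).
#' @export
fisher_enrichment <- function(study, background, annotation, alpha = 0.01,
                              correct = c("none", "BH")) {
  correct <- match.arg(correct)
  study <- unique(study)
  background <- unique(background)
  if (length(setdiff(study, background)) > 0L) {
    validation_error("study set must be a subset of the background")
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  n_bg <- length(background)
  n_st <- length(study)
  per_term <- ann %>%
    group_by(term_id = .data$term_id) %>%
    summarise(
      background_count = dplyr::n_distinct(.data$gene_id),
      study_count = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% study])
    ) %>%
    ungroup()
  out <- per_term %>%
    mutate(
      study_size = n_st,
      background_size = n_bg,
      p_value = phyper(.data$study_count - 1L, .data$background_count,
        n_bg - .data$background_count, n_st, lower.tail = FALSE),
      enriched = .data$p_value < alpha
    ) %>%
    arrange(.data$p_value, .data$term_id) %>%
    select("term_id", "study_count", "study_size", "background_count",
      "background_size", "p_value", "enriched")
  if (correct == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Hierarchical depth of every ontology term
#'
#' Depth is counted from the root: a root has depth 1, and every other term
#' has depth `1 + `the length of its shortest (default) or longest `is_a`
#' path to a root. The "third hierarchical level" of an ontology is the set
#' of terms at depth 3.
#'
#' @param dag An [ontology_dag()].
#' @param mode `"shortest"` (default) or `"longest"` path counting.
#' @return Named integer vector: term id -> depth.
#' @export
term_depth <- function(dag, mode = c("shortest", "longest")) {
  mode <- match.arg(mode)
  ids <- dag$terms$term_id
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  memo_get <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    ps <- dag$parents[[id]]
    d <- if (length(ps) == 0L) 1L else {
      pd <- vapply(ps, memo_get, integer(1))
      1L + if (mode == "shortest") min(pd) else max(pd)
    }
    depth[[id]] <<- d
    d
  }
  for (id in ids) memo_get(id)
  depth
}

#' Roll differentially expressed genes up to an ontology level
#'
#' Summarises a DE gene list at the terms of a fixed hierarchical level
#' (typically level 3): for each term at exactly that depth, the genes
#' whose propagated annotation contains the term, their count and their
#' mean log fold change. A gene contributes to every level-`level` term it
#' reaches, so rows are not disjoint.
#'
#' @param de DE tibble with `gene_id` and `log_fc` columns.
#' @param annotation Propagated annotation tibble.
#' @param dag An [ontology_dag()].
#' @param level Target depth (root = 1; default 3).
#' @param depth_mode Passed to [term_depth()].
#' @return Tibble: `term_id`, `n_genes`, `mean_log_fc`, `gene_ids`
#'   (list-column). Empty (with a warning) if no term sits at `level`.
#' @export
rollup_level <- function(de, annotation, dag, level = 3L,
                         depth_mode = c("shortest", "longest")) {
  depth_mode <- match.arg(depth_mode)
  if (level < 1L) param_error("`level` must be >= 1")
  depths <- term_depth(dag, depth_mode)
  at_level <- names(depths)[depths == level]
  if (length(at_level) == 0L) {
    warn(paste0("no ontology terms at level ", level))
    return(tibble(term_id = character(), n_genes = integer(),
      mean_log_fc = double(), gene_ids = list()))
  }
  ann <- annotation[annotation$term_id %in% at_level &
    annotation$gene_id %in% de$gene_id, , drop = FALSE]
  lfc <- setNames(de$log_fc, de$gene_id)
  ann %>%
    group_by(term_id = .data$term_id) %>%
    summarise(
      n_genes = dplyr::n_distinct(.data$gene_id),
      mean_log_fc = mean(lfc[unique(.data$gene_id)]),
      gene_ids = list(sort(unique(.data$gene_id)))
    ) %>%
    ungroup() %>%
    arrange(.data$term_id)
}

#' Ancestor-closed subgraph induced by a term set
#'
#' The induced subgraph of a set of (typically enriched) terms contains
#' those terms plus all their `is_a` ancestors, with every `is_a` edge
#' among the retained nodes. Comparing such subgraphs across species
#' exposes shared parent processes even when the enriched leaves differ.
#'
#' @param terms Character vector of term ids (all must exist in the DAG),
#'   or a [fisher_enrichment()] result, in which case the `top_k` terms by
#'   ascending p-value are used.
#' @param dag An [ontology_dag()].
#' @param top_k When `terms` is an enrichment table: how many top terms to
#'   induce on (default 8).
#' @return A list of class `ontology_subgraph`: `nodes` (tibble `term_id`,
#'   `name`, `seed` flag), `edges` (tibble `child`, `parent`).
#' @export
induced_subgraph <- function(terms, dag, top_k = 8L) {
  if (is.data.frame(terms)) {
    terms <- head(dplyr::arrange(terms, .data$p_value)$term_id, top_k)
  }
  unknown <- setdiff(terms, dag$terms$term_id)
  if (length(unknown) > 0L) {
    validation_error(paste0(
      "term(s) not in ontology: ", paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  anc <- ancestor_closure(dag)
  nodes <- sort(unique(unlist(anc[terms], use.names = FALSE)))
  edges <- purrr::map_dfr(nodes, function(id) {
    ps <- intersect(dag$parents[[id]], nodes)
    if (length(ps) == 0L) return(tibble(child = character(), parent = character()))
    tibble(child = id, parent = ps)
  })
  structure(
    list(
      nodes = tibble(
        term_id = nodes,
        name = dag$terms$name[match(nodes, dag$terms$term_id)],
        seed = nodes %in% terms
      ),
      edges = edges
    ),
    class = "ontology_subgraph"
  )
}

#' @export
print.ontology_subgraph <- function(x, ...) {
  cat("<ontology_subgraph> ", nrow(x$nodes), " terms (",
    sum(x$nodes$seed), " seed), ", nrow(x$edges), " is_a edges\n", sep = "")
  invisible(x)
}
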