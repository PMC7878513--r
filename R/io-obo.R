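#' Construct an ontology DAG
#'
#' Minimal directed acyclic `is_a` graph over ontology terms, as used for
#' Gene Ontology rollups and induced subgraphs. Acyclicity and reachability
#' of a root from every term are verified at construction.
#'
#' @param terms Tibble with columns `term_id`, `name`, `namespace`.
#' @param parents Named list: child term id -> character vector of `is_a`
#'   parent ids. Terms without parents are roots.
#' @return An object of class `ontology_dag` with elements `terms`,
#'   `parents`, `children` and `roots`.
#' @export
ontology_dag <- function(terms, parents) {
  stopifnot(all(c("term_id", "name", "namespace") %in% names(terms)))
  ids <- terms$term_id
  if (anyDuplicated(ids)) validation_error("duplicate term ids in ontology")
  parents <- parents[intersect(names(parents), ids)]
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0L) {
    validation_error(paste0(
      "is_a parent(s) not defined as terms: ", paste(head(unknown, 3L), collapse = ", ")
    ))
  }
  full_parents <- setNames(vector("list", length(ids)), ids)
  for (id in ids) full_parents[[id]] <- unique(parents[[id]] %||% character())
  cyc <- find_cycle_member(full_parents)
  if (!is.null(cyc)) {
    validation_error(paste0("is_a cycle detected involving term ", cyc))
  }
  roots <- ids[lengths(full_parents) == 0L]
  children <- invert_edges(full_parents)
  structure(
    list(terms = tibble::as_tibble(terms), parents = full_parents,
      children = children, roots = roots),
    class = "ontology_dag"
  )
}

# Kahn's algorithm; returns one member of a cycle, or NULL if acyclic.
find_cycle_member <- function(parents) {
  ids <- names(parents)
  indeg <- lengths(parents)
  children <- invert_edges(parents)
  queue <- ids[indeg == 0L]
  seen <- 0L
  indeg <- setNames(as.integer(indeg), ids)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) names(indeg)[indeg > 0L][[1L]] else NULL
}

invert_edges <- function(parents) {
  out <- setNames(vector("list", length(parents)), names(parents))
  for (id in names(parents)) out[[id]] <- character()
  for (id in names(parents)) {
    for (p in parents[[id]]) out[[p]] <- c(out[[p]], id)
  }
  out
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", nrow(x$terms), " terms, ",
    sum(lengths(x$parents)), " is_a edges, root(s): ",
    paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a minimal OBO 1.2 ontology
#'
#' Parses only what the pipeline needs from `[Term]` stanzas: `id`, `name`,
#' `namespace`, `is_a` and `is_obsolete`. Obsolete terms are dropped
#' (together with edges pointing at them), relationship lines other than
#' `is_a` are ignored, and the resulting graph is checked for cycles.
#'
#' @param path Path to an OBO file (optionally gzipped).
#' @return An [ontology_dag()].
#' @export
read_obo_min <- function(path) {
  lines <- read_text_lines(path)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur, stanzas) {
    if (!is.null(cur) && !is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <- cur
    stanzas
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)   # strip OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      stanzas <- flush(cur, stanzas)
      cur <- list(is_a = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      stanzas <- flush(cur, stanzas)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
      if (length(kv) == 3L) {
        key <- kv[[2L]]; val <- trimws(kv[[3L]])
        if (key == "id") cur$id <- val
        if (key == "name") cur$name <- val
        if (key == "namespace") cur$namespace <- val
        if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s")[[1L]][[1L]])
        if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
      }
    }
  }
  stanzas <- flush(cur, stanzas)
  stanzas <- purrr::keep(stanzas, ~ !.x$obsolete)
  if (length(stanzas) == 0L) {
    return(ontology_dag(
      tibble(term_id = character(), name = character(), namespace = character()),
      list()
    ))
  }
  terms <- tibble(
    term_id = purrr::map_chr(stanzas, "id"),
    name = purrr::map_chr(stanzas, ~ .x$name %||% NA_character_),
    namespace = purrr::map_chr(stanzas, ~ .x$namespace %||% NA_character_)
  )
  parents <- setNames(purrr::map(stanzas, "is_a"), terms$term_id)
  # drop edges into obsolete/undefined terms that were removed
  parents <- purrr::map(parents, ~ intersect(.x, terms$term_id))
  ontology_dag(terms, parents)
}
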