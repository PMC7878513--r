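#' Construct an orthogroup presence/count matrix
#'
#' Container for an orthogroup-by-dataset gene-count table (the
#' `Orthogroups.tsv` model of graph-based orthology inference) plus the
#' per-dataset lists of genes left unassigned to any orthogroup. Presence is
#' defined as a positive gene count.
#'
#' @param genes Long tibble with columns `orthogroup`, `dataset`, `gene_id`
#'   (one row per assigned gene); may have zero rows.
#' @param datasets Character vector of all dataset ids (columns of the
#'   matrix), in order.
#' @param unassigned Named list (dataset id -> character vector of gene ids
#'   not assigned to any orthogroup). Missing datasets get empty vectors.
#' @return An object of class `orthogroup_matrix` with elements `counts`
#'   (integer matrix, orthogroups x datasets), `genes`, `datasets`,
#'   `orthogroups` and `unassigned`.
#' @export
orthogroup_matrix <- function(genes, datasets, unassigned = list()) {
  if (anyDuplicated(datasets)) validation_error("dataset ids must be unique")
  stopifnot(all(c("orthogroup", "dataset", "gene_id") %in% names(genes)))
  bad <- setdiff(unique(genes$dataset), datasets)
  if (length(bad) > 0L) {
    validation_error(paste0("unknown dataset id(s): ", paste(bad, collapse = ", ")))
  }
  ogs <- unique(genes$orthogroup)
  counts <- matrix(0L, nrow = length(ogs), ncol = length(datasets),
    dimnames = list(ogs, datasets))
  if (nrow(genes) > 0L) {
    tab <- table(factor(genes$orthogroup, levels = ogs),
      factor(genes$dataset, levels = datasets))
    counts[] <- as.integer(tab)
  }
  ua <- setNames(vector("list", length(datasets)), datasets)
  for (d in datasets) ua[[d]] <- as.character(unassigned[[d]] %||% character())
  structure(
    list(
      counts = counts, genes = tibble::as_tibble(genes), datasets = datasets,
      orthogroups = ogs, unassigned = ua
    ),
    class = "orthogroup_matrix"
  )
}

#' @export
print.orthogroup_matrix <- function(x, ...) {
  cat("<orthogroup_matrix> ", length(x$orthogroups), " orthogroups x ",
    length(x$datasets), " datasets; ",
    sum(lengths(x$unassigned)), " unassigned genes\n", sep = "")
  invisible(x)
}

#' Coerce an orthogroup matrix to a long tibble
#'
#' @param x An `orthogroup_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `orthogroup`, `dataset`, `n_genes`, `present`.
#' @method as_tibble orthogroup_matrix
#' @export
as_tibble.orthogroup_matrix <- function(x, ...) {
  tibble(
    orthogroup = rep(x$orthogroups, times = length(x$datasets)),
    dataset = rep(x$datasets, each = length(x$orthogroups)),
    n_genes = as.integer(x$counts),
    present = as.integer(x$counts) > 0L
  )
}

#' Read an Orthogroups.tsv presence table
#'
#' Parses the tab-separated orthogroup table of OrthoFinder-style output:
#' first column the orthogroup id, one column per dataset, cells holding
#' comma-separated gene ids (possibly empty). Gene counts per cell define
#' presence. An optional companion table of unassigned genes (same dialect,
#' typically `Orthogroups_UnassignedGenes.tsv`) populates the per-dataset
#' unassigned lists.
#'
#' @param path Path to the orthogroups TSV.
#' @param unassigned Optional: path to an unassigned-genes TSV in the same
#'   dialect, or a named list of gene-id vectors per dataset.
#' @return An [orthogroup_matrix()].
#' @export
read_orthogroups <- function(path, unassigned = NULL) {
  parsed <- parse_orthogroup_tsv(path)
  ua <- list()
  if (is.character(unassigned)) {
    ua_parsed <- parse_orthogroup_tsv(unassigned)
    ua <- split(ua_parsed$genes$gene_id, ua_parsed$genes$dataset)
  } else if (is.list(unassigned)) {
    ua <- unassigned
  }
  orthogroup_matrix(parsed$genes, parsed$datasets, ua)
}

parse_orthogroup_tsv <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0L) parse_error("empty orthogroups file (no header)")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) parse_error("orthogroups header needs >= 2 columns", line = 1L)
  datasets <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(list(
      genes = tibble(orthogroup = character(), dataset = character(),
        gene_id = character()),
      datasets = datasets
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  og_ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- og_ids[duplicated(og_ids)]
  if (length(dup) > 0L) {
    validation_error(paste0("duplicate orthogroup id: ", dup[[1L]]))
  }
  rows <- purrr::map2(fields, og_ids, function(f, og) {
    cells <- c(f[-1L], rep("", length(datasets) - (length(f) - 1L)))
    genes <- lapply(cells, function(cell) {
      g <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      g[nzchar(g)]
    })
    tibble(
      orthogroup = og,
      dataset = rep(datasets, lengths(genes)),
      gene_id = unlist(genes, use.names = FALSE) %||% character()
    )
  })
  list(genes = dplyr::bind_rows(rows), datasets = datasets)
}

#' Write an Orthogroups.tsv table
#'
#' Inverse of [read_orthogroups()]; cells are comma+space separated gene
#' lists, matching the upstream dialect.
#'
#' @param x An `orthogroup_matrix`.
#' @param path Output path.
#' @param unassigned_path Optional path for the companion unassigned-genes
#'   table (one synthetic orthogroup row per gene).
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(x, path, unassigned_path = NULL) {
  stopifnot(inherits(x, "orthogroup_matrix"))
  header <- paste(c("Orthogroup", x$datasets), collapse = "\t")
  by_cell <- split(x$genes$gene_id,
    list(factor(x$genes$orthogroup, levels = x$orthogroups),
         factor(x$genes$dataset, levels = x$datasets)),
    sep = "\r")
  lines <- vapply(x$orthogroups, function(og) {
    cells <- vapply(x$datasets, function(d) {
      paste(by_cell[[paste(og, d, sep = "\r")]], collapse = ", ")
    }, character(1))
    paste(c(og, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  if (!is.null(unassigned_path)) {
    ua <- x$unassigned
    rows <- character()
    i <- 0L
    for (d in x$datasets) {
      for (g in ua[[d]]) {
        i <- i + 1L
        cells <- rep("", length(x$datasets))
        cells[match(d, x$datasets)] <- g
        rows <- c(rows, paste(c(sprintf("OGU%07d", i), cells), collapse = "\t"))
      }
    }
    writeLines(c(header, rows), unassigned_path)
  }
  invisible(path)
}
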