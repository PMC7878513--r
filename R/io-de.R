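#' Read a per-gene differential expression table
#'
#' Reads a TSV of differential expression results between nurse and forager
#' workers of one species. The header must provide a gene id, a log2 fold
#' change, a p-value and an annotation column (free-text protein description,
#' possibly empty); common aliases such as `logFC`, `p.value` or
#' `description` are recognised. An optional normalized-count column
#' (`norm_count`/`baseMean`) is carried through when present, for
#' methylation-expression coupling downstream.
#'
#' The sign convention of the fold change is not assumed: `orientation`
#' declares which subcaste a positive log fold change favours, and the
#' derived `bias` column stores the subcaste explicitly so that downstream
#' code never re-infers sign conventions.
#'
#' @param path Path to a TSV file (optionally gzipped).
#' @param orientation `"forager-positive"` (default) if positive `log_fc`
#'   means higher expression in foragers, else `"nurse-positive"`.
#' @return A tibble with columns `gene_id`, `log_fc`, `p_value`, `bias`
#'   (`"nurse"`/`"forager"`), `annotation`, and `norm_count` when supplied.
#' @export
read_de_table <- function(path, orientation = c("forager-positive", "nurse-positive")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE)
  id_col <- match_column(names(raw), c("gene_id", "id", "gene", "supertranscript", "transcript_id"))
  fc_col <- match_column(names(raw), c("log_fc", "logFC", "log2FoldChange", "log2fc", "lfc"))
  p_col <- match_column(names(raw), c("p_value", "pvalue", "p.value", "pval"))
  ann_col <- match_column(names(raw), c("annotation", "annot", "description", "protein_description"))
  missing_cols <- c(
    if (is.null(id_col)) "gene id",
    if (is.null(fc_col)) "logFC",
    if (is.null(p_col)) "p-value",
    if (is.null(ann_col)) "annotation"
  )
  if (length(missing_cols) > 0L) {
    schema_error(paste0(
      "DE table at ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  nc_col <- match_column(names(raw), c("norm_count", "baseMean", "normalized_count"))
  out <- tibble(
    gene_id = as.character(raw[[id_col]]),
    log_fc = as.numeric(raw[[fc_col]]),
    p_value = as.numeric(raw[[p_col]]),
    annotation = dplyr::coalesce(as.character(raw[[ann_col]]), "")
  )
  if (any(out$p_value < 0 | out$p_value > 1, na.rm = TRUE)) {
    validation_error("p_value outside [0, 1] in DE table")
  }
  out$bias <- derive_bias(out$log_fc, orientation)
  if (!is.null(nc_col)) out$norm_count <- as.numeric(raw[[nc_col]])
  out[, c("gene_id", "log_fc", "p_value", "bias", "annotation",
          intersect("norm_count", names(out)))]
}

derive_bias <- function(log_fc, orientation) {
  pos <- if (orientation == "forager-positive") "forager" else "nurse"
  neg <- if (orientation == "forager-positive") "nurse" else "forager"
  out <- ifelse(log_fc > 0, pos, ifelse(log_fc < 0, neg, NA_character_))
  if (anyNA(out)) warn("log_fc of exactly 0: bias set to NA")
  out
}

#' Summarise a differential expression table
#'
#' Report arithmetic for DE tables: stratum counts (total, nurse-biased,
#' forager-biased) and the annotation rate — the percentage of entries with
#' a non-empty annotation, the quantity quoted when describing how much of
#' a DE set has similarity to known protein-coding genes.
#'
#' @param x A DE tibble (see [read_de_table()]).
#' @return One-row tibble: `n_total`, `n_nurse`, `n_forager`,
#'   `n_annotated`, `pct_annotated`.
#' @export
de_summary <- function(x) {
  ann <- !is.na(x$annotation) & nzchar(trimws(x$annotation))
  tibble(
    n_total = nrow(x),
    n_nurse = sum(x$bias == "nurse", na.rm = TRUE),
    n_forager = sum(x$bias == "forager", na.rm = TRUE),
    n_annotated = sum(ann),
    pct_annotated = if (nrow(x) > 0) 100 * sum(ann) / nrow(x) else NA_real_
  )
}

#' Percentage of annotated entries
#'
#' @param annotation Character vector of annotation strings (empty or `NA`
#'   counts as unannotated).
#' @return Percentage in `[0, 100]` (`NA` for empty input).
#' @export
annotation_rate <- function(annotation) {
  if (length(annotation) == 0L) return(NA_real_)
  100 * mean(!is.na(annotation) & nzchar(trimws(annotation)))
}

#' Write a differential expression table
#'
#' @param x A tibble as returned by [read_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  need <- c("gene_id", "log_fc", "p_value", "bias", "annotation")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    schema_error(paste0(
      "missing DE columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  keep <- c(need, intersect("norm_count", names(x)))
  readr::write_tsv(x[keep], path, progress = FALSE)
  invisible(path)
}
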