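#' Read a FASTA file into a tibble
#'
#' Small strict FASTA reader for transcriptome references. Sequence ids are
#' the first whitespace-delimited token of the header; lowercase bases and
#' IUPAC ambiguity letters are tolerated and normalised to uppercase. A
#' sequence line appearing before any header is a parse error naming the
#' line; records with empty sequences are retained (length 0) with a
#' warning.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `seq_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  is_header <- startsWith(lines, ">")
  if (length(lines) > 0L) {
    first_seq <- which(!is_header & nzchar(trimws(lines)))
    if (length(first_seq) > 0L &&
        (!any(is_header) || first_seq[[1L]] < which(is_header)[[1L]])) {
      parse_error("sequence line before any FASTA header", line = first_seq[[1L]])
    }
  }
  if (!any(is_header)) {
    return(tibble(seq_id = character(), sequence = character()))
  }
  rec <- cumsum(is_header)
  headers <- lines[is_header]
  ids <- vapply(headers, function(h) {
    strsplit(sub("^>", "", h), "\\s+")[[1L]][[1L]] %||% ""
  }, character(1), USE.NAMES = FALSE)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]), function(x) {
    toupper(paste(trimws(x), collapse = ""))
  }, character(1))
  all_seqs <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  all_seqs[names(seqs)] <- seqs
  if (any(!nzchar(all_seqs))) {
    warn(paste0(sum(!nzchar(all_seqs)), " FASTA record(s) with empty sequence"))
  }
  tibble(seq_id = ids, sequence = unname(all_seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `seq_id` and `sequence` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$seq_id[[i]]), con)
    s <- x$sequence[[i]]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}
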