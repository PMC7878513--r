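#' Read per-cytosine methylation calls in CGmap format
#'
#' CGmap is the 8-column tab-separated table emitted by transcriptome/genome
#' bisulfite callers: reference name, the Watson-strand nucleotide (`C`, or
#' `G` for a cytosine on the Crick strand), 1-based position, three-letter
#' context (`CG`/`CHG`/`CHH`), dinucleotide context (`CA`/`CC`/`CG`/`CT`),
#' methylation level, methylated-read count and total coverage. Files may be
#' gzip-compressed; compression is detected from the magic bytes, not the
#' file name.
#'
#' Malformed lines (wrong column count, non-numeric counts, `mc_count`
#' exceeding `coverage`) raise an error naming the offending line; the parser
#' never skips silently. Input ordering is preserved.
#'
#' @param path Path to a CGmap file (optionally gzipped).
#' @return A tibble with columns `seq_id`, `nucleotide`, `position`,
#'   `context3`, `dinucleotide`, `level`, `mc_count`, `coverage`; one row per
#'   cytosine site.
#' @examples
#' f <- tempfile(fileext = ".cgmap")
#' writeLines("st1\tC\t15\tCG\tCG\t0.8\t8\t10", f)
#' read_cgmap(f)
#' @export
read_cgmap <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_cgmap())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 8L)
  if (length(bad) > 0L) {
    parse_error(
      paste0("expected 8 tab-separated columns, found ", nf[bad[1L]]),
      line = bad[1L]
    )
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  out <- tibble(
    seq_id       = m[, 1L],
    nucleotide   = m[, 2L],
    position     = suppressWarnings(as.integer(m[, 3L])),
    context3     = m[, 4L],
    dinucleotide = m[, 5L],
    level        = suppressWarnings(as.numeric(m[, 6L])),
    mc_count     = suppressWarnings(as.integer(m[, 7L])),
    coverage     = suppressWarnings(as.integer(m[, 8L]))
  )
  bad_num <- which(is.na(out$position) | is.na(out$level) |
    is.na(out$mc_count) | is.na(out$coverage))
  if (length(bad_num) > 0L) {
    parse_error("non-numeric position, level or counts", line = bad_num[1L])
  }
  bad_nuc <- which(!out$nucleotide %in% c("C", "G"))
  if (length(bad_nuc) > 0L) {
    parse_error(
      paste0("nucleotide must be C or G, found '", out$nucleotide[bad_nuc[1L]], "'"),
      line = bad_nuc[1L]
    )
  }
  bad_cov <- which(out$mc_count > out$coverage | out$mc_count < 0L)
  if (length(bad_cov) > 0L) {
    validation_error(paste0(
      "mc_count exceeds coverage at line ", bad_cov[1L],
      " (", out$mc_count[bad_cov[1L]], " > ", out$coverage[bad_cov[1L]], ")"
    ))
  }
  out
}

empty_cgmap <- function() {
  tibble(
    seq_id = character(), nucleotide = character(), position = integer(),
    context3 = character(), dinucleotide = character(), level = double(),
    mc_count = integer(), coverage = integer()
  )
}

#' Write a CGmap table
#'
#' Inverse of [read_cgmap()]: writes the 8 canonical columns, tab-separated,
#' without a header, so that write-then-read is the identity.
#'
#' @param x A tibble as returned by [read_cgmap()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(x, path) {
  cols <- c(
    "seq_id", "nucleotide", "position", "context3", "dinucleotide",
    "level", "mc_count", "coverage"
  )
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0L) {
    schema_error(paste0(
      "missing CGmap columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
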