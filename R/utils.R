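# Internal helpers shared across modules.

# Sniff gzip by magic bytes (never by extension).
is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Read all lines of a possibly gzip-compressed text file.
read_text_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "beecaste_io_error")
  }
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- paste0(msg, " (line ", line, ")")
  abort(msg, class = "beecaste_parse_error")
}

schema_error <- function(msg) abort(msg, class = "beecaste_schema_error")

validation_error <- function(msg) abort(msg, class = "beecaste_validation_error")

param_error <- function(msg) abort(msg, class = "beecaste_param_error")

# Locate one required column among accepted aliases (case/punctuation
# insensitive); returns the actual name or NULL.
match_column <- function(nms, aliases) {
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  hit <- match(canon(aliases), canon(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) NULL else nms[[hit[[1L]]]]
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    param_error("`seed` must be a single integer")
  }
  invisible(as.integer(seed))
}

# Complement of an A/C/G/T/N base vector.
complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}
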