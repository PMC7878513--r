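#' Normalise free-text annotation terms
#'
#' Cross-species comparison of differentially expressed gene sets matches
#' genes by their protein annotation text, using only unique and
#' non-redundant terms. Normalisation lowercases, collapses internal
#' whitespace, trims, deduplicates, and removes empty entries and entries
#' containing "uncharacterized protein" (which carry no comparable
#' information).
#'
#' @param x Character vector of raw annotation strings (a multiset).
#' @return Sorted character vector of normalised, unique terms.
#' @examples
#' normalize_terms(c("Cytochrome p450", "cytochrome   p450",
#'                   "Uncharacterized protein LOC123", ""))
#' @export
normalize_terms <- function(x) {
  if (length(x) == 0L) return(character())
  out <- stringr::str_squish(tolower(x))
  out <- out[nzchar(out)]
  out <- out[!stringr::str_detect(out, stringr::fixed("uncharacterized protein"))]
  sort(unique(out))
}

#' Default curation patterns for shared-term reporting
#'
#' Literal substrings flagged during manual curation of cross-species shared
#' annotation terms: generic or fragment-level annotations whose match
#' across species is not evidence of the same gene.
#'
#' @return Character vector of literal substring patterns.
#' @export
default_curation_patterns <- function() {
  c("transposase", "transporter", "cytochrome c oxidase subunit")
}

#' Curate a shared-term list
#'
#' Removes terms matching any of the configured literal substring patterns
#' (case-insensitive). Curation applies only to the reported shared-term
#' list, never inside the random-sampling statistic, whose observed overlap
#' stays the uncurated computational count.
#'
#' @param terms Character vector of (normalised) terms.
#' @param patterns Literal substrings to flag; see
#'   [default_curation_patterns()].
#' @return A list with `kept` (character), `removed` (tibble with columns
#'   `term`, `pattern`).
#' @export
curate_terms <- function(terms, patterns = default_curation_patterns()) {
  if (length(patterns) == 0L || length(terms) == 0L) {
    return(list(kept = terms,
      removed = tibble(term = character(), pattern = character())))
  }
  hit_pattern <- rep(NA_character_, length(terms))
  for (p in patterns) {
    hits <- is.na(hit_pattern) &
      stringr::str_detect(tolower(terms), stringr::fixed(tolower(p)))
    hit_pattern[hits] <- p
  }
  list(
    kept = terms[is.na(hit_pattern)],
    removed = tibble(term = terms[!is.na(hit_pattern)],
      pattern = hit_pattern[!is.na(hit_pattern)])
  )
}

#' Random-sampling overlap test for two term sets
#'
#' Tests whether the number of annotation terms shared by two
#' differentially-expressed gene sets exceeds chance expectation. The null
#' is built by repeatedly drawing `|A|` terms uniformly without replacement
#' from species A's annotated-term universe and `|B|` terms from species
#' B's, recording the intersection size each time. The empirical one-sided
#' p-value uses the `(m + 1) / (reps + 1)` convention, so it is never 0;
#' its minimum is `1 / (reps + 1)`.
#'
#' With `universe_mode = "shared"` both draws come from the union of the
#' two universes, which makes the null exactly hypergeometric-convolved and
#' is the mode used by the closed-form oracle checks. The default
#' `"per-species"` draws each set from its own species' universe, matching
#' the species-specific transcriptome annotations the term sets derive
#' from.
#'
#' @param a_terms,b_terms Character vectors of normalised terms (the DE
#'   sets).
#' @param a_universe,b_universe Normalised term universes of the two
#'   species' full annotated transcriptomes; must contain the respective
#'   term sets.
#' @param reps Number of random draws (>= 100; default 10000).
#' @param seed Integer seed for the draws (mandatory in reports; recorded
#'   in the result).
#' @param universe_mode `"per-species"` (default) or `"shared"`.
#' @return An object of class `overlap_test`: a list with `observed`,
#'   `shared_terms`, `expected_mean`, `expected_sd`, `p_value`, `reps`,
#'   `seed`, `universe_mode`, `n_a`, `n_b`, `n_universe_a`, `n_universe_b`.
#' @export
overlap_random_test <- function(a_terms, b_terms, a_universe, b_universe,
                                reps = 10000L, seed = NULL,
                                universe_mode = c("per-species", "shared")) {
  universe_mode <- match.arg(universe_mode)
  reps <- as.integer(reps)
  if (reps < 100L) param_error("`reps` must be at least 100")
  a_terms <- unique(a_terms); b_terms <- unique(b_terms)
  a_universe <- unique(a_universe); b_universe <- unique(b_universe)
  if (length(a_universe) == 0L || length(b_universe) == 0L) {
    validation_error("term universes must be non-empty")
  }
  if (length(setdiff(a_terms, a_universe)) > 0L ||
      length(setdiff(b_terms, b_universe)) > 0L) {
    validation_error("term sets must be subsets of their universes")
  }
  shared <- sort(intersect(a_terms, b_terms))
  observed <- length(shared)

  if (universe_mode == "shared") {
    pool <- sort(union(a_universe, b_universe))
    u_a <- pool; u_b <- pool
  } else {
    u_a <- a_universe; u_b <- b_universe
  }
  # integer coding over the union so intersection counting is O(n) per rep
  pool <- sort(union(u_a, u_b))
  ia <- match(u_a, pool); ib <- match(u_b, pool)
  n_a <- length(a_terms); n_b <- length(b_terms)

  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  draws <- integer(reps)
  mark <- integer(length(pool))
  for (r in seq_len(reps)) {
    da <- ia[sample.int(length(ia), n_a)]
    mark[da] <- r
    db <- ib[sample.int(length(ib), n_b)]
    draws[[r]] <- sum(mark[db] == r)
  }
  p <- (sum(draws >= observed) + 1) / (reps + 1)

  structure(
    list(
      observed = observed, shared_terms = shared,
      expected_mean = mean(draws), expected_sd = stats::sd(draws),
      p_value = p, reps = reps, seed = seed, universe_mode = universe_mode,
      n_a = n_a, n_b = n_b,
      n_universe_a = length(u_a), n_universe_b = length(u_b)
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("<overlap_test> observed ", x$observed, " shared terms (|A| = ", x$n_a,
    ", |B| = ", x$n_b, ")\n", sep = "")
  cat("  null (", x$reps, " draws, ", x$universe_mode, " universes): mean ",
    signif(x$expected_mean, 4), ", SD ", signif(x$expected_sd, 4),
    ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Stratified overlap of two species' DE tables
#'
#' Runs the random-sampling overlap test for the full DE sets and for the
#' nurse-biased and forager-biased strata separately, matching genes by
#' normalised annotation terms. Strata missing from either table are
#' skipped with a warning.
#'
#' @param de_a,de_b DE tibbles (see [read_de_table()]) for species A and B.
#' @param universe_a,universe_b Raw annotation strings of each species'
#'   full annotated transcriptome (normalised internally).
#' @param reps,seed,universe_mode Passed to [overlap_random_test()]; the
#'   seed is advanced per stratum deterministically.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.01).
#' @param curation Literal substring patterns used to curate the reported
#'   shared-term lists (never the statistic); `NULL` disables curation.
#' @return A tibble with one row per stratum (`all`, `nurse`, `forager`):
#'   observed overlap, null mean/SD, p-value, significance flag, and
#'   list-columns `shared_terms` (uncurated) and `curated_terms`.
#' @export
stratified_overlap <- function(de_a, de_b, universe_a, universe_b,
                               reps = 10000L, seed = NULL,
                               universe_mode = c("per-species", "shared"),
                               alpha = 0.01,
                               curation = default_curation_patterns()) {
  universe_mode <- match.arg(universe_mode)
  u_a <- normalize_terms(universe_a)
  u_b <- normalize_terms(universe_b)
  strata <- c("all", "nurse", "forager")
  seed <- check_seed(seed)
  rows <- list()
  for (i in seq_along(strata)) {
    s <- strata[[i]]
    ta <- if (s == "all") de_a else dplyr::filter(de_a, .data$bias == s)
    tb <- if (s == "all") de_b else dplyr::filter(de_b, .data$bias == s)
    if (nrow(ta) == 0L || nrow(tb) == 0L) {
      warn(paste0("stratum '", s, "' missing in one species; skipped"))
      next
    }
    terms_a <- intersect(normalize_terms(ta$annotation), u_a)
    terms_b <- intersect(normalize_terms(tb$annotation), u_b)
    res <- overlap_random_test(
      terms_a, terms_b, u_a, u_b, reps = reps,
      seed = if (is.null(seed)) NULL else seed + i - 1L,
      universe_mode = universe_mode
    )
    cur <- if (is.null(curation)) {
      list(kept = res$shared_terms,
        removed = tibble(term = character(), pattern = character()))
    } else {
      curate_terms(res$shared_terms, curation)
    }
    rows[[s]] <- tibble(
      stratum = s,
      observed = res$observed,
      expected_mean = res$expected_mean,
      expected_sd = res$expected_sd,
      p_value = res$p_value,
      significant = res$p_value < alpha,
      n_a = res$n_a, n_b = res$n_b, reps = res$reps,
      seed = res$seed %||% NA_integer_,
      shared_terms = list(res$shared_terms),
      curated_terms = list(cur$kept),
      curated_removed = list(cur$removed)
    )
  }
  dplyr::bind_rows(rows)
}
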