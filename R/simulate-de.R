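#' Parameters for the paired DE-table generator
#'
#' Emulates the cross-species comparison setting: two species whose
#' annotated-term universes partially overlap, two differentially
#' expressed gene sets with a planted number of common normalised terms,
#' and a per-species nurse/forager direction split. Default sizes are a
#' desk-scale rendition of two annotated bee transcriptomes and their DE
#' sets; the planted overlap (15 terms in common, 7 concordantly
#' nurse-biased, 2 concordantly forager-biased) mirrors the structure of a
#' bumblebee-vs-stingless-bee comparison.
#'
#' @param universe_a,universe_b Sizes of the two species' annotated-term
#'   universes.
#' @param shared_universe Number of terms common to both universes.
#' @param de_a,de_b Sizes of the two DE term sets.
#' @param k Planted overlap (terms common to both DE sets,
#'   post-normalisation).
#' @param concordant Named vector `c(nurse = ..., forager = ...)`: how many
#'   of the `k` common terms are biased the same way in both species; the
#'   remainder are discordant.
#' @param nurse_frac_a,nurse_frac_b Fraction of each species'
#'   non-overlapping DE terms biased towards nurses.
#' @param seed Integer seed.
#' @return A list of class `overlap_sim_params`.
#' @export
overlap_sim_params <- function(universe_a = 4000L, universe_b = 4500L,
                               shared_universe = 2500L,
                               de_a = 400L, de_b = 120L, k = 15L,
                               concordant = c(nurse = 7L, forager = 2L),
                               nurse_frac_a = 0.36, nurse_frac_b = 0.74,
                               seed = 1L) {
  if (k > min(de_a, de_b)) param_error("k must be <= min(de_a, de_b)")
  if (k > shared_universe) param_error("k must be <= shared_universe")
  if (shared_universe > min(universe_a, universe_b)) {
    param_error("shared_universe exceeds a universe size")
  }
  if (sum(concordant) > k) param_error("sum(concordant) must be <= k")
  structure(
    list(
      universe_a = as.integer(universe_a), universe_b = as.integer(universe_b),
      shared_universe = as.integer(shared_universe),
      de_a = as.integer(de_a), de_b = as.integer(de_b), k = as.integer(k),
      concordant = concordant,
      nurse_frac_a = nurse_frac_a, nurse_frac_b = nurse_frac_b,
      seed = check_seed(seed)
    ),
    class = "overlap_sim_params"
  )
}

#' Simulate a pair of annotated DE tables with planted overlap
#'
#' Builds two DE tibbles whose normalised-annotation overlap is exactly
#' `k`, plus the two full annotated-term universes, and a truth list
#' recording the planted terms and per-stratum overlap sizes. Annotation
#' case is jittered so that normalisation is actually exercised. Log fold
#' changes follow the forager-positive orientation.
#'
#' @param params An [overlap_sim_params()] object.
#' @return A list with `de_a`, `de_b` (DE tibbles including `norm_count`),
#'   `universe_a`, `universe_b` (raw annotation string vectors) and
#'   `truth` (list: `k`, `overlap_terms`, `observed_by_stratum`).
#' @export
simulate_de_pair <- function(params = overlap_sim_params()) {
  stopifnot(inherits(params, "overlap_sim_params"))
  set.seed(params$seed)
  p <- params
  shared_terms <- sprintf("shared protein %04d", seq_len(p$shared_universe))
  own_a <- sprintf("species a protein %04d", seq_len(p$universe_a - p$shared_universe))
  own_b <- sprintf("species b protein %04d", seq_len(p$universe_b - p$shared_universe))
  universe_a <- c(shared_terms, own_a)
  universe_b <- c(shared_terms, own_b)

  pool <- sample(shared_terms)
  overlap_terms <- pool[seq_len(p$k)]
  remaining_shared <- setdiff(pool, overlap_terms)

  extra_a <- sample(c(remaining_shared, own_a), p$de_a - p$k)
  avail_b <- setdiff(c(remaining_shared, own_b), extra_a)
  if (length(avail_b) < p$de_b - p$k) {
    param_error("universes too small for the requested disjoint DE sets")
  }
  extra_b <- sample(avail_b, p$de_b - p$k)

  n_nur <- p$concordant[["nurse"]]
  n_for <- p$concordant[["forager"]]
  bias_overlap_a <- c(
    rep("nurse", n_nur), rep("forager", n_for),
    rep("nurse", p$k - n_nur - n_for)   # discordant: nurse in A...
  )
  bias_overlap_b <- c(
    rep("nurse", n_nur), rep("forager", n_for),
    rep("forager", p$k - n_nur - n_for) # ...forager in B
  )
  bias_extra_a <- ifelse(runif(length(extra_a)) < p$nurse_frac_a, "nurse", "forager")
  bias_extra_b <- ifelse(runif(length(extra_b)) < p$nurse_frac_b, "nurse", "forager")

  make_table <- function(prefix, terms, bias) {
    n <- length(terms)
    lfc <- (stats::rexp(n, rate = 1) + 0.3) * ifelse(bias == "forager", 1, -1)
    # jitter case/whitespace so normalisation does real work
    ann <- ifelse(runif(n) < 0.5, toupper(substr(terms, 1, 1)), substr(terms, 1, 1))
    ann <- paste0(ann, substring(terms, 2))
    tibble(
      gene_id = sprintf("%s_g%05d", prefix, seq_len(n)),
      log_fc = lfc,
      p_value = runif(n, 0, 1e-3),
      bias = bias,
      annotation = ann,
      norm_count = rlnorm(n, log(100), 1)
    )
  }
  de_a <- make_table("A", c(overlap_terms, extra_a), c(bias_overlap_a, bias_extra_a))
  de_b <- make_table("B", c(overlap_terms, extra_b), c(bias_overlap_b, bias_extra_b))

  list(
    de_a = de_a, de_b = de_b,
    universe_a = universe_a, universe_b = universe_b,
    truth = list(
      k = p$k,
      overlap_terms = sort(overlap_terms),
      observed_by_stratum = c(all = p$k, nurse = n_nur, forager = n_for)
    ),
    params = params
  )
}
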