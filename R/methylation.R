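#' Dinucleotide context classes
#'
#' Cytosine sites are classified by the base that follows them: `CG`
#' (cytosine/guanine), `CW` (cytosine/adenine or cytosine/thymine — the
#' non-CG aggregate most relevant in insects) and `CC`. The three classes
#' partition the four dinucleotides.
#'
#' @param dinucleotide Character vector over `{"CA","CC","CG","CT"}`.
#' @return Character vector over `{"CG","CW","CC"}`.
#' @export
context_class <- function(dinucleotide) {
  out <- c(CA = "CW", CT = "CW", CG = "CG", CC = "CC")[dinucleotide]
  if (anyNA(out)) {
    validation_error(paste0(
      "unknown dinucleotide context: ",
      paste(unique(dinucleotide[is.na(out)]), collapse = ", ")
    ))
  }
  unname(out)
}

#' Filter methylation calls by minimum coverage
#'
#' Sites sequenced below `min_cov` reads are too noisy for level estimates
#' and are removed before any statistic (default 10x). The number of
#' dropped sites is reported via a message.
#'
#' @param x CGmap tibble (see [read_cgmap()]).
#' @param min_cov Minimum total read coverage (>= 1; default 10).
#' @return The filtered tibble.
#' @export
filter_coverage <- function(x, min_cov = 10L) {
  if (min_cov < 1L) param_error("`min_cov` must be >= 1")
  keep <- x$coverage >= min_cov
  if (any(!keep)) {
    inform(paste0(sum(!keep), " site(s) below ", min_cov, "x coverage dropped"))
  }
  x[keep, , drop = FALSE]
}

#' Census of available cytosine contexts in a transcriptome
#'
#' Counts every cytosine site on both strands of the reference sequences
#' and tabulates its dinucleotide context. A plus-strand `C` is read with
#' its following base; a plus-strand `G` is a minus-strand cytosine whose
#' following base is the complement of the base preceding the `G`. Sites at
#' sequence ends, or whose defining neighbour is `N` (or another ambiguity
#' letter), have undefined context: they are counted in an `undefined`
#' bucket that is excluded from the proportion denominator.
#'
#' @param fasta Tibble with `seq_id` and `sequence` columns (see
#'   [read_fasta()]), or a named character vector of sequences.
#' @return A tibble of class `context_census` with one row per
#'   dinucleotide (`CA`, `CC`, `CG`, `CT`): columns `dinucleotide`,
#'   `class`, `n`, `proportion`. Proportions are `NA` when no classified C
#'   site exists. Attributes `n_sites` (classified) and `n_undefined`.
#' @export
context_census <- function(fasta) {
  if (is.character(fasta)) {
    fasta <- tibble(seq_id = names(fasta) %||% as.character(seq_along(fasta)),
      sequence = unname(fasta))
  }
  dinucs <- c("CA", "CC", "CG", "CT")
  counts <- setNames(integer(4L), dinucs)
  n_undef <- 0L
  for (s in toupper(fasta$sequence)) {
    if (nchar(s) == 0L) next
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    # plus strand: C followed by x
    ci <- which(ch == "C")
    if (length(ci) > 0L) {
      nxt <- ifelse(ci < n, ch[pmin(ci + 1L, n)], NA_character_)
      d <- paste0("C", nxt)
      ok <- !is.na(nxt) & d %in% dinucs
      tab <- table(factor(d[ok], levels = dinucs))
      counts <- counts + as.integer(tab)
      n_undef <- n_undef + sum(!ok)
    }
    # minus strand: G at i is a C whose next base complements ch[i - 1]
    gi <- which(ch == "G")
    if (length(gi) > 0L) {
      prv <- ifelse(gi > 1L, ch[pmax(gi - 1L, 1L)], NA_character_)
      d <- paste0("C", complement_base(prv))
      ok <- !is.na(prv) & d %in% dinucs
      tab <- table(factor(d[ok], levels = dinucs))
      counts <- counts + as.integer(tab)
      n_undef <- n_undef + sum(!ok)
    }
  }
  total <- sum(counts)
  out <- tibble(
    dinucleotide = dinucs,
    class = context_class(dinucs),
    n = as.integer(counts),
    proportion = if (total > 0L) as.numeric(counts) / total else rep(NA_real_, 4L)
  )
  attr(out, "n_sites") <- total
  attr(out, "n_undefined") <- n_undef
  class(out) <- c("context_census", class(out))
  out
}

#' Aggregate a context census to CG/CW/CC classes
#'
#' @param census A `context_census` tibble.
#' @return Tibble with columns `class`, `n`, `proportion`.
#' @export
census_by_class <- function(census) {
  census %>%
    group_by(class = .data$class) %>%
    summarise(n = sum(.data$n), proportion = sum(.data$proportion)) %>%
    ungroup() %>%
    arrange(factor(.data$class, levels = c("CG", "CW", "CC")))
}

#' Call methylated cytosines
#'
#' Adds a logical `methylated` column to coverage-filtered CGmap records.
#' The default rule calls any site with at least one methylated read
#' (`mc_count >= 1`), the simplest reading of "methylated cytosines
#' reported". The `"binomial"` rule instead requires the one-sided binomial
#' tail probability of observing `mc_count` methylated reads out of
#' `coverage` under a bisulfite non-conversion error rate `error_rate` to
#' fall below `alpha`.
#'
#' @param x CGmap tibble (after [filter_coverage()]).
#' @param rule `"threshold"` (default) or `"binomial"`.
#' @param error_rate Assumed false-methylation rate per read for the
#'   binomial rule (default 0.005).
#' @param alpha Significance level for the binomial rule (default 0.01).
#' @return `x` with an added logical column `methylated`.
#' @export
call_methylated <- function(x, rule = c("threshold", "binomial"),
                            error_rate = 0.005, alpha = 0.01) {
  rule <- match.arg(rule)
  if (rule == "threshold") {
    x$methylated <- x$mc_count >= 1L
  } else {
    tail_p <- pbinom(x$mc_count - 1L, x$coverage, error_rate, lower.tail = FALSE)
    x$methylated <- x$mc_count >= 1L & tail_p < alpha
  }
  x
}

#' Context composition of methylated cytosines
#'
#' Proportion of methylated cytosines per context class (CG, CW, CC),
#' relative to all methylated cytosines, so the three percentages sum to
#' 100. This is the per-gene-set composition display; compare it with the
#' availability census from [context_census()] to see context enrichment.
#'
#' @param x CGmap tibble with a `methylated` column (see
#'   [call_methylated()]).
#' @return A tibble of class `mc_composition`: `class`, `n_methylated`,
#'   `percent` (plus a `by_dinucleotide` attribute splitting CW into CA and
#'   CT). With zero methylated sites the percents are `NA` and a warning is
#'   raised.
#' @export
methylation_context_composition <- function(x) {
  stopifnot("methylated" %in% names(x))
  m <- x[x$methylated, , drop = FALSE]
  classes <- c("CG", "CW", "CC")
  tab <- table(factor(context_class(m$dinucleotide), levels = classes))
  total <- sum(tab)
  if (total == 0L) warn("no methylated sites: composition undefined")
  out <- tibble(
    class = classes,
    n_methylated = as.integer(tab),
    percent = if (total > 0L) 100 * as.numeric(tab) / total else NA_real_
  )
  dtab <- table(factor(m$dinucleotide, levels = c("CA", "CC", "CG", "CT")))
  attr(out, "by_dinucleotide") <- tibble(
    dinucleotide = names(dtab),
    n_methylated = as.integer(dtab),
    percent = if (total > 0L) 100 * as.numeric(dtab) / total else NA_real_
  )
  class(out) <- c("mc_composition", class(out))
  out
}

#' Per-transcript methylation summaries
#'
#' Summarises coverage-filtered (and optionally called) sites per
#' transcript. `mean_mc` is the unweighted arithmetic mean of site-level
#' methylation fractions, in percent; `weighted_mc` is the read-weighted
#' alternative (total methylated reads over total reads), reported
#' alongside because the two can differ substantially when coverage is
#' uneven. Per-class means (`mean_mc_cg`, `mean_mc_cw`, `mean_mc_cc`) use
#' the same unweighted convention.
#'
#' @param x CGmap tibble (after [filter_coverage()]); a `methylated`
#'   column, when present, feeds the per-class methylated-site counts.
#' @param all_ids Optional character vector of transcript ids that should
#'   appear in the output even with zero covered C sites (their summaries
#'   are `NA`).
#' @return A tibble with one row per transcript: `seq_id`, `n_sites`,
#'   `mean_mc`, `weighted_mc`, per-class site counts and mean levels.
#' @export
transcript_mc <- function(x, all_ids = NULL) {
  x$class <- context_class(x$dinucleotide)
  meth <- if ("methylated" %in% names(x)) x$methylated else x$mc_count >= 1L
  x$.meth <- meth
  out <- x %>%
    group_by(seq_id = .data$seq_id) %>%
    summarise(
      n_sites = dplyr::n(),
      mean_mc = 100 * mean(.data$level),
      weighted_mc = 100 * sum(.data$mc_count) / sum(.data$coverage),
      n_cg = sum(.data$class == "CG"),
      n_cw = sum(.data$class == "CW"),
      n_cc = sum(.data$class == "CC"),
      n_meth = sum(.data$.meth),
      n_meth_cg = sum(.data$.meth & .data$class == "CG"),
      n_meth_cw = sum(.data$.meth & .data$class == "CW"),
      mean_mc_cg = 100 * mean(.data$level[.data$class == "CG"]),
      mean_mc_cw = 100 * mean(.data$level[.data$class == "CW"]),
      mean_mc_cc = 100 * mean(.data$level[.data$class == "CC"])
    ) %>%
    ungroup()
  if (!is.null(all_ids)) {
    missing_ids <- setdiff(all_ids, out$seq_id)
    if (length(missing_ids) > 0L) {
      out <- bind_rows(out, tibble(seq_id = missing_ids, n_sites = 0L))
    }
    out <- out[match(all_ids, out$seq_id), , drop = FALSE]
  }
  out
}

#' One-tailed z-test of a gene set's mean methylation
#'
#' Tests whether the mean transcript methylation of a gene subset differs
#' from the general transcriptomic mean, treating the global per-transcript
#' distribution as the reference population (its mean and standard
#' deviation enter as known): `z = (x_sub - mu) / (sigma / sqrt(n))`. The
#' tail defaults to `"auto"`, following the sign of the observed
#' difference; the p-value is the standard normal tail in that direction.
#' Also reports the 95% confidence interval of the subset mean and the
#' percent difference from the global mean.
#'
#' @param subset_values Numeric vector of per-transcript mean mC for the
#'   subset (n >= 2).
#' @param global_values Numeric vector for the full transcriptome
#'   (includes the subset).
#' @param tail `"auto"`, `"greater"` or `"less"`.
#' @return An object of class `mc_set_test`: list with `n_subset`,
#'   `subset_mean`, `global_mean`, `global_sd`, `z`, `p_value`, `tail`,
#'   `conf_low`, `conf_high`, `percent_diff`.
#' @export
subset_mean_ztest <- function(subset_values, global_values,
                              tail = c("auto", "greater", "less")) {
  tail <- match.arg(tail)
  subset_values <- subset_values[!is.na(subset_values)]
  global_values <- global_values[!is.na(global_values)]
  n <- length(subset_values)
  if (n < 2L) param_error("subset needs at least 2 transcripts")
  mu <- mean(global_values)
  sigma <- stats::sd(global_values)
  if (!is.finite(sigma) || sigma == 0) {
    validation_error("degenerate population: global SD is 0")
  }
  xbar <- mean(subset_values)
  se <- sigma / sqrt(n)
  z <- (xbar - mu) / se
  if (tail == "auto") tail <- if (z >= 0) "greater" else "less"
  p <- if (tail == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  ci <- xbar + c(-1, 1) * qnorm(0.975) * se
  structure(
    list(
      n_subset = n, subset_mean = xbar, global_mean = mu, global_sd = sigma,
      z = z, p_value = p, tail = tail,
      conf_low = ci[[1L]], conf_high = ci[[2L]],
      percent_diff = 100 * (xbar - mu) / mu
    ),
    class = "mc_set_test"
  )
}

#' @export
print.mc_set_test <- function(x, ...) {
  cat("<mc_set_test> subset mean ", signif(x$subset_mean, 4), "% vs global ",
    signif(x$global_mean, 4), "% (", signif(x$percent_diff, 4),
    "% difference)\n", sep = "")
  cat("  z = ", signif(x$z, 4), ", one-tailed (", x$tail, ") p = ",
    signif(x$p_value, 4), ", 95% CI [", signif(x$conf_low, 4), ", ",
    signif(x$conf_high, 4), "], n = ", x$n_subset, "\n", sep = "")
  invisible(x)
}

#' Random-sampling test of CG methylation enrichment
#'
#' Asks whether the observed fraction of methylated cytosines in the CG
#' context exceeds what the availability of CG sites alone would predict.
#' Each of `reps` draws assigns the observed number of methylated sites
#' context labels according to the census proportions and records the CG
#' fraction; since only the CG/non-CG split matters, the draw is a binomial
#' with the census CG proportion. The empirical one-sided p-value uses the
#' `(m + 1)/(reps + 1)` convention.
#'
#' @param x CGmap tibble with a `methylated` column, or a list/vector with
#'   elements `n_cg` and `n_total` giving methylated-site counts directly.
#' @param census A `context_census` (availability proportions).
#' @param reps Number of draws (default 10000).
#' @param seed Integer seed.
#' @return A list with `observed_cg_fraction`, `expected_cg_fraction`,
#'   `n_methylated`, `p_value`, `reps`, `seed`.
#' @export
cg_enrichment_test <- function(x, census, reps = 10000L, seed = NULL) {
  if (is.data.frame(x)) {
    stopifnot("methylated" %in% names(x))
    m <- x[x$methylated, , drop = FALSE]
    n_total <- nrow(m)
    n_cg <- sum(context_class(m$dinucleotide) == "CG")
  } else {
    n_cg <- x[["n_cg"]]
    n_total <- x[["n_total"]]
  }
  if (is.null(n_total) || n_total < 1L) {
    validation_error("no methylated sites: enrichment test undefined")
  }
  cls <- census_by_class(census)
  p_cg <- cls$proportion[cls$class == "CG"]
  if (!is.finite(p_cg)) validation_error("census proportions undefined")
  observed <- n_cg / n_total
  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  draws <- rbinom(reps, n_total, p_cg) / n_total
  p <- (sum(draws >= observed) + 1) / (reps + 1)
  list(
    observed_cg_fraction = observed, expected_cg_fraction = p_cg,
    n_methylated = as.integer(n_total), p_value = p,
    reps = as.integer(reps), seed = seed
  )
}

#' Spearman correlation of methylation with expression
#'
#' Correlates per-transcript mean methylation with normalized read counts,
#' separately for CG-context and CW-context methylation, over the full
#' transcriptome or a designated subset (e.g. the differentially expressed
#' transcripts). Ranks use average tie handling; pairs with missing values
#' are dropped listwise.
#'
#' @param tmc Per-transcript summary from [transcript_mc()] (needs
#'   `mean_mc_cg`, `mean_mc_cw`).
#' @param expression Tibble with `seq_id` (or `gene_id`) and `norm_count`
#'   columns.
#' @param subset Optional character vector of transcript ids to restrict
#'   to.
#' @return A tibble with one row per context class: `class`, `r_s`, `n`.
#' @export
methylation_expression_correlation <- function(tmc, expression, subset = NULL) {
  if ("gene_id" %in% names(expression) && !"seq_id" %in% names(expression)) {
    expression <- rename(expression, seq_id = "gene_id")
  }
  stopifnot(all(c("seq_id", "norm_count") %in% names(expression)))
  d <- dplyr::inner_join(tmc, expression[, c("seq_id", "norm_count")], by = "seq_id")
  if (!is.null(subset)) d <- d[d$seq_id %in% subset, , drop = FALSE]
  one <- function(col, class) {
    keep <- is.finite(d[[col]]) & is.finite(d$norm_count)
    n <- sum(keep)
    if (n < 3L) param_error(paste0("fewer than 3 complete pairs for ", class))
    tibble(class = class,
      r_s = cor(d[[col]][keep], d$norm_count[keep], method = "spearman"),
      n = n)
  }
  bind_rows(one("mean_mc_cg", "CG"), one("mean_mc_cw", "CW"))
}
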