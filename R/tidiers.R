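#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an overlap test
#'
#' @param x An `overlap_test` object.
#' @param ... Unused.
#' @return One-row tibble: observed overlap, null mean/SD, p-value and set
#'   sizes.
#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble(
    observed = x$observed,
    expected_mean = x$expected_mean,
    expected_sd = x$expected_sd,
    p_value = x$p_value,
    n_a = x$n_a, n_b = x$n_b
  )
}

#' @rdname tidy.overlap_test
#' @method glance overlap_test
#' @export
glance.overlap_test <- function(x, ...) {
  tibble(
    reps = x$reps, seed = x$seed %||% NA_integer_,
    universe_mode = x$universe_mode,
    n_universe_a = x$n_universe_a, n_universe_b = x$n_universe_b
  )
}

#' Tidy a gene-set methylation z-test
#'
#' @param x An `mc_set_test` object.
#' @param ... Unused.
#' @return One-row tibble with the subset and global means, z statistic,
#'   one-tailed p-value, confidence bounds and percent difference.
#' @method tidy mc_set_test
#' @export
tidy.mc_set_test <- function(x, ...) {
  tibble(
    subset_mean = x$subset_mean, global_mean = x$global_mean,
    z = x$z, p_value = x$p_value, tail = x$tail,
    conf_low = x$conf_low, conf_high = x$conf_high,
    percent_diff = x$percent_diff, n_subset = x$n_subset
  )
}

#' @rdname tidy.mc_set_test
#' @method glance mc_set_test
#' @export
glance.mc_set_test <- function(x, ...) {
  tibble(global_mean = x$global_mean, global_sd = x$global_sd,
    n_subset = x$n_subset)
}

#' Tidy a category report into ring/category rows
#'
#' @param x A `category_report` tibble.
#' @param ... Unused.
#' @return Long tibble: `category`, `ring` (`transcriptome`/`focal`), `n`,
#'   `proportion`.
#' @method tidy category_report
#' @export
tidy.category_report <- function(x, ...) {
  bind_rows(
    tibble(category = x$category, ring = "transcriptome",
      n = x$n_transcriptome, proportion = x$prop_transcriptome),
    tibble(category = x$category, ring = "focal",
      n = x$n_focal, proportion = x$prop_focal)
  )
}
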