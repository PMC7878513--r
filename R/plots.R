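#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_pointrange labs position_dodge facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the context composition of methylated cytosines
#'
#' Bar chart of the percent of methylated cytosines per context class
#' (CG/CW/CC), the per-gene-set display whose bars sum to 100%.
#'
#' @param object An `mc_composition` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_composition
#' @export
autoplot.mc_composition <- function(object, ...) {
  ggplot(object, aes(x = .data$class, y = .data$percent, fill = .data$class)) +
    geom_col(show.legend = FALSE) +
    labs(x = "context class", y = "% of methylated cytosines") +
    theme_minimal()
}

#' Plot available-context proportions
#'
#' @param object A `context_census` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot context_census
#' @export
autoplot.context_census <- function(object, ...) {
  ggplot(object, aes(x = .data$dinucleotide, y = .data$proportion)) +
    geom_col(fill = "grey40") +
    labs(x = "dinucleotide context", y = "proportion of C sites") +
    theme_minimal()
}

#' Plot category proportions as paired rings
#'
#' Dodged bars comparing each taxonomic-conservation category's proportion
#' in the whole transcriptome against the focal (differentially expressed)
#' orthogroups.
#'
#' @param object A `category_report` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot category_report
#' @export
autoplot.category_report <- function(object, ...) {
  d <- tidy.category_report(object)
  ggplot(d, aes(x = .data$category, y = .data$proportion, fill = .data$ring)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "proportion of orthogroups", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot gene-set mean methylation with confidence intervals
#'
#' Point-and-interval display of per-set mean mC levels, one point per
#' gene set, mirroring the set-means figure of the analysis.
#'
#' @param tests Named list of `mc_set_test` objects (names label the sets).
#' @return A ggplot object.
#' @export
plot_mc_set_means <- function(tests) {
  d <- purrr::imap_dfr(tests, function(t, nm) {
    mutate(tidy.mc_set_test(t), set = nm)
  })
  ggplot(d, aes(x = .data$set, y = .data$subset_mean)) +
    geom_pointrange(aes(ymin = .data$conf_low, ymax = .data$conf_high)) +
    ggplot2::geom_hline(aes(yintercept = .data$global_mean), linetype = 2) +
    labs(x = NULL, y = "mean mC (%)") +
    theme_minimal()
}

#' Plot stratified overlap results
#'
#' Observed overlaps against the resampled null mean with +/- 2 SD bars,
#' per stratum.
#'
#' @param x Tibble from [stratified_overlap()].
#' @return A ggplot object.
#' @export
plot_overlap_results <- function(x) {
  ggplot(x, aes(x = .data$stratum)) +
    geom_errorbar(
      aes(ymin = .data$expected_mean - 2 * .data$expected_sd,
          ymax = .data$expected_mean + 2 * .data$expected_sd),
      width = 0.2, colour = "grey50"
    ) +
    geom_point(aes(y = .data$expected_mean), colour = "grey50", shape = 1) +
    geom_point(aes(y = .data$observed), colour = "firebrick", size = 2) +
    labs(x = NULL, y = "shared annotation terms") +
    theme_minimal()
}
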