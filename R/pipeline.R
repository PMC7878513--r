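#' Run configuration for an end-to-end pipeline run
#'
#' Bundles the run-level constants: the global seed, the number of
#' resampling replicates, the minimum site coverage (default 10x) and the
#' significance threshold (default 0.01). Each pipeline stage derives its
#' own seed as `seed + ` a fixed per-stage offset, so adding a stage never
#' perturbs the draws of earlier stages.
#'
#' @param seed Global integer seed.
#' @param resample_reps Replicates for every resampling test (>= 1).
#' @param min_coverage Minimum site coverage (>= 1).
#' @param alpha Significance threshold.
#' @param methylome,de_pair,orthogroups,ontology Optional parameter
#'   objects overriding the stage defaults (see [methylome_sim_params()]
#'   and friends); their seeds are set from the global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, resample_reps = 10000L, min_coverage = 10L,
                       alpha = 0.01, methylome = NULL, de_pair = NULL,
                       orthogroups = NULL, ontology = NULL) {
  if (resample_reps < 1L) param_error("resample_reps must be >= 1")
  if (min_coverage < 1L) param_error("min_coverage must be >= 1")
  structure(
    list(
      seed = check_seed(seed), resample_reps = as.integer(resample_reps),
      min_coverage = as.integer(min_coverage), alpha = alpha,
      methylome = methylome, de_pair = de_pair,
      orthogroups = orthogroups, ontology = ontology
    ),
    class = "run_config"
  )
}

stage_offsets <- c(
  simulate = 0L, overlap = 101L, classify = 211L, methylation = 307L,
  go = 401L
)

#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates simulate -> overlap -> classify -> methylation -> go with
#' one configuration and one seed, writing tab-separated reports and a
#' JSON manifest to `out_dir`. Every report embeds its seed, replicate
#' count and thresholds; re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("simulate", "overlap", "classify", "methylation", "go")`. Analysis
#'   stages need the simulate stage (or `inputs`) for their data.
#' @param out_dir Output directory (created if missing).
#' @param inputs Optional pre-built inputs (a list with any of `de`,
#'   `ortho`, `methylome`, `ontology` as produced by the simulators),
#'   allowing analysis stages to run without the simulate stage.
#' @return The run manifest (list), invisibly: config snapshot, seed,
#'   per-stage output paths, file digests and package version.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "overlap", "classify",
                           "methylation", "go"),
                         out_dir = tempfile("beecaste_run_"),
                         inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_of <- function(stage) config$seed + stage_offsets[[stage]]
  outputs <- list()
  sim <- inputs %||% list()

  need <- function(what, stage) {
    if (is.null(sim[[what]])) {
      abort(paste0(
        "stage '", stage, "' needs '", what, "' data: enable the 'simulate' ",
        "stage or pass it via `inputs`"
      ), class = "beecaste_dependency_error")
    }
    sim[[what]]
  }

  if ("simulate" %in% stages) {
    s <- seed_of("simulate")
    mp <- config$methylome %||% methylome_sim_params()
    dp <- config$de_pair %||% overlap_sim_params()
    op <- config$orthogroups %||% ortho_sim_params()
    np <- config$ontology %||% ontology_sim_params()
    mp$seed <- s; dp$seed <- s + 1L; op$seed <- s + 2L; np$seed <- s + 3L
    sim$methylome <- simulate_methylome(mp)
    sim$de <- simulate_de_pair(dp)
    sim$ortho <- simulate_orthogroup_matrix(op)
    sim$ontology <- simulate_ontology(np)
  }

  if ("overlap" %in% stages) {
    de <- need("de", "overlap")
    res <- stratified_overlap(
      de$de_a, de$de_b, de$universe_a, de$universe_b,
      reps = config$resample_reps, seed = seed_of("overlap"),
      alpha = config$alpha
    )
    report <- res %>%
      select(-"shared_terms", -"curated_terms", -"curated_removed") %>%
      mutate(alpha = config$alpha)
    outputs$overlap_report <- file.path(out_dir, "overlap_report.tsv")
    readr::write_tsv(report, outputs$overlap_report, progress = FALSE)
    shared <- res %>%
      select("stratum", "shared_terms") %>%
      tidyr::unnest("shared_terms")
    outputs$shared_terms <- file.path(out_dir, "shared_terms.tsv")
    readr::write_tsv(shared, outputs$shared_terms, progress = FALSE)
  }

  if ("classify" %in% stages) {
    ortho <- need("ortho", "classify")
    assignments <- classify_orthogroup(ortho$matrix)
    set.seed(seed_of("classify"))
    focal <- sample(ortho$matrix$orthogroups,
      max(1L, round(0.25 * length(ortho$matrix$orthogroups))))
    report <- category_proportions(ortho$matrix, assignments, focal) %>%
      mutate(seed = seed_of("classify"))
    outputs$category_report <- file.path(out_dir, "category_report.tsv")
    readr::write_tsv(report, outputs$category_report, progress = FALSE)
    outputs$assignments <- file.path(out_dir, "orthogroup_assignments.tsv")
    readr::write_tsv(assignments, outputs$assignments, progress = FALSE)
  }

  if ("methylation" %in% stages) {
    my <- need("methylome", "methylation")
    census <- context_census(my$fasta)
    called <- my$cgmap %>%
      filter_coverage(config$min_coverage) %>%
      call_methylated()
    comp <- methylation_context_composition(called)
    tmc <- transcript_mc(called)
    enr <- cg_enrichment_test(called, census,
      reps = config$resample_reps, seed = seed_of("methylation"))
    expr <- my$truth[, c("seq_id", "norm_count")]
    hi <- expr$seq_id[expr$norm_count >=
      stats::quantile(expr$norm_count, 0.9)]
    zt <- subset_mean_ztest(
      tmc$mean_mc[tmc$seq_id %in% hi], tmc$mean_mc)
    corr <- methylation_expression_correlation(tmc, expr)
    outputs$transcript_mc <- file.path(out_dir, "transcript_mc.tsv")
    readr::write_tsv(tmc, outputs$transcript_mc, progress = FALSE)
    meth_report <- bind_rows(
      tibble(metric = paste0("composition_pct_", tolower(comp$class)),
        value = comp$percent),
      tibble(metric = paste0("census_prop_", tolower(census$dinucleotide)),
        value = census$proportion),
      tibble(metric = c(
        "cg_enrichment_p", "high_expr_ztest_z", "high_expr_ztest_p",
        "high_expr_pct_diff",
        paste0("spearman_", tolower(corr$class))
      ), value = c(
        enr$p_value, zt$z, zt$p_value, zt$percent_diff, corr$r_s
      ))
    ) %>%
      mutate(
        seed = seed_of("methylation"), reps = config$resample_reps,
        min_coverage = config$min_coverage, alpha = config$alpha
      )
    outputs$methylation_report <- file.path(out_dir, "methylation_report.tsv")
    readr::write_tsv(meth_report, outputs$methylation_report, progress = FALSE)
  }

  if ("go" %in% stages) {
    onto <- need("ontology", "go")
    ann <- propagate_annotations(onto$annotation, onto$dag)
    enr <- fisher_enrichment(onto$study, onto$background, ann,
      alpha = config$alpha)
    outputs$go_enrichment <- file.path(out_dir, "go_enrichment.tsv")
    readr::write_tsv(mutate(enr, alpha = config$alpha),
      outputs$go_enrichment, progress = FALSE)
    de_like <- tibble(gene_id = onto$study, log_fc = 0)
    if (!is.null(sim$de)) {
      # reuse simulated logFC magnitudes for the rollup display
      set.seed(seed_of("go"))
      de_like$log_fc <- sample(sim$de$de_a$log_fc, nrow(de_like),
        replace = TRUE)
    }
    roll <- rollup_level(de_like, ann, onto$dag, level = 3L) %>%
      select(-"gene_ids")
    outputs$go_rollup <- file.path(out_dir, "go_rollup_level3.tsv")
    readr::write_tsv(roll, outputs$go_rollup, progress = FALSE)
    sg <- induced_subgraph(enr, onto$dag, top_k = 8L)
    outputs$go_subgraph <- file.path(out_dir, "go_subgraph_edges.tsv")
    readr::write_tsv(sg$edges, outputs$go_subgraph, progress = FALSE)
  }

  manifest <- list(
    tool = "beecaste",
    version = as.character(utils::packageVersion("beecaste")),
    seed = config$seed,
    config = list(
      resample_reps = config$resample_reps,
      min_coverage = config$min_coverage,
      alpha = config$alpha
    ),
    stages = stages,
    outputs = lapply(outputs, normalizePath),
    digests = as.list(tools::md5sum(unlist(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
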