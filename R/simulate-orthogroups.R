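#' Parameters for the orthogroup-matrix generator
#'
#' Plants a known number of orthogroups in each taxonomic-conservation
#' category over the 11-dataset bee panel, plus per-dataset unassigned
#' gene lists. Category patterns are constructed to satisfy the shipped
#' classification rules (and only the intended rule, given the priority
#' order), so the classifier must recover the planted labels exactly.
#'
#' @param category_counts Named integer vector over the categories of
#'   [default_category_rules()] (any subset; `other` allowed).
#' @param unassigned_counts Named integer vector: dataset id -> number of
#'   unassigned genes to emit.
#' @param max_genes_per_cell Gene count per present cell is drawn uniformly
#'   from `1:max_genes_per_cell`.
#' @param datasets Dataset panel (default [default_datasets()]).
#' @param clades Clade configuration (default [default_clade_config()]).
#' @param seed Integer seed.
#' @return A list of class `ortho_sim_params`.
#' @export
ortho_sim_params <- function(category_counts = c(
                               apinae = 300L, corbiculates = 60L,
                               social_corbiculates = 40L, bumblebees = 25L,
                               bterrestris_G = 20L, stingless_bees = 20L,
                               stingless_bees_F = 15L, species_specific = 30L,
                               other = 50L
                             ),
                             unassigned_counts = c(
                               B_terrestris_trans = 60L, T_angustula_trans = 40L
                             ),
                             max_genes_per_cell = 3L,
                             datasets = default_datasets(),
                             clades = default_clade_config(),
                             seed = 1L) {
  if (any(category_counts < 0)) param_error("category counts must be >= 0")
  structure(
    list(
      category_counts = category_counts,
      unassigned_counts = unassigned_counts,
      max_genes_per_cell = as.integer(max_genes_per_cell),
      datasets = datasets, clades = clades, seed = check_seed(seed)
    ),
    class = "ortho_sim_params"
  )
}

# one presence pattern (named logical) satisfying the requested category
category_pattern <- function(category, datasets, clades) {
  pres <- setNames(rep(FALSE, length(datasets)), datasets)
  corb <- setdiff(names(clades), "outgroup")
  social <- c("bumblebees", "honeybees", "stingless_bees")
  switch(category,
    apinae = { pres[] <- TRUE },
    corbiculates = {
      for (cl in corb) {
        members <- clades[[cl]]
        on <- members[runif(length(members)) < 0.7]
        if (length(on) == 0L) on <- sample(members, 1L)
        pres[on] <- TRUE
      }
    },
    social_corbiculates = {
      for (cl in social) {
        members <- clades[[cl]]
        on <- members[runif(length(members)) < 0.7]
        if (length(on) == 0L) on <- sample(members, 1L)
        pres[on] <- TRUE
      }
    },
    bumblebees = {
      pres["B_impatiens"] <- TRUE
      bt <- c("B_terrestris_prot", "B_terrestris_trans")
      on <- bt[runif(2) < 0.7]
      if (length(on) == 0L) on <- sample(bt, 1L)
      pres[on] <- TRUE
    },
    stingless_bees_F = {
      pres[c("F_varia", "M_quadrifasciata", "T_angustula_trans")] <- TRUE
    },
    stingless_bees = {
      pres[c("M_quadrifasciata", "T_angustula_trans")] <- TRUE
    },
    bterrestris_G = {
      pres[c("B_terrestris_prot", "B_terrestris_trans")] <- TRUE
    },
    species_specific = {
      pres[sample(c("B_terrestris_trans", "T_angustula_trans"), 1L)] <- TRUE
    },
    other = {
      pres[sample(c("A_mellifera", "E_dilemma", "H_laboriosa"), 1L)] <- TRUE
    },
    param_error(paste0("no pattern constructor for category '", category, "'"))
  )
  pres
}

#' Simulate an orthogroup matrix with planted category labels
#'
#' @param params An [ortho_sim_params()] object.
#' @param rules Category rules used to verify the planted patterns
#'   (default [default_category_rules()]).
#' @return A list with `matrix` (an [orthogroup_matrix()]), `truth`
#'   (tibble `orthogroup`/`category`) and `params`.
#' @export
simulate_orthogroup_matrix <- function(params = ortho_sim_params(),
                                       rules = default_category_rules()) {
  stopifnot(inherits(params, "ortho_sim_params"))
  set.seed(params$seed)
  p <- params
  cats <- rep(names(p$category_counts), times = p$category_counts)
  n_og <- length(cats)
  og_ids <- sprintf("OG%07d", seq_len(n_og))
  gene_rows <- vector("list", n_og)
  truth <- tibble(orthogroup = og_ids, category = cats)
  for (i in seq_len(n_og)) {
    pres <- category_pattern(cats[[i]], p$datasets, p$clades)
    got <- classify_orthogroup(pres, rules)
    if (!identical(got, cats[[i]])) {
      param_error(paste0(
        "rule set cannot realise category '", cats[[i]],
        "' (pattern classified as '", got, "')"
      ))
    }
    on <- names(pres)[pres]
    n_per <- sample.int(p$max_genes_per_cell, length(on), replace = TRUE)
    gene_rows[[i]] <- tibble(
      orthogroup = og_ids[[i]],
      dataset = rep(on, n_per),
      gene_id = paste0(rep(on, n_per), "|", og_ids[[i]], "|",
        unlist(lapply(n_per, seq_len)))
    )
  }
  unassigned <- list()
  for (d in names(p$unassigned_counts)) {
    unassigned[[d]] <- sprintf("%s|unassigned|%04d", d,
      seq_len(p$unassigned_counts[[d]]))
  }
  mat <- orthogroup_matrix(bind_rows(gene_rows), p$datasets, unassigned)
  list(matrix = mat, truth = truth, params = params)
}
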