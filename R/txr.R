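#' Default dataset panel and clade configuration
#'
#' The orthology panel spans 11 datasets: nine NCBI proteomes (two honeybees,
#' two bumblebees, two orchid bees, two stingless bees, one outgroup) plus
#' the two transcriptome-derived datasets of the focal species
#' (*B. terrestris* and *T. angustula*). Clades partition the datasets.
#'
#' @return `default_datasets()`: character vector of the 11 dataset ids.
#'   `default_clade_config()`: named list of dataset-id sets (the clades).
#'   `default_species_groups()`: named list grouping datasets by species
#'   (used by the "present in all species" rule).
#' @export
default_datasets <- function() {
  c(
    "A_cerana", "A_mellifera", "B_impatiens", "B_terrestris_prot",
    "B_terrestris_trans", "E_dilemma", "E_mexicana", "F_varia",
    "M_quadrifasciata", "T_angustula_trans", "H_laboriosa"
  )
}

#' @rdname default_datasets
#' @export
default_clade_config <- function() {
  list(
    outgroup = "H_laboriosa",
    orchid_bees = c("E_dilemma", "E_mexicana"),
    bumblebees = c("B_impatiens", "B_terrestris_prot", "B_terrestris_trans"),
    honeybees = c("A_cerana", "A_mellifera"),
    stingless_bees = c("F_varia", "M_quadrifasciata", "T_angustula_trans")
  )
}

#' @rdname default_datasets
#' @export
default_species_groups <- function() {
  list(
    A_cerana = "A_cerana", A_mellifera = "A_mellifera",
    B_impatiens = "B_impatiens",
    B_terrestris = c("B_terrestris_prot", "B_terrestris_trans"),
    E_dilemma = "E_dilemma", E_mexicana = "E_mexicana",
    F_varia = "F_varia", M_quadrifasciata = "M_quadrifasciata",
    T_angustula = "T_angustula_trans", H_laboriosa = "H_laboriosa"
  )
}

#' Taxonomic-conservation category rules
#'
#' A rule is a named list with fields `name` (category), `require_all`
#' (datasets that must be present), `require_any` (list of dataset groups,
#' each needing at least one present member) and `free` (datasets whose
#' state is unconstrained). Any dataset not mentioned by a rule must be
#' absent. Rules are evaluated in order and the first match wins; a
#' catch-all `other` rule is appended automatically if missing, so
#' classification is total.
#'
#' The shipped default encodes three conserved classes (`apinae`: at least
#' one dataset per species; `corbiculates`: at least one member of each
#' corbiculate clade, outgroup absent; `social_corbiculates`: honeybees,
#' bumblebees and stingless bees only) and the restricted classes
#' (`bumblebees`, `bterrestris_G`, `stingless_bees_F`, `stingless_bees`,
#' `species_specific`), most-conserved first.
#'
#' @param clades Clade configuration, see [default_clade_config()].
#' @param species_groups Species grouping, see [default_species_groups()].
#' @return A list of rules (class `category_rules`).
#' @export
default_category_rules <- function(clades = default_clade_config(),
                                   species_groups = default_species_groups()) {
  corb <- setdiff(names(clades), "outgroup")
  social <- c("bumblebees", "honeybees", "stingless_bees")
  rules <- list(
    list(name = "apinae", require_any = unname(species_groups)),
    list(
      name = "corbiculates",
      require_any = unname(clades[corb]),
      free = unlist(clades[corb], use.names = FALSE)
    ),
    list(
      name = "social_corbiculates",
      require_any = unname(clades[social]),
      free = unlist(clades[social], use.names = FALSE)
    ),
    list(
      name = "bumblebees",
      require_all = "B_impatiens",
      require_any = list(c("B_terrestris_prot", "B_terrestris_trans")),
      free = c("B_terrestris_prot", "B_terrestris_trans")
    ),
    list(
      name = "stingless_bees_F",
      require_all = c("F_varia", "M_quadrifasciata", "T_angustula_trans")
    ),
    list(
      name = "stingless_bees",
      require_all = c("M_quadrifasciata", "T_angustula_trans"),
      free = "F_varia"
    ),
    list(
      name = "bterrestris_G",
      require_all = c("B_terrestris_prot", "B_terrestris_trans")
    ),
    list(name = "species_specific", require_all = "B_terrestris_trans"),
    list(name = "species_specific", require_all = "T_angustula_trans")
  )
  new_category_rules(rules)
}

new_category_rules <- function(rules) {
  rules <- lapply(rules, function(r) {
    list(
      name = r$name,
      require_all = as.character(r$require_all %||% character()),
      require_any = lapply(r$require_any %||% list(), as.character),
      free = as.character(r$free %||% character())
    )
  })
  if (!any(vapply(rules, `[[`, character(1), "name") == "other")) {
    rules <- c(rules, list(list(
      name = "other", require_all = character(),
      require_any = list(), free = "*"
    )))
  }
  structure(rules, class = "category_rules")
}

#' Read category rules or a clade configuration from YAML
#'
#' Lets the contested category boundaries be edited without code changes.
#' The YAML schema mirrors [default_category_rules()]: a list of rules with
#' `name`, optional `require_all`, `require_any` (list of lists) and `free`
#' fields; clade files are a simple name -> dataset-id-list mapping.
#'
#' @param path Path to a YAML file.
#' @return `read_category_rules()`: a `category_rules` list;
#'   `read_clade_config()`: a named list of dataset ids.
#' @export
read_category_rules <- function(path) {
  new_category_rules(yaml::read_yaml(path))
}

#' @rdname read_category_rules
#' @export
read_clade_config <- function(path) {
  lapply(yaml::read_yaml(path), as.character)
}

#' Classify orthogroups into taxonomic-conservation categories
#'
#' Applies the category rules to each orthogroup's presence pattern over
#' the dataset panel. Classification is deterministic, total (the catch-all
#' guarantees a match) and independent of row order.
#'
#' @param x An [orthogroup_matrix()], or a named logical vector (one
#'   presence flag per dataset id) for a single pattern.
#' @param rules A `category_rules` list; defaults to
#'   [default_category_rules()].
#' @return For a matrix: a tibble with columns `orthogroup` and `category`.
#'   For a single pattern: the category name.
#' @export
classify_orthogroup <- function(x, rules = default_category_rules()) {
  if (inherits(x, "orthogroup_matrix")) {
    presence <- x$counts > 0L
    check_rule_datasets(rules, colnames(presence))
    cats <- apply_rules(presence, rules)
    return(tibble(orthogroup = x$orthogroups, category = cats))
  }
  if (!is.logical(x) || is.null(names(x))) {
    param_error("single patterns must be named logical vectors")
  }
  check_rule_datasets(rules, names(x))
  apply_rules(matrix(x, nrow = 1L, dimnames = list(NULL, names(x))), rules)[[1L]]
}

check_rule_datasets <- function(rules, datasets) {
  mentioned <- unique(unlist(lapply(rules, function(r) {
    c(r$require_all, unlist(r$require_any), setdiff(r$free, "*"))
  }), use.names = FALSE))
  unknown <- setdiff(mentioned, datasets)
  if (length(unknown) > 0L) {
    validation_error(paste0(
      "rule references unknown dataset id(s): ", paste(unknown, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

apply_rules <- function(presence, rules) {
  datasets <- colnames(presence)
  out <- rep(NA_character_, nrow(presence))
  todo <- rep(TRUE, nrow(presence))
  for (r in rules) {
    if (!any(todo)) break
    allowed <- if ("*" %in% r$free) datasets else {
      unique(c(r$require_all, unlist(r$require_any), r$free))
    }
    forbidden <- setdiff(datasets, allowed)
    ok <- todo
    for (d in r$require_all) ok <- ok & presence[, d]
    for (grp in r$require_any) {
      ok <- ok & (rowSums(presence[, grp, drop = FALSE]) > 0L)
    }
    if (length(forbidden) > 0L) {
      ok <- ok & (rowSums(presence[, forbidden, drop = FALSE]) == 0L)
    }
    out[ok] <- r$name
    todo <- todo & !ok
  }
  out
}

#' Drop focal genes unassigned to any orthogroup
#'
#' Genes of the focal species that orthology inference left unassigned have
#' no support from related sequences and are treated as probable assembly
#' or annotation errors: only genes assigned to orthogroups are carried
#' into the taxonomic-restriction analysis. The audit records counts and
#' percentages of both fractions.
#'
#' @param x An [orthogroup_matrix()].
#' @param focal_genes Character vector of focal gene ids (one dataset).
#' @param dataset Dataset id the focal genes belong to.
#' @return A list with `kept`, `excluded` (character vectors) and `audit`
#'   (one-row tibble: `n_focal`, `n_assigned`, `n_unassigned`,
#'   `pct_assigned`, `pct_unassigned`).
#' @export
exclude_unassigned <- function(x, focal_genes, dataset) {
  stopifnot(inherits(x, "orthogroup_matrix"))
  if (!dataset %in% x$datasets) {
    validation_error(paste0("unknown dataset id: ", dataset))
  }
  focal_genes <- unique(focal_genes)
  excluded <- intersect(focal_genes, x$unassigned[[dataset]])
  kept <- setdiff(focal_genes, excluded)
  if (length(kept) == 0L && length(focal_genes) > 0L) {
    warn("all focal genes are unassigned; nothing kept")
  }
  n <- length(focal_genes)
  audit <- tibble(
    dataset = dataset,
    n_focal = n,
    n_assigned = length(kept),
    n_unassigned = length(excluded),
    pct_assigned = if (n > 0) 100 * length(kept) / n else NA_real_,
    pct_unassigned = if (n > 0) 100 * length(excluded) / n else NA_real_
  )
  list(kept = kept, excluded = excluded, audit = audit)
}

#' Category proportions for transcriptome and focal orthogroups
#'
#' Summarises the taxonomic-conservation classification as the two rings of
#' the proportion plot: the whole-transcriptome ring (all orthogroups) and
#' the focal ring (orthogroups containing differentially expressed genes).
#' Each ring's proportions sum to 1.
#'
#' @param x An [orthogroup_matrix()].
#' @param assignments Tibble from [classify_orthogroup()] covering all
#'   orthogroups of `x`.
#' @param focal_orthogroups Character vector of focal orthogroup ids; must
#'   all exist in `x`.
#' @return A tibble of class `category_report` with columns `category`,
#'   `n_transcriptome`, `prop_transcriptome`, `n_focal`, `prop_focal`.
#' @export
category_proportions <- function(x, assignments, focal_orthogroups) {
  stopifnot(inherits(x, "orthogroup_matrix"))
  if (!all(x$orthogroups %in% assignments$orthogroup)) {
    validation_error("assignments must cover every orthogroup")
  }
  missing_og <- setdiff(focal_orthogroups, x$orthogroups)
  if (length(missing_og) > 0L) {
    validation_error(paste0(
      "focal orthogroup(s) not in matrix: ", paste(head(missing_og, 3L), collapse = ", ")
    ))
  }
  cats <- unique(assignments$category)
  cat_of <- setNames(assignments$category, assignments$orthogroup)
  t_tab <- table(factor(cat_of[x$orthogroups], levels = cats))
  f_tab <- table(factor(cat_of[unique(focal_orthogroups)], levels = cats))
  out <- tibble(
    category = cats,
    n_transcriptome = as.integer(t_tab),
    prop_transcriptome = as.numeric(t_tab) / sum(t_tab),
    n_focal = as.integer(f_tab),
    prop_focal = if (sum(f_tab) > 0) as.numeric(f_tab) / sum(f_tab) else NA_real_
  )
  class(out) <- c("category_report", class(out))
  out
}
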