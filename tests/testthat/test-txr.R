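presence <- function(on) {
  p <- setNames(rep(FALSE, 11L), default_datasets())
  p[on] <- TRUE
  p
}

test_that("canonical presence patterns map to their categories", {
  expect_equal(classify_orthogroup(presence(default_datasets())), "apinae")
  expect_equal(
    classify_orthogroup(presence(c(
      "A_cerana", "B_impatiens", "F_varia", "T_angustula_trans"
    ))),
    "social_corbiculates"
  )
  expect_equal(
    classify_orthogroup(presence(c(
      "A_mellifera", "B_terrestris_prot", "E_dilemma", "M_quadrifasciata"
    ))),
    "corbiculates"
  )
  expect_equal(classify_orthogroup(presence("T_angustula_trans")), "species_specific")
  expect_equal(classify_orthogroup(presence("B_terrestris_trans")), "species_specific")
  expect_equal(
    classify_orthogroup(presence(c("B_impatiens", "B_terrestris_trans"))),
    "bumblebees"
  )
  expect_equal(
    classify_orthogroup(presence(c("B_terrestris_prot", "B_terrestris_trans"))),
    "bterrestris_G"
  )
  expect_equal(
    classify_orthogroup(presence(c("F_varia", "M_quadrifasciata", "T_angustula_trans"))),
    "stingless_bees_F"
  )
  expect_equal(
    classify_orthogroup(presence(c("M_quadrifasciata", "T_angustula_trans"))),
    "stingless_bees"
  )
  expect_equal(classify_orthogroup(presence("H_laboriosa")), "other")
})

test_that("classification is total over every possible presence pattern", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 11L))
  colnames(grid) <- default_datasets()
  m <- as.matrix(grid)
  cats <- beecaste:::apply_rules(m, default_category_rules())
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c(
    "apinae", "corbiculates", "social_corbiculates", "bumblebees",
    "bterrestris_G", "stingless_bees", "stingless_bees_F",
    "species_specific", "other"
  )))
})

test_that("assignments are independent of row order", {
  sim <- simulate_orthogroup_matrix(ortho_sim_params(seed = 5))
  a1 <- classify_orthogroup(sim$matrix)
  perm <- sample(nrow(sim$matrix$counts))
  m2 <- sim$matrix
  m2$counts <- m2$counts[perm, ]
  m2$orthogroups <- m2$orthogroups[perm]
  a2 <- classify_orthogroup(m2)
  joined <- dplyr::inner_join(a1, a2, by = "orthogroup")
  expect_equal(joined$category.x, joined$category.y)
})

test_that("unknown dataset ids are rejected", {
  p <- setNames(rep(TRUE, 2L), c("A_cerana", "Mystery_bee"))
  expect_error(classify_orthogroup(p), class = "beecaste_validation_error")
})

test_that("rules round-trip through YAML files", {
  rules <- default_category_rules()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(rules), function(r) {
    r$require_any <- lapply(r$require_any, as.list)
    r
  }), f)
  back <- read_category_rules(f)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 11L))[sample(2048, 200), ]
  colnames(grid) <- default_datasets()
  m <- as.matrix(grid)
  expect_equal(
    beecaste:::apply_rules(m, back),
    beecaste:::apply_rules(m, rules)
  )

  fc <- tempfile(fileext = ".yaml")
  yaml::write_yaml(default_clade_config(), fc)
  expect_equal(read_clade_config(fc), default_clade_config())
})

test_that("unassigned focal genes are excluded with an audit trail", {
  genes <- tibble::tibble(
    orthogroup = paste0("OG", 1:5),
    dataset = "B_terrestris_trans",
    gene_id = paste0("g", 1:5)
  )
  m <- orthogroup_matrix(genes, default_datasets(),
    list(B_terrestris_trans = c("u1", "u2")))
  res <- exclude_unassigned(m, c("g1", "g2", "u1"), "B_terrestris_trans")
  expect_setequal(res$kept, c("g1", "g2"))
  expect_equal(res$excluded, "u1")
  expect_equal(res$audit$pct_assigned, 100 * 2 / 3)

  res2 <- exclude_unassigned(m, c("g3", "g4"), "B_terrestris_trans")
  expect_setequal(res2$kept, c("g3", "g4"))
  expect_equal(res2$excluded, character())

  expect_warning(
    res3 <- exclude_unassigned(m, c("u1", "u2"), "B_terrestris_trans"),
    "unassigned"
  )
  expect_equal(res3$kept, character())
})

test_that("category proportions form two closed rings", {
  sim <- simulate_orthogroup_matrix(ortho_sim_params(
    category_counts = c(apinae = 50L, corbiculates = 30L, species_specific = 20L),
    seed = 9
  ))
  asn <- classify_orthogroup(sim$matrix)
  rep_all <- category_proportions(sim$matrix, asn, sim$matrix$orthogroups)
  expect_equal(sum(rep_all$prop_transcriptome), 1, tolerance = 1e-12)
  expect_equal(sum(rep_all$prop_focal), 1, tolerance = 1e-12)
  expect_equal(rep_all$prop_transcriptome, c(0.5, 0.3, 0.2))
  expect_equal(rep_all$prop_focal, rep_all$prop_transcriptome)

  # singleton focal set concentrates in its own class
  one <- sim$matrix$orthogroups[[1L]]
  rep_one <- category_proportions(sim$matrix, asn, one)
  cls <- asn$category[asn$orthogroup == one]
  expect_equal(rep_one$prop_focal[rep_one$category == cls], 1)

  expect_error(category_proportions(sim$matrix, asn, "OG_nope"),
    class = "beecaste_validation_error")
})

test_that("planted restricted-class enrichment is visible in the focal ring", {
  sim <- simulate_orthogroup_matrix(ortho_sim_params(seed = 13))
  asn <- classify_orthogroup(sim$matrix)
  restricted <- c("bumblebees", "bterrestris_G", "stingless_bees",
    "stingless_bees_F", "species_specific")
  set.seed(31)
  w <- ifelse(sim$truth$category %in% restricted, 3, 1)
  focal <- sample(sim$matrix$orthogroups, 120L, prob = w)
  rep <- category_proportions(sim$matrix, asn, focal)
  r_focal <- sum(rep$prop_focal[rep$category %in% restricted])
  r_trans <- sum(rep$prop_transcriptome[rep$category %in% restricted])
  expect_gt(r_focal, r_trans)
})
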