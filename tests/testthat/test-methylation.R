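test_that("coverage filter is a strict threshold", {
  x <- read_cgmap(write_lines_tmp(c(
    make_cgmap_line(pos = 1, cov = 5),
    make_cgmap_line(pos = 2, cov = 10),
    make_cgmap_line(pos = 3, cov = 50)
  )))
  expect_equal(nrow(suppressMessages(filter_coverage(x, 10))), 2L)
  expect_equal(nrow(filter_coverage(x, 1)), 3L)
  expect_equal(nrow(filter_coverage(x[0, ], 10)), 0L)
  expect_error(filter_coverage(x, 0), class = "beecaste_param_error")
})

test_that("both-strand context census matches hand enumeration", {
  # "ACGT": plus-strand C2 -> CG; G3 is a minus-strand C, preceding base C
  # complements to G -> CG. Two CG sites.
  cen <- context_census(c(s1 = "ACGT"))
  expect_equal(attr(cen, "n_sites"), 2L)
  expect_equal(cen$proportion[cen$dinucleotide == "CG"], 1)

  # "ACAT": one plus-strand CA site, no G anywhere
  cen2 <- context_census(c(s1 = "ACAT"))
  expect_equal(attr(cen2, "n_sites"), 1L)
  cls2 <- census_by_class(cen2)
  expect_equal(cls2$proportion[cls2$class == "CW"], 1)

  # no C sites at all -> proportions undefined
  cen3 <- context_census(c(s1 = "AAAA"))
  expect_true(all(is.na(cen3$proportion)))

  # terminal and N-adjacent sites fall in the undefined bucket
  cen4 <- context_census(c(s1 = "CNC"))
  expect_equal(attr(cen4, "n_sites"), 0L)
  expect_equal(attr(cen4, "n_undefined"), 2L)
})

test_that("methylation calls follow the threshold and binomial rules", {
  x <- read_cgmap(write_lines_tmp(c(
    make_cgmap_line(pos = 1, mc = 0, cov = 10),
    make_cgmap_line(pos = 2, mc = 8, cov = 10, level = 0.8),
    make_cgmap_line(pos = 3, mc = 1, cov = 200, level = 0.01)
  )))
  thr <- call_methylated(x, "threshold")
  expect_equal(thr$methylated, c(FALSE, TRUE, TRUE))
  bin <- call_methylated(x, "binomial", error_rate = 0.005, alpha = 0.01)
  # P(X >= 1 | n = 200, eps = 0.005) = 1 - 0.995^200 ~ 0.63: not called
  expect_equal(1 - 0.995^200, 0.6330, tolerance = 1e-4)
  expect_equal(bin$methylated, c(FALSE, TRUE, FALSE))
  # P(X >= 8 | n = 10, eps = 0.005) is astronomically small: called
  expect_lt(sum(choose(10, 8:10) * 0.005^(8:10) * 0.995^(10 - (8:10))), 1e-10)
})

test_that("context composition of methylated sites closes to 100%", {
  x <- read_cgmap(write_lines_tmp(c(
    make_cgmap_line(pos = 1, dinuc = "CG", mc = 5, cov = 10, level = 0.5),
    make_cgmap_line(pos = 2, dinuc = "CG", mc = 5, cov = 10, level = 0.5),
    make_cgmap_line(pos = 3, dinuc = "CA", ctx3 = "CHH", mc = 5, cov = 10, level = 0.5),
    make_cgmap_line(pos = 4, dinuc = "CT", ctx3 = "CHH", mc = 5, cov = 10, level = 0.5),
    make_cgmap_line(pos = 5, dinuc = "CC", ctx3 = "CHH", mc = 0, cov = 10)
  )))
  comp <- methylation_context_composition(call_methylated(x))
  expect_equal(comp$percent[comp$class == "CG"], 50)
  expect_equal(comp$percent[comp$class == "CW"], 50)
  expect_equal(comp$percent[comp$class == "CC"], 0)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
  by_d <- attr(comp, "by_dinucleotide")
  expect_equal(by_d$percent[by_d$dinucleotide == "CA"], 25)

  x0 <- call_methylated(x[5, ])
  expect_warning(comp0 <- methylation_context_composition(x0), "no methylated")
  expect_true(all(is.na(comp0$percent)))
})

test_that("per-transcript means separate unweighted and weighted views", {
  x <- read_cgmap(write_lines_tmp(c(
    make_cgmap_line(pos = 1, mc = 8, cov = 10, level = 0.8),
    make_cgmap_line(pos = 2, mc = 0, cov = 90, level = 0.0)
  )))
  t1 <- transcript_mc(x)
  expect_equal(t1$mean_mc, 40)       # (0.8 + 0) / 2
  expect_equal(t1$weighted_mc, 8)    # 8 / 100
  # arithmetic on site levels
  x2 <- read_cgmap(write_lines_tmp(c(
    make_cgmap_line(pos = 1, mc = 0, cov = 10, level = 0),
    make_cgmap_line(pos = 2, mc = 5, cov = 10, level = 0.5),
    make_cgmap_line(pos = 3, mc = 10, cov = 10, level = 1)
  )))
  expect_equal(transcript_mc(x2)$mean_mc, 50)
  # absent transcripts surface as NA rows when requested
  t3 <- transcript_mc(x, all_ids = c("st1", "st9"))
  expect_equal(t3$seq_id, c("st1", "st9"))
  expect_true(is.na(t3$mean_mc[2]))
})

test_that("z-test matches the closed-form normal computation", {
  # global population mean 1, sd 1
  glob <- c(0, 1, 2)
  res <- subset_mean_ztest(c(2, 2, 2), glob)
  expect_equal(res$z, sqrt(3), tolerance = 1e-12)
  expect_equal(res$p_value, pnorm(sqrt(3), lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0416, tolerance = 1e-3)
  expect_equal(res$percent_diff, 100)
  expect_true(res$conf_low <= res$subset_mean && res$subset_mean <= res$conf_high)

  # subset equal to global mean: z = 0, percent difference 0
  res0 <- subset_mean_ztest(c(1, 1), glob)
  expect_equal(res0$z, 0)
  expect_equal(res0$percent_diff, 0)

  expect_error(subset_mean_ztest(c(1, 1), c(2, 2, 2)),
    class = "beecaste_validation_error")
  expect_error(subset_mean_ztest(1, glob), class = "beecaste_param_error")

  td <- tidy(res)
  expect_equal(td$z, res$z)
  expect_equal(glance(res)$global_sd, 1)
})

test_that("CG enrichment test agrees with the exact binomial tail", {
  cen <- context_census(c(s = "ACGTACATACGT"))  # some CG, some CW
  cls <- census_by_class(cen)
  p_cg <- cls$proportion[cls$class == "CG"]
  # all 10 methylated sites in CG context
  res <- cg_enrichment_test(list(n_cg = 10L, n_total = 10L), cen,
    reps = 10000, seed = 3)
  exact <- p_cg^10
  expect_lt(abs(res$p_value - exact), 4 * sqrt(exact * (1 - exact) / 10000) + 2e-4)

  # observed at the null centre: p around 0.5
  resc <- cg_enrichment_test(list(n_cg = round(2000 * p_cg), n_total = 2000L),
    cen, reps = 4000, seed = 5)
  expect_gt(resc$p_value, 0.3)
  expect_lt(resc$p_value, 0.75)

  # degenerate all-CG census: every draw is all CG
  cen_cg <- context_census(c(s = "ACGT"))
  res1 <- cg_enrichment_test(list(n_cg = 7L, n_total = 7L), cen_cg,
    reps = 500, seed = 1)
  expect_equal(res1$p_value, 1)

  expect_error(cg_enrichment_test(list(n_cg = 0L, n_total = 0L), cen,
    reps = 100), class = "beecaste_validation_error")
})

test_that("Spearman coupling matches a first-principles rank oracle", {
  tmc <- tibble::tibble(
    seq_id = c("a", "b", "c"),
    mean_mc_cg = c(1, 2, 3),
    mean_mc_cw = c(3, 1, 2)
  )
  expr <- tibble::tibble(seq_id = c("a", "b", "c"), norm_count = c(10, 20, 30))
  res <- methylation_expression_correlation(tmc, expr)
  expect_equal(res$r_s[res$class == "CG"], 1)
  expect_equal(res$r_s[res$class == "CW"], -0.5)

  # randomised cases with ties against the naive rank formula
  set.seed(14)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    mc <- round(stats::rexp(n), 1)
    ct <- round(stats::rlnorm(n, 3, 1))
    tmc2 <- tibble::tibble(seq_id = as.character(seq_len(n)),
      mean_mc_cg = mc, mean_mc_cw = rev(mc))
    ex2 <- tibble::tibble(seq_id = as.character(seq_len(n)), norm_count = ct)
    r <- methylation_expression_correlation(tmc2, ex2)
    expect_equal(r$r_s[r$class == "CG"], naive_spearman(mc, ct), tolerance = 1e-12)
  }

  expect_error(
    methylation_expression_correlation(tmc[1:2, ], expr),
    class = "beecaste_param_error"
  )
})
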