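test_that("the packaged cohort fixture reproduces every published margin", {
  co <- t790m_cohort()
  expect_equal(nrow(co), 68L)
  expect_equal(sum(co$t790m), 27L)
  mut_levels <- c("exon19_LRE_delE746_A750", "exon19_LRE_other",
                  "exon19_nonLRE", "L858R")
  expect_equal(as.vector(table(factor(co$initial_egfr_mutation,
                                      mut_levels))),
               c(31L, 3L, 3L, 31L))
  expect_equal(sum(co$bone_met), 34L)
  expect_equal(sum(co$bone_met & co$t790m), 21L)
  expect_equal(sum(!co$bone_met & co$t790m), 6L)
  delE <- co$initial_egfr_mutation == "exon19_LRE_delE746_A750"
  expect_equal(sum(co$bone_met & delE), 18L)
  expect_equal(sum(co$bone_met & delE & co$t790m), 15L)
  expect_equal(sum(co$number_sites_met == 1), 15L)
  expect_equal(sum(co$number_sites_met == 1 & !co$t790m), 14L)
  expect_equal(unname(colSums(co[, c("lung_met", "pleural_met",
                                     "brain_met", "liver_met", "bone_met",
                                     "distant_ln_met")])),
               c(59, 30, 15, 11, 34, 18))
  expect_equal(as.vector(table(co$number_sites_met)),
               c(15L, 22L, 19L, 9L, 3L))
  expect_equal(sum(co$sex == "male"), 14L)
  expect_equal(as.vector(table(factor(co$smoking,
                                      c("never", "chronic", "ex")))),
               c(58L, 2L, 8L))
  expect_equal(as.vector(table(co$number_lines_tki)), c(53L, 12L, 3L))
  expect_equal(as.vector(table(co$number_lines_chemo)),
               c(44L, 16L, 6L, 2L))
  expect_equal(as.vector(table(factor(co$first_tki,
                                      c("gefitinib", "erlotinib",
                                        "afatinib")))),
               c(54L, 7L, 7L))
  # site flags always consistent with the declared number of sites
  expect_equal(unname(rowSums(co[, c("lung_met", "pleural_met",
                                     "brain_met", "liver_met", "bone_met",
                                     "distant_ln_met")])),
               co$number_sites_met)
})

test_that("the packaged CSV loads, validates, and equals the in-code fixture", {
  path <- system.file("extdata", "t790m_cohort_synthetic.csv",
                      package = "resiflex")
  co <- load_cohort(path)
  expect_equal(nrow(co), 68L)
  ref <- t790m_cohort()
  expect_equal(co[order(names(co))], ref[order(names(ref))],
               ignore_attr = TRUE)
  # 65 evaluable patients for the mutation-by-TKI analysis
  expect_equal(sum(co$initial_egfr_mutation != "exon19_LRE_other"), 65L)
})

test_that("cohort validation reports offending rows and columns", {
  co <- t790m_cohort()
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(names(co), collapse = ","), empty)
  expect_error(load_cohort(empty), "empty")

  bad <- co
  bad$age_70[3] <- TRUE
  bad$age_65[3] <- FALSE
  expect_error(validate_cohort(bad), "row 3, column age_70")

  bad <- co
  bad$smoking[7] <- "sometimes"
  expect_error(validate_cohort(bad), "row 7, column smoking")

  bad <- co
  bad$number_sites_met[2] <- 9L
  expect_error(validate_cohort(bad), "row 2, column number_sites_met")
})

test_that("contingency tables and proportions follow the printed conventions", {
  co <- t790m_cohort()
  tab <- build_contingency(co, "bone_met")
  expect_equal(as.vector(unclass(tab)), c(21L, 6L, 13L, 28L))
  p1 <- proportion(tab, "TRUE", "TRUE")
  expect_equal(p1$percent_printed, 61.8)
  # single-patient cohort sums to one
  one <- build_contingency(co[1, ], "bone_met")
  expect_equal(sum(one), 1L)
  # an attribute with one observed level yields a 1 x 2 table
  const <- co; const$sex <- "female"
  expect_equal(dim(build_contingency(const, "sex")), c(1L, 2L))

  expect_equal(round_half_up(100 * 17 / 28, 1), 60.7)
  expect_equal(round_half_up(100 * 0 / 3, 1), 0)
  expect_equal(round_half_up(100 * 1 / 3, 1), 33.3)
  # half-up, not banker's: 0.25 -> 0.3 at one decimal
  expect_equal(round_half_up(0.25, 1), 0.3)
  zero <- matrix(c(0L, 5L, 0L, 3L), 2)
  expect_true(is.na(proportion(zero, 1, 1)$percent_printed))
})

test_that("the mutation-by-TKI grid reproduces the published outcome table", {
  grid <- mutation_tki_table(t790m_cohort())
  expect_equal(grid$tki, c("gefitinib", "erlotinib", "afatinib",
                           "overall"))
  expect_equal(grid$delE746_A750_pos, c(17L, 4L, 4L, 19L))
  expect_equal(grid$delE746_A750_n, c(28L, 9L, 6L, 31L))
  expect_equal(grid$delE746_A750_pct, c(60.7, 44.4, 66.7, 61.3))
  expect_equal(grid$nonLRE_pos, c(0L, 0L, 0L, 0L))
  expect_equal(grid$nonLRE_n, c(3L, 1L, 0L, 3L))
  expect_equal(grid$nonLRE_pct, c(0, 0, NA, 0))
  expect_equal(grid$L858R_pos, c(7L, 0L, 1L, 8L))
  expect_equal(grid$L858R_n, c(23L, 5L, 5L, 31L))
  expect_equal(grid$L858R_pct, c(30.4, 0, 20.0, 25.8))
  expect_equal(grid$overall_pos, c(24L, 4L, 5L, 27L))
  expect_equal(grid$overall_n, c(54L, 15L, 11L, 65L))
  expect_equal(grid$overall_pct, c(44.4, 26.7, 45.5, 41.5))
})

test_that("two-sided Fisher's exact follows the point-probability rule", {
  # no association
  expect_equal(fisher_exact_two_sided(matrix(5, 2, 2)), 1)
  # bone-metastasis table: p prints as 0.0004 at one significant figure
  p <- fisher_exact_two_sided(matrix(c(21, 13, 6, 28), 2, byrow = TRUE))
  expect_equal(signif(p, 1), 4e-4)
  expect_error(fisher_exact_two_sided(matrix(1, 3, 3)), "2x2")

  # equals the independent implementation on random small tables, and is
  # invariant under transposition and row/column swaps
  set.seed(404)
  for (i in 1:200) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_gte(p, 0)
    expect_lte(p, 1)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1]), p,
                 tolerance = 1e-12)
  }
})

test_that("evaluators score a perfect predictor at the top and noise near zero", {
  set.seed(55)
  n <- 400
  co <- generate_cohort(cohort_recipe(n_patients = n, seed = 2))
  co$oracle_copy <- as.character(co$t790m)
  co$coin <- sample(c("a", "b"), n, replace = TRUE)
  attrs <- c("oracle_copy", "coin", "bone_met")
  h_outcome <- -sum(prop.table(table(co$t790m)) *
                    log2(prop.table(table(co$t790m))))
  rk_ig <- rank_attributes(co, "info_gain", attributes = attrs)
  expect_equal(rk_ig$attribute[1], "oracle_copy")
  expect_equal(rk_ig$score[1], h_outcome, tolerance = 1e-12)
  rk_su <- rank_attributes(co, "symmetrical_uncertainty",
                           attributes = attrs)
  expect_equal(rk_su$attribute[1], "oracle_copy")
  expect_equal(rk_su$score[1], 1)
  # independent-by-construction attribute scores near zero
  expect_lt(info_gain(co$coin, co$t790m), 0.01)
  expect_lt(resiflex:::correlation_score(co$coin, co$t790m), 0.1)
  # constant attribute scores zero, never errors
  co$flat <- "x"
  for (ev in c("chi2", "info_gain", "symmetrical_uncertainty",
               "correlation")) {
    rk <- rank_attributes(co, ev, attributes = c("flat", "coin"))
    expect_equal(rk$score[rk$attribute == "flat"], 0)
  }
})

test_that("chi-squared of an exactly independent table is zero", {
  # margins (6, 4) x (10, 10): counts = products of margins / n
  attr_v <- rep(c("p", "q"), c(12, 8))
  out_v <- c(rep(c("yes", "no"), c(6, 6)), rep(c("yes", "no"), c(4, 4)))
  expect_equal(resiflex:::chi2_score(attr_v, out_v), 0, tolerance = 1e-12)
  expect_equal(info_gain(attr_v, out_v), 0, tolerance = 1e-12)
})

test_that("symmetrical uncertainty and info gain respect their bounds", {
  set.seed(77)
  for (i in 1:25) {
    a <- sample(letters[1:3], 60, replace = TRUE)
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    ig <- info_gain(a, y)
    su <- symmetrical_uncertainty(a, y)
    expect_gte(ig, 0)
    expect_gte(su, 0)
    expect_lte(su, 1)
  }
})

test_that("ReliefF is deterministic under a fixed seed and finds a planted signal", {
  co <- generate_cohort(cohort_recipe(n_patients = 300,
                                      effects = list(bone_met = 10),
                                      seed = 31))
  r1 <- rank_attributes(co, "relieff", seed = 7)
  r2 <- rank_attributes(co, "relieff", seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$attribute[1], "bone_met")
})

test_that("the filtered evaluator is information gain after validation", {
  co <- t790m_cohort()
  f <- rank_attributes(co, "filtered")
  g <- rank_attributes(co, "info_gain")
  expect_equal(f$score, g$score)
  expect_equal(attr(f, "evaluator"), "filtered")
})
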