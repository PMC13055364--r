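test_that("deduplication groups byte-identical proteins", {
  loci <- tibble::tibble(
    locus_id = c("b_1", "a_1", "c_1", "d_1"),
    protein = c("MKV", "MKV", "MKV", "MAV")
  )
  dd <- dedup_identical(loci)
  expect_equal(dd$n_input, 4)
  expect_equal(dd$n_unique, 2)
  expect_equal(dd$n_duplicate_groups, 1)
  expect_equal(sort(dd$unique_loci$locus_id), c("a_1", "d_1"))
  # all distinct -> no duplicate groups
  dd2 <- dedup_identical(tibble::tibble(locus_id = c("x", "y"),
                                        protein = c("MA", "MC")))
  expect_equal(dd2$n_duplicate_groups, 0)
  # idempotent
  dd3 <- dedup_identical(dd$unique_loci)
  expect_equal(dd3$n_unique, dd$n_unique)
})

test_that("dedup groups on the synthetic study match the planted paralogs", {
  sim <- small_sim()
  loci <- small_loci()
  dd <- dedup_identical(loci)
  truth_groups <- length(unique(sim$truth$protein))
  expect_equal(dd$n_unique, truth_groups)
  truth_dup <- sum(table(sim$truth$paralog_group) > 1)
  expect_equal(dd$n_duplicate_groups, truth_dup)
})

test_that("one-way ANOVA reproduces the textbook sum-of-squares case", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    grp = rep(c("a", "b", "c"), each = 3)
  )
  got <- one_way_anova(df, "value", "grp")
  # by hand: SSB = 54 (MSB 27), SSW = 6 (MSW 1) -> F = 27 on (2, 6) df
  expect_equal(got$statistic, 27)
  expect_equal(got$df, 2)
  expect_equal(got$df_residual, 6)
  expect_equal(got$p_value, pf(27, 2, 6, lower.tail = FALSE))
  # adding a constant leaves F unchanged
  df2 <- dplyr::mutate(df, value = value + 100)
  expect_equal(one_way_anova(df2, "value", "grp")$statistic, 27)
  # identical group means -> F ~ 0
  df3 <- tibble::tibble(value = c(1, 3, 1, 3, 1, 3),
                        grp = rep(c("a", "b", "c"), each = 2))
  expect_lt(one_way_anova(df3, "value", "grp")$statistic, 1e-10)
  expect_error(one_way_anova(df3[1:3, ], "value", "grp"), "at least 2")
})

test_that("Tukey HSD matches the independent reference fixture", {
  # adjusted p-values computed once with statsmodels pairwise_tukeyhsd
  # (alpha 0.05) on this exact fixture and frozen here
  df <- tibble::tibble(
    value = c(12.1, 14.3, 13.8, 11.9, 15.2,
              18.4, 17.9, 19.3, 16.8, 18.0,
              24.5, 23.1, 25.9, 24.8, 23.7),
    grp = rep(c("g1", "g2", "g3"), each = 5)
  )
  tk <- tukey_hsd(df, "value", "grp")
  expect_equal(nrow(tk), 3)
  frozen <- c("g2-g1" = 1.04186469e-04, "g3-g1" = 1.10947174e-08,
              "g3-g2" = 4.63817972e-06)
  expect_lt(max(abs(tk$adj_p_value[match(names(frozen), tk$pair)] -
                      unname(frozen))), 1e-6)
  # two identical groups -> p ~ 1 for that pair
  df2 <- tibble::tibble(value = c(1, 2, 3, 1, 2, 3, 50, 51, 52),
                        grp = rep(c("a", "b", "c"), each = 3))
  tk2 <- tukey_hsd(df2, "value", "grp")
  expect_gt(tk2$adj_p_value[tk2$pair == "b-a"], 0.99)
  expect_lt(tk2$adj_p_value[tk2$pair == "c-a"], 0.001)
})

test_that("F is preserved under group-label permutation of a balanced design", {
  set.seed(8)
  df <- tibble::tibble(value = rnorm(30), grp = rep(c("a", "b", "c"), 10))
  f0 <- one_way_anova(df, "value", "grp")$statistic
  # permuting values within the whole sample changes F, but the collection
  # of F values over permutations is label-symmetric; spot-check that a
  # full relabelling of group ids (a bijection) leaves F unchanged
  df2 <- dplyr::mutate(df, grp = c(a = "z", b = "x", c = "y")[grp])
  expect_equal(one_way_anova(df2, "value", "grp")$statistic, f0)
})

test_that("clade statistics wire identity and coverage through ANOVA", {
  set.seed(13)
  loci <- tibble::tibble(
    locus_id = sprintf("l%02d", 1:30),
    clade = rep(c("clade_1", "clade_2", "clade_3"), each = 10),
    confirm_identity = c(rnorm(10, 94, 5), rnorm(10, 46, 4), rnorm(10, 70, 9)),
    confirm_coverage = c(rnorm(10, 97, 2), rnorm(10, 97, 2), rnorm(10, 89, 6))
  )
  cs <- clade_stats(loci)
  expect_equal(nrow(cs$summary), 6)
  gl <- glance(cs)
  expect_lt(gl$p_value[gl$measure == "identity"], 0.001)
  td <- tidy(cs)
  expect_equal(nrow(td), 6)  # 3 pairs x 2 measures
  expect_true(all(td$adj_p_value >= 0 & td$adj_p_value <= 1))
  expect_s3_class(autoplot(cs), "ggplot")
})

test_that("taxonomy flow counts are conserved across levels", {
  loci <- tibble::tibble(species = c("s1", "s1", "s2", "s3"))
  taxonomy <- tibble::tibble(
    species = c("s1", "s2", "s3"),
    genus = c("g1", "g1", "g2"),
    family = c("f1", "f1", "f2"),
    order = c("o1", "o1", "o2")
  )
  tt <- taxonomy_table(loci, taxonomy)
  expect_equal(sum(tt$n), nrow(loci))
  lc <- attr(tt, "level_counts")
  expect_equal(unname(lc["species"]), 3)
  expect_equal(unname(lc["genera"]), 2)
  expect_error(taxonomy_table(tibble::tibble(species = "zz"), taxonomy),
               "unmapped")
})
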