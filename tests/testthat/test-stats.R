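# Printed reference tuples from the breast-cancer cohort (C = 220 cases,
# N = 334 controls): matched (controls, cases) -> OR at 3 d.p.
reference_or <- list(
  list(controls = 4, cases = 11, or = 4.342),     # two-SNP high-risk
  list(controls = 137, cases = 69, or = 0.657),   # two-SNP low-risk
  list(controls = 20, cases = 29, or = 2.384),    # three-SNP high-risk
  list(controls = 9, cases = 17, or = 3.024),     # four-SNP high-risk
  list(controls = 1, cases = 4, or = 6.167),      # seven-SNP high-risk
  list(controls = 24, cases = 5, or = 0.300),     # five-SNP low-risk
  list(controls = 9, cases = 1, or = 0.165),      # seven-SNP low-risk
  list(controls = 97, cases = 66, or = 1.047)     # pair-grid reference cell
)

test_that("pattern-vs-rest tables reproduce the printed odds ratios", {
  for (ref in reference_or) {
    tab <- pattern_vs_rest_table(
      list(controls_matched = ref$controls, cases_matched = ref$cases),
      n_cases = 220, n_controls = 334)
    expect_equal(tab$tp + tab$fn, 220)
    expect_equal(tab$fp + tab$tn, 334)
    expect_equal(round_half_away(odds_ratio(tab), 3), ref$or)
  }
})

test_that("pattern_vs_rest_table handles edge counts and rejects excess", {
  tab <- pattern_vs_rest_table(list(controls_matched = 0, cases_matched = 0),
                               10, 20)
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 10, tn = 20))
  expect_error(
    pattern_vs_rest_table(list(controls_matched = 21, cases_matched = 0),
                          10, 20), "exceed")
})

test_that("classification metrics match the printed report rows", {
  m1 <- classification_metrics(contingency_table(11, 4, 209, 330))
  expect_equal(round_half_away(m1$cc, 3), 0.616)
  expect_equal(round_half_away(m1$sn, 3), 0.050)
  expect_equal(round_half_away(m1$sp, 3), 0.988)
  expect_equal(round_half_away(m1$average, 3), 0.551)

  m2 <- classification_metrics(contingency_table(29, 20, 191, 314))
  expect_equal(round_half_away(m2$cc, 3), 0.619)
  expect_equal(round_half_away(m2$sn, 3), 0.132)
  expect_equal(round_half_away(m2$sp, 3), 0.940)

  perfect <- classification_metrics(contingency_table(220, 0, 0, 334))
  expect_equal(perfect$cc, 1); expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1); expect_equal(perfect$average, 1)

  degenerate <- classification_metrics(contingency_table(0, 0, 0, 0))
  expect_true(is.na(degenerate$cc))
  expect_true(is.na(degenerate$average))
})

test_that("single-SNP genotype-vs-reference table reproduces the cohort OR", {
  # Reconstruct a cohort where SNP 1 has 174 controls / 128 cases with the
  # reference genotype and 141 / 76 with the heterozygote.
  geno_case <- c(rep(1L, 128), rep(2L, 76), rep(3L, 16))
  geno_ctrl <- c(rep(1L, 174), rep(2L, 141), rep(3L, 19))
  d <- genotype_dataset(matrix(c(geno_case, geno_ctrl), ncol = 1),
                        c(rep("case", 220), rep("control", 334)))
  tab <- genotype_vs_reference_table(d, 1, genotype_code = 2)
  expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
               c(tp = 76, fp = 141, fn = 128, tn = 174))
  expect_equal(round_half_away(odds_ratio(tab), 3), 0.733)
  # re-verified against genotype_counts
  gc <- genotype_counts(d, 1)
  expect_equal(gc$cases[gc$code == 2], tab$tp)
  expect_equal(gc$controls[gc$code == 2], tab$fp)
  expect_error(genotype_vs_reference_table(d, 1, 1, 1), "must differ")
})

test_that("odds ratio inversion and zero-cell semantics", {
  tab <- contingency_table(69, 137, 151, 197)
  swapped <- contingency_table(137, 69, 197, 151)  # case/control roles swapped
  expect_equal(odds_ratio(tab) * odds_ratio(swapped), 1)

  zero <- contingency_table(4, 0, 216, 334)
  expect_true(is.na(odds_ratio(zero)))
  expect_equal(odds_ratio(zero, zero_correction = TRUE),
               (4.5 * 334.5) / (216.5 * 0.5))
})

test_that("Woolf CI matches its closed form and behaves monotonically", {
  tab <- contingency_table(11, 4, 209, 330)
  ci <- odds_ratio_ci(tab, method = "woolf")
  or <- (11 * 330) / (209 * 4)
  se <- sqrt(1 / 11 + 1 / 4 + 1 / 209 + 1 / 330)
  expect_equal(ci$lower, exp(log(or) - qnorm(0.975) * se))
  expect_equal(ci$upper, exp(log(or) + qnorm(0.975) * se))
  expect_lt(ci$lower, or); expect_gt(ci$upper, or)
  wider <- odds_ratio_ci(tab, level = 0.99, method = "woolf")
  expect_lt(wider$lower, ci$lower)
  expect_gt(wider$upper, ci$upper)

  sym <- contingency_table(10, 10, 30, 30)
  ci_sym <- odds_ratio_ci(sym, method = "woolf")
  expect_lt(ci_sym$lower, 1); expect_gt(ci_sym$upper, 1)

  zero <- contingency_table(4, 0, 216, 334)
  expect_true(is.na(odds_ratio_ci(zero, method = "woolf")$lower))
})

test_that("exact CI brackets the printed intervals within tolerance", {
  ci <- odds_ratio_ci(contingency_table(69, 137, 151, 197), method = "exact")
  expect_equal(ci$lower, 0.45, tolerance = 0.02 / 0.45)
  expect_gt(ci$upper, 0.9); expect_lt(ci$upper, 1.01)
})

test_that("association p-values: Fisher matches the printed value, chi2 its identity", {
  tab <- contingency_table(69, 137, 151, 197)
  expect_equal(association_p_value(tab, "fisher"), 0.025, tolerance = 0.005 / 0.025)
  # Pearson statistic via the n(ad-bc)^2 / margins identity
  a <- 69; b <- 137; c <- 151; d <- 197; n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(stat, 5.29, tolerance = 0.01)
  expect_equal(association_p_value(tab, "chi2"),
               pchisq(stat, 1, lower.tail = FALSE))
  expect_lt(association_p_value(tab, "chi2_yates"),
            1)  # Yates correction is applied without error
  # independence table -> p ~ 1
  indep <- contingency_table(10, 20, 30, 60)
  expect_gt(association_p_value(indep, "fisher"), 0.99)
  degenerate <- contingency_table(0, 0, 5, 5)
  expect_true(is.na(association_p_value(degenerate)))
})

test_that("combination_metrics propagates N.E from a zero-cell OR", {
  # six-SNP high-risk row: 0 controls / 4 cases matched
  tab <- pattern_vs_rest_table(list(controls_matched = 0, cases_matched = 4),
                               220, 334)
  met <- combination_metrics(tab)
  expect_equal(round_half_away(met$cc, 3), 0.610)
  expect_equal(round_half_away(met$sn, 3), 0.018)
  expect_equal(met$sp, 1)
  expect_true(is.na(met$odds_ratio))
  expect_true(is.na(met$average))  # Average prints N.E with the OR
  expect_true(is.na(met$ci_lower))
  expect_true(is.na(met$p_value))
})

test_that("metrics stay in [0, 1] on random tables", {
  set.seed(99)
  for (i in 1:200) {
    cells <- sample(0:50, 4, replace = TRUE)
    m <- classification_metrics(contingency_table(cells[1], cells[2],
                                                  cells[3], cells[4]))
    for (v in c(m$cc, m$sn, m$sp, m$average)) {
      if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 1) }
    }
  }
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_away(0.6155, 3), 0.616)
  expect_equal(round_half_away(-0.6155, 3), -0.616)
  expect_equal(round_half_away(2.5, 0), 3)
  expect_equal(round_half_away(0.0005, 3), 0.001)
})
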