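test_that("Cochran's Q matches closed-form arithmetic on hand-set values", {
  est <- make_estimates(c(0, 0.5, 1.0), c(0.1, 0.1, 0.1))
  het <- cochran_q(est)
  # w = 100 each, y_fixed = 0.5, Q = 100*(0.25 + 0 + 0.25) = 50
  expect_equal(het$q, 50, tolerance = 1e-12)
  expect_equal(het$df, 2)
  expect_equal(het$p_het, pchisq(50, 2, lower.tail = FALSE))
  # DL denominator: sum(w) - sum(w^2)/sum(w) = 300 - 30000/300 = 200
  expect_equal(het$tau2, (50 - 2) / 200, tolerance = 1e-12)
  expect_equal(het$i2, (50 - 2) / 50, tolerance = 1e-12)
})

test_that("identical estimates are perfectly homogeneous", {
  est <- make_estimates(c(0.3, 0.3), c(0.2, 0.2))
  het <- cochran_q(est)
  expect_equal(het$q, 0)
  expect_equal(het$p_het, 1)
  expect_equal(het$tau2, 0)
  expect_equal(het$i2, 0)
  expect_error(cochran_q(make_estimates(0.3, 0.2)), "fewer than 2")
})

test_that("Q is invariant under shifting every log odds ratio", {
  set.seed(5)
  y <- rnorm(8); se <- runif(8, 0.05, 0.5)
  q0 <- cochran_q(make_estimates(y, se))$q
  for (shift in c(-2, 0.7, 13)) {
    expect_equal(cochran_q(make_estimates(y + shift, se))$q, q0,
                 tolerance = 1e-9)
  }
})

test_that("Mantel-Haenszel pooling follows the weighted cross-product form", {
  one <- pool_mh(data.frame(a = 49, b = 17, c = 32, d = 30))
  expect_equal(round(one$pooled_or, 2), 2.70)

  two <- pool_mh(data.frame(a = c(10, 20), b = c(10, 5),
                            c = c(10, 5), d = c(10, 20)))
  expect_equal(two$pooled_or, 3.5, tolerance = 1e-12)

  # replication invariance: pooling two copies equals the single table
  rep2 <- pool_mh(data.frame(a = c(30, 30), b = c(12, 12),
                             c = c(18, 18), d = c(25, 25)))
  single <- pool_mh(data.frame(a = 30, b = 12, c = 18, d = 25))
  expect_equal(rep2$pooled_or, single$pooled_or, tolerance = 1e-12)

  expect_error(pool_mh(data.frame(a = 5, b = 0, c = 0, d = 5)),
               "undefined Mantel-Haenszel")
})

test_that("DL random effects collapses to IV fixed when tau2 = 0", {
  est <- make_estimates(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))
  dl <- pool_dl_random(est)
  iv <- pool_iv_fixed(est)
  expect_equal(dl$het$tau2, 0)
  expect_equal(dl$log_or, iv$log_or, tolerance = 1e-12)
  expect_equal(dl$se, iv$se, tolerance = 1e-12)
})

test_that("DL pooling matches a from-scratch arithmetic oracle", {
  y <- c(0, 0.5, 1.0); se <- c(0.1, 0.1, 0.1)
  dl <- pool_dl_random(make_estimates(y, se))
  # oracle: tau2 = 0.24 (see Q test); w* = 1/(0.01+0.24) each
  w_star <- 1 / (se^2 + 0.24)
  expect_equal(dl$log_or, sum(w_star * y) / sum(w_star), tolerance = 1e-12)
  expect_equal(dl$se, 1 / sqrt(sum(w_star)), tolerance = 1e-12)
  expect_equal(dl$ci_low, exp(dl$log_or - 1.96 * dl$se), tolerance = 1e-12)
})

test_that("random-effects interval is never narrower than fixed effects", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    est <- make_estimates(rnorm(k, 0.2, 0.4), runif(k, 0.05, 0.5))
    dl <- pool_dl_random(est); iv <- pool_iv_fixed(est)
    expect_gte(dl$se, iv$se - 1e-12)
    # pooled effect stays inside the span of the study effects
    expect_gte(dl$log_or, min(est$log_or) - 1e-12)
    expect_lte(dl$log_or, max(est$log_or) + 1e-12)
  }
})

test_that("a single study passes through every policy unchanged", {
  tab <- tiny_table(1)
  est <- estimate_all(tab, "dominant")
  for (p in c("auto", "force_random", "force_fixed")) {
    pooled <- pool(est, policy = p)
    expect_equal(pooled$pooled_or, est$or, info = p)
    expect_equal(pooled$ci_low, est$ci_low, info = p)
    expect_equal(pooled$ci_high, est$ci_high, info = p)
    expect_equal(pooled$k, 1)
  }
})

test_that("the auto policy switches on the heterogeneity p-value", {
  tab <- bundled_fixture("rs2294008")
  bladder <- as_study_table(
    as.data.frame(tab)[tab$cancer_type == "bladder", , drop = FALSE])
  est <- estimate_all(bladder, "homozygous")
  expect_equal(round(cochran_q(est)$p_het, 3), 0.572)
  expect_equal(pool(est, policy = "auto")$method, "MH_fixed")

  all_est <- estimate_all(tab, "homozygous")
  expect_equal(pool(all_est, policy = "auto")$method, "DL_random")
  expect_equal(pool(all_est, policy = "force_fixed")$method, "MH_fixed")
})

test_that("pooled estimates agree with the metafor reference implementation", {
  tab <- bundled_fixture("rs2976392")
  est <- estimate_all(tab, "dominant")

  ref_dl <- metafor::rma(yi = est$log_or, sei = est$se, method = "DL")
  dl <- pool_dl_random(est)
  expect_equal(dl$log_or, as.numeric(ref_dl$beta), tolerance = 1e-10)
  expect_equal(dl$se, ref_dl$se, tolerance = 1e-10)
  expect_equal(dl$het$tau2, ref_dl$tau2, tolerance = 1e-10)
  expect_equal(dl$het$q, ref_dl$QE, tolerance = 1e-10)

  ref_mh <- metafor::rma.mh(ai = est$a, bi = est$b, ci = est$c, di = est$d,
                            measure = "OR", correct = FALSE)
  mh <- pool_mh(est)
  expect_equal(mh$log_or, as.numeric(ref_mh$beta), tolerance = 1e-10)
  expect_equal(mh$se, ref_mh$se, tolerance = 1e-10)
})

test_that("MH and IV fixed effects nearly coincide on large-count strata", {
  est <- estimate_all(bundled_fixture("rs2294008"), "allele")
  expect_lt(abs(pool_mh(est)$pooled_or - pool_iv_fixed(est)$pooled_or), 0.01)
})
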