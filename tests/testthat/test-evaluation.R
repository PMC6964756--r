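test_that("percent difference reproduces the worked film-comparison values", {
  expect_equal(percent_difference(3.91, 4.0), -2.25, tolerance = 1e-12)
  expect_equal(percent_difference(3.88, 4.0), -3.0, tolerance = 1e-12)
  expect_equal(percent_difference(5.2, 5.2), 0)
  expect_error(percent_difference(1, 0), "non-zero")
  # designating the other engine as reference flips every sign
  set.seed(61)
  a <- runif(10, 3, 5); b <- runif(10, 3, 5)
  expect_true(all(sign(percent_difference(a, b)) == -sign(percent_difference(b, a))))
})

test_that("signed-rank test matches exhaustive enumeration at small n", {
  cases <- list(
    list(a = c(1.1, 2.3, 0.4, 5.5, 3.2, 4.0), b = c(0.9, 2.8, 0.1, 4.9, 3.9, 3.1)),
    list(a = c(2, 4, 6, 8, 10, 12, 14, 13), b = c(1, 5, 2, 9, 4, 11, 20, 13)),
    list(a = c(1, 2, 2, 3, 5, 5, 7), b = c(2, 1, 2, 5, 3, 6, 4)) # with ties
  )
  for (cs in cases) {
    got <- wilcoxon_signed_rank(cs$a, cs$b)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_wsrt_p(cs$a, cs$b), tolerance = 1e-12)
  }
})

test_that("signed-rank degenerate and extreme cases behave as documented", {
  a <- c(1, 2, 3, 4, 5)
  deg <- wilcoxon_signed_rank(a, a)
  expect_true(deg$degenerate)
  expect_equal(deg$n_zero, 5L)
  # a uniformly greater than b: all ranks positive, W- = 0
  b <- a - 1
  ext <- wilcoxon_signed_rank(c(a, 6:10), c(b, 5:9))
  expect_equal(ext$statistic, 10 * 11 / 2)
})

test_that("signed-rank asymptotic branch matches the classical approximation", {
  set.seed(62)
  a <- rnorm(30); b <- rnorm(30, 0.3)
  got <- wilcoxon_signed_rank(a, b)
  expect_false(got$exact)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Mann-Whitney matches exhaustive label enumeration at small n", {
  cases <- list(
    list(a = c(1.2, 3.4, 0.5, 2.2), b = c(2.1, 4.4, 0.1, 5.5, 3.3)),
    list(a = c(10, 12, 9), b = c(11, 8, 14, 13, 7, 15)),
    list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4, 5)) # with ties
  )
  for (cs in cases) {
    got <- mann_whitney_u(cs$a, cs$b)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_mwu_p(cs$a, cs$b), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney boundary and degenerate behaviour", {
  # every a below every b: U_a = 0
  expect_equal(mann_whitney_u(1:4, 11:15)$statistic, 0)
  # identical groups: p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # large-sample branch agrees with the classical tie-corrected approximation
  set.seed(63)
  a <- rnorm(25); b <- rnorm(30, 0.4)
  got <- mann_whitney_u(a, b)
  expect_false(got$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Kendall tau-b equals the pair-counting oracle and handles ties", {
  x <- 1:10
  expect_equal(kendall_tau(x, 2 * x + 1)$statistic, 1)
  expect_equal(kendall_tau(x, -x)$statistic, -1)
  set.seed(64)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  got <- kendall_tau(x, y)
  expect_equal(got$statistic, oracle_tau_b(x, y), tolerance = 1e-12)
  expect_equal(got$statistic, unname(cor(x, y, method = "kendall")),
               tolerance = 1e-12)
  # tied data still matches the oracle and base R's tau-b
  xt <- round(rnorm(30), 0); yt <- round(0.5 * xt + rnorm(30), 0)
  gt <- kendall_tau(xt, yt)
  expect_equal(gt$statistic, oracle_tau_b(xt, yt), tolerance = 1e-12)
  expect_equal(gt$statistic, unname(cor(xt, yt, method = "kendall")),
               tolerance = 1e-12)
  # constant input is flagged, not silently scored
  expect_true(kendall_tau(rep(1, 5), 1:5)$degenerate)
})

test_that("cohort evaluation summarises, stratifies and correlates", {
  rec <- simulate_cohort(n_targets = 120, nonstandard_count = 12,
                         depth_slope = -0.4, gamma_offset = 2, seed = 71)
  cmp <- dplyr::mutate(rec, secondary_dose = reference_dose * (1 + 1.6 *
    (secondary_dose / reference_dose - 1)))
  ev <- cohort_evaluation(rec, comparator = cmp)
  expect_equal(ev$n, 120L)
  expect_equal(ev$summary$n_violations,
               sum(abs(rec$percent_diff) > 5))
  expect_lt(ev$tests$depth_kendall$statistic, 0)
  expect_lt(ev$tests$gamma_mwu$p_value, 0.05)
  expect_false(ev$tests$engines_wsrt$degenerate)
  g <- glance(ev)
  expect_equal(g$median_abs, median(abs(rec$percent_diff)))
  td <- tidy(ev)
  expect_setequal(td$term, c("engines_wsrt", "gamma_mwu", "depth_kendall"))
})

test_that("degenerate cohorts are flagged or skipped with warnings", {
  rec <- simulate_cohort(n_targets = 40, nonstandard_count = 5, seed = 72)
  # identical engines: the paired test is degenerate
  ev <- cohort_evaluation(rec, comparator = rec)
  expect_true(ev$tests$engines_wsrt$degenerate)
  # single gamma category: stratified test skipped
  all90 <- simulate_cohort(n_targets = 40, nonstandard_count = 0, seed = 73)
  expect_warning(ev90 <- cohort_evaluation(all90), "gamma")
  expect_null(ev90$tests$gamma_mwu)
  # missing depth covariate: correlation skipped
  nodepth <- dplyr::mutate(rec, average_depth_cm = NA_real_)
  expect_warning(evnd <- cohort_evaluation(nodepth), "depth")
  expect_null(evnd$tests$depth_kendall)
})

test_that("tolerance violations equal a direct filter on the record table", {
  rec <- simulate_cohort(n_targets = 200, sigma_pct = 3, seed = 74)
  ev <- suppressWarnings(cohort_evaluation(rec, tolerance = 5))
  expect_equal(ev$summary$n_violations,
               nrow(dplyr::filter(rec, abs_percent_diff > 5)))
  ev2 <- suppressWarnings(cohort_evaluation(rec, tolerance = 2))
  expect_equal(ev2$summary$n_violations,
               nrow(dplyr::filter(rec, abs_percent_diff > 2)))
})
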