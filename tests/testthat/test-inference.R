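test_that("a workflow identical to DR is non-inferior but not superior", {
  # when AI always disagrees with reader 1, sIR defers every case to DR
  cases <- with_seed_helper(1, random_opinion_cohort(2000, p_sd = 0.05))
  cases$ai_recall <- !cases$r1_recall
  res <- bootstrap_compare(cases, "sIR", "CDR", n_boot = 300, seed = 5)
  expect_equal(res$point_ratio, 1)
  expect_true(res$noninferior)
  expect_identical(res$superior, "false")
})

test_that("a workflow at 90% of DR fails the 5% non-inferiority margin", {
  cases <- with_seed_helper(2, boundary_ratio_cohort(20000, p_cancer = 0.05,
                                                     p_miss = 0.10, exact = TRUE))
  res <- bootstrap_compare(cases, "DRT", "CDR", n_boot = 400, seed = 8)
  expect_equal(res$point_ratio, 0.9)
  expect_false(res$noninferior)
  expect_identical(res$superior, "not_tested")
})

test_that("results are deterministic given the seed", {
  cases <- with_seed_helper(3, random_opinion_cohort(1500, p_sd = 0.05,
                                                     centres = c("c1", "c2")))
  a <- bootstrap_compare(cases, "DRT", "RR", n_boot = 200, seed = 11)
  b <- bootstrap_compare(cases, "DRT", "RR", n_boot = 200, seed = 11)
  expect_identical(a, b)
  c <- bootstrap_compare(cases, "DRT", "RR", n_boot = 200, seed = 12)
  expect_false(identical(a$critical_quantile, c$critical_quantile))
})

test_that("enlarging the margin never flips non-inferiority to false", {
  for (s in 1:5) {
    cases <- with_seed_helper(s, boundary_ratio_cohort(4000, p_miss = 0.05))
    r1 <- bootstrap_compare(cases, "DRT", "CDR", margin = 0.05,
                            n_boot = 200, seed = 21)
    r2 <- bootstrap_compare(cases, "DRT", "CDR", margin = 0.10,
                            n_boot = 200, seed = 21)
    expect_identical(r1$critical_quantile, r2$critical_quantile)
    if (r1$noninferior) expect_true(r2$noninferior)
  }
})

test_that("DRT recall-rate ratios never exceed one on any replicate", {
  cases <- with_seed_helper(9, random_opinion_cohort(3000, centres = c("c1", "c2")))
  res <- bootstrap_compare(cases, "DRT", "RR", n_boot = 300, seed = 14)
  # lower-better critical quantile is the high percentile of the ratio; the
  # recall subset property caps every replicate at 1
  expect_lte(res$critical_quantile, 1)
  expect_lte(res$point_ratio, 1)
})

test_that("compare_all covers strata, refuses workload tests, handles one centre", {
  cases <- with_seed_helper(4, random_opinion_cohort(2500, p_sd = 0.05,
                                                     centres = c("c1", "c2")))
  res <- suppressWarnings(
    compare_all(cases, workflows = "DRT", metrics = c("CDR", "WORKLOAD_SAVING"),
                schemes = c("overall", "age2"), n_boot = 150, seed = 2)
  )
  expect_setequal(unique(res$scheme), c("overall", "age2"))
  wl <- res[res$metric == "WORKLOAD_SAVING", ]
  expect_true(all(wl$superior == "not_tested"))
  expect_true(all(is.na(wl$noninferior)))
  # a single-centre cohort degenerates to a simple bootstrap and still works
  one <- cases[cases$centre_id == "c1", ]
  res1 <- bootstrap_compare(one, "DRT", "RR", n_boot = 150, seed = 3)
  expect_true(is.finite(res1$critical_quantile))
})

test_that("superiority is gated on non-inferiority throughout", {
  cases <- with_seed_helper(6, random_opinion_cohort(2500, p_sd = 0.05,
                                                     centres = c("c1", "c2")))
  res <- compare_all(cases, n_boot = 150, seed = 4)
  expect_true(all(res$superior[!res$noninferior] == "not_tested"))
  expect_true(all(res$superior[res$noninferior] %in% c("true", "false")))
})

test_that("cohort tests reproduce the hand-computed chi-squared table", {
  # centre x density table [[10, 20], [20, 10]]: expected counts all 15,
  # X^2 = 4 * 25 / 15 = 6.667 on 1 df, without continuity correction
  cases <- dplyr::bind_rows(
    make_cases(r1 = rep(FALSE, 30), density = rep(c("A", "B"), c(10, 20)), centre = "c1"),
    make_cases(r1 = rep(FALSE, 30), density = rep(c("A", "B"), c(20, 10)), centre = "c2")
  )
  res <- cohort_tests(cases, "density")
  expect_equal(res$test_used, "chi_square")
  x2 <- stats::qchisq(res$overall_p, df = 1, lower.tail = FALSE)
  expect_equal(x2, 100 / 15, tolerance = 1e-10)
  # overall significant at 0.05, and with two centres one pairwise test runs
  expect_true(res$significant)
  expect_equal(nrow(res$pairwise[[1]]), 1)
})

test_that("single-level variables are skipped with a warning", {
  cases <- make_cases(r1 = rep(FALSE, 40), density = "B",
                      centre = rep(c("c1", "c2"), 20), ethnicity = NA)
  expect_warning(res <- cohort_tests(cases, "density"), "single level")
  expect_equal(nrow(res), 0)
  # ethnicity entirely missing leaves no centres to compare
  expect_warning(res2 <- cohort_tests(cases, "ethnicity"), "skipped")
  expect_equal(nrow(res2), 0)
})

test_that("pairwise tests appear only when the overall test rejects", {
  # three centres drawn from one distribution: usually not significant
  cases <- with_seed_helper(15, make_cases(
    r1 = rep(FALSE, 900),
    density = sample(c("A", "B", "C"), 900, replace = TRUE),
    centre = rep(c("c1", "c2", "c3"), each = 300)
  ))
  res <- cohort_tests(cases, "density")
  if (!res$significant) expect_equal(nrow(res$pairwise[[1]]), 0)
  # ... and the null rejection rate is near alpha
  set.seed(16)
  rejections <- replicate(200, {
    v <- sample(c("A", "B"), 600, replace = TRUE)
    centre <- rep(c("c1", "c2", "c3"), each = 200)
    chisq.test(table(centre, v), correct = FALSE)$p.value < 0.05
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("ANOVA branch handles age and gates Bonferroni pairwise tests", {
  set.seed(17)
  cases <- make_cases(
    r1 = rep(FALSE, 600),
    age = c(rnorm(200, 58, 7), rnorm(200, 61, 7), rnorm(200, 60, 7)),
    centre = rep(c("c1", "c2", "c3"), each = 200)
  )
  res <- cohort_tests(cases, "age")
  expect_equal(res$test_used, "anova")
  if (res$significant) {
    expect_equal(nrow(res$pairwise[[1]]), 3)
    expect_true(all(res$pairwise[[1]]$significant ==
                      (res$pairwise[[1]]$p_value < 0.05 / 3)))
  }
})
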