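test_that("wilson_ci matches hand-evaluated closed forms and boundary cases", {
  expect_equal(wilson_ci(10, 10)[, "high"], 1.0, ignore_attr = TRUE)
  expect_equal(round(wilson_ci(0, 10), 4), cbind(low = 0, high = 0.2775))
  expect_equal(round(wilson_ci(5, 10), 4), cbind(low = 0.2366, high = 0.7634))
  expect_error(wilson_ci(0, 0), class = "screenflow_undefined_interval")
})

test_that("wilson_ci agrees with the score interval from prop.test", {
  grid <- expand.grid(x = c(0, 1, 8, 250, 999), n = c(10, 1000))
  grid <- grid[grid$x <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    want <- stats::prop.test(grid$x[i], grid$n[i], correct = FALSE)$conf.int
    got <- wilson_ci(grid$x[i], grid$n[i], z = stats::qnorm(0.975))
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
  }
})

# Twelve cases with hand-enumerable DR outcomes (direct_recall policy):
# detected = rows 1, 2, 12; recalled = rows 1, 2, 6, 9, 12; cancers = rows
# 1-5 and 12; arbitration on rows 2, 5, 8, 9.
twelve_case_fixture <- function() {
  make_cases(
    r1 = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    r2 = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    arb = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    ai = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    sd = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    ic = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

test_that("all six metrics match hand computation on the 12-case fixture", {
  cases <- twelve_case_fixture()
  dec <- decide_dr(cases)
  got <- function(m) compute_metric(cases, dec, m)
  cdr <- got("CDR")
  expect_equal(cdr$numerator, 3)
  expect_equal(cdr$point, 3 / 12 * 1000)
  expect_equal(got("PPV")$point, 3 / 5 * 100)
  expect_equal(got("RR")$point, 5 / 12 * 100)
  expect_equal(got("SEN")$point, 3 / 6 * 100)
  expect_equal(got("SPEC")$point, 4 / 6 * 100)
  expect_equal(got("AR")$point, 4 / 12 * 100)
  # Wilson interval attached on the reporting scale
  expect_equal(cdr$ci_low / 1000, wilson_ci(3, 12)[, "low"], ignore_attr = TRUE)
})

test_that("toy rates rescale correctly and zero denominators flag undefined", {
  cases <- make_cases(r1 = rep(c(TRUE, FALSE), c(4, 496)),
                      r2 = rep(c(TRUE, FALSE), c(4, 496)),
                      sd = rep(c(TRUE, FALSE), c(4, 496)))
  dec <- decide_dr(cases)
  expect_equal(compute_metric(cases, dec, "CDR")$point, 8.0)
  # no recalls at all: PPV undefined but not an error
  none <- make_cases(r1 = rep(FALSE, 10), r2 = rep(FALSE, 10))
  ppv <- compute_metric(none, decide_dr(none), "PPV")
  expect_true(is.na(ppv$point) && is.na(ppv$ci_low))
  expect_equal(ppv$denominator, 0)
})

test_that("metric identities hold on any cohort", {
  for (s in 1:10) {
    cases <- with_seed_helper(s, random_opinion_cohort(400, centres = c("c1", "c2")))
    dec <- decide_dr(cases)
    cdr <- compute_metric(cases, dec, "CDR")$point
    rr <- compute_metric(cases, dec, "RR")$point
    ppv <- compute_metric(cases, dec, "PPV")$point
    expect_lte(cdr / 10, rr)
    expect_lte(rr, 100)
    if (!is.na(ppv)) {
      expect_equal(ppv * rr / 100, cdr / 10, tolerance = 1e-12)
    }
    # DRT dominance follows from the recall subset property
    drt <- decide_drt(cases)
    expect_lte(compute_metric(cases, drt, "RR")$point, rr)
    expect_lte(compute_metric(cases, drt, "CDR")$point, cdr)
  }
})

test_that("workload saving reproduces hand counts and bounds", {
  cases <- with_seed_helper(2, random_opinion_cohort(100))
  dr <- decide_dr(cases)
  expect_equal(workload_saving(dr, dr)$point, 0)
  # 10 cases, four R1/AI disagreements resolved without arbitration: 14 vs 20
  cases10 <- make_cases(
    r1 = c(rep(FALSE, 6), TRUE, TRUE, FALSE, FALSE),
    ai = c(rep(FALSE, 6), FALSE, FALSE, TRUE, TRUE),
    r2 = c(rep(FALSE, 6), TRUE, TRUE, FALSE, FALSE),
    arb = FALSE
  )
  sav <- workload_saving(decide_sir(cases10), decide_dr(cases10))
  expect_equal(sav$numerator, 14)
  expect_equal(sav$denominator, 20)
  expect_equal(sav$point, 30)
  # all-agree no-recall cohort: the theoretical 50% ceiling of a second read
  allno <- make_cases(r1 = rep(FALSE, 8), ai = rep(FALSE, 8))
  expect_equal(workload_saving(decide_sir(allno), decide_dr(allno))$point, 50)
})

test_that("equally weighted pooling is size-independent", {
  expect_equal(pool_equal_weight(c(8.9, 8.9, 6.6)), 8.1333333, tolerance = 1e-6)
  expect_equal(pool_equal_weight(c(7, 7, 7)), 7)
  expect_error(pool_equal_weight(numeric(0)), class = "screenflow_config_error")
  # replicating one centre's cases 10x leaves the pooled point unchanged
  cases <- with_seed_helper(5, random_opinion_cohort(300, centres = c("c1", "c2", "c3")))
  rep_c3 <- cases[cases$centre_id == "c3", ]
  rep_c3 <- rep_c3[rep(seq_len(nrow(rep_c3)), 10), ]
  rep_c3$case_id <- sprintf("c3rep-%04d", seq_len(nrow(rep_c3)))
  inflated <- dplyr::bind_rows(cases[cases$centre_id != "c3", ], rep_c3)
  p1 <- metric_by_centre(cases, decide_dr(cases), "RR")
  p2 <- metric_by_centre(inflated, decide_dr(inflated), "RR")
  expect_equal(p1$point[p1$centre == "pooled"], p2$point[p2$centre == "pooled"])
})

test_that("IC flag rate counts interval cancers and pools centre rates", {
  none <- make_cases(r1 = rep(FALSE, 10), ic = rep(TRUE, 10), ai = FALSE)
  expect_equal(ic_flag_rate(none)$point[1], 0)
  # three centres with rates 30/40/50 pool to 40
  cases <- dplyr::bind_rows(
    make_cases(ai = rep(c(TRUE, FALSE), c(3, 7)), ic = TRUE, r1 = FALSE, centre = "c1"),
    make_cases(ai = rep(c(TRUE, FALSE), c(4, 6)), ic = TRUE, r1 = FALSE, centre = "c2"),
    make_cases(ai = rep(c(TRUE, FALSE), c(5, 5)), ic = TRUE, r1 = FALSE, centre = "c3")
  )
  tab <- ic_flag_rate(cases)
  expect_equal(tab$point[tab$centre == "pooled"], 40)
  # a centre without interval cancers is excluded with a warning
  extra <- dplyr::bind_rows(cases, make_cases(r1 = rep(FALSE, 5), centre = "c4"))
  expect_warning(tab2 <- ic_flag_rate(extra), "without interval cancers")
  expect_equal(tab2$point[tab2$centre == "pooled"], 40)
})

test_that("stratification partitions the cohort and applies the boundary rules", {
  cases <- make_cases(r1 = rep(FALSE, 6), age = c(45, 59, 60, 60.5, 71, 80),
                      density = c("A", "B", "C", "D", NA, "B"),
                      ethnicity = c("White", "Asian", "Black", "Mixed/other", NA, NA))
  st <- stratify(cases, "age2")
  expect_identical(st$strata[["<60"]]$age_years, c(45, 59))
  expect_identical(st$strata[[">=60"]]$age_years, c(60, 60.5, 71, 80))
  st4 <- stratify(cases, "age4")
  expect_identical(st4$strata[[">=71"]]$age_years, c(71, 80))
  d2 <- stratify(cases, "density2")
  expect_identical(d2$strata[["A/B"]]$density, c("A", "B", "B"))
  expect_equal(nrow(d2$excluded), 1)
  e2 <- stratify(cases, "ethnicity2")
  expect_identical(sort(e2$strata[["Non-White"]]$ethnicity),
                   c("Asian", "Black", "Mixed/other"))
  expect_equal(nrow(e2$excluded), 2)
  # partition conservation across every scheme
  for (scheme in c("centre", "age2", "age4", "density2", "density4",
                   "ethnicity2", "ethnicity4", "year")) {
    st <- stratify(cases, scheme)
    expect_equal(sum(vapply(st$strata, nrow, integer(1))) + nrow(st$excluded),
                 nrow(cases), label = scheme)
  }
  # all-missing variable: empty strata plus full exclusion count
  blank <- make_cases(r1 = rep(FALSE, 4), density = NA)
  stb <- stratify(blank, "density4")
  expect_true(all(vapply(stb$strata, nrow, integer(1)) == 0))
  expect_equal(nrow(stb$excluded), 4)
  expect_error(stratify(cases, "postcode"), class = "screenflow_config_error")
})
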