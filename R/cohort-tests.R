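COHORT_TEST_VARIABLES <- c("age", "age_band", "density", "ethnicity", "year",
                           "positives")

cohort_test_value <- function(cases, variable) {
  switch(variable,
    age = cases$age_years,
    age_band = as.character(stratum_variable(cases, "age4")$value),
    density = cases$density,
    ethnicity = cases$ethnicity,
    year = as.character(cases$screen_year),
    positives = ifelse(cases$truth_screen_detected, "screen_detected",
                       ifelse(cases$truth_interval, "interval", "negative")),
    config_error("variables", paste0("unknown variable: ", variable))
  )
}

#' Between-centre cohort characteristic tests
#'
#' Tests each requested characteristic for differences between centres: ANOVA
#' for age (a continuous variable), chi-squared tests without continuity
#' correction for categorical variables. The overall test is judged at
#' `alpha`; only when it is significant are all pairwise centre comparisons
#' performed (two-sample t-tests for age, 2 x k chi-squared otherwise), each
#' judged against a Bonferroni-corrected level `alpha / n_pairs`. Cases with
#' a missing value are excluded from that variable's test; variables left
#' with a single level or a single centre are skipped with a warning.
#'
#' @param cases Cohort tibble.
#' @param variables Subset of `"age"`, `"age_band"`, `"density"`,
#'   `"ethnicity"`, `"year"`, `"positives"` (a three-level outcome factor:
#'   screen-detected / interval / negative, overlap cases counted as
#'   screen-detected).
#' @param alpha Overall test level.
#' @return Tibble with `variable`, `test_used`, `overall_p`, `significant`,
#'   and a `pairwise` list-column (a tibble of centre pairs with Bonferroni
#'   flags, empty unless the overall test is significant).
#' @export
cohort_tests <- function(cases, variables = COHORT_TEST_VARIABLES, alpha = 0.05) {
  rows <- lapply(variables, function(variable) {
    value <- cohort_test_value(cases, variable)
    keep <- !is.na(value)
    v <- value[keep]
    centre <- cases$centre_id[keep]
    centres <- unique(centre)
    continuous <- variable == "age"
    if (length(centres) < 2 || (!continuous && length(unique(v)) < 2)) {
      warning(sprintf("variable %s has a single level or centre; skipped", variable))
      return(NULL)
    }
    if (continuous) {
      fit <- aov(v ~ factor(centre))
      overall_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      test_used <- "anova"
    } else {
      overall_p <- chisq.test(table(centre, v), correct = FALSE)$p.value
      test_used <- "chi_square"
    }
    significant <- overall_p < alpha
    pairwise <- tibble::tibble(pair = character(), p_value = double(),
                               significant = logical())
    if (significant) {
      pairs <- utils::combn(sort(centres), 2, simplify = FALSE)
      adj_alpha <- alpha / length(pairs)
      pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
        sel <- centre %in% pr
        p <- if (continuous) {
          t.test(v[centre == pr[1]], v[centre == pr[2]])$p.value
        } else {
          chisq.test(table(centre[sel], v[sel]), correct = FALSE)$p.value
        }
        tibble::tibble(pair = paste(pr, collapse = " vs "), p_value = p,
                       significant = p < adj_alpha)
      }))
    }
    tibble::tibble(variable = variable, test_used = test_used,
                   overall_p = overall_p, significant = significant,
                   pairwise = list(pairwise))
  })
  dplyr::bind_rows(rows)
}
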