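STRATIFICATION_SCHEMES <- c("centre", "age2", "age4", "density2", "density4",
                            "ethnicity2", "ethnicity4", "year")

stratum_variable <- function(cases, scheme) {
  switch(scheme,
    centre = list(value = cases$centre_id,
                  levels = sort(unique(cases$centre_id))),
    age2 = list(value = ifelse(cases$age_years < 60, "<60", ">=60"),
                levels = c("<60", ">=60")),
    age4 = list(
      value = cut(cases$age_years, breaks = c(-Inf, 50, 60, 71, Inf),
                  labels = c("<=49", "50-59", "60-70", ">=71"), right = FALSE),
      levels = c("<=49", "50-59", "60-70", ">=71")
    ),
    density2 = list(
      value = ifelse(cases$density %in% c("A", "B"), "A/B",
                     ifelse(cases$density %in% c("C", "D"), "C/D", NA)),
      levels = c("A/B", "C/D")
    ),
    density4 = list(value = cases$density, levels = DENSITY_LEVELS),
    ethnicity2 = list(
      value = ifelse(cases$ethnicity == "White", "White",
                     ifelse(cases$ethnicity %in% c("Asian", "Black", "Mixed/other"),
                            "Non-White", NA)),
      levels = c("White", "Non-White")
    ),
    ethnicity4 = list(value = cases$ethnicity, levels = ETHNICITY_LEVELS),
    year = list(value = as.character(cases$screen_year),
                levels = as.character(sort(unique(cases$screen_year)))),
    config_error("scheme", paste0("unknown stratification scheme: ", scheme))
  )
}

#' Stratify a cohort into labelled subgroups
#'
#' Splits the cohort into the disjoint strata of one scheme. Cases with a
#' missing value for the scheme's variable are excluded from that
#' stratification only and returned separately, so stratum sizes plus the
#' exclusion count always equal the cohort size. `Non-White` is the union of
#' Asian, Black and Mixed/other. Age boundaries are inclusive on the right
#' stratum: 60.0 years falls in `>=60`, 71.0 in `>=71`.
#'
#' @param cases Cohort tibble.
#' @param scheme One of `"centre"`, `"age2"` (<60 / >=60), `"age4"`
#'   (<=49 / 50-59 / 60-70 / >=71), `"density2"` (A/B vs C/D), `"density4"`,
#'   `"ethnicity2"` (White vs Non-White), `"ethnicity4"`, `"year"`.
#' @return A list with `scheme`, `strata` (named list of tibbles, fixed-level
#'   schemes always carry all levels, possibly empty) and `excluded` (tibble
#'   of cases missing the scheme's variable).
#' @export
stratify <- function(cases, scheme) {
  v <- stratum_variable(cases, scheme)
  value <- as.character(v$value)
  keep <- !is.na(value)
  strata <- lapply(setNames(v$levels, v$levels), function(lv) {
    cases[keep & value == lv, , drop = FALSE]
  })
  list(scheme = scheme,
       strata = strata,
       excluded = cases[!keep, , drop = FALSE])
}
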