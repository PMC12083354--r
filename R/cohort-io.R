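COHORT_COLUMNS <- c(
  "case_id", "woman_id", "centre_id", "screen_year", "age_years",
  "density", "ethnicity", "r1_recall", "r2_recall", "arbiter_recall",
  "ai_recall", "truth_screen_detected", "truth_interval"
)

BOOL_COLUMNS <- c("r1_recall", "r2_recall", "arbiter_recall", "ai_recall",
                  "truth_screen_detected", "truth_interval")

#' Write a cohort to CSV
#'
#' UTF-8 CSV with one header row and the canonical column order. Booleans are
#' encoded as 0/1 and missing density/ethnicity as the sentinel token `NA`.
#'
#' @param cases Cohort tibble as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cases, path) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cases))
  if (length(missing_cols)) {
    schema_error(paste0("cohort is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- cases[COHORT_COLUMNS]
  for (col in BOOL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]: validates the schema (all thirteen columns
#' present, opinion/truth columns strictly 0/1, positive ages, density and
#' ethnicity drawn from their category sets) and reports the first offending
#' row on failure. `read_cohort(write_cohort(x))` is the identity.
#'
#' @param path CSV file path.
#' @return A cohort tibble (see [generate_cohort()] for the schema).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      case_id = readr::col_character(),
      woman_id = readr::col_character(),
      centre_id = readr::col_character(),
      screen_year = readr::col_integer(),
      age_years = readr::col_double(),
      density = readr::col_character(),
      ethnicity = readr::col_character(),
      r1_recall = readr::col_integer(),
      r2_recall = readr::col_integer(),
      arbiter_recall = readr::col_integer(),
      ai_recall = readr::col_integer(),
      truth_screen_detected = readr::col_integer(),
      truth_interval = readr::col_integer()
    ),
    na = "NA",
    progress = FALSE,
    show_col_types = FALSE
  )
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    schema_error(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    schema_error(sprintf("unparseable value at row %d, column %s",
                         probs$row[1] - 1L, probs$col[1]))
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      schema_error(sprintf("%s at row %d", what, which(!ok)[1]))
    }
  }
  for (col in BOOL_COLUMNS) {
    bad_row(!is.na(raw[[col]]) & raw[[col]] %in% c(0L, 1L),
            sprintf("column %s must be 0/1", col))
    raw[[col]] <- raw[[col]] == 1L
  }
  if (nrow(raw)) {
    bad_row(!is.na(raw$age_years) & raw$age_years > 0, "age_years must be > 0")
    bad_row(is.na(raw$density) | raw$density %in% DENSITY_LEVELS,
            "density must be one of A/B/C/D/NA")
    bad_row(is.na(raw$ethnicity) | raw$ethnicity %in% ETHNICITY_LEVELS,
            "ethnicity must be one of White/Asian/Black/Mixed/other/NA")
  }
  raw[COHORT_COLUMNS]
}
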