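#' Generate a synthetic screening cohort
#'
#' Draws one row per screening episode. Outcome labels are drawn first; all
#' four recall opinions (reader 1, reader 2, arbiter, AI) are then drawn
#' conditionally on cancer status, so every workflow variant can be replayed
#' on the same cases. Screen-detected cases use the sensitivity branch of
#' each opinion; all other cases use the specificity branch, except that the
#' AI flag on interval-cancer-only cases is drawn with
#' `ai_interval_flag_rate`. Reader 2 copies reader 1 with probability
#' `reader_dependence` and is otherwise an independent draw from the same
#' branch.
#'
#' The result is deterministic given `params` (including its seed); each
#' centre has its own stream derived from the master seed, so adding or
#' reordering centres does not perturb the others.
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per case and columns `case_id`, `woman_id`,
#'   `centre_id`, `screen_year`, `age_years`, `density`, `ethnicity`,
#'   `r1_recall`, `r2_recall`, `arbiter_recall`, `ai_recall`,
#'   `truth_screen_detected`, `truth_interval`. Missing density/ethnicity are
#'   `NA`; opinion and truth columns are logical and never missing.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "screenflow_cohort_params")) {
    config_error("params", "must be a cohort_params() object")
  }
  lapply(params$centres, validate_centre_params)
  centre_seeds <- with_seed(params$seed,
                            sample.int(.Machine$integer.max, length(params$centres)))
  parts <- Map(function(cp, s) with_seed(s, generate_centre(cp)),
               params$centres, centre_seeds)
  dplyr::bind_rows(parts)
}

empty_cohort <- function() {
  tibble::tibble(
    case_id = character(),
    woman_id = character(),
    centre_id = character(),
    screen_year = integer(),
    age_years = double(),
    density = character(),
    ethnicity = character(),
    r1_recall = logical(),
    r2_recall = logical(),
    arbiter_recall = logical(),
    ai_recall = logical(),
    truth_screen_detected = logical(),
    truth_interval = logical()
  )
}

# One centre under an already-seeded RNG. Draw order is fixed (truths, ages,
# categoricals, opinions, woman assignment) and vectorised so the stream is
# reproducible.
generate_centre <- function(cp) {
  n <- as.integer(cp$n_cases)
  if (n == 0L) return(empty_cohort())

  truth_sd <- runif(n) < cp$p_screen_detected
  truth_ic <- runif(n) < cp$p_interval

  band <- sample.int(nrow(cp$age_bands), n, replace = TRUE, prob = cp$age_bands$prob)
  age <- runif(n, cp$age_bands$lower[band], cp$age_bands$upper[band])

  draw_cat <- function(probs) {
    lv <- names(probs)
    x <- sample(lv, n, replace = TRUE, prob = probs)
    x[x == "missing"] <- NA_character_
    x
  }
  density <- draw_cat(cp$density_probs)
  ethnicity <- draw_cat(cp$ethnicity_probs)
  year <- as.integer(sample(names(cp$year_probs), n, replace = TRUE, prob = cp$year_probs))

  modifier <- function(var, values) {
    m <- cp$ai_subgroup_modifiers[[var]]
    if (is.null(m)) return(rep(1, n))
    out <- rep(1, n)
    hit <- !is.na(values) & values %in% names(m)
    out[hit] <- m[values[hit]]
    out
  }
  ai_mod <- modifier("density", density) * modifier("ethnicity", ethnicity)

  p_reader <- ifelse(truth_sd, cp$reader_sensitivity, 1 - cp$reader_specificity)
  r1 <- runif(n) < p_reader
  r2_indep <- runif(n) < p_reader
  copy <- runif(n) < cp$reader_dependence
  r2 <- ifelse(copy, r1, r2_indep)

  p_arb <- ifelse(truth_sd, cp$arbiter_sensitivity, 1 - cp$arbiter_specificity)
  arbiter <- runif(n) < p_arb

  p_ai <- ifelse(truth_sd, pmin(1, cp$ai_sensitivity * ai_mod),
                 ifelse(truth_ic, pmin(1, cp$ai_interval_flag_rate * ai_mod),
                        1 - cp$ai_specificity))
  ai <- runif(n) < p_ai

  # Women: a fixed fraction contribute two episodes each; assignment is a
  # random interleaving so repeat visits are not adjacent.
  n_two <- min(floor(n / 2), round(n * cp$p_second_episode / (1 + cp$p_second_episode)))
  n_women <- n - n_two
  woman_idx <- sample(c(seq_len(n_women), seq_len(n_two)))

  tibble::tibble(
    case_id = sprintf("%s-%07d", cp$centre_id, seq_len(n)),
    woman_id = sprintf("%s-w%07d", cp$centre_id, woman_idx),
    centre_id = cp$centre_id,
    screen_year = year,
    age_years = age,
    density = density,
    ethnicity = ethnicity,
    r1_recall = r1,
    r2_recall = r2,
    arbiter_recall = arbiter,
    ai_recall = ai,
    truth_screen_detected = truth_sd,
    truth_interval = truth_ic
  )
}
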