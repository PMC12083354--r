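#' Per-centre simulation parameters
#'
#' Describes one screening centre: its size, the marginal distributions of
#' participant attributes, the rare-outcome rates, and the operating
#' characteristics of the human readers, the arbiter and the AI system.
#' Opinions are drawn conditionally on cancer status: sensitivities apply to
#' screen-detected cancer cases, specificities to all other cases, and
#' interval-cancer-only cases get their AI flag from `ai_interval_flag_rate`
#' (human opinions on those cases come from the specificity branch, encoding
#' the retrospective constraint that readers did not recall them).
#'
#' @param centre_id Centre label (character scalar).
#' @param n_cases Number of screening episodes to simulate (non-negative).
#' @param age_bands Data frame with columns `band`, `prob`, `lower`, `upper`;
#'   ages are drawn as a band then uniformly within `[lower, upper)`.
#' @param density_probs Named probabilities over `c("A","B","C","D","missing")`.
#' @param ethnicity_probs Named probabilities over
#'   `c("White","Asian","Black","Mixed/other","missing")`. Use
#'   `missing = 1` for centres that do not capture ethnicity.
#' @param year_probs Named probabilities over screening years, e.g.
#'   `c("2017" = 0.2, ...)`.
#' @param p_screen_detected Per-case probability of a screen-detected cancer.
#' @param p_interval Per-case probability of an interval cancer. The two
#'   outcome flags are drawn independently, so a case can carry both.
#' @param reader_sensitivity,reader_specificity Human reader operating
#'   characteristics in `[0, 1]` (shared by readers 1 and 2).
#' @param reader_dependence Probability that reader 2 copies reader 1's
#'   opinion; otherwise reader 2 is an independent draw.
#' @param arbiter_sensitivity,arbiter_specificity Arbiter operating
#'   characteristics.
#' @param ai_sensitivity,ai_specificity AI operating characteristics at its
#'   fixed operating point.
#' @param ai_interval_flag_rate Probability that an interval-cancer-only case
#'   is flagged by the AI.
#' @param ai_subgroup_modifiers Optional named list of named numeric vectors,
#'   e.g. `list(density = c(C = 1.1, D = 1.2))`, applied multiplicatively to
#'   `ai_sensitivity` and `ai_interval_flag_rate` for matching cases
#'   (clamped to `[0, 1]`).
#' @param p_second_episode Fraction of women contributing two episodes
#'   (a woman may appear more than once in a multi-year cohort).
#'
#' @return A list of class `screenflow_centre_params`.
#' @seealso [cohort_params()], [three_centre_preset()]
#' @export
centre_params <- function(centre_id,
                          n_cases,
                          age_bands,
                          density_probs,
                          ethnicity_probs,
                          year_probs,
                          p_screen_detected,
                          p_interval,
                          reader_sensitivity,
                          reader_specificity,
                          reader_dependence,
                          arbiter_sensitivity,
                          arbiter_specificity,
                          ai_sensitivity,
                          ai_specificity,
                          ai_interval_flag_rate,
                          ai_subgroup_modifiers = NULL,
                          p_second_episode = 0.3) {
  out <- structure(
    list(
      centre_id = centre_id,
      n_cases = n_cases,
      age_bands = as.data.frame(age_bands),
      density_probs = density_probs,
      ethnicity_probs = ethnicity_probs,
      year_probs = year_probs,
      p_screen_detected = p_screen_detected,
      p_interval = p_interval,
      reader_sensitivity = reader_sensitivity,
      reader_specificity = reader_specificity,
      reader_dependence = reader_dependence,
      arbiter_sensitivity = arbiter_sensitivity,
      arbiter_specificity = arbiter_specificity,
      ai_sensitivity = ai_sensitivity,
      ai_specificity = ai_specificity,
      ai_interval_flag_rate = ai_interval_flag_rate,
      ai_subgroup_modifiers = ai_subgroup_modifiers,
      p_second_episode = p_second_episode
    ),
    class = "screenflow_centre_params"
  )
  validate_centre_params(out)
  out
}

#' Cohort simulation parameters
#'
#' Bundles per-centre parameter blocks with a master seed. Per-centre random
#' streams are derived deterministically from the master seed, so the same
#' `cohort_params` object always yields the same cohort.
#'
#' @param centres List of [centre_params()] objects.
#' @param seed Integer master seed.
#' @return A list of class `screenflow_cohort_params`.
#' @export
cohort_params <- function(centres, seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }
  if (!is.list(centres) || length(centres) == 0 ||
      !all(vapply(centres, inherits, logical(1), "screenflow_centre_params"))) {
    config_error("centres", "must be a non-empty list of centre_params()")
  }
  ids <- vapply(centres, function(x) x$centre_id, character(1))
  if (anyDuplicated(ids)) config_error("centres", "duplicated centre_id")
  structure(
    list(centres = setNames(centres, ids), seed = as.integer(seed)),
    class = "screenflow_cohort_params"
  )
}

DENSITY_LEVELS <- c("A", "B", "C", "D")
ETHNICITY_LEVELS <- c("White", "Asian", "Black", "Mixed/other")

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    config_error(field, "must be a probability in [0, 1]")
  }
}

check_dist <- function(x, field, levels) {
  if (!is.numeric(x) || is.null(names(x))) {
    config_error(field, "must be a named numeric vector of probabilities")
  }
  if (!setequal(names(x), levels)) {
    config_error(field, sprintf("names must be {%s}", paste(levels, collapse = ", ")))
  }
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    config_error(field, "probabilities must lie in [0, 1]")
  }
  if (abs(sum(x) - 1) > 1e-9) {
    config_error(field, sprintf("probabilities must sum to 1 (got %.12f)", sum(x)))
  }
}

validate_centre_params <- function(cp) {
  if (!is.character(cp$centre_id) || length(cp$centre_id) != 1 || is.na(cp$centre_id)) {
    config_error("centre_id", "must be a character scalar")
  }
  if (!is.numeric(cp$n_cases) || length(cp$n_cases) != 1 ||
      is.na(cp$n_cases) || cp$n_cases < 0 || cp$n_cases != round(cp$n_cases)) {
    config_error("n_cases", "must be a non-negative integer")
  }
  ab <- cp$age_bands
  if (!all(c("band", "prob", "lower", "upper") %in% names(ab))) {
    config_error("age_bands", "needs columns band, prob, lower, upper")
  }
  if (any(ab$prob < 0) || abs(sum(ab$prob) - 1) > 1e-9) {
    config_error("age_bands", "band probabilities must be >= 0 and sum to 1")
  }
  if (any(ab$lower <= 0) || any(ab$upper <= ab$lower)) {
    config_error("age_bands", "bands must satisfy 0 < lower < upper")
  }
  check_dist(cp$density_probs, "density_probs", c(DENSITY_LEVELS, "missing"))
  check_dist(cp$ethnicity_probs, "ethnicity_probs", c(ETHNICITY_LEVELS, "missing"))
  if (!is.numeric(cp$year_probs) || is.null(names(cp$year_probs)) ||
      any(cp$year_probs < 0) || abs(sum(cp$year_probs) - 1) > 1e-9) {
    config_error("year_probs", "must be named probabilities summing to 1")
  }
  for (f in c("p_screen_detected", "p_interval", "reader_sensitivity",
              "reader_specificity", "reader_dependence", "arbiter_sensitivity",
              "arbiter_specificity", "ai_sensitivity", "ai_specificity",
              "ai_interval_flag_rate", "p_second_episode")) {
    check_prob(cp[[f]], f)
  }
  if (!is.null(cp$ai_subgroup_modifiers)) {
    m <- cp$ai_subgroup_modifiers
    if (!is.list(m) || is.null(names(m)) ||
        !all(names(m) %in% c("density", "ethnicity")) ||
        !all(vapply(m, function(v) is.numeric(v) && !is.null(names(v)) && all(v >= 0), logical(1)))) {
      config_error("ai_subgroup_modifiers",
                   "must be a named list (density/ethnicity) of named non-negative multipliers")
    }
  }
  invisible(cp)
}

#' Default three-centre study preset
#'
#' Parameters emulating a published multi-centre UK breast-screening cohort
#' of 306 839 episodes screened 2017-2021 across three centres of sizes
#' 189 257, 65 839 and 51 743. Marginal distributions (age bands, automated
#' BI-RADS density, ethnicity where captured, screening year) and the
#' screen-detected (~0.8%) and interval-cancer (~0.1%) rates follow the
#' published per-centre counts. Ethnicity is captured only at `centre1`;
#' the other two centres record it as missing.
#'
#' Reader, arbiter and AI operating characteristics are calibrated defaults
#' (the source cohort reports workflow-level outcomes, not reader-level
#' characteristics), chosen from closed-form expectations so that simulated
#' standard double reading lands near the published cancer-detection and
#' recall rates; see the package vignette for the derivation.
#'
#' @param seed Master seed for [generate_cohort()].
#' @return A [cohort_params()] object.
#' @export
three_centre_preset <- function(seed = 1L) {
  bands <- function(counts) {
    data.frame(
      band = c("<=49", "50-59", "60-70", ">=71"),
      prob = counts / sum(counts),
      lower = c(47, 50, 60, 71),
      upper = c(50, 60, 71, 76)
    )
  }
  dist <- function(counts, levels) setNames(counts / sum(counts), levels)
  dlev <- c(DENSITY_LEVELS, "missing")
  elev <- c(ETHNICITY_LEVELS, "missing")
  ylev <- as.character(2017:2021)

  common <- list(
    reader_sensitivity = 0.99,
    reader_dependence = 0.4,
    arbiter_sensitivity = 0.97,
    arbiter_specificity = 0.80,
    ai_sensitivity = 0.87,
    ai_specificity = 0.94,
    ai_interval_flag_rate = 0.412
  )

  c1 <- do.call(centre_params, c(list(
    centre_id = "centre1",
    n_cases = 189257L,
    age_bands = bands(c(12135, 93697, 73032, 10393)),
    density_probs = dist(c(21836, 85465, 72333, 9410, 213), dlev),
    ethnicity_probs = dist(c(92644, 33505, 19273, 12282, 31553), elev),
    year_probs = dist(c(43472, 42316, 47711, 17755, 38003), ylev),
    p_screen_detected = 1673 / 189257,
    p_interval = 158 / 189257,
    reader_specificity = 0.938
  ), common))

  c2 <- do.call(centre_params, c(list(
    centre_id = "centre2",
    n_cases = 65839L,
    age_bands = bands(c(798, 29928, 29997, 5116)),
    density_probs = dist(c(8877, 30119, 24336, 2505, 2), dlev),
    ethnicity_probs = setNames(c(0, 0, 0, 0, 1), elev),
    year_probs = dist(c(14132, 14435, 14910, 9231, 13131), ylev),
    p_screen_detected = 577 / 65839,
    p_interval = 141 / 65839,
    reader_specificity = 0.938
  ), common))

  c3 <- do.call(centre_params, c(list(
    centre_id = "centre3",
    n_cases = 51743L,
    age_bands = bands(c(470, 25998, 23039, 2236)),
    density_probs = dist(c(8192, 23823, 18200, 1391, 137), dlev),
    ethnicity_probs = setNames(c(0, 0, 0, 0, 1), elev),
    year_probs = dist(c(8737, 12261, 12237, 4820, 13688), ylev),
    p_screen_detected = 342 / 51743,
    p_interval = 78 / 51743,
    reader_specificity = 0.9597
  ), common))

  cohort_params(list(c1, c2, c3), seed = seed)
}
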