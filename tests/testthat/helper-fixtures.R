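with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Build a minimal cohort tibble from explicit opinion/outcome vectors.
make_cases <- function(r1, r2 = FALSE, arb = FALSE, ai = FALSE,
                       sd = FALSE, ic = FALSE, centre = "c1",
                       age = 55, density = "B", ethnicity = "White",
                       year = 2019L) {
  n <- max(lengths(list(r1, r2, arb, ai, sd, ic, centre, age)))
  tibble::tibble(
    case_id = sprintf("%s-%04d", rep_len(centre, n), seq_len(n)),
    woman_id = sprintf("w%04d", seq_len(n)),
    centre_id = rep_len(centre, n),
    screen_year = rep_len(as.integer(year), n),
    age_years = rep_len(age, n),
    density = rep_len(density, n),
    ethnicity = rep_len(ethnicity, n),
    r1_recall = rep_len(r1, n),
    r2_recall = rep_len(r2, n),
    arbiter_recall = rep_len(arb, n),
    ai_recall = rep_len(ai, n),
    truth_screen_detected = rep_len(sd, n),
    truth_interval = rep_len(ic, n)
  )
}

# Cohort with independent random opinions, for property-style checks.
random_opinion_cohort <- function(n, p_recall = 0.3, p_sd = 0.1, p_ic = 0.05,
                                  centres = "c1") {
  make_cases(
    r1 = runif(n) < p_recall,
    r2 = runif(n) < p_recall,
    arb = runif(n) < p_recall,
    ai = runif(n) < p_recall,
    sd = runif(n) < p_sd,
    ic = runif(n) < p_ic,
    centre = sample(centres, n, replace = TRUE)
  )
}

# Single-centre simulation parameters with overridable fields.
one_centre_params <- function(n = 1000L, seed = 1L, centre_id = "c1", ...) {
  dots <- list(...)
  args <- list(
    centre_id = centre_id,
    n_cases = n,
    age_bands = data.frame(band = c("<=49", "50-59", "60-70", ">=71"),
                           prob = c(0.05, 0.49, 0.41, 0.05),
                           lower = c(47, 50, 60, 71), upper = c(50, 60, 71, 76)),
    density_probs = c(A = 0.127, B = 0.454, C = 0.374, D = 0.043, missing = 0.002),
    ethnicity_probs = c(White = 0.49, Asian = 0.18, Black = 0.10,
                        `Mixed/other` = 0.06, missing = 0.17),
    year_probs = c(`2017` = 0.2, `2018` = 0.2, `2019` = 0.25, `2020` = 0.1,
                   `2021` = 0.25),
    p_screen_detected = 0.008,
    p_interval = 0.001,
    reader_sensitivity = 0.95,
    reader_specificity = 0.95,
    reader_dependence = 0.3,
    arbiter_sensitivity = 0.9,
    arbiter_specificity = 0.8,
    ai_sensitivity = 0.85,
    ai_specificity = 0.94,
    ai_interval_flag_rate = 0.412
  )
  args[names(dots)] <- dots
  cohort_params(list(do.call(centre_params, args)), seed = seed)
}

# Cohort in which DR detects every cancer while the AI workflows miss each
# one independently with probability `p_miss`: cancers are read as
# r1 = r2 = ai = recall except a `p_miss` fraction where r1 = ai = no and the
# case is only rescued by reader 2 plus the arbiter. The true CDR ratio
# (sIR or DRT vs DR) is therefore exactly 1 - p_miss.
boundary_ratio_cohort <- function(n, p_cancer = 0.05, p_miss = 0.05,
                                  exact = FALSE) {
  if (exact) {
    n_cancer <- round(n * p_cancer)
    n_missed <- round(n_cancer * p_miss)
    cancer <- c(rep(TRUE, n_cancer), rep(FALSE, n - n_cancer))
    missed <- c(rep(TRUE, n_missed), rep(FALSE, n - n_missed))
  } else {
    cancer <- runif(n) < p_cancer
    missed <- cancer & runif(n) < p_miss
  }
  make_cases(
    r1 = cancer & !missed,
    r2 = cancer,
    arb = cancer,
    ai = cancer & !missed,
    sd = cancer,
    ic = FALSE
  )
}
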