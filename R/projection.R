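#' Published interval-cancer calibration reference points
#'
#' Reference pairs linking a retrospectively measured standalone AI
#' interval-cancer flag rate to the cancer-detection-rate increase observed
#' after prospective deployment of the same AI as an additional reader.
#' Shipped as annotated calibration data for sensitivity analyses; the
#' default projection is calibrated to the headline pair (flag rate 0.412
#' mapping to +1.2 per 1000), not fitted to these.
#'
#' @return Tibble with `flag_rate_fraction`, `uplift_low`, `uplift_high`
#'   (per 1000) and a `note` describing the source setting.
#' @export
ic_calibration_reference <- function() {
  tibble::tibble(
    flag_rate_fraction = c(0.247, 0.341),
    uplift_low = c(0.7, 1.0),
    uplift_high = c(1.6, 1.0),
    note = c("2-year interval cancers; prospective additional-reader rollout",
             "3-year interval cancers; subsequent prospective evaluation")
  )
}

#' Projection parameters
#'
#' The projection is a proportional model: expected prospective CDR uplift
#' (per 1000 screens) = `kappa` x interval-cancer flag fraction. The default
#' `kappa` is calibrated so a flag fraction of 0.412 projects to +1.2 per
#' 1000.
#'
#' @param kappa Uplift (per 1000) per unit flag fraction; must be >= 0.
#' @param calibration_pairs Annotated reference pairs, by default
#'   [ic_calibration_reference()].
#' @return A list of class `screenflow_projection_params`.
#' @export
projection_params <- function(kappa = 1.2 / 0.412,
                              calibration_pairs = ic_calibration_reference()) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa < 0) {
    config_error("kappa", "must be a single non-negative number")
  }
  if (!is.null(calibration_pairs)) {
    fr <- calibration_pairs$flag_rate_fraction
    if (any(fr < 0 | fr > 1)) {
      config_error("calibration_pairs", "flag fractions must lie in [0, 1]")
    }
  }
  structure(list(kappa = kappa, calibration_pairs = calibration_pairs),
            class = "screenflow_projection_params")
}

#' Fit the proportionality constant to one calibration pair
#'
#' @param flag_rate_fraction Flag fraction in (0, 1].
#' @param uplift_per_1000 Observed prospective CDR uplift (per 1000).
#' @return A [projection_params()] object whose `kappa` reproduces the pair
#'   exactly.
#' @export
fit_kappa <- function(flag_rate_fraction, uplift_per_1000) {
  if (flag_rate_fraction <= 0 || flag_rate_fraction > 1) {
    config_error("flag_rate_fraction", "must lie in (0, 1]")
  }
  projection_params(kappa = uplift_per_1000 / flag_rate_fraction)
}

#' Project prospective CDR uplift from the interval-cancer flag rate
#'
#' Converts the standalone AI interval-cancer flag rate (the retrospective
#' proxy) into the expected cancer-detection-rate increase of an
#' additional-reader deployment, per 1000 screens.
#'
#' @param flag_rate_fraction Flag rate as a fraction in `[0, 1]`.
#' @param params A [projection_params()] object.
#' @return Expected CDR uplift, per 1000 screens.
#' @export
project_uplift <- function(flag_rate_fraction, params = projection_params()) {
  if (!is.numeric(flag_rate_fraction) || any(is.na(flag_rate_fraction)) ||
      any(flag_rate_fraction < 0) || any(flag_rate_fraction > 1)) {
    config_error("flag_rate_fraction", "must lie in [0, 1]")
  }
  params$kappa * flag_rate_fraction
}

#' Net CDR change of a combination workflow
#'
#' An independent-reader workflow trades a small simulated CDR decrease for
#' workload savings; adding the AI as an additional reader projects an
#' uplift. The net change of the combination is their difference.
#'
#' @param projected_uplift Projected uplift, per 1000 (from
#'   [project_uplift()]).
#' @param simulated_cdr_decrease Simulated CDR decrease of the
#'   independent-reader workflow relative to DR, per 1000 (a positive number
#'   for a decrease).
#' @return Net CDR change, per 1000 screens.
#' @export
net_cdr_change <- function(projected_uplift, simulated_cdr_decrease) {
  stopifnot(is.finite(projected_uplift), is.finite(simulated_cdr_decrease))
  projected_uplift - simulated_cdr_decrease
}
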