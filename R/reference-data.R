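#' Published per-centre reference estimates
#'
#' Per-centre point estimates reported by a published three-centre UK
#' evaluation of the double-reading workflows this package simulates:
#' standard-double-reading cancer detection rate (per 1000) and recall rate
#' (%), the AI-workflow recall rates, and the per-centre workload savings
#' (%). Centre labels follow the package convention (`centre1` is the
#' largest centre). These are reporting-scale values as printed; pooling them
#' with [pool_equal_weight()] reproduces the published overall figures and is
#' used by the acceptance checks.
#'
#' @return Tibble with columns `workflow`, `metric`, `centre`, `value`.
#' @export
published_centre_estimates <- function() {
  path <- system.file("extdata", "published_centre_estimates.csv",
                      package = "screenflow", mustWork = TRUE)
  readr::read_csv(path, col_types = "cccd", progress = FALSE)
}
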