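METRIC_SCALES <- c(
  CDR = "per_1000", PPV = "percent", RR = "percent", SEN = "percent",
  SPEC = "percent", AR = "percent", WORKLOAD_SAVING = "percent",
  IC_FLAG_RATE = "percent"
)

scale_factor <- function(scale) {
  switch(scale, per_1000 = 1000, percent = 100, fraction = 1)
}

#' Wilson score confidence interval
#'
#' Two-sided score interval for a binomial proportion; well behaved for the
#' small proportions typical of screening outcomes. Vectorised over
#' `successes`/`trials`.
#'
#' @param successes Number of successes (0 <= successes <= trials).
#' @param trials Number of trials (>= 1).
#' @param z Normal quantile; 1.96 gives the conventional 95% interval.
#' @return A two-column matrix with columns `low` and `high`, on the
#'   proportion scale, clipped to `[0, 1]`.
#' @export
wilson_ci <- function(successes, trials, z = 1.96) {
  if (any(trials < 1)) {
    stop(errorCondition("Wilson interval undefined for zero trials",
                        class = c("screenflow_undefined_interval", "error", "condition")))
  }
  if (any(successes < 0) || any(successes > trials)) {
    config_error("successes", "must satisfy 0 <= successes <= trials")
  }
  p <- successes / trials
  z2 <- z^2
  denom <- 1 + z2 / trials
  centre <- (p + z2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z2 / (4 * trials^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

metric_estimate <- function(metric, numerator, denominator, z = 1.96) {
  scale <- METRIC_SCALES[[metric]]
  f <- scale_factor(scale)
  if (denominator == 0) {
    return(tibble::tibble(
      metric = metric, numerator = numerator, denominator = denominator,
      point = NA_real_, ci_low = NA_real_, ci_high = NA_real_, scale = scale
    ))
  }
  ci <- wilson_ci(numerator, denominator, z)
  tibble::tibble(
    metric = metric,
    numerator = numerator,
    denominator = denominator,
    point = numerator / denominator * f,
    ci_low = ci[1, "low"] * f,
    ci_high = ci[1, "high"] * f,
    scale = scale
  )
}

join_decisions <- function(cases, decisions) {
  stopifnot(nrow(cases) == nrow(decisions))
  d <- dplyr::inner_join(
    cases,
    decisions[c("case_id", "final_recall", "human_reads", "arbitration_used")],
    by = "case_id"
  )
  if (nrow(d) != nrow(cases)) {
    schema_error("decisions are not aligned to cases by case_id")
  }
  d
}

metric_counts <- function(joined, metric) {
  detected <- joined$final_recall & joined$truth_screen_detected
  cancer <- joined$truth_screen_detected | joined$truth_interval
  switch(metric,
    CDR = c(sum(detected), nrow(joined)),
    PPV = c(sum(detected), sum(joined$final_recall)),
    RR = c(sum(joined$final_recall), nrow(joined)),
    SEN = c(sum(detected), sum(cancer)),
    SPEC = c(sum(!joined$final_recall & !cancer), sum(!cancer)),
    AR = c(sum(joined$arbitration_used), nrow(joined)),
    config_error("metric_name", paste0("unknown metric: ", metric))
  )
}

#' Compute a screening metric with its Wilson interval
#'
#' Metrics follow the screening conventions: CDR is recalled screen-detected
#' cancers per 1000 episodes; PPV is detected cancers as a percentage of
#' recalls; RR is recalls per 100 episodes; SEN counts detected
#' screen-detected cancers against all cancers (screen-detected or interval,
#' so interval cancers depress SEN equally for every simulated workflow);
#' SPEC is non-recalled non-cancers per 100 non-cancers; AR is arbitrations
#' per 100 episodes. A workflow "detects" a cancer only when it recalls a
#' screen-detected case — interval cancers are never countable as detections
#' in a retrospective replay.
#'
#' A zero denominator (e.g. PPV with no recalls) yields a flagged-undefined
#' estimate (`NA` point and interval), not an error.
#'
#' @param cases Cohort tibble.
#' @param decisions Decision tibble aligned to `cases` by `case_id`.
#' @param metric One of `"CDR"`, `"PPV"`, `"RR"`, `"SEN"`, `"SPEC"`, `"AR"`.
#' @param z Normal quantile for the Wilson interval.
#' @return One-row tibble: `metric`, `numerator`, `denominator`, `point`,
#'   `ci_low`, `ci_high`, `scale`.
#' @export
compute_metric <- function(cases, decisions, metric, z = 1.96) {
  joined <- join_decisions(cases, decisions)
  counts <- metric_counts(joined, metric)
  metric_estimate(metric, counts[1], counts[2], z)
}

#' Equally weighted pooling of per-centre estimates
#'
#' Arithmetic mean of the per-centre points, so each centre contributes
#' equally to the overall statistic regardless of its size.
#'
#' @param points Numeric vector of per-centre point estimates (length >= 1,
#'   no missing values).
#' @return The pooled point estimate.
#' @export
pool_equal_weight <- function(points) {
  if (length(points) == 0) {
    config_error("points", "needs at least one centre estimate")
  }
  if (any(is.na(points))) {
    config_error("points", "undefined estimates must be excluded before pooling")
  }
  mean(points)
}

#' Per-centre metric table with an equally weighted pooled row
#'
#' Computes `metric` within each centre and appends a `pooled` row whose
#' point is the equally weighted centre mean. Centres with an undefined
#' estimate (zero denominator) are excluded from pooling with a warning. The
#' pooled row's interval is left `NA` here; pipelines attach a stratified
#' bootstrap percentile interval (see [run_pipeline()]), since the Wilson
#' form does not apply to a mean of proportions.
#'
#' @inheritParams compute_metric
#' @return Tibble with a `centre` column (`"pooled"` for the pooled row).
#' @export
metric_by_centre <- function(cases, decisions, metric, z = 1.96) {
  joined <- join_decisions(cases, decisions)
  per <- lapply(split(joined, joined$centre_id), function(g) {
    counts <- metric_counts(g, metric)
    metric_estimate(metric, counts[1], counts[2], z)
  })
  out <- dplyr::bind_rows(per, .id = "centre")
  ok <- !is.na(out$point)
  if (!all(ok)) {
    warning(sprintf("excluding %d centre(s) with undefined %s from pooling",
                    sum(!ok), metric))
  }
  if (nrow(out) >= 2 && any(ok)) {
    pooled <- tibble::tibble(
      centre = "pooled", metric = metric,
      numerator = sum(out$numerator[ok]), denominator = sum(out$denominator[ok]),
      point = pool_equal_weight(out$point[ok]),
      ci_low = NA_real_, ci_high = NA_real_, scale = out$scale[1]
    )
    out <- dplyr::bind_rows(out, pooled)
  }
  out
}

#' Workload saving relative to double reading
#'
#' One unit of workload is one human reading event (first read, second read,
#' or arbitration read; AI opinions cost nothing). The saving is
#' `1 - total reads under the workflow / total reads under DR`, in percent,
#' so DR itself is the 100% baseline with saving 0.
#'
#' @param decisions_workflow Decision tibble for the evaluated workflow.
#' @param decisions_dr Decision tibble for standard DR on the same case set.
#' @return One-row tibble in the [compute_metric()] layout, with `numerator`
#'   and `denominator` holding the two read totals.
#' @export
workload_saving <- function(decisions_workflow, decisions_dr) {
  if (!setequal(decisions_workflow$case_id, decisions_dr$case_id)) {
    config_error("decisions", "both workflows must cover the same case set")
  }
  reads_w <- sum(decisions_workflow$human_reads)
  reads_dr <- sum(decisions_dr$human_reads)
  if (reads_dr == 0) {
    config_error("decisions_dr", "zero total reads under DR")
  }
  tibble::tibble(
    metric = "WORKLOAD_SAVING",
    numerator = reads_w, denominator = reads_dr,
    point = (1 - reads_w / reads_dr) * 100,
    ci_low = NA_real_, ci_high = NA_real_, scale = "percent"
  )
}

#' Standalone AI interval-cancer flag rate
#'
#' Percentage of interval-cancer cases the AI flags as suspicious, the
#' retrospective proxy for additional detection available to an
#' additional-reader workflow. Computed per centre with Wilson intervals and
#' pooled as the equally weighted centre mean; centres without interval
#' cancers are excluded from pooling with a warning.
#'
#' @param cases Cohort tibble.
#' @param z Normal quantile for the Wilson interval.
#' @return Tibble with a `centre` column (`"pooled"` for the pooled row).
#' @export
ic_flag_rate <- function(cases, z = 1.96) {
  per <- lapply(split(cases, cases$centre_id), function(g) {
    ic <- g[g$truth_interval, , drop = FALSE]
    metric_estimate("IC_FLAG_RATE", sum(ic$ai_recall), nrow(ic), z)
  })
  out <- dplyr::bind_rows(per, .id = "centre")
  ok <- !is.na(out$point)
  if (!all(ok)) {
    warning(sprintf("excluding %d centre(s) without interval cancers from pooling",
                    sum(!ok)))
  }
  if (nrow(out) >= 2 && any(ok)) {
    pooled <- tibble::tibble(
      centre = "pooled", metric = "IC_FLAG_RATE",
      numerator = sum(out$numerator[ok]), denominator = sum(out$denominator[ok]),
      point = pool_equal_weight(out$point[ok]),
      ci_low = NA_real_, ci_high = NA_real_, scale = "percent"
    )
    out <- dplyr::bind_rows(out, pooled)
  }
  out
}
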