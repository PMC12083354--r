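METRIC_DIRECTIONS <- c(CDR = "higher_better", PPV = "higher_better",
                       RR = "lower_better")

# Per-case numerator/denominator contributions of `metric` for one decision
# set; all supported metrics are functions of sums of these indicators, which
# is what makes the multinomial bootstrap below exact.
case_contrib <- function(joined, metric) {
  detected <- joined$final_recall & joined$truth_screen_detected
  cancer <- joined$truth_screen_detected | joined$truth_interval
  switch(metric,
    CDR = cbind(num = as.integer(detected), den = 1L),
    PPV = cbind(num = as.integer(detected), den = as.integer(joined$final_recall)),
    RR = cbind(num = as.integer(joined$final_recall), den = 1L),
    SEN = cbind(num = as.integer(detected), den = as.integer(cancer)),
    SPEC = cbind(num = as.integer(!joined$final_recall & !cancer),
                 den = as.integer(!cancer)),
    AR = cbind(num = as.integer(joined$arbitration_used), den = 1L),
    config_error("metric_name", paste0("unknown or untestable metric: ", metric))
  )
}

# Collapse per-case contributions to distinct profiles with counts.
contrib_profiles <- function(contrib) {
  key <- apply(contrib, 1, paste, collapse = "|")
  counts <- table(key)
  profiles <- do.call(rbind, strsplit(names(counts), "|", fixed = TRUE))
  storage.mode(profiles) <- "double"
  list(profiles = profiles, counts = as.numeric(counts), n = nrow(contrib))
}

# Resampling n cases with replacement is distributionally identical to a
# multinomial draw over the counts of distinct per-case contribution
# profiles; per centre this reduces a replicate to a K-cell draw (K small),
# so full-size cohorts bootstrap in seconds.
centre_boot_sums <- function(prof, n_boot) {
  draws <- stats::rmultinom(n_boot, size = prof$n, prob = prof$counts)
  # (n_boot x 4): replicate sums of num_dr, den_dr, num_w, den_w
  t(draws) %*% prof$profiles
}

# Stratified jackknife of the pooled ratio: removing one case only shifts its
# own centre's sums, and cases sharing a profile share a leave-one-out value,
# so the full jackknife costs one pass over the (few) distinct profiles.
jackknife_ratios <- function(profs) {
  totals <- lapply(profs, function(p) colSums(p$profiles * p$counts))
  pooled_from <- function(sums_list) {
    dr <- vapply(sums_list, function(s) if (s[2] > 0) s[1] / s[2] else NA_real_,
                 numeric(1))
    w <- vapply(sums_list, function(s) if (s[4] > 0) s[3] / s[4] else NA_real_,
                numeric(1))
    ok <- !is.na(dr) & !is.na(w)
    if (!any(ok) || mean(dr[ok]) == 0) return(NA_real_)
    mean(w[ok]) / mean(dr[ok])
  }
  vals <- numeric(0)
  wts <- numeric(0)
  for (cn in names(profs)) {
    p <- profs[[cn]]
    for (j in seq_len(nrow(p$profiles))) {
      loo <- totals
      loo[[cn]] <- totals[[cn]] - p$profiles[j, ]
      r <- pooled_from(loo)
      if (is.finite(r)) {
        vals <- c(vals, r)
        wts <- c(wts, p$counts[j])
      }
    }
  }
  list(values = vals, weights = wts)
}

# One-sided BCa-adjusted quantile of the bootstrap ratios (Efron's
# bias-corrected and accelerated percentile). Degenerate distributions
# (all replicates equal) fall back to the unadjusted quantile.
bca_quantile <- function(ratios, hat, jack, prob) {
  b <- length(ratios)
  p0 <- (sum(ratios < hat) + 0.5 * sum(ratios == hat)) / b
  p0 <- min(max(p0, 1 / (b + 1)), b / (b + 1))
  z0 <- stats::qnorm(p0)
  mbar <- sum(jack$weights * jack$values) / sum(jack$weights)
  d <- mbar - jack$values
  denom <- sum(jack$weights * d^2)
  a <- if (denom > 0) sum(jack$weights * d^3) / (6 * denom^1.5) else 0
  zq <- stats::qnorm(prob)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  quantile(ratios, adj, names = FALSE)
}

#' Bootstrap non-inferiority and gated superiority test
#'
#' Compares an AI workflow against standard double reading on one pooled
#' metric using a one-sided percentile bootstrap of the metric ratio
#' (workflow / DR). Cases are resampled with replacement within each centre
#' (stratified); each replicate recomputes the equally weighted pooled metric
#' for both workflows from the same resample, preserving the paired design.
#'
#' For `higher_better` metrics the workflow is non-inferior when the
#' `alpha`-quantile of the ratio exceeds `1 - margin`, and superior when that
#' quantile also exceeds 1. For `lower_better` metrics (recall rate) the
#' `1 - alpha` quantile must fall below `1 + margin` (below 1 for
#' superiority). Superiority is only evaluated when non-inferiority passes.
#'
#' With `variant = "bca"` (the default) the one-sided critical quantile is
#' bias-corrected and accelerated (Efron's BCa, with a stratified jackknife
#' over cases): the plain one-sided percentile bound is only first-order
#' accurate and is anticonservative for skewed ratio statistics when the
#' boundary event count is small, whereas the BCa bound is second-order
#' accurate and holds the test's size near `alpha` (the suite verifies this
#' by simulation at the margin boundary). `variant = "percentile"` gives the
#' unadjusted quantile.
#'
#' Replicates whose pooled DR metric is zero are skipped; if more than 1% are
#' skipped the comparison aborts with a diagnostic.
#'
#' @param cases Cohort tibble.
#' @param workflow `"sIR"` or `"DRT"`.
#' @param metric `"CDR"`, `"PPV"` or `"RR"`.
#' @param direction `"higher_better"` or `"lower_better"`; defaults to the
#'   metric's convention.
#' @param margin Relative non-inferiority margin (default 0.05).
#' @param alpha One-sided test level (default 0.05).
#' @param n_boot Number of bootstrap replicates (default 2000; use at least
#'   200 for reporting runs).
#' @param seed Integer seed; results are deterministic given it.
#' @param agree_recall Agreed-recall handling passed to both workflows.
#' @param variant `"bca"` (default) or `"percentile"`; see Details.
#' @return One-row tibble: `metric`, `workflow`, `direction`, `point_ratio`
#'   (full-sample pooled ratio, unrounded), `abs_diff` (on the reporting
#'   scale), `margin`, `alpha`, `n_boot`, `seed`, `critical_quantile`,
#'   `noninferior` (logical), `superior` (`"true"`, `"false"` or
#'   `"not_tested"`), `n_skipped`.
#' @export
bootstrap_compare <- function(cases, workflow = c("sIR", "DRT"),
                              metric = c("CDR", "PPV", "RR"),
                              direction = NULL,
                              margin = 0.05, alpha = 0.05,
                              n_boot = 2000, seed = 1L,
                              agree_recall = "direct_recall",
                              variant = c("bca", "percentile")) {
  workflow <- match.arg(workflow)
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  if (is.null(direction)) direction <- METRIC_DIRECTIONS[[metric]]
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  if (!is.numeric(margin) || margin <= 0) config_error("margin", "must be > 0")
  if (n_boot < 1) config_error("n_boot", "must be >= 1")
  if (nrow(cases) == 0) config_error("cases", "empty cohort")

  dec_dr <- decide_dr(cases, workflow_policy("DR", agree_recall))
  dec_w <- run_workflow(cases, workflow_policy(workflow, agree_recall))
  contrib <- cbind(case_contrib(join_decisions(cases, dec_dr), metric),
                   case_contrib(join_decisions(cases, dec_w), metric))
  by_centre <- lapply(split.data.frame(contrib, cases$centre_id), contrib_profiles)

  pooled_pair <- function(sums_list) {
    # sums_list: per centre a (replicates x 4) matrix of indicator sums
    dr <- sapply(sums_list, function(s) ifelse(s[, 2] > 0, s[, 1] / s[, 2], NA_real_))
    w <- sapply(sums_list, function(s) ifelse(s[, 4] > 0, s[, 3] / s[, 4], NA_real_))
    dr <- matrix(dr, ncol = length(sums_list))
    w <- matrix(w, ncol = length(sums_list))
    # a centre with an undefined denominator in either arm drops out of both
    # arms' pooling for that replicate, keeping the ratio comparable
    valid <- !is.na(dr) & !is.na(w)
    dr[!valid] <- NA_real_
    w[!valid] <- NA_real_
    cbind(dr = rowMeans(dr, na.rm = TRUE), w = rowMeans(w, na.rm = TRUE))
  }

  full <- pooled_pair(lapply(by_centre, function(p) {
    matrix(colSums(p$profiles * p$counts), nrow = 1)
  }))
  point_dr <- unname(full[1, "dr"])
  point_w <- unname(full[1, "w"])
  f <- scale_factor(METRIC_SCALES[[metric]])

  boots <- with_seed(seed, lapply(by_centre, centre_boot_sums, n_boot = n_boot))
  pooled <- pooled_pair(boots)
  usable <- is.finite(pooled[, "dr"]) & pooled[, "dr"] > 0 & is.finite(pooled[, "w"])
  n_skipped <- sum(!usable)
  if (n_skipped > 0.01 * n_boot) {
    stop(errorCondition(
      sprintf("%d of %d bootstrap replicates had a zero pooled DR %s; cohort too sparse for a ratio test",
              n_skipped, n_boot, metric),
      class = c("screenflow_bootstrap_error", "error", "condition")
    ))
  }
  ratios <- pooled[usable, "w"] / pooled[usable, "dr"]

  point_ratio <- point_w / point_dr
  crit <- function(prob) {
    if (variant == "bca") {
      bca_quantile(ratios, point_ratio, jackknife_ratios(by_centre), prob)
    } else {
      quantile(ratios, prob, names = FALSE)
    }
  }
  if (direction == "higher_better") {
    q <- crit(alpha)
    noninferior <- q > 1 - margin
    superior <- if (noninferior) q > 1 else NA
  } else {
    q <- crit(1 - alpha)
    noninferior <- q < 1 + margin
    superior <- if (noninferior) q < 1 else NA
  }

  tibble::tibble(
    metric = metric, workflow = workflow, direction = direction,
    point_ratio = point_ratio,
    abs_diff = (point_w - point_dr) * f,
    margin = margin, alpha = alpha, n_boot = n_boot, seed = as.integer(seed),
    critical_quantile = q,
    noninferior = noninferior,
    superior = if (is.na(superior)) "not_tested" else tolower(as.character(superior)),
    n_skipped = n_skipped
  )
}

#' Run the comparison battery over strata and workflows
#'
#' Applies [bootstrap_compare()] to each stratum of the requested
#' stratification schemes (plus `"overall"` for the whole cohort), for every
#' workflow and metric. CDR and PPV are tested as higher-better, RR as
#' lower-better. Workload saving is reported descriptively, never tested: if
#' requested it yields a `not_tested` row. Single-centre strata degenerate to
#' a simple bootstrap. Each (scheme, stratum, workflow, metric) cell gets its
#' own deterministic seed derived from `seed`.
#'
#' @param cases Cohort tibble.
#' @param workflows Character vector of workflows to compare against DR.
#' @param metrics Metrics to test (`"WORKLOAD_SAVING"` allowed but refused).
#' @param schemes Stratification schemes; `"overall"` means no stratification.
#' @param margin,alpha,n_boot,seed,agree_recall Passed to
#'   [bootstrap_compare()].
#' @param min_stratum Minimum stratum size to attempt a test; smaller strata
#'   are skipped with a warning.
#' @return Tibble of comparison rows with `scheme` and `stratum` columns.
#' @export
compare_all <- function(cases, workflows = c("sIR", "DRT"),
                        metrics = c("CDR", "PPV", "RR"),
                        schemes = "overall",
                        margin = 0.05, alpha = 0.05, n_boot = 2000,
                        seed = 1L, agree_recall = "direct_recall",
                        min_stratum = 50L) {
  out <- list()
  counter <- 0L
  for (scheme in schemes) {
    strata <- if (identical(scheme, "overall")) {
      list(overall = cases)
    } else {
      stratify(cases, scheme)$strata
    }
    for (stratum in names(strata)) {
      sub <- strata[[stratum]]
      for (wf in workflows) {
        for (m in metrics) {
          counter <- counter + 1L
          if (m %in% c("WORKLOAD_SAVING", "WORKLOAD")) {
            out[[length(out) + 1L]] <- tibble::tibble(
              scheme = scheme, stratum = stratum, metric = "WORKLOAD_SAVING",
              workflow = wf, direction = NA_character_, point_ratio = NA_real_,
              abs_diff = NA_real_, margin = margin, alpha = alpha,
              n_boot = n_boot, seed = NA_integer_,
              critical_quantile = NA_real_, noninferior = NA,
              superior = "not_tested", n_skipped = NA_integer_
            )
            next
          }
          if (nrow(sub) < min_stratum) {
            warning(sprintf("stratum %s/%s too small (%d cases); skipped",
                            scheme, stratum, nrow(sub)))
            next
          }
          res <- bootstrap_compare(sub, wf, m, margin = margin, alpha = alpha,
                                   n_boot = n_boot, seed = seed + counter,
                                   agree_recall = agree_recall)
          out[[length(out) + 1L]] <- tibble::tibble(scheme = scheme,
                                                    stratum = stratum, res)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
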