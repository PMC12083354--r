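#' Pipeline run configuration
#'
#' Exactly one cohort source must be given: a preset name, a
#' [cohort_params()] object, or a cohort CSV path. The seed is always
#' explicit so persisted configurations reproduce their runs.
#'
#' @param preset Preset name (currently `"three_centre"`), or `NULL`.
#' @param params A [cohort_params()] object, or `NULL`.
#' @param cohort_file Path to a cohort CSV (see [read_cohort()]), or `NULL`.
#' @param workflows AI workflows to evaluate against DR.
#' @param agree_recall Agreed-recall handling for every workflow.
#' @param schemes Stratification schemes for subgroup tables (in addition to
#'   the overall and per-centre tables always produced).
#' @param margin,alpha,n_boot Non-inferiority test settings.
#' @param seed Integer master seed for simulation and bootstrap.
#' @param projection A [projection_params()] object.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `screenflow_config`.
#' @export
run_config <- function(preset = NULL, params = NULL, cohort_file = NULL,
                       workflows = c("sIR", "DRT"),
                       agree_recall = "direct_recall",
                       schemes = c("age2", "density2", "ethnicity2"),
                       margin = 0.05, alpha = 0.05, n_boot = 2000,
                       seed = 1L,
                       projection = projection_params(),
                       out_dir = "screenflow-report") {
  sources <- c(preset = !is.null(preset), params = !is.null(params),
               cohort_file = !is.null(cohort_file))
  if (sum(sources) != 1) {
    config_error("cohort source",
                 "exactly one of preset, params, cohort_file must be set")
  }
  if (!is.null(preset) && !identical(preset, "three_centre")) {
    config_error("preset", paste0("unknown preset: ", preset))
  }
  if (!all(workflows %in% c("sIR", "DRT"))) {
    config_error("workflows", "must be drawn from {sIR, DRT}")
  }
  agree_recall <- match.arg(agree_recall, c("direct_recall", "arbitrate"))
  bad <- setdiff(schemes, STRATIFICATION_SCHEMES)
  if (length(bad)) config_error("schemes", paste0("unknown scheme(s): ",
                                                  paste(bad, collapse = ", ")))
  if (!is.numeric(margin) || margin <= 0) config_error("margin", "must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    config_error("alpha", "must lie in (0, 1)")
  }
  if (!is.numeric(n_boot) || n_boot < 1) config_error("n_boot", "must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    config_error("seed", "must be a single integer")
  }
  structure(
    list(preset = preset, params = params, cohort_file = cohort_file,
         workflows = workflows, agree_recall = agree_recall, schemes = schemes,
         margin = margin, alpha = alpha, n_boot = as.integer(n_boot),
         seed = as.integer(seed), projection = projection, out_dir = out_dir),
    class = "screenflow_config"
  )
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort_file)) {
    if (!file.exists(config$cohort_file)) {
      stop(errorCondition(paste0("cohort file not found: ", config$cohort_file),
                          class = c("screenflow_io_error", "error", "condition")))
    }
    return(read_cohort(config$cohort_file))
  }
  params <- if (!is.null(config$params)) {
    config$params
  } else {
    three_centre_preset(seed = config$seed)
  }
  generate_cohort(params)
}

characteristics_table <- function(cases) {
  centres <- c(sort(unique(cases$centre_id)))
  one_var <- function(variable) {
    value <- cohort_test_value(cases, variable)
    value[is.na(value)] <- "missing"
    rows <- lapply(c("all", centres), function(cn) {
      v <- if (cn == "all") value else value[cases$centre_id == cn]
      tab <- table(v)
      tibble::tibble(variable = variable, level = names(tab), centre = cn,
                     n = as.integer(tab),
                     percent = as.numeric(tab) / length(v) * 100)
    })
    dplyr::bind_rows(rows)
  }
  age_rows <- dplyr::bind_rows(lapply(c("all", centres), function(cn) {
    a <- if (cn == "all") cases$age_years else cases$age_years[cases$centre_id == cn]
    tibble::tibble(variable = "age", level = "mean (sd)", centre = cn,
                   n = length(a), percent = NA_real_,
                   mean = mean(a), sd = stats::sd(a))
  }))
  cat_rows <- dplyr::bind_rows(lapply(
    c("age_band", "density", "ethnicity", "year", "positives"), one_var))
  dplyr::bind_rows(age_rows, cat_rows)
}

round_display <- function(metrics_raw) {
  out <- metrics_raw
  for (col in c("point", "ci_low", "ci_high")) {
    out[[col]] <- round(out[[col]], 1)
  }
  out
}

# Percentile interval for the equally weighted pooled point of one metric,
# from the same stratified multinomial bootstrap used for testing.
pooled_bootstrap_ci <- function(cases, decisions, metric, n_boot, seed, z = 1.96) {
  alpha2 <- 2 * stats::pnorm(-abs(z))
  joined <- join_decisions(cases, decisions)
  contrib <- case_contrib(joined, metric)
  contrib <- cbind(contrib, contrib) # reuse the paired machinery, arms equal
  by_centre <- lapply(split.data.frame(contrib, cases$centre_id), contrib_profiles)
  boots <- with_seed(seed, lapply(by_centre, centre_boot_sums, n_boot = n_boot))
  vals <- sapply(boots, function(s) ifelse(s[, 2] > 0, s[, 1] / s[, 2], NA_real_))
  vals <- matrix(vals, ncol = length(by_centre))
  pooled <- rowMeans(vals, na.rm = TRUE)
  f <- scale_factor(METRIC_SCALES[[metric]])
  quantile(pooled[is.finite(pooled)], c(alpha2 / 2, 1 - alpha2 / 2), names = FALSE) * f
}

#' Run the full evaluation pipeline
#'
#' Simulates or loads the cohort, replays DR and the configured AI workflows,
#' and writes a report bundle to `config$out_dir`:
#'
#' * `cohort_characteristics.csv` - per-centre marginals with the
#'   between-centre test battery in `cohort_tests.csv`;
#' * `metrics_raw.csv` / `metrics_display.csv` - per-centre and pooled
#'   CDR/PPV/RR/SEN/SPEC/AR per workflow (unrounded and display-rounded; the
#'   pooled rows carry stratified-bootstrap percentile intervals), clinical
#'   metrics (CDR, PPV) additionally per subgroup stratum, plus per-centre
#'   and overall workload savings;
#' * `comparisons.csv` - bootstrap non-inferiority/superiority results
#'   overall and per configured scheme;
#' * `ic_flag_rate.csv` - standalone interval-cancer flag rates, per centre,
#'   pooled, and per subgroup scheme;
#' * `projection.csv` - flag rate, kappa, projected uplift and the net CDR
#'   change per workflow;
#' * `manifest.json` - configuration echo (seed, margin, alpha, n_boot,
#'   policy, schemes), package version and exclusion/skip counts.
#'
#' Reruns with the same configuration produce identical bundles. The exit
#' behaviour reflects validation only: scientific outcomes (failed tests,
#' inferior workflows) never raise errors.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a named list of the report tables.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "screenflow_config")) {
    config_error("config", "must be a run_config() object")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cases <- resolve_cohort(config)
  if (nrow(cases) == 0) {
    config_error("cohort", "empty cohort; nothing to evaluate")
  }

  characteristics <- characteristics_table(cases)
  tests <- cohort_tests(cases)
  tests_flat <- dplyr::bind_rows(lapply(seq_len(nrow(tests)), function(i) {
    pw <- tests$pairwise[[i]]
    base <- tibble::tibble(variable = tests$variable[i],
                           test_used = tests$test_used[i],
                           comparison = "overall",
                           p_value = tests$overall_p[i],
                           significant = tests$significant[i])
    if (nrow(pw)) {
      base <- dplyr::bind_rows(base, tibble::tibble(
        variable = tests$variable[i], test_used = tests$test_used[i],
        comparison = pw$pair, p_value = pw$p_value, significant = pw$significant
      ))
    }
    base
  }))

  all_workflows <- c("DR", config$workflows)
  decisions <- setNames(lapply(all_workflows, function(wf) {
    run_workflow(cases, workflow_policy(wf, config$agree_recall))
  }), all_workflows)

  metric_names <- c("CDR", "PPV", "RR", "SEN", "SPEC", "AR")
  metrics_raw <- list()
  seed_offset <- 0L
  metric_rows <- function(sub_cases, wf, m, scheme, stratum) {
    sub_dec <- decisions[[wf]][match(sub_cases$case_id, decisions[[wf]]$case_id), ]
    tab <- suppressWarnings(metric_by_centre(sub_cases, sub_dec, m))
    pooled_row <- tab$centre == "pooled" & !is.na(tab$point)
    if (any(pooled_row)) {
      seed_offset <<- seed_offset + 1L
      ci <- pooled_bootstrap_ci(sub_cases, sub_dec, m, n_boot = config$n_boot,
                                seed = config$seed + 1000L + seed_offset)
      tab$ci_low[pooled_row] <- ci[1]
      tab$ci_high[pooled_row] <- ci[2]
    }
    tibble::tibble(scheme = scheme, stratum = stratum, workflow = wf, tab)
  }
  for (wf in all_workflows) {
    for (m in metric_names) {
      metrics_raw[[length(metrics_raw) + 1L]] <-
        metric_rows(cases, wf, m, "overall", "overall")
    }
  }
  # subgroup clinical-impact rows (detection rate and PPV per stratum)
  for (scheme in config$schemes) {
    st <- stratify(cases, scheme)
    for (stratum in names(st$strata)) {
      sub <- st$strata[[stratum]]
      if (!nrow(sub)) next
      for (wf in all_workflows) {
        for (m in c("CDR", "PPV")) {
          metrics_raw[[length(metrics_raw) + 1L]] <-
            metric_rows(sub, wf, m, scheme, stratum)
        }
      }
    }
  }
  centre_ids <- sort(unique(cases$centre_id))
  for (wf in config$workflows) {
    per_centre <- lapply(centre_ids, function(cn) {
      ids <- cases$case_id[cases$centre_id == cn]
      sav <- workload_saving(
        decisions[[wf]][decisions[[wf]]$case_id %in% ids, ],
        decisions$DR[decisions$DR$case_id %in% ids, ]
      )
      tibble::tibble(scheme = "overall", stratum = "overall", workflow = wf,
                     centre = cn, sav)
    })
    per_centre <- dplyr::bind_rows(per_centre)
    pooled <- tibble::tibble(
      scheme = "overall", stratum = "overall",
      workflow = wf, centre = "pooled", metric = "WORKLOAD_SAVING",
      numerator = sum(per_centre$numerator), denominator = sum(per_centre$denominator),
      point = pool_equal_weight(per_centre$point),
      ci_low = NA_real_, ci_high = NA_real_, scale = "percent"
    )
    metrics_raw[[length(metrics_raw) + 1L]] <- dplyr::bind_rows(per_centre, pooled)
  }
  metrics_raw <- dplyr::bind_rows(metrics_raw)

  comparisons <- compare_all(
    cases, workflows = config$workflows,
    schemes = c("overall", config$schemes),
    margin = config$margin, alpha = config$alpha, n_boot = config$n_boot,
    seed = config$seed, agree_recall = config$agree_recall
  )

  ic_overall <- tibble::tibble(scheme = "overall", stratum = "overall",
                               ic_flag_rate(cases))
  ic_strata <- dplyr::bind_rows(lapply(config$schemes, function(scheme) {
    st <- stratify(cases, scheme)
    dplyr::bind_rows(lapply(names(st$strata), function(lv) {
      sub <- st$strata[[lv]]
      if (!nrow(sub) || !any(sub$truth_interval)) return(NULL)
      tibble::tibble(scheme = scheme, stratum = lv, ic_flag_rate(sub))
    }))
  }))
  ic_table <- dplyr::bind_rows(ic_overall, ic_strata)

  pooled_flag <- ic_overall$point[ic_overall$centre == "pooled"] / 100
  uplift <- project_uplift(pooled_flag, config$projection)
  pooled_cdr <- function(wf) {
    metrics_raw$point[metrics_raw$workflow == wf & metrics_raw$metric == "CDR" &
                        metrics_raw$centre == "pooled" &
                        metrics_raw$stratum == "overall"]
  }
  projection <- dplyr::bind_rows(lapply(config$workflows, function(wf) {
    decrease <- pooled_cdr("DR") - pooled_cdr(wf)
    tibble::tibble(
      workflow = wf,
      ic_flag_rate_fraction = pooled_flag,
      kappa = config$projection$kappa,
      projected_uplift_per_1000 = uplift,
      simulated_cdr_decrease_per_1000 = decrease,
      net_cdr_change_per_1000 = net_cdr_change(uplift, decrease)
    )
  }))

  excluded <- vapply(config$schemes, function(scheme) {
    nrow(stratify(cases, scheme)$excluded)
  }, integer(1))
  manifest <- list(
    package = "screenflow",
    version = as.character(utils::packageVersion("screenflow")),
    config = list(
      preset = config$preset,
      cohort_file = config$cohort_file,
      workflows = config$workflows,
      agree_recall = config$agree_recall,
      schemes = config$schemes,
      margin = config$margin,
      alpha = config$alpha,
      n_boot = config$n_boot,
      seed = config$seed,
      kappa = config$projection$kappa
    ),
    n_cases = nrow(cases),
    excluded_missing_by_scheme = as.list(excluded),
    bootstrap_replicates_skipped = sum(comparisons$n_skipped, na.rm = TRUE)
  )

  paths <- list(
    cohort_characteristics = characteristics,
    cohort_tests = tests_flat,
    metrics_raw = metrics_raw,
    metrics_display = round_display(metrics_raw),
    comparisons = comparisons,
    ic_flag_rate = ic_table,
    projection = projection
  )
  for (nm in names(paths)) {
    readr::write_csv(paths[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
                     na = "NA")
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, list(manifest = manifest, cases = cases)))
}
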