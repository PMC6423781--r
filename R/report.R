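# Run orchestration: simulate / classify / compare entry points with
# machine-readable reports. Every count in a report is re-derivable from the
# persisted per-student results file.

log_msg <- function(...) {
  message(sprintf("[msap] %s", sprintf(...)))
}

#' Build a run report for a classified cohort
#'
#' Summarises a classification run: input digest, status counts, self-report
#' vs MSAP percentages (denominator excluding non-responders), staged
#' attribution under the default order, the profile-category table, and
#' warnings. Each headline number carries a reproduction grade:
#' `exact_from_counts` for quantities determined by the per-student results
#' file, `estimator_only` for cluster-summary statistics whose value depends
#' on cluster composition, and `synthetic` when the cohort's cluster labels
#' are synthetic.
#'
#' @param cohort A cohort tibble.
#' @param results Matching `msap_results` (omit to classify with defaults).
#' @param cohort_path Optional path of the input file (hashed into the
#'   digest).
#' @param warnings Extra warning strings to carry in the report.
#' @return A list of class `msap_report`.
#' @export
run_report <- function(cohort, results = classify_cohort(cohort),
                       cohort_path = NULL, warnings = character()) {
  status_counts <- as.list(table(factor(results$status, levels = msap_statuses())))
  n_kept <- nrow(results) - status_counts$excluded
  attribution <- attribute_stages(results)
  report <- list(
    input = list(
      n_records = nrow(cohort),
      n_clusters = length(unique(cohort$cluster_id)),
      file = cohort_path,
      md5 = if (!is.null(cohort_path)) unname(tools::md5sum(cohort_path)) else NULL
    ),
    classification = list(
      status_counts = status_counts,
      self_report_percent = 100 * status_counts$self_reported_active / n_kept,
      msap_percent = 100 * (status_counts$self_reported_active +
                              status_counts$newly_identified) / n_kept,
      gap_percent = 100 * status_counts$newly_identified / n_kept,
      denominator = n_kept,
      grade = "exact_from_counts"
    ),
    attribution = attribution$counts,
    profile_categories = profile_breakdown(results),
    warnings = warnings
  )
  structure(report, class = "msap_report")
}

#' @export
print.msap_report <- function(x, ...) {
  cat(sprintf("MSAP run report: %d records, %d clusters\n",
              x$input$n_records, x$input$n_clusters))
  cat(sprintf("  self-report %.1f%% vs MSAP %.1f%% (gap %.1f points, n = %d)\n",
              x$classification$self_report_percent,
              x$classification$msap_percent,
              x$classification$gap_percent,
              x$classification$denominator))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a cohort to files
#'
#' Generates a synthetic cohort and writes `cohort.csv` and
#' `cohort_truth.csv` (the latent truth table) plus `simulate_log.json`
#' recording the seed and a digest of the configuration. Re-running with the
#' same configuration and seed reproduces the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `msap_sim_config`, a path to a YAML configuration, or
#'   `NULL` for the defaults.
#' @param seed Optional seed overriding the configuration's.
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = NULL, seed = NULL) {
  cfg <- if (is.null(config)) {
    simulation_config()
  } else if (is.character(config)) {
    read_simulation_config(config)
  } else {
    validate_simulation_config(config)
    config
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(cfg)
  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             truth = file.path(out_dir, "cohort_truth.csv"),
             log = file.path(out_dir, "simulate_log.json"))
  write_cohort(sim$cohort, paths[["cohort"]])
  readr::write_csv(sim$truth, paths[["truth"]], na = "")
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE) else x
  }), cfg_file)
  jsonlite::write_json(list(seed = cfg$seed,
                            n_records = nrow(sim$cohort),
                            n_clusters = cfg$n_clusters,
                            config_md5 = unname(tools::md5sum(cfg_file))),
                       paths[["log"]], auto_unbox = TRUE, pretty = TRUE)
  unlink(cfg_file)
  log_msg("simulated %d students in %d clusters (seed %d)",
          nrow(sim$cohort), cfg$n_clusters, cfg$seed)
  invisible(paths)
}

#' Classify a cohort file to per-student results and a report
#'
#' Reads a cohort file, classifies it, and writes `results.csv` (one row per
#' student) and `report.json` (the [run_report()]). Cohorts whose cluster
#' labels look synthetic (fixture round-robin) get a warning in the report
#' that cluster-summary statistics on them are estimator demonstrations.
#'
#' @param cohort_path Path to a cohort file readable by [read_cohort()].
#' @param out_dir Output directory.
#' @param policy Classification policy from [msap_policy()].
#' @param dialect Optional dialect for [read_cohort()].
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_classify <- function(cohort_path, out_dir, policy = msap_policy(),
                         dialect = NULL) {
  cohort <- read_cohort(cohort_path, dialect = dialect)
  results <- classify_cohort(cohort, policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  sizes <- table(cohort$cluster_id)
  if (length(sizes) > 1 && max(sizes) - min(sizes) <= 1) {
    warnings <- c(warnings,
                  "near-uniform cluster sizes suggest synthetic cluster labels; cluster-summary statistics are estimator demonstrations only")
  }
  report <- run_report(cohort, results, cohort_path = cohort_path,
                       warnings = warnings)
  paths <- c(results = file.path(out_dir, "results.csv"),
             report = file.path(out_dir, "report.json"))
  readr::write_csv(tibble::as_tibble(results), paths[["results"]], na = "")
  report_to_json(report, paths[["report"]])
  log_msg("classified %d students: self-report %.1f%%, MSAP %.1f%%",
          nrow(results), report$classification$self_report_percent,
          report$classification$msap_percent)
  invisible(paths)
}

#' Run a batch of group comparisons from a contrast specification
#'
#' Each contrast names a binary variable and two group predicates, all as R
#' expressions over the joined cohort + results columns (e.g. `variable =
#' 'sex == "female"'`, `group_a = 'status == "newly_identified"'`). Results
#' are written as long-format CSV and JSON.
#'
#' @param cohort_path Path to the cohort file.
#' @param results_path Path to the `results.csv` written by [cmd_classify()].
#' @param contrasts List of contrasts; each a list with string fields
#'   `variable`, `group_a`, `group_b` and optional `label_a`, `label_b`.
#'   Alternatively a path to a YAML file holding a `contrasts:` list.
#' @param out_dir Output directory.
#' @param mode `"pooled"` or `"welch"` variance mode.
#' @return The comparison tibble, invisibly (also written to
#'   `comparisons.csv`/`comparisons.json`).
#' @export
cmd_compare <- function(cohort_path, results_path, contrasts, out_dir,
                        mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  cohort <- read_cohort(cohort_path)
  results <- readr::read_csv(results_path, show_col_types = FALSE, progress = FALSE)
  if (is.character(contrasts) && length(contrasts) == 1) {
    contrasts <- yaml::read_yaml(contrasts)$contrasts
  }
  data <- join_results(cohort, results)
  rows <- lapply(contrasts, function(ct) {
    v <- eval_tidy(rlang::parse_expr(ct$variable), data)
    ga <- eval_tidy(rlang::parse_expr(ct$group_a), data)
    gb <- eval_tidy(rlang::parse_expr(ct$group_b), data)
    ga[is.na(ga)] <- FALSE
    gb[is.na(gb)] <- FALSE
    prev_a <- prevalence(data[ga, , drop = FALSE], !!rlang::parse_expr(ct$variable))
    prev_b <- prevalence(data[gb, , drop = FALSE], !!rlang::parse_expr(ct$variable))
    cmp <- cluster_summary_ttest(prev_a$clusters$percent, prev_b$clusters$percent,
                                 mode = mode,
                                 labels = c(ct$label_a %||% ct$group_a,
                                            ct$label_b %||% ct$group_b))
    cmp$variable <- ct$variable
    cmp$unadjusted_percent_a <- prev_a$unadjusted_percent
    cmp$unadjusted_percent_b <- prev_b$unadjusted_percent
    comparison_row(cmp)
  })
  out <- dplyr::bind_rows(rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out, file.path(out_dir, "comparisons.csv"), na = "")
  jsonlite::write_json(out, file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("wrote %d comparison(s) [%s t-test on cluster summaries]",
          nrow(out), mode)
  invisible(out)
}
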