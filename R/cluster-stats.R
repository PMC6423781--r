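# Prevalence estimation (pooled and cluster-summary adjusted), two-sample
# t-tests on cluster summaries, group comparisons and risk cross-tabulations.
#
# The design is the cluster-summary analysis standard for cluster-randomised
# trials with few clusters: compute one prevalence per cluster (school) and
# apply simple two-sample inference to the cluster-level values.

# Join a cohort with its classification for predicate evaluation.
#' Join a cohort with its classification results
#'
#' Convenience join used by the comparison operations so predicates can refer
#' to both raw fields (e.g. `sex`, `risk_perception`) and derived ones
#' (`status`, indicator columns).
#'
#' @param cohort A cohort tibble.
#' @param results The matching `msap_results`.
#' @return A tibble with one row per student and both sets of columns.
#' @export
join_results <- function(cohort, results) {
  dplyr::left_join(tibble::as_tibble(cohort),
                   tibble::as_tibble(results)[, setdiff(names(results), c("cluster_id", "sex"))],
                   by = "student_id")
}

#' Prevalence with pooled and cluster-summary estimates
#'
#' Computes the prevalence of a binary condition within an optional subset of
#' a cohort, with a complete-case denominator (records where the condition
#' evaluates to `NA` are dropped). Two estimates are returned: the unadjusted
#' (pooled) percent, `100 * numerator / denominator` across all clusters
#' combined, and the adjusted percent, the unweighted mean of the per-cluster
#' percents over clusters with a non-empty denominator — the cluster-summary
#' estimate appropriate for school-based sampling.
#'
#' @param data A cohort tibble, or a cohort joined with classification results
#'   via [join_results()].
#' @param variable Expression in the columns of `data` evaluating to logical;
#'   `NA` marks a record as missing for this variable.
#' @param subset Optional logical expression restricting the records analysed.
#' @param cluster Column holding the cluster identifier (default
#'   `cluster_id`).
#' @return A list of class `msap_prevalence`: `variable`, `numerator`,
#'   `denominator`, `unadjusted_percent`, `adjusted_percent`, `clusters`
#'   (tibble `cluster_id`, `numerator`, `denominator`, `percent`) and
#'   `clusters_used`.
#' @export
#' @examples
#' fx <- build_inpaper_fixture()
#' prevalence(fx, hiv_result == "positive", subset = self_report_active == "yes")
prevalence <- function(data, variable, subset = NULL, cluster = "cluster_id") {
  data <- tibble::as_tibble(data)
  v <- eval_tidy(enquo(variable), data)
  var_label <- rlang::as_label(enquo(variable))
  keep <- eval_tidy(enquo(subset), data)
  if (is.null(keep)) keep <- rep(TRUE, nrow(data))
  keep[is.na(keep)] <- FALSE
  v <- v[keep]
  cl <- data[[cluster]][keep]
  ok <- !is.na(v)
  if (!any(ok)) {
    abort(sprintf("no complete cases for '%s' in the requested subset", var_label),
          class = "msap_estimation_error")
  }
  per_cluster <- tibble::tibble(cluster_id = cl[ok], positive = v[ok]) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(numerator = sum(.data$positive),
                     denominator = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percent = 100 * .data$numerator / .data$denominator)
  structure(list(
    variable = var_label,
    numerator = sum(v[ok]),
    denominator = sum(ok),
    unadjusted_percent = 100 * sum(v[ok]) / sum(ok),
    adjusted_percent = mean(per_cluster$percent),
    clusters = per_cluster,
    clusters_used = nrow(per_cluster)
  ), class = "msap_prevalence")
}

#' @export
print.msap_prevalence <- function(x, ...) {
  cat(sprintf("%s: %d/%d = %.1f%% unadjusted; %.1f%% adjusted (%d clusters)\n",
              x$variable, x$numerator, x$denominator,
              x$unadjusted_percent, x$adjusted_percent, x$clusters_used))
  invisible(x)
}

#' Two-sample t-test on cluster-level summaries
#'
#' Compares two groups through their vectors of cluster-level percents with a
#' two-sided two-independent-sample t-test: pooled-variance Student form by
#' default, Welch optional, and a paired variant for contrasts between
#' subgroups measured in the same clusters.
#'
#' @param values_a,values_b Numeric vectors of per-cluster percents (one entry
#'   per cluster; at least two clusters per group).
#' @param mode `"pooled"` (default) or `"welch"`.
#' @param paired Treat the vectors as paired by cluster (requires equal
#'   lengths). Not the default: contrasts are conventionally analysed as
#'   independent samples of cluster summaries.
#' @param labels Length-2 character vector naming the groups.
#' @return A list of class `msap_comparison`: group labels, group means
#'   (`adjusted_percent_a/b`), `t_statistic`, `degrees_of_freedom`,
#'   `p_value`, `variance_mode`, `paired`.
#' @export
#' @examples
#' cluster_summary_ttest(c(10, 20, 30), c(40, 50, 60))
cluster_summary_ttest <- function(values_a, values_b,
                                  mode = c("pooled", "welch"),
                                  paired = FALSE,
                                  labels = c("group_a", "group_b")) {
  mode <- match.arg(mode)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs summaries from at least 2 clusters",
          class = "msap_inference_error")
  }
  if (paired && length(values_a) != length(values_b)) {
    abort("paired comparison requires the same clusters in both groups",
          class = "msap_inference_error")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = (mode == "pooled"),
                      paired = paired, alternative = "two.sided")
  structure(list(
    group_a = labels[[1]], group_b = labels[[2]],
    adjusted_percent_a = mean(values_a),
    adjusted_percent_b = mean(values_b),
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    variance_mode = mode,
    paired = paired,
    n_clusters = c(length(values_a), length(values_b))
  ), class = "msap_comparison")
}

#' @export
print.msap_comparison <- function(x, ...) {
  cat(sprintf("%s (%.1f%%) vs %s (%.1f%%): t = %.3f, df = %.2f, p = %.4f [%s%s]\n",
              x$group_a, x$adjusted_percent_a, x$group_b, x$adjusted_percent_b,
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$variance_mode,
              if (isTRUE(x$paired)) ", paired" else ""))
  invisible(x)
}

#' Compare two groups on a binary variable via cluster summaries
#'
#' Builds, for each group, the per-cluster prevalence of `variable` (complete
#' cases only), then runs [cluster_summary_ttest()] on the two cluster-percent
#' vectors. Both pooled (unadjusted) and cluster-mean (adjusted) percents are
#' reported for each group.
#'
#' @param cohort A cohort tibble.
#' @param results The matching `msap_results` (omit to classify with
#'   defaults).
#' @param variable Logical expression over cohort/result columns (`NA` =
#'   missing for this variable).
#' @param group_a,group_b Logical expressions selecting the two groups.
#' @param labels Length-2 character vector naming the groups; defaults to the
#'   deparsed predicates.
#' @inheritParams cluster_summary_ttest
#' @return An `msap_comparison` augmented with `variable`,
#'   `unadjusted_percent_a/b`, and the per-group `msap_prevalence` objects in
#'   `$prevalence`.
#' @export
#' @examples
#' fx <- build_inpaper_fixture()
#' res <- classify_cohort(fx)
#' compare_groups(fx, res, sex == "female",
#'                status == "newly_identified",
#'                status == "self_reported_active")
compare_groups <- function(cohort, results = classify_cohort(cohort),
                           variable, group_a, group_b,
                           mode = c("pooled", "welch"), paired = FALSE,
                           labels = NULL) {
  mode <- match.arg(mode)
  data <- join_results(cohort, results)
  q_var <- enquo(variable)
  q_a <- enquo(group_a)
  q_b <- enquo(group_b)
  labels <- labels %||% c(rlang::as_label(q_a), rlang::as_label(q_b))
  prev_a <- prevalence(data, !!q_var, subset = !!q_a)
  prev_b <- prevalence(data, !!q_var, subset = !!q_b)
  out <- cluster_summary_ttest(prev_a$clusters$percent, prev_b$clusters$percent,
                               mode = mode, paired = paired, labels = labels)
  out$variable <- prev_a$variable
  out$unadjusted_percent_a <- prev_a$unadjusted_percent
  out$unadjusted_percent_b <- prev_b$unadjusted_percent
  out$prevalence <- list(a = prev_a, b = prev_b)
  out
}

#' Tidy a comparison into one row
#'
#' @param x An `msap_comparison`.
#' @return A one-row tibble suitable for binding into a long report.
#' @export
comparison_row <- function(x) {
  tibble::tibble(
    variable = x$variable %||% NA_character_,
    group_a = x$group_a, group_b = x$group_b,
    unadjusted_percent_a = x$unadjusted_percent_a %||% NA_real_,
    unadjusted_percent_b = x$unadjusted_percent_b %||% NA_real_,
    adjusted_percent_a = x$adjusted_percent_a,
    adjusted_percent_b = x$adjusted_percent_b,
    t_statistic = x$t_statistic,
    degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value,
    variance_mode = x$variance_mode
  )
}

#' Risk-perception cross-tabulation by group
#'
#' Tabulates the 4-level risk-perception item (no risk / low / some / high)
#' within each requested group, with complete-case denominators. With
#' `collapse = TRUE` the levels are collapsed to a binary no-risk vs at-risk
#' (= low, some or high) table.
#'
#' @param cohort A cohort tibble.
#' @param results Matching `msap_results` (omit to classify with defaults).
#' @param groups Named list of logical expressions (quosures created with
#'   [rlang::quos()], or plain strings parsed as expressions) selecting the
#'   groups to tabulate.
#' @param collapse Collapse to no-risk vs at-risk.
#' @return A tibble: `group`, `category`, `n`, `N` (group complete cases),
#'   `percent`.
#' @export
#' @examples
#' fx <- build_inpaper_fixture()
#' res <- classify_cohort(fx)
#' risk_crosstab(fx, res,
#'               groups = rlang::quos(active = status == "self_reported_active",
#'                                    newly = status == "newly_identified"))
risk_crosstab <- function(cohort, results = classify_cohort(cohort),
                          groups, collapse = FALSE) {
  data <- join_results(cohort, results)
  levels4 <- risk_levels()
  rows <- lapply(names(groups), function(label) {
    g <- groups[[label]]
    keep <- if (is.character(g)) {
      eval_tidy(rlang::parse_expr(g), data)
    } else {
      eval_tidy(g, data)
    }
    keep[is.na(keep)] <- FALSE
    rp <- data$risk_perception[keep]
    rp <- rp[!is.na(rp)]
    if (collapse) {
      cat_levels <- c("no_risk", "at_risk")
      rp <- ifelse(rp == "no_risk", "no_risk", "at_risk")
    } else {
      cat_levels <- levels4
    }
    n <- unname(vapply(cat_levels, function(l) sum(rp == l), integer(1)))
    tibble::tibble(group = label, category = cat_levels, n = n,
                   N = length(rp),
                   percent = if (length(rp) > 0) 100 * n / length(rp) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
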