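# MSAP classification: indicator derivation, per-student status, staged
# attribution and the mutually exclusive profile-combination breakdown.

#' Classification policy options
#'
#' @param missing_self_report How to classify a student whose self-report is
#'   missing but who has at least one positive indicator: `"newly_identified"`
#'   (default; the profile aims to identify the maximum number of possibly
#'   active students) or `"excluded"` (strict: only an explicit "no" can be
#'   overturned).
#' @param include_hiv Whether a positive HIV result counts as an indicator of
#'   sexual activity. Defaults to `TRUE`; setting `FALSE` supports a
#'   sensitivity analysis in which HIV positives (possibly acquired by
#'   vertical transmission) are not treated as evidence of sexual activity.
#' @return A policy list used by [classify_cohort()].
#' @export
msap_policy <- function(missing_self_report = c("newly_identified", "excluded"),
                        include_hiv = TRUE) {
  missing_self_report <- match.arg(missing_self_report)
  stopifnot(is.logical(include_hiv), length(include_hiv) == 1)
  list(missing_self_report = missing_self_report, include_hiv = include_hiv)
}

#' Derive the STI symptom composite
#'
#' Combines the three symptomatic-screen items used in South African public
#' health care (genital/urethral discharge; genital sore or ulcer; pain on
#' urination) into one ternary variable: `"yes"` if any item is yes, `"no"`
#' if all three are no, and `NA` if no item is yes but at least one is
#' missing.
#'
#' @param discharge,sore_ulcer,dysuria Character vectors with values
#'   `"yes"`/`"no"`/`NA`.
#' @return Character vector (`"yes"`/`"no"`/`NA`) of the same length.
#' @export
#' @examples
#' derive_sti_symptom("no", "yes", "no")     # "yes"
#' derive_sti_symptom("no", NA, "no")        # NA: could be either
derive_sti_symptom <- function(discharge, sore_ulcer, dysuria) {
  m <- cbind(discharge == "yes", sore_ulcer == "yes", dysuria == "yes")
  any_yes <- rowSums(m, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  out <- ifelse(any_yes, "yes", ifelse(any_na, NA_character_, "no"))
  as.character(out)
}

# Logical indicator matrix (n x 5); missing fields never contribute a positive.
indicator_matrix <- function(cohort, policy = msap_policy()) {
  sti <- derive_sti_symptom(cohort$symptom_discharge, cohort$symptom_sore_ulcer,
                            cohort$symptom_dysuria)
  m <- cbind(
    HIV         = !is.na(cohort$hiv_result) & cohort$hiv_result == "positive",
    HSV2        = !is.na(cohort$hsv2_result) & cohort$hsv2_result == "positive",
    PREG_TEST   = !is.na(cohort$pregnancy_test) & cohort$pregnancy_test == "positive",
    EVER_PREG   = !is.na(cohort$ever_pregnant_or_made_pregnant) &
                  cohort$ever_pregnant_or_made_pregnant == "yes",
    STI_SYMPTOM = !is.na(sti) & sti == "yes"
  )
  if (!policy$include_hiv) m[, "HIV"] <- FALSE
  m
}

#' Classify every student in a cohort
#'
#' Applies the MSAP rule to each record. A student's positive-indicator set
#' contains HIV if the HIV test is positive, HSV2 if the HSV-2 test is
#' positive, PREG_TEST if the urine pregnancy test is positive, EVER_PREG if
#' the student reports a prior pregnancy or having made someone pregnant, and
#' STI_SYMPTOM if the symptom composite is yes. Status is then:
#'
#' * `self_reported_active` — self-report is yes;
#' * `newly_identified` — self-report is no and the indicator set is
#'   non-empty (also the default for missing self-report with a positive
#'   indicator, see [msap_policy()]);
#' * `not_active` — self-report is no and the indicator set is empty;
#' * `excluded` — self-report is missing and the indicator set is empty
#'   (non-responders carrying no evidence either way).
#'
#' @param cohort A validated cohort tibble.
#' @param policy A policy list from [msap_policy()].
#' @return A tibble of class `msap_results` with one row per student:
#'   `student_id`, `cluster_id`, `sex`, `status`, one logical column per
#'   indicator, `n_positive`, and `profile_category` (the canonical
#'   combination label, set only for newly identified students).
#' @export
#' @examples
#' res <- classify_cohort(build_inpaper_fixture())
#' table(res$status)
classify_cohort <- function(cohort, policy = msap_policy()) {
  validate_cohort(cohort)
  m <- indicator_matrix(cohort, policy)
  n_pos <- rowSums(m)
  sr <- cohort$self_report_active
  status <- ifelse(
    !is.na(sr) & sr == "yes", "self_reported_active",
    ifelse(!is.na(sr) & sr == "no",
           ifelse(n_pos > 0, "newly_identified", "not_active"),
           ifelse(n_pos > 0, policy$missing_self_report, "excluded"))
  )
  res <- tibble::tibble(
    student_id = cohort$student_id,
    cluster_id = cohort$cluster_id,
    sex = cohort$sex,
    status = status
  )
  res <- dplyr::bind_cols(res, tibble::as_tibble(m))
  res$n_positive <- as.integer(n_pos)
  res$profile_category <- ifelse(status == "newly_identified",
                                 profile_labels(m), NA_character_)
  structure(res, class = c("msap_results", class(res)))
}

#' Classify a single student record
#'
#' Convenience wrapper around [classify_cohort()] for one record.
#'
#' @param record A one-row data frame with the cohort columns.
#' @inheritParams classify_cohort
#' @return A list with `student_id`, `status`, `positive_indicators`
#'   (character vector), and `profile_category` (or `NA`).
#' @export
classify_student <- function(record, policy = msap_policy()) {
  res <- classify_cohort(as_cohort(tibble::as_tibble(record)), policy)
  ind <- msap_indicators()
  list(
    student_id = res$student_id[[1]],
    status = res$status[[1]],
    positive_indicators = ind[unlist(res[1, ind])],
    profile_category = res$profile_category[[1]]
  )
}

#' Canonical profile-category label for an indicator set
#'
#' Singleton sets render as `"Only <label>"`; larger sets render as the member
#' labels joined by `"*"` in the canonical indicator order (HIV, HSV-2,
#' pregnancy test, ever pregnant, STI symptom). Labels are mutually exclusive
#' and exhaustive over non-empty indicator sets.
#'
#' @param indicators Character vector: a non-empty subset of
#'   [msap_indicators()].
#' @return The label string.
#' @export
#' @examples
#' profile_category(c("HIV"))          # "Only HIV"
#' profile_category(c("HSV2", "HIV"))  # "HIV*HSV-2"
profile_category <- function(indicators) {
  ind <- msap_indicators()
  if (length(indicators) == 0) {
    abort("profile_category requires a non-empty indicator set",
          class = "msap_contract_error")
  }
  if (!all(indicators %in% ind)) {
    abort(sprintf("unknown indicator(s): %s",
                  paste(setdiff(indicators, ind), collapse = ", ")),
          class = "msap_contract_error")
  }
  members <- ind[ind %in% indicators]
  if (length(members) == 1) {
    paste0("Only ", indicator_labels[[members]])
  } else {
    paste(indicator_labels[members], collapse = "*")
  }
}

# Vectorised labels from a logical indicator matrix; "" for empty rows.
profile_labels <- function(m) {
  apply(m, 1, function(row) {
    if (!any(row)) return(NA_character_)
    profile_category(colnames(m)[row])
  })
}

#' Staged attribution of newly identified students
#'
#' Attributes each newly identified student to the first indicator, in a fixed
#' order, that is positive for them, yielding the incremental contribution of
#' each indicator when the profile is built up one variable at a time. Stage
#' counts always sum to the number of newly identified students; the count at
#' the first stage equals that indicator's marginal count.
#'
#' @param results An `msap_results` tibble (any rows whose status is not
#'   `newly_identified` are ignored).
#' @param order Permutation of [msap_indicators()] giving the staging order.
#'   The default follows the order in which the profile variables are
#'   conventionally listed: HIV, HSV-2, pregnancy test, ever pregnant, STI
#'   symptom.
#' @return A list of class `msap_attribution` with `order`, `counts` (tibble:
#'   `stage`, `indicator`, `n`, `percent` of newly identified), and `students`
#'   (tibble: `student_id`, `attribution_stage`).
#' @export
#' @examples
#' res <- classify_cohort(build_inpaper_fixture())
#' attribute_stages(res)$counts
attribute_stages <- function(results, order = msap_indicators()) {
  ind <- msap_indicators()
  if (length(order) != length(ind) || !setequal(order, ind) || anyDuplicated(order)) {
    abort("order must be a permutation of the five MSAP indicators",
          class = "msap_config_error")
  }
  newly <- results[results$status == "newly_identified", , drop = FALSE]
  m <- as.matrix(newly[, order, drop = FALSE])
  stage_idx <- apply(m, 1, function(row) which(row)[1])
  students <- tibble::tibble(
    student_id = newly$student_id,
    attribution_stage = order[stage_idx]
  )
  n_total <- nrow(newly)
  counts <- tibble::tibble(
    stage = seq_along(order),
    indicator = order,
    n = as.integer(tabulate(stage_idx, nbins = length(order)))
  )
  counts$percent <- if (n_total > 0) 100 * counts$n / n_total else rep(NA_real_, nrow(counts))
  structure(list(order = order, counts = counts, students = students,
                 n_newly_identified = n_total),
            class = "msap_attribution")
}

#' @export
print.msap_attribution <- function(x, ...) {
  cat("Staged attribution of", x$n_newly_identified, "newly identified students\n")
  cat("Order:", paste(x$order, collapse = " -> "), "\n")
  print(x$counts)
  invisible(x)
}

#' Profile-combination breakdown of newly identified students
#'
#' Tabulates the mutually exclusive indicator combinations (profile
#' categories) among newly identified students, overall and by sex.
#'
#' @param results An `msap_results` tibble.
#' @return A tibble: `profile_category`, `n_indicators`, `n`, `percent` (of
#'   newly identified), `n_male`, `n_female`, ordered by decreasing `n`.
#' @export
profile_breakdown <- function(results) {
  newly <- results[results$status == "newly_identified", , drop = FALSE]
  n_total <- nrow(newly)
  out <- newly |>
    dplyr::count(.data$profile_category, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$profile_category)
  sex_n <- newly |>
    dplyr::count(.data$profile_category, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (col in c("n_male", "n_female")) {
    if (!col %in% names(sex_n)) sex_n[[col]] <- 0L
  }
  out <- dplyr::left_join(out, sex_n[, c("profile_category", "n_male", "n_female")],
                          by = "profile_category")
  out$n_indicators <- nchar(gsub("[^*]", "", out$profile_category)) + 1L
  out$n_indicators[startsWith(out$profile_category, "Only ")] <- 1L
  out$percent <- if (n_total > 0) 100 * out$n / n_total else NA_real_
  out[, c("profile_category", "n_indicators", "n", "percent", "n_male", "n_female")]
}
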