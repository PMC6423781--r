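# Participant flow diagram: self-report split, then sex, with per-indicator
# numerators and complete-case denominators in each cell.

#' Build the participant flow diagram
#'
#' Summarises a classified cohort the way a participant flow diagram presents
#' it: total enrolled; non-responders excluded (missing self-report, no
#' positive indicator); the self-report split (active / not active), each
#' split by sex; and, within each of the four cells, the numerator and
#' complete-case denominator of every MSAP indicator. Within the
#' not-active-by-self-report cells the count of newly identified students is
#' also recorded.
#'
#' @param cohort A validated cohort tibble.
#' @param results The matching `msap_results` from [classify_cohort()]. If
#'   omitted, the cohort is classified with the default policy.
#' @return A list of class `msap_flow`: `total`, `excluded`,
#'   `missing_self_report_positive` (students with missing self-report routed
#'   by policy), and `cells`, a tibble with one row per (self-report group,
#'   sex, indicator): `group`, `sex`, `n_cell`, `indicator`, `numerator`,
#'   `denominator`, `newly_identified`.
#' @export
#' @examples
#' flow <- build_flow_diagram(build_inpaper_fixture())
#' subset(flow$cells, group == "not_active" & indicator == "HIV")
build_flow_diagram <- function(cohort, results = classify_cohort(cohort)) {
  stopifnot(nrow(cohort) == nrow(results))
  sti <- derive_sti_symptom(cohort$symptom_discharge, cohort$symptom_sore_ulcer,
                            cohort$symptom_dysuria)
  field_yes <- list(
    HIV         = cohort$hiv_result == "positive",
    HSV2        = cohort$hsv2_result == "positive",
    PREG_TEST   = cohort$pregnancy_test == "positive",
    EVER_PREG   = cohort$ever_pregnant_or_made_pregnant == "yes",
    STI_SYMPTOM = sti == "yes"
  )
  sr <- cohort$self_report_active
  group <- ifelse(!is.na(sr) & sr == "yes", "self_reported_active",
                  ifelse(!is.na(sr) & sr == "no", "not_active", "missing"))
  cells <- list()
  for (g in c("self_reported_active", "not_active")) {
    for (s in c("male", "female")) {
      in_cell <- group == g & cohort$sex == s
      n_cell <- sum(in_cell)
      newly <- sum(in_cell & results$status == "newly_identified")
      for (ind in msap_indicators()) {
        v <- field_yes[[ind]][in_cell]
        cells[[length(cells) + 1L]] <- tibble::tibble(
          group = g, sex = s, n_cell = n_cell, indicator = ind,
          numerator = sum(v, na.rm = TRUE),
          denominator = sum(!is.na(v)),
          newly_identified = newly
        )
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  structure(list(
    total = nrow(cohort),
    excluded = sum(results$status == "excluded"),
    missing_self_report_positive = sum(group == "missing" &
                                         results$status != "excluded"),
    cells = cells
  ), class = "msap_flow")
}

#' @export
print.msap_flow <- function(x, ...) {
  cat("MSAP flow diagram:", x$total, "enrolled,", x$excluded, "excluded\n")
  groups <- x$cells |>
    dplyr::distinct(.data$group, .data$sex, .data$n_cell, .data$newly_identified)
  print(groups)
  invisible(x)
}

#' Export a flow diagram as JSON
#'
#' @param flow An `msap_flow` object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
flow_to_json <- function(flow, path = NULL) {
  payload <- list(
    total = flow$total,
    excluded = flow$excluded,
    missing_self_report_positive = flow$missing_self_report_positive,
    cells = flow$cells
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export a flow diagram as Graphviz DOT
#'
#' Renders the enrolment -> self-report split -> sex cell structure as a DOT
#' digraph, one node per cell with its indicator numerators/denominators.
#'
#' @inheritParams flow_to_json
#' @return The DOT source as a character string, invisibly when written.
#' @export
flow_to_dot <- function(flow, path = NULL) {
  esc <- function(s) gsub('"', '\\\\"', s)
  node_label <- function(g, s) {
    rows <- flow$cells[flow$cells$group == g & flow$cells$sex == s, ]
    lines <- sprintf("%s: %d/%d", indicator_labels[rows$indicator],
                     rows$numerator, rows$denominator)
    header <- sprintf("%s %s (n=%d)", esc(g), s, rows$n_cell[1])
    if (g == "not_active") {
      header <- paste0(header, sprintf("\\nnewly identified: %d",
                                       rows$newly_identified[1]))
    }
    paste(c(header, lines), collapse = "\\n")
  }
  ids <- expand.grid(sex = c("male", "female"),
                     group = c("self_reported_active", "not_active"),
                     stringsAsFactors = FALSE)
  nodes <- sprintf('  "%s_%s" [shape=box, label="%s"];',
                   ids$group, ids$sex,
                   mapply(node_label, ids$group, ids$sex))
  edges <- c(
    sprintf('  "enrolled" -> "excluded" [label="%d"];', flow$excluded),
    '  "enrolled" -> "self_reported_active";',
    '  "enrolled" -> "not_active";',
    sprintf('  "%s" -> "%s_%s";', ids$group, ids$group, ids$sex)
  )
  dot <- paste(c(
    "digraph msap_flow {",
    sprintf('  "enrolled" [shape=box, label="Enrolled (n=%d)"];', flow$total),
    sprintf('  "excluded" [shape=box, label="Excluded (n=%d)"];', flow$excluded),
    sprintf('  "self_reported_active" [shape=box, label="Self-reported active"];'),
    sprintf('  "not_active" [shape=box, label="Self-reported not active"];'),
    nodes, edges, "}"), collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}
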