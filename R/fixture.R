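# Deterministic fixture cohort reconstructed from published marginal counts:
# group sizes and per-sex indicator numerators/denominators for the
# self-report split, the exact indicator combinations of the newly identified
# students, age-band counts per cell, and risk-perception distributions.
#
# Only marginals are published for the self-reported-active stratum, so
# indicator overlaps there are one documented deterministic completion
# (positives assigned to distinct students, which the marginal totals
# permit). Cluster membership is synthetic (round-robin over 14 schools):
# real school compositions are unpublished, so cluster-level statistics on
# the fixture are estimator demonstrations, not reproductions.

# Indicator combinations among the newly identified, with per-sex counts.
fixture_combo_table <- function() {
  combo <- function(indicators, male, female) {
    tibble::tibble(indicators = list(indicators), male = male, female = female)
  }
  dplyr::bind_rows(
    combo("STI_SYMPTOM", 51, 42),
    combo("HIV", 8, 24),
    combo("HSV2", 13, 38),
    combo("PREG_TEST", 0, 15),
    combo("EVER_PREG", 2, 5),
    combo(c("HIV", "STI_SYMPTOM"), 0, 2),
    combo(c("HIV", "PREG_TEST"), 0, 1),
    combo(c("EVER_PREG", "STI_SYMPTOM"), 0, 1),
    combo(c("HIV", "EVER_PREG"), 0, 4),
    combo(c("HSV2", "STI_SYMPTOM"), 1, 4),
    combo(c("HIV", "HSV2"), 0, 5),
    combo(c("HSV2", "PREG_TEST"), 0, 3),
    combo(c("HSV2", "EVER_PREG"), 0, 2),
    combo(c("HSV2", "PREG_TEST", "EVER_PREG"), 0, 1),
    combo(c("HIV", "HSV2", "PREG_TEST", "STI_SYMPTOM"), 0, 1)
  )
}

# Published per-cell indicator margins: numerator and complete-case
# denominator for each (self-report group, sex, indicator). NA denominator =
# structurally not applicable.
fixture_margin_constants <- function() {
  row <- function(group, sex, variable, numerator, denominator) {
    tibble::tibble(group = group, sex = sex, variable = variable,
                   numerator = numerator, denominator = denominator)
  }
  dplyr::bind_rows(
    row("self_reported_active", "male", "HIV", 10, 619),
    row("self_reported_active", "male", "HSV2", 24, 619),
    row("self_reported_active", "male", "PREG_TEST", 0, 0),
    row("self_reported_active", "male", "EVER_PREG", 36, 73),
    row("self_reported_active", "male", "STI_SYMPTOM", 89, 614),
    row("self_reported_active", "female", "HIV", 51, 447),
    row("self_reported_active", "female", "HSV2", 94, 447),
    row("self_reported_active", "female", "PREG_TEST", 28, 444),
    row("self_reported_active", "female", "EVER_PREG", 134, 140),
    row("self_reported_active", "female", "STI_SYMPTOM", 60, 444),
    row("not_active", "male", "HIV", 8, 620),
    row("not_active", "male", "HSV2", 14, 620),
    row("not_active", "male", "PREG_TEST", 0, 0),
    row("not_active", "male", "EVER_PREG", 2, 613),
    row("not_active", "male", "STI_SYMPTOM", 52, 615),
    row("not_active", "female", "HIV", 37, 959),
    row("not_active", "female", "HSV2", 54, 959),
    row("not_active", "female", "PREG_TEST", 21, 951),
    row("not_active", "female", "EVER_PREG", 13, 952),
    row("not_active", "female", "STI_SYMPTOM", 50, 950)
  )
}

# Age-band counts (15_or_under, 16_17, 18_19, 20_plus) per cell. The newly
# identified split of the not-active cells is published separately, so the
# all-negative remainder gets the difference.
fixture_age_counts <- function() {
  list(
    active_male    = c(94, 228, 227, 70),
    active_female  = c(84, 188, 115, 60),
    newly_male     = c(20, 30, 18, 7),
    newly_female   = c(60, 51, 27, 10),
    negative_male  = c(179, 244, 95, 27),
    negative_female = c(441, 292, 65, 13),
    excluded_male  = c(4, 3, 4, 2),
    excluded_female = c(6, 6, 5, 0)
  )
}

# Risk-perception counts (no_risk, low, some, high, missing) per block.
fixture_risk_counts <- function() {
  list(
    active      = c(204, 191, 87, 417, 167),   # both sexes combined
    newly_male  = c(18, 12, 10, 23, 12),
    newly_female = c(48, 21, 11, 56, 12),
    negatives   = c(441, 211, 115, 467, 122)   # all-negative not-active, both sexes
  )
}

# n-length character vector: `default` everywhere, then positional overrides.
code_vec <- function(n, default, ...) {
  v <- rep(default, n)
  overrides <- list(...)
  for (ov in overrides) v[ov$idx] <- ov$value
  v
}

ages_from_counts <- function(counts) {
  rep(c(14L, 16L, 18L, 21L), counts)
}

risk_from_counts <- function(counts) {
  rep(c(risk_levels(), NA_character_), counts)
}

# Self-reported-active cell: positives assigned to disjoint index ranges (the
# marginal totals permit it), missing codes to tail indices clear of any
# positive range.
fixture_active_block <- function(sex) {
  if (sex == "male") {
    n <- 619
    hiv <- code_vec(n, "negative", list(idx = 1:10, value = "positive"))
    hsv2 <- code_vec(n, "negative", list(idx = 11:34, value = "positive"))
    preg <- rep(NA_character_, n)
    everpreg <- code_vec(n, NA_character_,
                         list(idx = 35:70, value = "yes"),
                         list(idx = 197:233, value = "no"))
    sti_yes <- 71:159
    sti_missing <- 615:619
    ages <- ages_from_counts(fixture_age_counts()$active_male)
  } else {
    n <- 447
    hiv <- code_vec(n, "negative", list(idx = 1:51, value = "positive"))
    hsv2 <- code_vec(n, "negative", list(idx = 52:145, value = "positive"))
    preg <- code_vec(n, "negative",
                     list(idx = 146:173, value = "positive"),
                     list(idx = 445:447, value = NA_character_))
    everpreg <- code_vec(n, NA_character_,
                         list(idx = 174:307, value = "yes"),
                         list(idx = 368:373, value = "no"))
    sti_yes <- 308:367
    sti_missing <- 436:438
    ages <- ages_from_counts(fixture_age_counts()$active_female)
  }
  tibble::tibble(
    sex = sex,
    age_years = ages,
    self_report_active = "yes",
    hiv_result = hiv,
    hsv2_result = hsv2,
    pregnancy_test = preg,
    ever_pregnant_or_made_pregnant = everpreg,
    symptom_discharge = code_vec(n, "no", list(idx = sti_yes, value = "yes"),
                                 list(idx = sti_missing, value = NA_character_)),
    symptom_sore_ulcer = code_vec(n, "no", list(idx = sti_missing, value = NA_character_)),
    symptom_dysuria = code_vec(n, "no", list(idx = sti_missing, value = NA_character_))
  )
}

# Newly identified rows carry exactly the published indicator combinations.
fixture_newly_block <- function(sex) {
  is_male <- sex == "male"
  combos <- fixture_combo_table()
  counts <- combos[[sex]]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    k <- counts[[i]]
    if (k == 0) return(NULL)
    set <- combos$indicators[[i]]
    tibble::tibble(
      sex = sex,
      age_years = NA_integer_,
      self_report_active = "no",
      hiv_result = ifelse("HIV" %in% set, "positive", "negative"),
      hsv2_result = ifelse("HSV2" %in% set, "positive", "negative"),
      pregnancy_test = if (is_male) NA_character_ else {
        ifelse("PREG_TEST" %in% set, "positive", "negative")
      },
      ever_pregnant_or_made_pregnant = ifelse("EVER_PREG" %in% set, "yes", "no"),
      symptom_discharge = ifelse("STI_SYMPTOM" %in% set, "yes", "no"),
      symptom_sore_ulcer = "no",
      symptom_dysuria = "no"
    )[rep(1, k), ]
  })
  out <- dplyr::bind_rows(rows)
  band_counts <- fixture_age_counts()[[paste0("newly_", sex)]]
  out$age_years <- ages_from_counts(band_counts)
  out
}

# All-negative not-active rows, with the published per-variable missing counts
# assigned to disjoint tail indices.
fixture_negative_block <- function(sex) {
  is_male <- sex == "male"
  if (is_male) {
    n <- 545
    everpreg_missing <- 534:540
    sti_missing <- 541:545
    preg_missing <- integer(0)
    ages <- ages_from_counts(fixture_age_counts()$negative_male)
  } else {
    n <- 811
    preg_missing <- 788:795
    everpreg_missing <- 796:802
    sti_missing <- 803:811
    ages <- ages_from_counts(fixture_age_counts()$negative_female)
  }
  tibble::tibble(
    sex = sex,
    age_years = ages,
    self_report_active = "no",
    hiv_result = "negative",
    hsv2_result = "negative",
    pregnancy_test = if (is_male) NA_character_ else {
      code_vec(n, "negative", list(idx = preg_missing, value = NA_character_))
    },
    ever_pregnant_or_made_pregnant = code_vec(n, "no",
                                              list(idx = everpreg_missing, value = NA_character_)),
    symptom_discharge = code_vec(n, "no", list(idx = sti_missing, value = NA_character_)),
    symptom_sore_ulcer = code_vec(n, "no", list(idx = sti_missing, value = NA_character_)),
    symptom_dysuria = code_vec(n, "no", list(idx = sti_missing, value = NA_character_))
  )
}

fixture_excluded_block <- function(sex) {
  is_male <- sex == "male"
  n <- if (is_male) 13 else 17
  ages <- ages_from_counts(fixture_age_counts()[[paste0("excluded_", sex)]])
  tibble::tibble(
    sex = sex,
    age_years = ages,
    self_report_active = NA_character_,
    hiv_result = "negative",
    hsv2_result = "negative",
    pregnancy_test = if (is_male) NA_character_ else "negative",
    ever_pregnant_or_made_pregnant = "no",
    symptom_discharge = "no",
    symptom_sore_ulcer = "no",
    symptom_dysuria = "no",
    risk_perception = NA_character_
  )
}

#' Build the deterministic in-paper fixture cohort
#'
#' Constructs a 2,675-student cohort whose published margins are exact: 1,066
#' self-reported active (619 male, 447 female) with the per-sex indicator
#' numerators and complete-case denominators of the published table; 1,579
#' self-reported not active of whom 223 carry exactly the published indicator
#' combinations (and 1,356 are negative on every indicator); and 30
#' non-responders who are negative on all indicators. Age-band counts per
#' cell and risk-perception distributions follow the published tables;
#' unconstrained fields are set to missing rather than invented.
#'
#' Indicator overlaps in the self-reported-active stratum are not published;
#' positives there are assigned to distinct students (one valid completion —
#' the marginal totals permit it). Cluster membership is synthetic:
#' round-robin over 14 schools.
#'
#' @return A validated cohort tibble of 2,675 records.
#' @export
#' @examples
#' fx <- build_inpaper_fixture()
#' table(classify_cohort(fx)$status)
build_inpaper_fixture <- function() {
  active <- dplyr::bind_rows(fixture_active_block("male"),
                             fixture_active_block("female"))
  risk <- fixture_risk_counts()
  active$risk_perception <- risk_from_counts(risk$active)

  newly_m <- fixture_newly_block("male")
  newly_m$risk_perception <- risk_from_counts(risk$newly_male)
  newly_f <- fixture_newly_block("female")
  newly_f$risk_perception <- risk_from_counts(risk$newly_female)

  negatives <- dplyr::bind_rows(fixture_negative_block("male"),
                                fixture_negative_block("female"))
  negatives$risk_perception <- risk_from_counts(risk$negatives)

  cohort <- dplyr::bind_rows(
    active,
    newly_m,
    newly_f,
    negatives,
    fixture_excluded_block("male"),
    fixture_excluded_block("female")
  )
  n <- nrow(cohort)
  cohort <- dplyr::bind_cols(
    tibble::tibble(
      student_id = sprintf("S%04d", seq_len(n)),
      cluster_id = sprintf("school_%02d", ((seq_len(n) - 1L) %% 14L) + 1L)
    ),
    cohort
  )
  cohort <- cohort[, cohort_columns()]
  as_cohort(cohort)
}

#' Recount the published margins from a fixture cohort
#'
#' Recounts, from the records themselves, every indicator
#' numerator/denominator per (self-report group, sex) cell, in the same shape
#' as the transcribed constants table, for the automated fidelity
#' cross-check.
#'
#' @param cohort A cohort tibble (normally [build_inpaper_fixture()]).
#' @return A tibble: `group`, `sex`, `variable`, `numerator`, `denominator`.
#' @export
fixture_margins <- function(cohort) {
  flow <- build_flow_diagram(cohort)
  out <- flow$cells[, c("group", "sex", "indicator", "numerator", "denominator")]
  names(out)[names(out) == "indicator"] <- "variable"
  out
}
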