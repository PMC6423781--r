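# Random schema-valid cohorts for property tests, with per-field missingness.

sample_tern <- function(n, values, p_missing = 0.15) {
  sample(c(values, NA_character_), n, replace = TRUE,
         prob = c(rep((1 - p_missing) / length(values), length(values)), p_missing))
}

random_cohort <- function(n = 60, seed = 1, n_clusters = 3, p_missing = 0.15) {
  set.seed(seed)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  preg <- sample_tern(n, c("positive", "negative"), p_missing)
  preg[sex == "male"] <- NA_character_
  as_cohort(tibble::tibble(
    student_id = sprintf("R%04d", seq_len(n)),
    cluster_id = sample(sprintf("school_%02d", seq_len(n_clusters)), n, replace = TRUE),
    sex = sex,
    age_years = sample(13:22, n, replace = TRUE),
    self_report_active = sample_tern(n, c("yes", "no"), p_missing / 3),
    hiv_result = sample_tern(n, c("positive", "negative"), p_missing),
    hsv2_result = sample_tern(n, c("positive", "negative"), p_missing),
    pregnancy_test = preg,
    ever_pregnant_or_made_pregnant = sample_tern(n, c("yes", "no"), p_missing),
    symptom_discharge = sample_tern(n, c("yes", "no"), p_missing),
    symptom_sore_ulcer = sample_tern(n, c("yes", "no"), p_missing),
    symptom_dysuria = sample_tern(n, c("yes", "no"), p_missing),
    risk_perception = sample_tern(n, c("no_risk", "low", "some", "high"), p_missing)
  ))
}

# Minimal all-negative record, overridable field by field.
one_record <- function(...) {
  rec <- tibble::tibble(
    student_id = "X001", cluster_id = "school_01", sex = "female",
    age_years = 16L, self_report_active = "no",
    hiv_result = "negative", hsv2_result = "negative",
    pregnancy_test = "negative", ever_pregnant_or_made_pregnant = "no",
    symptom_discharge = "no", symptom_sore_ulcer = "no", symptom_dysuria = "no",
    risk_perception = "low"
  )
  overrides <- list(...)
  for (k in names(overrides)) rec[[k]] <- overrides[[k]]
  rec
}

# Generator configuration scaled down for fast simulation tests; overrides in
# `...` win over the scaled-down defaults.
small_config <- function(...) {
  args <- list(n_clusters = 6, cluster_size_mean = 40,
               cluster_size_dispersion = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# Matrices of constant probability over sex and age band.
const_rates <- function(p) sex_band_matrix(female = rep(p, 4), male = rep(p, 4))

# Indicator rate list with every sensitivity/false-positive rate set flat
# (pregnancy test stays female-only).
flat_indicator_rates <- function(active = 0.2, inactive = 0) {
  rates <- lapply(setNames(nm = msap_indicators()), function(ind) {
    list(active = c(female = active, male = active),
         inactive = c(female = inactive, male = inactive))
  })
  rates$PREG_TEST$active[["male"]] <- 0
  rates$PREG_TEST$inactive[["male"]] <- 0
  rates
}
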