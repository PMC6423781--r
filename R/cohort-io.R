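# Cohort schema, validated delimited I/O, and missing-code normalisation.
#
# A cohort is a tibble with one row per student and the canonical columns
# below. All ternary survey/test fields are stored as lower-case character
# values with NA as the single missing state; "not applicable" (the pregnancy
# test in males) is stored as NA and enforced structurally by `sex`.

cohort_columns <- function() {
  c("student_id", "cluster_id", "sex", "age_years", "self_report_active",
    "hiv_result", "hsv2_result", "pregnancy_test",
    "ever_pregnant_or_made_pregnant",
    "symptom_discharge", "symptom_sore_ulcer", "symptom_dysuria",
    "risk_perception")
}

# Allowed (non-missing) values per enumerated column.
cohort_value_sets <- function() {
  yn <- c("yes", "no")
  pn <- c("positive", "negative")
  list(
    sex                            = c("male", "female"),
    self_report_active             = yn,
    hiv_result                     = pn,
    hsv2_result                    = pn,
    pregnancy_test                 = pn,
    ever_pregnant_or_made_pregnant = yn,
    symptom_discharge              = yn,
    symptom_sore_ulcer             = yn,
    symptom_dysuria                = yn,
    risk_perception                = risk_levels()
  )
}

default_na_codes <- function() {
  c("", "na", "n/a", "missing", "not_applicable", "not applicable", ".")
}

new_cohort <- function(x) {
  structure(x, class = c("msap_cohort", class(tibble::as_tibble(x))))
}

#' Construct a validated cohort from a data frame
#'
#' Coerces a data frame holding the canonical cohort columns into a validated
#' cohort object. Enumerated values are lower-cased; recognised missing codes
#' become `NA`. Extra columns are kept only if prefixed `cov_` (free-form
#' categorical covariates).
#'
#' @param x A data frame with the canonical cohort columns (see
#'   [read_cohort()] for the list).
#' @param dialect Optional dialect mapping as for [read_cohort()].
#' @return A cohort tibble of class `msap_cohort`.
#' @export
as_cohort <- function(x, dialect = NULL) {
  x <- tibble::as_tibble(x)
  required <- cohort_columns()
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "msap_schema_error")
  }
  cov_cols <- grep("^cov_", names(x), value = TRUE)
  x <- x[, c(required, cov_cols)]
  x <- normalise_cohort_values(x, dialect)
  validate_cohort(x)
  new_cohort(x)
}

normalise_cohort_values <- function(x, dialect = NULL) {
  dialect <- load_dialect(dialect)
  na_codes <- unique(c(default_na_codes(), tolower(dialect$na_codes %||% character())))
  value_sets <- cohort_value_sets()
  for (col in names(value_sets)) {
    v <- tolower(trimws(as.character(x[[col]])))
    remap <- dialect$values[[col]]
    if (!is.null(remap)) {
      names(remap) <- tolower(names(remap))
      hit <- v %in% names(remap)
      v[hit] <- unname(remap[v[hit]])
    }
    v[v %in% na_codes] <- NA_character_
    x[[col]] <- v
  }
  x$student_id <- as.character(x$student_id)
  x$cluster_id <- as.character(x$cluster_id)
  x$age_years <- as.integer(x$age_years)
  for (col in grep("^cov_", names(x), value = TRUE)) {
    v <- as.character(x[[col]])
    v[tolower(v) %in% na_codes] <- NA_character_
    x[[col]] <- v
  }
  x
}

# Dialect: list(values = list(column = c(code = canonical, ...)),
#               na_codes = c(...)), or a path to a YAML file with that shape.
load_dialect <- function(dialect) {
  if (is.null(dialect)) return(list())
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- yaml::read_yaml(dialect)
    dialect$values <- lapply(dialect$values, unlist)
  }
  stopifnot(is.list(dialect))
  dialect
}

#' Validate a cohort against the schema
#'
#' Checks the structural invariants: required columns present, enumerated
#' fields hold only their allowed values or `NA`, `student_id` unique, ages
#' within 10--35 years, at least one cluster, and no male with a positive
#' pregnancy test (the test is structurally not applicable to males).
#'
#' @param x A cohort tibble.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `msap_schema_error` or `msap_validation_error`.
#' @export
validate_cohort <- function(x) {
  if (nrow(x) == 0) {
    abort("cohort must contain at least one record", class = "msap_validation_error")
  }
  value_sets <- cohort_value_sets()
  for (col in names(value_sets)) {
    bad <- !is.na(x[[col]]) & !(x[[col]] %in% value_sets[[col]])
    if (any(bad)) {
      abort(sprintf("column '%s' contains unrecognised value(s): %s",
                    col, paste(unique(x[[col]][bad]), collapse = ", ")),
            class = "msap_validation_error")
    }
  }
  dup <- duplicated(x$student_id)
  if (any(dup)) {
    abort(sprintf("duplicate student_id: %s",
                  paste(unique(x$student_id[dup]), collapse = ", ")),
          class = "msap_validation_error")
  }
  if (any(is.na(x$student_id)) || any(is.na(x$cluster_id))) {
    abort("student_id and cluster_id must be non-missing",
          class = "msap_validation_error")
  }
  bad_age <- !is.na(x$age_years) & (x$age_years < 10 | x$age_years > 35)
  if (any(bad_age)) {
    abort(sprintf("age_years outside the valid 10-35 range for student(s): %s",
                  paste(x$student_id[bad_age], collapse = ", ")),
          class = "msap_validation_error")
  }
  male_preg <- x$sex == "male" & !is.na(x$pregnancy_test) & x$pregnancy_test == "positive"
  male_preg[is.na(male_preg)] <- FALSE
  if (any(male_preg)) {
    abort(sprintf("male student(s) with a positive pregnancy test: %s",
                  paste(x$student_id[male_preg], collapse = ", ")),
          class = "msap_validation_error")
  }
  invisible(x)
}

#' Read a cohort file
#'
#' Reads a delimited cohort file (comma by default; tab detected
#' automatically), normalises value codes, and validates the result. The file
#' must have a header row with the canonical columns `student_id, cluster_id,
#' sex, age_years, self_report_active, hiv_result, hsv2_result,
#' pregnancy_test, ever_pregnant_or_made_pregnant, symptom_discharge,
#' symptom_sore_ulcer, symptom_dysuria, risk_perception`, optionally followed
#' by covariate columns prefixed `cov_`.
#'
#' Value codes are matched case-insensitively; empty fields and common missing
#' codes (`NA`, `missing`, `not_applicable`, ...) are normalised to `NA`.
#' Site-specific export codes can be remapped through `dialect`.
#'
#' @param path Path to the cohort file.
#' @param dialect Optional code mapping: either a list with elements `values`
#'   (per-column named vectors `c(code = canonical)`) and `na_codes`
#'   (additional missing codes), or a path to a YAML file with that structure.
#' @return A validated cohort tibble of class `msap_cohort`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(build_inpaper_fixture()[1:5, ], path)
#' read_cohort(path)
read_cohort <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path), class = "msap_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE, show_col_types = FALSE)
  as_cohort(raw, dialect = dialect)
}

#' Write a cohort file
#'
#' Writes a cohort as UTF-8 comma-separated text with a header row. Missing
#' values are written as empty fields, so `read_cohort(write_cohort(x))`
#' reproduces `x` field for field.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(tibble::as_tibble(cohort), path, na = "")
  invisible(path)
}
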