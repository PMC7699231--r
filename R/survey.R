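# Survey data model and I/O. A survey is a long-format tibble, one
# measurement per row:
#   product_id, category, subcategory, chemical, concentration (mg/kg),
#   unit, detected (logical)
# Non-detected measurements carry a missing concentration until substitution
# is applied explicitly.

survey_chemicals <- function() c("DBP", "DEHA", "DEHP", "DEP", "DIBP", "DINP")

survey_col_types <- function() {
  readr::cols(
    product_id = readr::col_character(),
    category = readr::col_character(),
    subcategory = readr::col_character(),
    chemical = readr::col_character(),
    concentration = readr::col_double(),
    unit = readr::col_character(),
    detected = readr::col_integer()
  )
}

#' Validate a product-survey table
#'
#' Checks schema, category and chemical vocabularies, and the censoring
#' invariant (a detected measurement must carry a non-negative
#' concentration). Offending rows are reported by position.
#'
#' @param survey A survey tibble.
#' @return The survey, invisibly, if valid; otherwise an error listing the
#'   offenders.
#' @export
validate_survey <- function(survey) {
  required <- c(
    "product_id", "category", "subcategory", "chemical",
    "concentration", "unit", "detected"
  )
  missing_cols <- setdiff(required, names(survey))
  if (length(missing_cols) > 0) {
    stop("survey is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_cat <- which(!survey$category %in% survey_categories())
  if (length(bad_cat) > 0) {
    stop(
      "unknown category in row(s) ",
      paste(head(bad_cat, 5), collapse = ", "), ": ",
      paste(unique(survey$category[head(bad_cat, 5)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_chem <- which(!survey$chemical %in% survey_chemicals())
  if (length(bad_chem) > 0) {
    stop(
      "unknown chemical in row(s) ",
      paste(head(bad_chem, 5), collapse = ", "), ": ",
      paste(unique(survey$chemical[head(bad_chem, 5)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad_conc <- which(as.logical(survey$detected) &
    (is.na(survey$concentration) | survey$concentration < 0))
  if (length(bad_conc) > 0) {
    stop(
      "detected measurement with missing or negative concentration in row(s) ",
      paste(head(bad_conc, 5), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(survey)
}

#' Read a product survey from CSV
#'
#' Long format, one measurement per row; concentrations given in percent
#' w/w (`unit = "percent_ww"`) are converted to mg/kg on load
#' (1% w/w = 10,000 mg/kg), so the in-memory representation is always
#' mg/kg.
#'
#' @param path Path to a survey CSV with columns `product_id`, `category`,
#'   `subcategory`, `chemical`, `concentration`, `unit`
#'   (`mg_per_kg` or `percent_ww`), `detected` (0/1).
#' @return A validated survey tibble with concentrations in mg/kg and
#'   `detected` as logical.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  survey <- readr::read_csv(path, col_types = survey_col_types(), progress = FALSE)
  prob <- readr::problems(survey)
  if (nrow(prob) > 0) {
    stop(
      "malformed survey row(s) at line(s) ",
      paste(head(prob$row, 5), collapse = ", "),
      call. = FALSE
    )
  }
  bad_unit <- which(!survey$unit %in% c("mg_per_kg", "percent_ww"))
  if (length(bad_unit) > 0) {
    stop("unknown concentration unit in row(s) ",
      paste(head(bad_unit, 5), collapse = ", "),
      call. = FALSE
    )
  }
  pct <- survey$unit == "percent_ww"
  survey$concentration[pct] <- survey$concentration[pct] * 1e4
  survey$unit <- "mg_per_kg"
  survey$detected <- as.logical(survey$detected)
  validate_survey(survey)
  survey
}

#' Write a product survey to CSV
#'
#' Emits the same long-format schema that [read_survey()] accepts, with
#' concentrations in mg/kg and `detected` as 0/1.
#'
#' @param survey A survey tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  validate_survey(survey)
  out <- survey
  out$detected <- as.integer(out$detected)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Substitute non-detected concentrations at half the quantitation limit
#'
#' Left-censored (non-detected) measurements are imputed at LOQ/2 for the
#' respective chemical, the convention used when fitting concentration
#' distributions for the probabilistic assessment. Detected measurements
#' and the censoring flag itself are untouched, so the operation is
#' idempotent and reversible in intent (the flag records what was imputed).
#'
#' @param survey A survey tibble.
#' @param registry Chemical registry for LOQ lookup.
#' @return The survey with every non-detect's concentration set to LOQ/2.
#' @examples
#' # a DEHP non-detect becomes 32.5 / 2 = 16.25 mg/kg
#' @export
substitute_nondetects <- function(survey, registry = plasticizer_registry()) {
  validate_survey(survey)
  half_loq <- setNames(registry$loq_mg_kg / 2, registry$abbreviation)
  nd <- !survey$detected
  survey$concentration[nd] <- unname(half_loq[survey$chemical[nd]])
  survey
}

#' Screen measurements for the exposure assessment
#'
#' A measurement enters the exposure assessment only when it was detected
#' and its concentration is strictly above the inclusion threshold of
#' 100 mg/kg (a safety margin over the ~30-44 mg/kg quantitation limits).
#' Products retaining no measurement drop out. Idempotent.
#'
#' @param survey A survey tibble.
#' @param threshold_mg_kg Inclusion threshold, mg/kg; default 100.
#' @return The retained measurements.
#' @export
filter_for_exposure <- function(survey, threshold_mg_kg = INCLUSION_THRESHOLD_MG_KG) {
  validate_survey(survey)
  dplyr::filter(
    survey,
    .data$detected & !is.na(.data$concentration) &
      .data$concentration > threshold_mg_kg
  )
}

#' Per-category, per-chemical concentration summaries
#'
#' One row per (category, chemical) combination with at least one detected
#' measurement in the supplied records: detection count and the maximum and
#' minimum concentration. Apply [filter_for_exposure()] first if the
#' summary should reflect only measurements in the assessment.
#'
#' @param survey A survey tibble (filtered as the caller requires).
#' @return A tibble with columns `category`, `chemical`, `n_detected`,
#'   `conc_max`, `conc_min` (mg/kg).
#' @export
summarize_survey <- function(survey) {
  validate_survey(survey)
  survey |>
    dplyr::filter(.data$detected & !is.na(.data$concentration)) |>
    dplyr::group_by(.data$category, .data$chemical) |>
    dplyr::summarise(
      n_detected = dplyr::n(),
      conc_max = max(.data$concentration),
      conc_min = min(.data$concentration),
      .groups = "drop"
    )
}
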