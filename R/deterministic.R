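# Deterministic screening: per category x chemical maximum/minimum daily
# doses by route, route totals, margins of exposure, and the migration-rate
# sensitivity analysis.

#' Margin of exposure
#'
#' `MOE = reference_dose / dose`. A dose of zero gives `NA` (no exposure:
#' the margin is undefined, not infinite). Vectorized.
#'
#' @param reference_dose Reference dose, mg/kg/d (> 0).
#' @param dose Estimated daily dose, mg/kg/d (>= 0).
#' @return The margin of exposure; `NA` where `dose == 0`.
#' @export
moe <- function(reference_dose, dose) {
  if (any(reference_dose <= 0)) {
    stop("reference_dose must be strictly positive", call. = FALSE)
  }
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  ifelse(dose == 0, NA_real_, reference_dose / dose)
}

# Screening concern threshold for the MOE flag.
MOE_SCREEN_THRESHOLD <- 100

#' Deterministic exposure range for one chemical in one category
#'
#' Reproduces the screening table arithmetic for a (category, chemical)
#' cell of a filtered survey:
#'
#' * the maximum scenario evaluates both routes at the category's maximum
#'   retained concentration;
#' * the minimum scenario evaluates them at the 100 mg/kg (0.01% w/w)
#'   inclusion-threshold concentration, the lowest content any retained
#'   product can carry;
#' * ingestion is computed only for accessories, stationery and toys;
#'   dermal for all categories; the total sums the applicable routes
#'   within a scenario at full precision.
#'
#' @param survey A survey already passed through [filter_for_exposure()].
#' @param chemical Chemical abbreviation.
#' @param category Category name.
#' @param factors A calibrated [exposure_factors()] set.
#' @param registry Chemical registry.
#' @param policy A [migration_policy()].
#' @param min_conc_mg_kg Concentration of the minimum scenario, mg/kg.
#' @return A tibble with one row per route x scenario (`route` in
#'   ingestion/dermal/total, `scenario` in max/min) holding `dose`
#'   (mg/kg/d), `moe` and `moe_below_100`; empty when the chemical is not
#'   retained in the category.
#' @export
category_exposure_range <- function(survey, chemical, category, factors,
                                    registry = plasticizer_registry(),
                                    policy = migration_policy("two_level"),
                                    min_conc_mg_kg = INCLUSION_THRESHOLD_MG_KG) {
  rows <- dplyr::filter(
    survey, .data$chemical == !!chemical, .data$category == !!category
  )
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      category = character(), chemical = character(), route = character(),
      scenario = character(), dose = numeric(), moe = numeric(),
      moe_below_100 = logical()
    ))
  }
  spec <- get_chemical(chemical, registry)
  conc <- c(max = max(rows$concentration), min = min_conc_mg_kg)
  inter <- dermal_intermediates(spec, factors, registry)
  out <- lapply(names(conc), function(scn) {
    c_mg_kg <- conc[[scn]]
    dermal <- dermal_daily_dose(
      article_concentration(c_mg_kg, factors$rho_article), factors, inter
    )
    doses <- c(dermal = dermal)
    if (category %in% ingestion_categories()) {
      mr <- assign_migration_rate(c_mg_kg * 1e-6, policy)
      doses <- c(ingestion = ingestion_daily_dose(mr, factors), doses)
    }
    doses <- c(doses, total = sum(doses))
    tibble::tibble(
      category = category, chemical = chemical,
      route = names(doses), scenario = scn, dose = unname(doses)
    )
  })
  out <- dplyr::bind_rows(out)
  out$moe <- moe(spec$reference_dose, out$dose)
  out$moe_below_100 <- !is.na(out$moe) & out$moe < MOE_SCREEN_THRESHOLD
  out
}

#' Deterministic screening table
#'
#' Runs [category_exposure_range()] over every (category, chemical) cell
#' retained by [filter_for_exposure()] and pivots to the published table
#' shape: one row per cell with ingestion/dermal/total max and min doses
#' and the MOE of the total at each scenario. Values are carried at full
#' precision; use [format_sci2()] for the 2-significant-figure scientific
#' display convention.
#'
#' @inheritParams category_exposure_range
#' @return A tibble with columns `category`, `chemical`,
#'   `reference_dose`, `ingestion_max`, `ingestion_min`, `dermal_max`,
#'   `dermal_min`, `total_max`, `total_min`, `moe_max`, `moe_min`.
#' @export
exposure_table <- function(survey, factors,
                           registry = plasticizer_registry(),
                           policy = migration_policy("two_level")) {
  retained <- filter_for_exposure(survey)
  cells <- dplyr::distinct(retained, .data$category, .data$chemical)
  if (nrow(cells) == 0) {
    return(tibble::tibble(
      category = character(), chemical = character(),
      reference_dose = numeric(),
      ingestion_max = numeric(), ingestion_min = numeric(),
      dermal_max = numeric(), dermal_min = numeric(),
      total_max = numeric(), total_min = numeric(),
      moe_max = numeric(), moe_min = numeric()
    ))
  }
  cells <- dplyr::arrange(cells, .data$category, .data$chemical)
  long <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    category_exposure_range(
      retained, cells$chemical[i], cells$category[i], factors,
      registry, policy
    )
  }))
  wide <- long |>
    dplyr::select("category", "chemical", "route", "scenario", "dose") |>
    tidyr::pivot_wider(
      names_from = c("route", "scenario"), values_from = "dose"
    )
  moe_cols <- long |>
    dplyr::filter(.data$route == "total") |>
    dplyr::select("category", "chemical", "scenario", "moe") |>
    tidyr::pivot_wider(
      names_from = "scenario", values_from = "moe", names_prefix = "moe_"
    )
  wide <- dplyr::left_join(wide, moe_cols, by = c("category", "chemical"))
  rfd <- setNames(registry$reference_dose, registry$abbreviation)
  wide$reference_dose <- unname(rfd[wide$chemical])
  for (col in c("ingestion_max", "ingestion_min")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  dplyr::select(
    wide, "category", "chemical", "reference_dose",
    "ingestion_max", "ingestion_min", "dermal_max", "dermal_min",
    "total_max", "total_min", "moe_max", "moe_min"
  )
}

#' Migration-rate sensitivity of the ingestion dose
#'
#' Recomputes the ingestion dose and MOE for every retained
#' (category, chemical) cell in the mouthing categories at each of the
#' four discrete CEM migration-rate levels (10, 0.1, 1e-3, 1e-4 mg/cm2/h
#' by default), optionally adding a user-supplied experimentally measured
#' rate. Because the dose is linear in MR, the span across the default
#' levels is exactly 1e5.
#'
#' @inheritParams category_exposure_range
#' @param mr_levels Migration-rate levels to evaluate, mg/cm2/h.
#' @param experimental_mr Optional single measured migration rate to add,
#'   labelled `"experimental"`.
#' @return A tibble with columns `category`, `chemical`, `mr_source`
#'   (`"assigned"` or `"experimental"`), `mr`, `dose`, `moe`.
#' @export
migration_sensitivity <- function(survey, factors,
                                  registry = plasticizer_registry(),
                                  mr_levels = c(10, 0.1, 1e-3, 1e-4),
                                  experimental_mr = NULL) {
  stopifnot(all(mr_levels > 0))
  retained <- filter_for_exposure(survey)
  cells <- retained |>
    dplyr::filter(.data$category %in% ingestion_categories()) |>
    dplyr::distinct(.data$category, .data$chemical) |>
    dplyr::arrange(.data$category, .data$chemical)
  mr_tab <- tibble::tibble(mr_source = "assigned", mr = mr_levels)
  if (!is.null(experimental_mr)) {
    stopifnot(length(experimental_mr) == 1, experimental_mr > 0)
    mr_tab <- dplyr::bind_rows(
      mr_tab, tibble::tibble(mr_source = "experimental", mr = experimental_mr)
    )
  }
  out <- tidyr::crossing(cells, mr_tab)
  out$dose <- ingestion_daily_dose(out$mr, factors)
  rfd <- setNames(registry$reference_dose, registry$abbreviation)
  out$moe <- moe(unname(rfd[out$chemical]), out$dose)
  out
}

#' Format to the 2-significant-figure scientific display convention
#'
#' @param x Numeric vector.
#' @return Character vector like `"5.0e-03"`; `NA` preserved.
#' @export
format_sci2 <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.1e", signif(x, 2)))
}
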