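# Chemical registry: identity, physicochemical properties, quantitation
# limits, reference doses and skin-permeability components for the six
# plasticizers under assessment.

#' Skin-permeability pathway components from molecular weight and log Kow
#'
#' The overall stratum-corneum permeability coefficient is a series
#' combination of a lipid (micro-)pathway in parallel with a polar pore
#' pathway, in series with the aqueous boundary layer of the viable
#' epidermis. The three components are estimated from standard published
#' correlations:
#'
#' * lipid pathway (Potts & Guy 1992):
#'   `K_lip = 10^(-2.8 + 0.66 * log_kow - 0.0056 * mw)` cm/h
#' * polar (aqueous pore) pathway: `K_pol = 1.5e-4 / sqrt(mw)` cm/h
#' * aqueous boundary layer (Cleek & Bunge 1993, as used in the EPA dermal
#'   guidance): `K_aq = 2.6 / sqrt(mw)` cm/h
#'
#' These correlations are a documented modelling choice: they are the
#' EPA-lineage forms consistent with the series-resistance permeability
#' model, and each component can be pinned per chemical to a literature
#' value through the registry file (columns `k_lip`, `k_pol`, `k_aq`).
#'
#' @param mw Molecular weight, mg/mmol (numerically g/mol). Must be > 0.
#' @param log_kow Base-10 octanol-water partition coefficient.
#' @return A list with elements `k_lip`, `k_pol`, `k_aq` (cm/h), all
#'   strictly positive.
#' @examples
#' permeability_components(278.34, 4.5)
#' @export
permeability_components <- function(mw, log_kow) {
  stopifnot(is.numeric(mw), is.numeric(log_kow))
  if (any(mw <= 0)) {
    stop("molecular weight must be strictly positive", call. = FALSE)
  }
  list(
    k_lip = 10^(-2.8 + 0.66 * log_kow - 0.0056 * mw),
    k_pol = 1.5e-4 / sqrt(mw),
    k_aq = 2.6 / sqrt(mw)
  )
}

registry_cache <- new.env(parent = emptyenv())

#' Registry of the six surveyed plasticizers
#'
#' Loads the packaged plain-text registry (one row per chemical) holding
#' molecular weight, vapor pressure, water solubility, log Kow, the
#' per-chemical GC-MS limit of quantitation and the reference dose with its
#' toxicological basis. Permeability pathway components absent from the file
#' are filled in from [permeability_components()] at load time, so users may
#' pin literature values by supplying them in an override file.
#'
#' Property values (MW, p_vap, S_w, log Kow) are inputs of the assessment,
#' packaged from standard experimental compilations with a per-row source
#' note; they are deliberately not estimated by this package.
#'
#' @param path Path to a registry CSV; defaults to the packaged file.
#' @param overrides Optional data frame (or path to a CSV) with column
#'   `abbreviation` plus any registry columns to replace, merged over the
#'   packaged values.
#' @return A tibble with one row per chemical and columns `abbreviation`,
#'   `full_name`, `mw`, `p_vap_torr`, `s_w_mg_ml`, `log_kow`, `k_lip`,
#'   `k_pol`, `k_aq`, `loq_mg_kg`, `reference_dose`, `rfd_basis`,
#'   `property_source`.
#' @export
plasticizer_registry <- function(path = NULL, overrides = NULL) {
  default_call <- is.null(path) && is.null(overrides)
  if (default_call && !is.null(registry_cache$default)) {
    return(registry_cache$default)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "plasticizer_properties.csv",
      package = "plastexpo", mustWork = TRUE
    )
  }
  reg <- readr::read_csv(path,
    col_types = readr::cols(
      abbreviation = readr::col_character(),
      full_name = readr::col_character(),
      mw = readr::col_double(),
      p_vap_torr = readr::col_double(),
      s_w_mg_ml = readr::col_double(),
      log_kow = readr::col_double(),
      k_lip = readr::col_double(),
      k_pol = readr::col_double(),
      k_aq = readr::col_double(),
      loq_mg_kg = readr::col_double(),
      reference_dose = readr::col_double(),
      rfd_basis = readr::col_character(),
      property_source = readr::col_character()
    ),
    progress = FALSE
  )
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      overrides <- readr::read_csv(overrides, show_col_types = FALSE)
    }
    overrides <- tibble::as_tibble(overrides)
    stopifnot("abbreviation" %in% names(overrides))
    for (i in seq_len(nrow(overrides))) {
      j <- match(toupper(overrides$abbreviation[i]), reg$abbreviation)
      if (is.na(j)) {
        stop("override refers to unknown chemical: ", overrides$abbreviation[i],
          call. = FALSE
        )
      }
      for (col in setdiff(names(overrides), "abbreviation")) {
        val <- overrides[[col]][i]
        if (!is.na(val)) reg[[col]][j] <- val
      }
    }
  }
  missing_k <- is.na(reg$k_lip) | is.na(reg$k_pol) | is.na(reg$k_aq)
  if (any(missing_k)) {
    comp <- permeability_components(reg$mw[missing_k], reg$log_kow[missing_k])
    reg$k_lip[missing_k] <- ifelse(is.na(reg$k_lip[missing_k]), comp$k_lip, reg$k_lip[missing_k])
    reg$k_pol[missing_k] <- ifelse(is.na(reg$k_pol[missing_k]), comp$k_pol, reg$k_pol[missing_k])
    reg$k_aq[missing_k] <- ifelse(is.na(reg$k_aq[missing_k]), comp$k_aq, reg$k_aq[missing_k])
  }
  validate_registry(reg)
  if (default_call) registry_cache$default <- reg
  reg
}

validate_registry <- function(reg) {
  expected <- sort(c("DBP", "DEHP", "DEP", "DIBP", "DINP", "DEHA"))
  if (!identical(sort(reg$abbreviation), expected)) {
    stop(
      "registry must contain exactly the six chemicals: ",
      paste(expected, collapse = ", "),
      call. = FALSE
    )
  }
  with(reg, stopifnot(
    all(mw > 0), all(p_vap_torr >= 0), all(s_w_mg_ml > 0),
    all(k_lip > 0), all(k_pol > 0), all(k_aq > 0),
    all(loq_mg_kg > 0), all(reference_dose > 0)
  ))
  invisible(reg)
}

#' Look up one chemical in the registry
#'
#' @param abbreviation One of DBP, DEHP, DEP, DIBP, DINP, DEHA
#'   (case-insensitive).
#' @param registry A registry tibble from [plasticizer_registry()].
#' @return A one-row list with the fields of the registry row, accessible
#'   as `spec$mw`, `spec$loq_mg_kg`, etc.
#' @examples
#' get_chemical("DEHP")$reference_dose # 3 mg/kg/d
#' @export
get_chemical <- function(abbreviation, registry = plasticizer_registry()) {
  stopifnot(is.character(abbreviation), length(abbreviation) == 1)
  j <- match(toupper(abbreviation), registry$abbreviation)
  if (is.na(j)) {
    stop(
      "unknown chemical '", abbreviation, "'; valid chemicals are: ",
      paste(sort(registry$abbreviation), collapse = ", "),
      call. = FALSE
    )
  }
  as.list(registry[j, ])
}
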