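# Dermal absorption micro-model: per contact event, a film of article
# material loads the skin over a diffusion distance l; the fraction FA of
# the loaded chemical that is absorbed (rather than evaporating from the
# skin surface) follows from the competition between evaporation and
# permeation through the stratum corneum.

#' Exposure factor set
#'
#' Bundles every non-chemical parameter of the ingestion and dermal dose
#' equations, with units checked at construction:
#'
#' * `CA` mouthing contact area, cm2
#' * `D_mouthing` duration of mouthing, min/h of product use
#' * `use_hours` daily product use driving mouthing, h/d
#' * `ED` exposure duration, d; `AT` averaging time, d (ED <= AT)
#' * `BW` body weight, kg
#' * `SA_over_BW` exposed (hands) skin surface area per body weight, cm2/kg
#' * `Dur` duration of one article contact, min
#' * `D` solid-phase diffusion coefficient in the article, m2/h
#' * `T` temperature, K; `h` gas-phase mass-transfer coefficient, m/h
#' * `a` dimensionless rate constant of the absorption exponent
#' * `h_sc` stratum corneum thickness, cm (default 15 um)
#' * `rho_article` article density, g/cm3, used to convert mass fraction to
#'   mg/cm3 (default 1.2, typical plasticized PVC)
#'
#' `use_hours` and `D` default to `NA` here; [default_exposure_factors()]
#' fills them by calibration.
#'
#' @param CA,D_mouthing,use_hours,ED,AT,BW,SA_over_BW,Dur,D,T,h,a,h_sc,rho_article
#'   See description.
#' @return An object of class `exposure_factors` (a named list).
#' @export
exposure_factors <- function(CA = 10, D_mouthing = 6, use_hours = NA_real_,
                             ED = 365, AT = 365, BW = 15, SA_over_BW = 30,
                             Dur = 60, D = NA_real_, T = 298, h = 10, a = 1,
                             h_sc = 1.5e-3, rho_article = 1.2) {
  f <- list(
    CA = CA, D_mouthing = D_mouthing, use_hours = use_hours, ED = ED,
    AT = AT, BW = BW, SA_over_BW = SA_over_BW, Dur = Dur, D = D, T = T,
    h = h, a = a, h_sc = h_sc, rho_article = rho_article
  )
  for (nm in setdiff(names(f), c("a", "use_hours", "D"))) {
    if (!is.na(f[[nm]]) && f[[nm]] <= 0) {
      stop("exposure factor '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  if (f$a < 0) stop("exposure factor 'a' must be non-negative", call. = FALSE)
  if (f$ED > f$AT) stop("ED must not exceed AT", call. = FALSE)
  structure(f, class = "exposure_factors")
}

#' @export
print.exposure_factors <- function(x, ...) {
  cat("Exposure factor set:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert a bulk concentration to an article-phase concentration
#'
#' `C_art` (mg per cm3 of article) equals the mass fraction times the
#' article density: `conc_mg_kg * 1e-6 * rho * 1000`.
#'
#' @param conc_mg_kg Concentration in the article, mg/kg.
#' @param rho_article Article density, g/cm3.
#' @return Concentration in mg/cm3.
#' @export
article_concentration <- function(conc_mg_kg, rho_article = 1.2) {
  stopifnot(all(conc_mg_kg >= 0), rho_article > 0)
  conc_mg_kg * 1e-6 * rho_article * 1000
}

#' Diffusion distance travelled per contact
#'
#' Average distance a molecule diffuses into/out of the article during one
#' contact of `Dur` minutes: `l = 2 * sqrt(D * Dur/60)` evaluated in metres
#' and returned in cm. The literal linear form `2 * D * Dur/60` (which is
#' dimensionally inconsistent for a length) is retained behind
#' `literal = TRUE` for auditability.
#'
#' @param D Solid-phase diffusion coefficient, m2/h.
#' @param Dur Contact duration, min.
#' @param literal Use the literal linear product instead of the
#'   diffusion-length (square-root) reading. Default `FALSE`.
#' @return Diffusion distance, cm.
#' @examples
#' diffusion_distance(2.5e-9, 60) # 0.01 cm
#' @export
diffusion_distance <- function(D, Dur, literal = FALSE) {
  if (any(D < 0) || any(Dur < 0)) {
    stop("D and Dur must be non-negative", call. = FALSE)
  }
  if (literal) {
    return(2 * D * Dur / 60 * 100)
  }
  2 * sqrt(D * Dur / 60) * 100
}

#' Lag time for transport through the stratum corneum
#'
#' `t_lag = h_sc / (6 * 10^(-2.8 - 0.0056 * MW))` with `h_sc` in cm and the
#' denominator (an effective diffusive velocity) in cm/h; heavier molecules
#' lag longer.
#'
#' @param mw Molecular weight, mg/mmol.
#' @param h_sc Stratum corneum thickness, cm (default 15 um).
#' @return Lag time, h.
#' @export
lag_time <- function(mw, h_sc = 1.5e-3) {
  if (any(mw <= 0) || any(h_sc <= 0)) {
    stop("mw and h_sc must be strictly positive", call. = FALSE)
  }
  h_sc / (6 * 10^(-2.8 - 0.0056 * mw))
}

#' Overall skin permeability coefficient
#'
#' Series combination of the stratum corneum (lipid pathway in parallel
#' with the polar pore pathway) and the aqueous boundary layer:
#' `K_p = 1 / (1/(K_lip + K_pol) + 1/K_aq)`. `K_p` is bounded above by each
#' series resistance.
#'
#' @param k_lip,k_pol,k_aq Pathway permeabilities, cm/h, all > 0.
#' @return Permeability coefficient, cm/h.
#' @export
skin_permeability <- function(k_lip, k_pol, k_aq) {
  if (any(k_lip <= 0) || any(k_pol <= 0) || any(k_aq <= 0)) {
    stop("permeability components must be strictly positive", call. = FALSE)
  }
  1 / (1 / (k_lip + k_pol) + 1 / k_aq)
}

#' Evaporation-to-absorption (volatility) ratio
#'
#' Ratio of the evaporation rate from the skin surface to the dermal
#' absorption rate through the stratum corneum:
#' `chi = (h * p_vap * MW) / (K_p * S_w * R * T)` with
#' R = 62.37 mL Torr /(K mmol). `h` is supplied in m/h and converted to
#' cm/h (x100) so the ratio is dimensionless against `K_p` in cm/h:
#' (cm/h * Torr * mg/mmol) / (cm/h * mg/mL * mL Torr /(K mmol) * K).
#'
#' @param h Gas-phase mass-transfer coefficient, m/h.
#' @param p_vap Vapor pressure, Torr (>= 0).
#' @param mw Molecular weight, mg/mmol.
#' @param k_p Skin permeability coefficient, cm/h.
#' @param s_w Water solubility, mg/mL.
#' @param T Temperature, K.
#' @return Dimensionless ratio chi >= 0.
#' @export
volatility_ratio <- function(h, p_vap, mw, k_p, s_w, T) {
  if (any(p_vap < 0)) stop("p_vap must be non-negative", call. = FALSE)
  if (any(h <= 0) || any(mw <= 0) || any(k_p <= 0) || any(s_w <= 0) || any(T <= 0)) {
    stop("h, mw, k_p, s_w and T must be strictly positive", call. = FALSE)
  }
  (h * 100) * p_vap * mw / (k_p * s_w * GAS_CONSTANT_R * T)
}

#' Fraction of the skin load absorbed
#'
#' `FA = (3 + chi * (1 - exp(-a * Dur_h / t_lag))) / (3 * (1 + chi))` with
#' the contact duration converted to hours (`Dur_h = Dur / 60`) so the
#' exponent is dimensionless. Non-volatile chemicals (chi = 0) are fully
#' absorbed (FA = 1); in the volatile, long-contact limit FA tends to 1/3.
#' FA is non-increasing in chi and non-decreasing in Dur.
#'
#' @param chi Volatility ratio, >= 0.
#' @param Dur Contact duration, min.
#' @param t_lag Stratum corneum lag time, h.
#' @param a Dimensionless rate constant (default 1).
#' @return Fraction absorbed in (0, 1].
#' @export
fraction_absorbed <- function(chi, Dur, t_lag, a = 1) {
  if (any(t_lag <= 0)) stop("t_lag must be strictly positive", call. = FALSE)
  if (any(chi < 0) || any(Dur < 0) || any(a < 0)) {
    stop("chi, Dur and a must be non-negative", call. = FALSE)
  }
  dur_h <- Dur / 60
  (3 + chi * (1 - exp(-a * dur_h / t_lag))) / (3 * (1 + chi))
}

#' Chemical-specific dermal intermediates
#'
#' Computes the diffusion distance, lag time, permeability, volatility
#' ratio and fraction absorbed for one chemical under a factor set.
#'
#' @param chemical A chemical abbreviation or a registry row list from
#'   [get_chemical()].
#' @param factors An [exposure_factors()] set with `D` filled in.
#' @param registry Chemical registry.
#' @return A list with elements `l` (cm), `t_lag` (h), `k_p` (cm/h),
#'   `chi`, `fa`.
#' @export
dermal_intermediates <- function(chemical, factors, registry = plasticizer_registry()) {
  spec <- if (is.character(chemical)) get_chemical(chemical, registry) else chemical
  if (is.na(factors$D)) {
    stop("factor set has no diffusion coefficient D; calibrate or set it",
      call. = FALSE
    )
  }
  k_p <- skin_permeability(spec$k_lip, spec$k_pol, spec$k_aq)
  t_lag <- lag_time(spec$mw, factors$h_sc)
  chi <- volatility_ratio(
    factors$h, spec$p_vap_torr, spec$mw, k_p, spec$s_w_mg_ml, factors$T
  )
  list(
    l = diffusion_distance(factors$D, factors$Dur),
    t_lag = t_lag,
    k_p = k_p,
    chi = chi,
    fa = fraction_absorbed(chi, factors$Dur, t_lag, factors$a)
  )
}

#' Daily dermal dose
#'
#' `dose = C_art * (SA/BW) * l * FA * ED/AT`, mg/kg/d; strictly linear in
#' `C_art`, so doses at two concentrations stand in the ratio of the
#' concentrations.
#'
#' @param c_art Chemical concentration in the article, mg/cm3 (>= 0).
#' @param factors An [exposure_factors()] set.
#' @param intermediates Output of [dermal_intermediates()] computed under
#'   the same factor set.
#' @return Daily dose, mg/kg/d.
#' @export
dermal_daily_dose <- function(c_art, factors, intermediates) {
  stopifnot(all(c_art >= 0))
  c_art * factors$SA_over_BW * intermediates$l * intermediates$fa *
    factors$ED / factors$AT
}

#' Calibrate the solid-phase diffusivity to a dermal dose anchor
#'
#' The CEM defaults behind the published screening assessment are not all
#' public; what is published is the dermal dose of DEHP at the 100 mg/kg
#' inclusion-threshold concentration (8.6e-6 mg/kg/d). Since the fraction
#' absorbed does not depend on `D`, the required diffusion distance, and
#' hence `D`, follows in closed form from that anchor:
#' `l = anchor / (C_art * SA/BW * FA * ED/AT)`, `D = (l/200)^2 / (Dur/60)`.
#'
#' @param factors An [exposure_factors()] set (its `D` is ignored).
#' @param anchor_dose Anchor dermal dose, mg/kg/d.
#' @param anchor_conc_mg_kg Concentration at which the anchor holds, mg/kg.
#' @param anchor_chemical Chemical of the anchor (default "DEHP").
#' @param registry Chemical registry.
#' @return The diffusion coefficient D, m2/h.
#' @export
calibrate_diffusivity <- function(factors, anchor_dose = 8.6e-6,
                                  anchor_conc_mg_kg = 100,
                                  anchor_chemical = "DEHP",
                                  registry = plasticizer_registry()) {
  stopifnot(anchor_dose > 0, anchor_conc_mg_kg > 0)
  spec <- get_chemical(anchor_chemical, registry)
  k_p <- skin_permeability(spec$k_lip, spec$k_pol, spec$k_aq)
  t_lag <- lag_time(spec$mw, factors$h_sc)
  chi <- volatility_ratio(
    factors$h, spec$p_vap_torr, spec$mw, k_p, spec$s_w_mg_ml, factors$T
  )
  fa <- fraction_absorbed(chi, factors$Dur, t_lag, factors$a)
  c_art <- article_concentration(anchor_conc_mg_kg, factors$rho_article)
  l_cm <- anchor_dose / (c_art * factors$SA_over_BW * fa * factors$ED / factors$AT)
  l_m <- l_cm / 100
  (l_m / 2)^2 / (factors$Dur / 60)
}

#' Default calibrated exposure factor set
#'
#' Builds [exposure_factors()] with the two free components fixed by
#' calibration to the published screening outputs: `use_hours` so that the
#' high-migration ingestion scenario (MR = 10 mg/cm2/h) yields
#' 5.0e-1 mg/kg/d, and `D` so that DEHP at the 100 mg/kg threshold yields a
#' dermal dose of 8.6e-6 mg/kg/d. All other components are conventional
#' child defaults, each overridable through `...`.
#'
#' @param ... Overrides passed to [exposure_factors()].
#' @param registry Chemical registry.
#' @return A calibrated `exposure_factors` object.
#' @export
default_exposure_factors <- function(..., registry = plasticizer_registry()) {
  f <- exposure_factors(...)
  if (is.na(f$use_hours)) {
    f$use_hours <- calibrate_use_hours(f)
  }
  if (is.na(f$D)) {
    f$D <- calibrate_diffusivity(f, registry = registry)
  }
  f
}
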