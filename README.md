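# plastexpo

Screening-level exposure assessment of plasticizers in children's
products: deterministic and probabilistic (Monte Carlo) estimation of
daily ingestion and dermal doses with margin-of-exposure (MOE)
screening.

## The problem

Phthalate plasticizers (and adipate alternatives) migrate out of the
plastic parts of children's products. Given a concentration survey — one
row per product with its category and per-chemical content in mg/kg plus
a detected/non-detected flag — a screening assessment asks: how much of
each chemical does a child plausibly ingest (by mouthing) and absorb (by
skin contact) per day, and how does that compare with the toxicological
reference dose? The package covers six chemicals (DBP, DEHP, DEP, DIBP,
DINP, DEHA) across six product categories (accessories, mats, shoes,
stationery, toilet products, toys), for users doing consumer-product
risk screening who need the full pipeline — censoring rules, content-based
migration-rate assignment, a dermal absorption micro-model, Monte Carlo
uncertainty propagation — as inspectable, tested code.

## The model

Two routes, following the U.S. EPA Consumer Exposure Model (CEM)
algorithm structure:

**Ingestion** (mouthing; accessories, stationery and toys only):

    dose_ing = MR · CA · (D_mouthing/60) · use_hours · ED / (BW · AT)

where the migration rate MR (mg cm⁻² h⁻¹) is assigned from the
chemical's content class: ≥ 1% w/w → 10, below → 0.1 (two-level
screening policy; the four-level CEM ladder 10 / 0.1 / 10⁻³ / 10⁻⁴ is
available for sensitivity analysis).

**Dermal** (hands only, all categories):

    dose_derm = C_art · (SA/BW) · l · FA · ED/AT

with diffusion distance l = 2·√(D·Dur/60), stratum-corneum lag time
t_lag = h_sc / (6·10^(−2.8 − 0.0056·MW)), series permeability
K_p = [(K_lip + K_pol)⁻¹ + K_aq⁻¹]⁻¹, volatility ratio
χ = h·p_vap·MW / (K_p·S_w·R·T), and fraction absorbed
FA = (3 + χ[1 − e^(−a·Dur/t_lag)]) / (3(1 + χ)).

**Screening**: MOE = RfD / dose per chemical, flagged below 100.

Two published anchors calibrate the factor set in closed form (the
high-migration ingestion dose 5.0×10⁻¹ mg kg⁻¹ d⁻¹ and the DEHP dermal
dose 8.6×10⁻⁶ mg kg⁻¹ d⁻¹ at the 100 mg/kg inclusion threshold); both
dose equations are linear in their scaling input, so the anchors
propagate to every scenario. A seeded synthetic survey generator
reproduces the published occurrence margins of the 3345-product study
exactly (387 products with ≥ 1 plasticizer, 286 single-plasticizer, all
per-cell detection counts and concentration maxima), so the entire
pipeline runs without any proprietary data. See
`vignettes/exposure-methods.Rmd` for the full account.

## Worked example

```r
library(plastexpo)
factors <- default_exposure_factors()       # calibrated defaults
survey  <- generate_survey(seed = 42)       # synthetic 3345-product survey
tab     <- exposure_table(survey, factors)  # deterministic screening table

dehp <- tab[tab$chemical == "DEHP",
            c("category","ingestion_max","dermal_max","total_max","moe_max","moe_min")]
for (col in setdiff(names(dehp), "category")) dehp[[col]] <- format_sci2(dehp[[col]])
print(as.data.frame(dehp), row.names = FALSE)
#>     category ingestion_max dermal_max total_max moe_max moe_min
#>  accessories       5.0e-01    2.0e-02   5.2e-01 5.8e+00 6.0e+02
#>          mat          <NA>    1.7e-02   1.7e-02 1.7e+02 3.5e+05
#>        shoes          <NA>    3.3e-02   3.3e-02 9.0e+01 3.5e+05
#>   stationery       5.0e-01    2.9e-02   5.3e-01 5.7e+00 6.0e+02
#>       toilet          <NA>    7.2e-03   7.2e-03 4.1e+02 3.5e+05
#>          toy       5.0e-01    2.4e-02   5.2e-01 5.7e+00 6.0e+02
```

Reading the DEHP rows: in the three mouthing categories the maximum
ingestion dose is 5.0×10⁻¹ mg kg⁻¹ d⁻¹ (DEHP exceeds 1% w/w there, so
the high migration rate applies); the dermal maxima scale linearly with
each category's highest concentration (e.g. 1.7×10⁻² at 20.13% w/w in
mats, 2.9×10⁻² at 33.68% w/w in stationery); mats, shoes and toilet
products carry no ingestion route, so their totals equal the dermal
dose. The worst-case MOE of ~5.7 (reference dose 3 mg kg⁻¹ d⁻¹ over a
total of ~0.52) sits far below the screening concern level of 100 —
driven almost entirely by the assigned migration rate, which the
sensitivity analysis (`migration_sensitivity()`) shows can overstate
measured migration by up to five orders of magnitude.

The full workflow lives in `analysis/`: `01_simulate_survey.R` (generate
and validate the survey), `02_deterministic_exposure.R` (screening
table), `03_probabilistic_exposure.R` (10,000-iteration Monte Carlo per
age group, 0–2 and 3–12 years), `04_migration_sensitivity.R`. Each
writes its tables under `results/`.

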