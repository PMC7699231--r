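Package: plastexpo
Title: Screening-Level Exposure Assessment of Plasticizers in Children's Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic (Monte Carlo) estimation of daily
    ingestion and dermal doses of six plasticizers (DBP, DEHP, DEP, DIBP, DINP,
    DEHA) from product concentration surveys of children's products, following
    the exposure algorithms of the U.S. EPA Consumer Exposure Model (CEM):
    content-based migration-rate assignment for mouthing ingestion, and a
    stratum-corneum absorption micro-model (diffusion distance, lag time,
    permeability in series, evaporation/absorption competition) for dermal
    contact. Includes margin-of-exposure (MOE) screening against reference
    doses, a migration-rate sensitivity analysis, handling of left-censored
    concentrations (substitution at half the quantitation limit), and a seeded
    synthetic survey generator constrained to published occurrence margins so
    the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
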