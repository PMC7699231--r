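# Mouthing-ingestion dose and the content-based migration-rate assignment
# used by the CEM screening algorithm.

#' Migration-rate assignment policy
#'
#' The screening model assigns the article-to-saliva migration rate from
#' the chemical's mass fraction in the article. Two policies:
#'
#' * `two_level` (the deterministic screening default): content >= 1% w/w
#'   maps to 10 mg/cm2/h, below 1% to 0.1 mg/cm2/h.
#' * `four_level` (full CEM ladder, used in the sensitivity analysis):
#'   10, 0.1, 1e-3, 1e-4 mg/cm2/h on content classes
#'   >= 1%, >= 0.1%, >= 0.01%, below 0.01%.
#'
#' @param mode `"two_level"` or `"four_level"`.
#' @return A `migration_policy` object holding decreasing content
#'   thresholds (fractions w/w) and the MR assigned at or above each; the
#'   last MR applies below the last threshold.
#' @export
migration_policy <- function(mode = c("two_level", "four_level")) {
  mode <- match.arg(mode)
  pol <- switch(mode,
    two_level = list(thresholds = 0.01, mr = c(10, 0.1)),
    four_level = list(thresholds = c(0.01, 0.001, 1e-4), mr = c(10, 0.1, 1e-3, 1e-4))
  )
  stopifnot(all(pol$mr > 0), all(diff(pol$mr) < 0))
  structure(c(pol, list(mode = mode)), class = "migration_policy")
}

#' Assign a migration rate from chemical content
#'
#' Deterministic mapping from mass fraction to migration rate under a
#' [migration_policy()]; boundaries are inclusive upwards (content exactly
#' 1% receives the high rate).
#'
#' @param content Mass fraction w/w in `[0, 1]` (vectorized).
#' @param policy A [migration_policy()].
#' @return Migration rate(s), mg/cm2/h.
#' @examples
#' assign_migration_rate(0.229) # 10
#' assign_migration_rate(0.0035) # 0.1
#' @export
assign_migration_rate <- function(content, policy = migration_policy("two_level")) {
  stopifnot(inherits(policy, "migration_policy"))
  if (any(content < 0 | content > 1)) {
    stop("content must be a mass fraction in [0, 1]", call. = FALSE)
  }
  # findInterval over descending thresholds: count thresholds met
  idx <- vapply(
    content,
    function(x) sum(x >= policy$thresholds),
    numeric(1)
  )
  policy$mr[length(policy$thresholds) + 1 - idx]
}

#' Daily ingestion dose from mouthing
#'
#' `dose = MR * CA * (D_mouthing/60) * use_hours * ED / (BW * AT)` in
#' mg/kg/d: the migration flux over the mouthed area, accumulated over the
#' mouthing minutes per hour of product use and the daily use hours,
#' normalized by body weight and averaged over ED/AT. Strictly linear in
#' MR, so the two-level policy's rates 10 and 0.1 produce doses exactly
#' 100x apart.
#'
#' @param mr Migration rate, mg/cm2/h (>= 0, vectorized).
#' @param factors An [exposure_factors()] set with `use_hours` filled in.
#' @return Daily dose, mg/kg/d.
#' @export
ingestion_daily_dose <- function(mr, factors) {
  if (any(mr < 0)) stop("migration rate must be non-negative", call. = FALSE)
  if (is.na(factors$use_hours)) {
    stop("factor set has no use_hours; calibrate or set it", call. = FALSE)
  }
  mr * factors$CA * (factors$D_mouthing / 60) * factors$use_hours *
    factors$ED / (factors$BW * factors$AT)
}

#' Calibrate daily use hours to an ingestion dose anchor
#'
#' The published screening output fixes the high-migration ingestion dose:
#' MR = 10 mg/cm2/h yields 5.0e-1 mg/kg/d. With contact area, mouthing
#' minutes and body weight at their defaults, the daily product-use hours
#' follow in closed form:
#' `use_hours = anchor * BW * AT / (MR * CA * (D_mouthing/60) * ED)`.
#'
#' @param factors An [exposure_factors()] set (its `use_hours` is ignored).
#' @param anchor_dose Anchor dose, mg/kg/d (default 0.5).
#' @param anchor_mr Migration rate of the anchor scenario, mg/cm2/h
#'   (default 10).
#' @return Daily use hours, h/d.
#' @export
calibrate_use_hours <- function(factors, anchor_dose = 0.5, anchor_mr = 10) {
  stopifnot(anchor_dose > 0, anchor_mr > 0)
  anchor_dose * factors$BW * factors$AT /
    (anchor_mr * factors$CA * (factors$D_mouthing / 60) * factors$ED)
}
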