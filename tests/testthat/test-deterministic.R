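test_that("margin of exposure divides reference dose by dose and marks zero exposure undefined", {
  expect_equal(moe(2, 2), 1)
  expect_equal(moe(3, 7.3e-3), 3 / 7.3e-3)
  expect_true(is.na(moe(2, 0)))
  expect_equal(moe(15, c(1, 0, 3)), c(15, NA, 5))
  expect_error(moe(0, 1), "positive")
  expect_error(moe(2, -1), "non-negative")
})

test_that("exposure ranges compute both scenarios with routes per category policy", {
  f <- test_factors()
  s <- filter_for_exposure(test_survey())

  # toilet: dermal only, total equals dermal
  res <- category_exposure_range(s, "DEHP", "toilet", f)
  expect_false("ingestion" %in% res$route)
  tot <- res[res$route == "total", ]
  der <- res[res$route == "dermal", ]
  expect_equal(tot$dose, der$dose)

  # toy: both routes, total is the route sum within scenario
  res <- category_exposure_range(s, "DEHP", "toy", f)
  for (scn in c("max", "min")) {
    parts <- res[res$route %in% c("ingestion", "dermal") & res$scenario == scn, ]
    expect_equal(res$dose[res$route == "total" & res$scenario == scn], sum(parts$dose))
  }
  # max scenario of a >1% cell uses the high migration rate
  expect_equal(res$dose[res$route == "ingestion" & res$scenario == "max"], 0.5)
  # min scenario sits at the inclusion threshold, hence the low rate
  expect_equal(res$dose[res$route == "ingestion" & res$scenario == "min"], 5e-3)

  # absent chemical yields an empty result, not an error
  expect_equal(nrow(category_exposure_range(s, "DEP", "mat", f)), 0)

  # a cell entirely below 1% has identical ingestion max and min
  low <- tibble::tibble(
    product_id = c("q1", "q2"), category = "accessories", subcategory = "x",
    chemical = "DEHA", concentration = c(5000, 300), unit = "mg_per_kg",
    detected = TRUE
  )
  res <- category_exposure_range(low, "DEHA", "accessories", f)
  ing <- res[res$route == "ingestion", ]
  expect_equal(ing$dose[ing$scenario == "max"], ing$dose[ing$scenario == "min"])
})

test_that("the screening table is internally consistent across routes, scenarios and MOEs", {
  f <- test_factors()
  tab <- exposure_table(test_survey(), f)
  # 23 detected cells minus the two whose maximum sits exactly at the
  # 100 mg/kg inclusion boundary (mat/DBP, stationery/DIBP)
  expect_equal(nrow(tab), 21)
  # ingestion assessed only for the mouthing categories
  non_mouth <- tab[!tab$category %in% ingestion_categories(), ]
  expect_true(all(is.na(non_mouth$ingestion_max)))
  mouth <- tab[tab$category %in% ingestion_categories(), ]
  expect_true(all(!is.na(mouth$ingestion_max)))
  # totals are route sums at full precision
  expect_equal(
    mouth$total_max, mouth$ingestion_max + mouth$dermal_max,
    tolerance = 1e-12
  )
  expect_equal(non_mouth$total_max, non_mouth$dermal_max, tolerance = 1e-12)
  # the margin shrinks as the dose grows
  expect_true(all(tab$moe_max <= tab$moe_min))
  expect_equal(tab$moe_max, tab$reference_dose / tab$total_max)

  # dermal max/min ratio equals the concentration ratio (linearity)
  sm <- summarize_survey(filter_for_exposure(test_survey()))
  for (i in seq_len(nrow(tab))) {
    cmax <- sm$conc_max[sm$category == tab$category[i] & sm$chemical == tab$chemical[i]]
    expect_equal(tab$dermal_max[i] / tab$dermal_min[i], cmax / 100, tolerance = 1e-9)
  }

  # empty survey -> empty report
  expect_equal(nrow(exposure_table(tiny_survey()[0, ], f)), 0)
})

test_that("screening table reproduces the published DEHP dermal column from the calibration anchor", {
  f <- test_factors()
  tab <- exposure_table(test_survey(), f)
  dehp <- tab[tab$chemical == "DEHP", ]
  # the minimum scenario is the same threshold concentration in every category
  expect_true(all(abs(dehp$dermal_min - 8.6e-6) < 1e-12))
  expect_equal(
    signif(dehp$dermal_max[dehp$category == "mat"], 2), 1.7e-2
  )
  expect_equal(
    signif(dehp$dermal_max[dehp$category == "stationery"], 2), 2.9e-2
  )
  expect_equal(
    signif(dehp$dermal_max[dehp$category == "accessories"], 2), 2.0e-2
  )
  expect_equal(
    signif(dehp$dermal_max[dehp$category == "toy"], 2), 2.4e-2
  )
})

test_that("migration sensitivity spans the CEM ladder linearly and admits measured rates", {
  f <- test_factors()
  sens <- migration_sensitivity(test_survey(), f)
  expect_true(all(sens$category %in% ingestion_categories()))
  one <- sens[sens$category == "toy" & sens$chemical == "DINP", ]
  expect_equal(max(one$dose) / min(one$dose), 1e5)
  expect_equal(max(one$mr) / min(one$mr), 1e5)

  with_exp <- migration_sensitivity(test_survey(), f, experimental_mr = 8.3e-2)
  dinp <- with_exp[with_exp$chemical == "DINP" & with_exp$category == "toy", ]
  assigned_high <- dinp$dose[dinp$mr_source == "assigned" & dinp$mr == 10]
  measured <- dinp$dose[dinp$mr_source == "experimental"]
  expect_equal(assigned_high / measured, 10 / 8.3e-2, tolerance = 1e-12)

  # a single level degenerates to one ingestion column
  single <- migration_sensitivity(test_survey(), f, mr_levels = 0.1)
  expect_equal(unique(single$dose), ingestion_daily_dose(0.1, f))
})

test_that("scientific display formatting rounds to two significant figures", {
  expect_equal(format_sci2(0.024011), "2.4e-02")
  expect_equal(format_sci2(30612245), "3.1e+07")
  expect_true(is.na(format_sci2(NA_real_)))
})
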