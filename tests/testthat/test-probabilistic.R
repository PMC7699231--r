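make_cell_survey <- function(conc, category = "toy", chemical = "DEHP",
                             detected = TRUE) {
  tibble::tibble(
    product_id = sprintf("s%03d", seq_along(conc)),
    category = category, subcategory = "x", chemical = chemical,
    concentration = ifelse(rep(detected, length.out = length(conc)), conc, NA_real_),
    unit = "mg_per_kg", detected = rep(detected, length.out = length(conc))
  )
}

test_that("distribution constructors sample their nominal laws", {
  expect_equal(sample_dist(dist_point(3.2), 5), rep(3.2, 5))
  set.seed(1)
  x <- sample_dist(dist_truncnorm(10, 3), 5000)
  expect_true(all(x >= 1 & x <= 19)) # mean +/- 3 sd bounds
  expect_equal(mean(x), 10, tolerance = 0.05)
  set.seed(1)
  y <- sample_dist(dist_lognormal(log(1000), 0.5), 5000)
  expect_equal(median(y), 1000, tolerance = 0.05)
})

test_that("concentration fits match the log moments and degenerate correctly", {
  s <- make_cell_survey(c(100, 1000, 10000))
  fit <- fit_concentration_distribution(s, "DEHP", "toy")
  expect_equal(fit$kind, "lognormal")
  expect_equal(fit$meanlog, log(1000))
  expect_equal(fit$sdlog, sd(log(c(100, 1000, 10000))))

  # all-nondetect cell collapses to a point mass at LOQ/2
  nd <- make_cell_survey(c(NA, NA, NA), detected = FALSE)
  fit <- fit_concentration_distribution(nd, "DEHP", "toy")
  expect_equal(fit$kind, "point")
  expect_equal(fit$value, 32.5 / 2)

  # a single measurement is insufficient, not an error
  one <- make_cell_survey(500)
  expect_equal(fit_concentration_distribution(one, "DEHP", "toy")$kind, "insufficient")

  # sanity: fitted median below the observed maximum on a real cell
  s2 <- filter_for_exposure(test_survey())
  fit2 <- fit_concentration_distribution(test_survey(), "DEHP", "toy")
  expect_lt(
    exp(fit2$meanlog),
    max(s2$concentration[s2$chemical == "DEHP" & s2$category == "toy"])
  )
})

test_that("degenerate point-mass simulation collapses onto the deterministic engine", {
  # a factor set whose dermal contact duration and ingestion use hours
  # describe the same one-hour daily activity
  f <- default_exposure_factors(use_hours = 1, Dur = 60)
  s <- make_cell_survey(c(250000, 250000))
  mc <- run_mc(s,
    profiles = list(deg = point_profile(f)),
    factors = f, n_iter = 25, seed = 3
  )
  det <- category_exposure_range(s, "DEHP", "toy", f)
  for (route in c("ingestion", "dermal", "total")) {
    mc_row <- mc[mc$route == route, ]
    det_dose <- det$dose[det$route == route & det$scenario == "max"]
    expect_equal(mc_row$median, det_dose, tolerance = 1e-12)
    expect_equal(mc_row$p95, det_dose, tolerance = 1e-12)
  }
})

test_that("simulation is bit-reproducible under its seed", {
  s <- dplyr::filter(test_survey(), category %in% c("toy", "mat"))
  f <- test_factors()
  prof <- default_age_profiles(f)
  a <- run_mc(s, prof, factors = f, n_iter = 200, seed = 11)
  b <- run_mc(s, prof, factors = f, n_iter = 200, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_mc(s, prof, factors = f, n_iter = 200, seed = 12)
  expect_false(identical(a$median, c$median))
})

test_that("younger children receive the higher ingestion dose for every chemical", {
  f <- test_factors()
  mc <- run_mc(test_survey(), default_age_profiles(f),
    factors = f, n_iter = 2000, seed = 7
  )
  ing <- mc[mc$route == "ingestion", ]
  for (chem in unique(ing$chemical)) {
    expect_gt(
      ing$median[ing$chemical == chem & ing$age_group == "0-2"],
      ing$median[ing$chemical == chem & ing$age_group == "3-12"]
    )
  }
  # order statistics and their margins are coherent
  expect_true(all(mc$median <= mc$p95))
  expect_true(all(mc$moe_p95 <= mc$moe_median))
})

test_that("the summary table pairs each MOE with its dose statistic", {
  f <- test_factors()
  s <- dplyr::filter(test_survey(), category == "toy")
  mc <- run_mc(s, default_age_profiles(f), factors = f, n_iter = 300, seed = 2)
  tab <- summarize_mc(mc)
  expect_setequal(
    names(tab),
    c(
      "chemical", "age_group", "ingestion_median", "ingestion_p95",
      "dermal_median", "dermal_p95", "total_median", "total_p95",
      "moe_median", "moe_p95"
    )
  )
  expect_true(all(tab$moe_p95 <= tab$moe_median))
  expect_true(all(tab$total_median <= tab$total_p95))
  rfd <- setNames(
    plasticizer_registry()$reference_dose,
    plasticizer_registry()$abbreviation
  )
  expect_equal(tab$moe_p95, unname(rfd[tab$chemical]) / tab$total_p95)
  expect_equal(nrow(summarize_mc(mc[0, ])), 0)
})
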