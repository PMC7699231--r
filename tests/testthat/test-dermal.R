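test_that("diffusion distance follows the square-root reading with unit conversion", {
  expect_equal(diffusion_distance(2.5e-9, 60), 0.01) # 1.0e-4 m = 1.0e-2 cm
  expect_equal(diffusion_distance(0, 60), 0)
  expect_equal(diffusion_distance(1e-9, 0), 0)
  expect_error(diffusion_distance(-1e-9, 60), "non-negative")
  # the literal linear reading stays available for auditing
  expect_equal(diffusion_distance(2.5e-9, 60, literal = TRUE), 2 * 2.5e-9 * 100)
})

test_that("stratum corneum lag time matches direct evaluation and vanishes with thickness", {
  expect_equal(lag_time(390.56), 24.27034829, tolerance = 1e-8) # DEHP
  expect_equal(lag_time(278.34), 5.710103874, tolerance = 1e-8) # DBP
  expect_equal(lag_time(300, h_sc = 1.5e-6), lag_time(300) / 1000)
  expect_error(lag_time(-1), "positive")
})

test_that("series permeability is bounded by each resistance and matches arithmetic cases", {
  expect_equal(skin_permeability(1, 1, 2), 1)
  k <- 0.4
  expect_equal(skin_permeability(k / 2, k / 2, k), k / 2)
  # large aqueous permeability recovers the stratum corneum limit
  expect_equal(skin_permeability(0.3, 0.01, 1e9), 0.31, tolerance = 1e-6)
  for (i in 1:50) {
    k3 <- exp(runif(3, -8, 2))
    kp <- skin_permeability(k3[1], k3[2], k3[3])
    expect_lt(kp, min(k3[1] + k3[2], k3[3]))
  }
  expect_error(skin_permeability(0, 1, 1), "positive")
})

test_that("volatility ratio matches direct substitution and scales as expected", {
  # frozen against single-expression hand evaluation
  expect_equal(
    volatility_ratio(h = 10, p_vap = 1e-5, mw = 278.34, k_p = 1e-3,
                     s_w = 1.12e-2, T = 298),
    13.37105244,
    tolerance = 1e-8
  )
  expect_equal(volatility_ratio(10, 0, 278.34, 1e-3, 1.12e-2, 298), 0)
  chi1 <- volatility_ratio(10, 1e-5, 278.34, 1e-3, 1.12e-2, 298)
  chi2 <- volatility_ratio(10, 1e-5, 278.34, 1e-3, 2 * 1.12e-2, 298)
  expect_equal(chi1 / chi2, 2) # doubling solubility halves chi
  expect_error(volatility_ratio(10, 1e-5, 278.34, 0, 1.12e-2, 298), "positive")
})

test_that("fraction absorbed respects its limits, bounds and monotonicities", {
  expect_equal(fraction_absorbed(0, 60, 5), 1)
  expect_equal(fraction_absorbed(0, 1e4, 0.01), 1)
  # chi = 1 with exponent ln 2 gives (3 + 1/2) / 6
  t_lag <- 2
  dur <- log(2) * t_lag * 60
  expect_equal(fraction_absorbed(1, dur, t_lag, a = 1), 7 / 12)
  # volatile, long-contact limit -> 1/3
  expect_equal(fraction_absorbed(1e9, 1e6, 0.1), 1 / 3, tolerance = 1e-4)

  set.seed(7)
  for (i in 1:200) {
    chi <- exp(runif(1, -5, 8))
    dur <- runif(1, 0, 600)
    t_lag <- exp(runif(1, -2, 4))
    a <- runif(1, 0, 3)
    fa <- fraction_absorbed(chi, dur, t_lag, a)
    expect_gt(fa, 0)
    expect_lte(fa, 1)
    # non-increasing in chi, non-decreasing in Dur
    expect_lte(fraction_absorbed(chi * 2, dur, t_lag, a), fa + 1e-12)
    expect_gte(fraction_absorbed(chi, dur * 2, t_lag, a) + 1e-12, fa)
  }
  expect_error(fraction_absorbed(1, 60, 0), "positive")
})

test_that("dermal dose is linear in concentration and anchored by calibration", {
  f <- test_factors()
  inter <- dermal_intermediates("DEHP", f)
  d1 <- dermal_daily_dose(article_concentration(100, f$rho_article), f, inter)
  d2 <- dermal_daily_dose(article_concentration(200, f$rho_article), f, inter)
  expect_equal(d2, 2 * d1)
  expect_equal(dermal_daily_dose(0, f, inter), 0)
  # calibration anchor: DEHP at the 100 mg/kg threshold
  expect_equal(d1, 8.6e-6, tolerance = 1e-10)
})

test_that("factor set construction validates signs and the ED/AT ordering", {
  expect_error(exposure_factors(BW = -1), "strictly positive")
  expect_error(exposure_factors(a = -0.1), "non-negative")
  expect_error(exposure_factors(ED = 400, AT = 365), "ED must not exceed AT")
  f <- exposure_factors()
  expect_s3_class(f, "exposure_factors")
  expect_equal(f$h_sc, 1.5e-3)
  expect_error(dermal_intermediates("DEHP", f), "no diffusion coefficient")
})
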