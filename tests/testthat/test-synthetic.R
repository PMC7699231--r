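test_that("generated survey reproduces every published margin", {
  s <- test_survey()
  bp <- default_blueprint()
  vm <- validate_margins(s, bp)
  expect_true(attr(vm, "pass"))
  expect_equal(vm$observed[vm$constraint == "total_products"], 3345)
  expect_equal(vm$observed[vm$constraint == "products_with_any_detection"], 387)
  expect_equal(vm$observed[vm$constraint == "products_with_single_detection"], 286)
  # survey-wide detection counts per chemical
  det <- dplyr::count(dplyr::filter(s, detected), chemical)
  counts <- setNames(det$n, det$chemical)
  expect_equal(
    counts[c("DEHP", "DINP", "DBP", "DEHA", "DIBP", "DEP")],
    c(DEHP = 264, DINP = 141, DBP = 66, DEHA = 30, DIBP = 14, DEP = 10)
  )
  # per-category column sums recompose the per-chemical totals
  dinp <- dplyr::count(
    dplyr::filter(s, detected, chemical == "DINP"), category
  )
  expect_equal(sum(dinp$n), 29 + 1 + 29 + 54 + 9 + 19)
})

test_that("concentration structure honours the threshold, the maxima and both migration classes", {
  s <- test_survey()
  det <- dplyr::filter(s, detected)
  expect_true(all(det$concentration >= 100))
  # each cell's maximum is hit exactly once
  sm <- summarize_survey(det)
  bp <- default_blueprint()
  for (i in seq_len(nrow(bp$maxima))) {
    cell <- det[det$category == bp$maxima$category[i] &
      det$chemical == bp$maxima$chemical[i], ]
    expect_equal(max(cell$concentration), bp$maxima$conc_max[i])
    expect_equal(sum(cell$concentration == bp$maxima$conc_max[i]), 1)
  }
  # the eraser: one stationery product at exactly 40.52% w/w DINP
  eraser <- det[det$category == "stationery" & det$chemical == "DINP" &
    det$concentration == 405200, ]
  expect_equal(nrow(eraser), 1)
  # both migration-rate classes occur among DEHP detections
  dehp <- det$concentration[det$chemical == "DEHP"]
  expect_gt(sum(dehp >= 1e4), 0)
  expect_gt(sum(dehp < 1e4), 0)
})

test_that("generation is reproducible for a seed and sensitive to it only in concentrations", {
  a <- generate_survey(seed = 5)
  b <- generate_survey(seed = 5)
  expect_identical(a, b)
  c <- generate_survey(seed = 6)
  expect_false(identical(a$concentration, c$concentration))
  # the structural assignment does not depend on the seed
  expect_identical(a$detected, c$detected)
  expect_identical(a$product_id, c$product_id)
})

test_that("margin validation localizes a perturbed survey", {
  s <- test_survey()
  idx <- which(s$detected & s$chemical == "DEHP")[1]
  broken <- s
  broken$detected[idx] <- FALSE
  broken$concentration[idx] <- NA_real_
  vm <- validate_margins(broken)
  expect_false(attr(vm, "pass"))
  bad <- vm[!vm$pass, ]
  expect_true("detections_total_DEHP" %in% bad$constraint)
  expect_equal(vm$observed[vm$constraint == "detections_total_DEHP"], 263)
})

test_that("inconsistent blueprints are rejected before generation, naming the violation", {
  bp <- default_blueprint()
  bp$category_sizes[["toy"]] <- 1630
  expect_error(check_blueprint(bp), "category sizes")
  bp <- default_blueprint()
  bp$attach$n[bp$attach$category == "accessories" & bp$attach$chemical == "DINP"] <- 25
  expect_error(check_blueprint(bp), "attachment count exceeds")
  bp <- default_blueprint()
  bp$n_single <- 290
  expect_error(check_blueprint(bp), "single-chemical")
  bp <- default_blueprint()
  bp$attach <- dplyr::bind_rows(
    bp$attach, tibble::tibble(category = "toy", chemical = "DEP", n = 1)
  )
  expect_error(check_blueprint(bp), "DEP")
})
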