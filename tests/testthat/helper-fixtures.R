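# Shared fixtures built in code.

# A small hand-written survey covering both routes, censoring, and the
# inclusion boundary.
tiny_survey <- function() {
  tibble::tibble(
    product_id = c("p1", "p1", "p2", "p3", "p4", "p5"),
    category = c("toy", "toy", "toy", "accessories", "mat", "toy"),
    subcategory = "misc",
    chemical = c("DEHP", "DBP", "DEHP", "DEHP", "DEHP", "DEP"),
    concentration = c(250000, NA, 500, 150, 99, 100),
    unit = "mg_per_kg",
    detected = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

# Calibrated default factors, computed once per test run.
test_factors <- local({
  f <- NULL
  function() {
    if (is.null(f)) f <<- default_exposure_factors()
    f
  }
})

# Default synthetic survey, generated once per test run.
test_survey <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- generate_survey(seed = 20261)
    s
  }
})
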