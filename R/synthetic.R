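# Seeded synthetic survey generator. The published survey (3345 products)
# is not deposited; what is published are its margins: category sizes,
# per-(category, chemical) detection counts, the co-occurrence structure
# (387 products with >= 1 plasticizer, 286 with exactly one, DEHP present
# in every multi-plasticizer product except two shoes with DBP+DINP, DEP
# only as a single chemical in 10 toys) and per-(category, chemical)
# maximum concentrations. The generator reproduces every margin exactly
# with a deterministic structural assignment; only concentrations (and the
# cosmetic subcategory labels) are random, under the supplied seed.

#' Default survey blueprint
#'
#' Encodes the published margins: category sizes, per-(category, chemical)
#' detection counts, the per-category maximum concentrations (% w/w
#' converted to mg/kg), the global co-occurrence constraints, and a fixed
#' feasible allocation of co-detections onto DEHP-hosting products. The
#' margins constrain totals, not the joint contingency table, so any
#' consistent allocation is acceptable; this one is fixed so the generator
#' is reproducible. Detected concentrations are drawn from a truncated
#' lognormal on (100 mg/kg, cell maximum); the log-scale location and
#' spread are chosen so that roughly a quarter of detected values exceed
#' 1% w/w in cells whose maximum allows it, which exercises both
#' migration-rate classes.
#'
#' @return A `survey_blueprint` list with elements `category_sizes`,
#'   `detections`, `maxima`, `multi`, `attach`, `n_pair_products`,
#'   `n_products`, `n_any`, `n_single`, `conc_meanlog`, `conc_sdlog`,
#'   `subcategories`.
#' @export
default_blueprint <- function() {
  detections <- tibble::tribble(
    ~category, ~chemical, ~n,
    "accessories", "DBP", 6,
    "accessories", "DEHA", 15,
    "accessories", "DEHP", 51,
    "accessories", "DINP", 29,
    "mat", "DBP", 1,
    "mat", "DEHP", 6,
    "mat", "DINP", 1,
    "shoes", "DBP", 36,
    "shoes", "DEHP", 30,
    "shoes", "DINP", 29,
    "stationery", "DBP", 11,
    "stationery", "DEHA", 6,
    "stationery", "DEHP", 126,
    "stationery", "DIBP", 1,
    "stationery", "DINP", 54,
    "toilet", "DEHP", 5,
    "toilet", "DINP", 9,
    "toy", "DBP", 12,
    "toy", "DEHA", 9,
    "toy", "DEHP", 46,
    "toy", "DEP", 10,
    "toy", "DIBP", 13,
    "toy", "DINP", 19
  )
  maxima <- tibble::tribble(
    ~category, ~chemical, ~conc_max,
    "accessories", "DBP", 3500,
    "accessories", "DEHA", 5900,
    "accessories", "DEHP", 229000,
    "accessories", "DINP", 155200,
    "mat", "DBP", 100,
    "mat", "DEHP", 201300,
    "mat", "DINP", 600,
    "shoes", "DBP", 331200,
    "shoes", "DEHP", 389500,
    "shoes", "DINP", 143400,
    "stationery", "DBP", 1600,
    "stationery", "DEHA", 2000,
    "stationery", "DEHP", 336800,
    "stationery", "DIBP", 100,
    "stationery", "DINP", 405200,
    "toilet", "DEHP", 84100,
    "toilet", "DINP", 48300,
    "toy", "DBP", 80300,
    "toy", "DEHA", 800,
    "toy", "DEHP", 281100,
    "toy", "DEP", 9200,
    "toy", "DIBP", 272000,
    "toy", "DINP", 46800
  )
  # Number of DEHP-hosting multi-plasticizer products per category (99 in
  # total; the remaining 2 multi products are the DBP+DINP shoes pair).
  multi <- c(
    accessories = 20, mat = 2, shoes = 25, stationery = 30,
    toilet = 5, toy = 17
  )
  # Co-detections attached to those DEHP-hosting products.
  attach <- tibble::tribble(
    ~category, ~chemical, ~n,
    "accessories", "DBP", 5,
    "accessories", "DEHA", 10,
    "accessories", "DINP", 20,
    "mat", "DBP", 1,
    "mat", "DINP", 1,
    "shoes", "DBP", 20,
    "shoes", "DINP", 15,
    "stationery", "DBP", 8,
    "stationery", "DEHA", 4,
    "stationery", "DIBP", 1,
    "stationery", "DINP", 25,
    "toilet", "DINP", 5,
    "toy", "DBP", 6,
    "toy", "DEHA", 3,
    "toy", "DIBP", 7,
    "toy", "DINP", 5
  )
  bp <- structure(list(
    category_sizes = c(
      accessories = 605, mat = 110, shoes = 176, stationery = 785,
      toilet = 38, toy = 1631
    ),
    detections = detections,
    maxima = maxima,
    multi = multi,
    attach = attach,
    n_pair_products = 2, # shoes products carrying DBP + DINP, no DEHP
    n_products = 3345,
    n_any = 387,
    n_single = 286,
    conc_meanlog = log(2500),
    conc_sdlog = 2.2,
    subcategories = list(
      accessories = c(
        "clothes", "jewelry", "mobile accessories", "household stuffs",
        "DIY tools"
      ),
      mat = c("non-slip mat", "play mat"),
      shoes = c(
        "roller shoes", "sandals", "summer shoes", "indoor shoes",
        "shower sandals"
      ),
      stationery = c(
        "beauty and personal care", "kitchen stuffs", "office products",
        "painting and drawing supplies", "tools and furniture"
      ),
      toilet = "potty toilet",
      toy = c(
        "gift and party goods", "play figures", "shape and size toys",
        "arts and crafts", "preschool games", "aquatic toys",
        "other infant toys"
      )
    )
  ), class = "survey_blueprint")
  bp
}

#' Check a survey blueprint for internal consistency
#'
#' Verifies that the blueprint's allocation satisfies every margin before
#' generation: category sizes sum to the product total; attachments never
#' exceed the cell detection counts nor the number of hosting products;
#' each hosting product can receive at least one co-detection; DEP is
#' never attached (single-chemical only); and the allocation implies
#' exactly the stated number of products with any detection and with a
#' single detection. Stops at the first violated constraint, naming it.
#'
#' @param bp A `survey_blueprint`.
#' @return The blueprint, invisibly, if consistent.
#' @export
check_blueprint <- function(bp) {
  fail <- function(...) stop("blueprint constraint violated: ", ..., call. = FALSE)
  if (sum(bp$category_sizes) != bp$n_products) {
    fail("category sizes sum to ", sum(bp$category_sizes), " != ", bp$n_products)
  }
  if ("DEP" %in% bp$attach$chemical) fail("DEP may not co-occur")
  for (cat in names(bp$multi)) {
    det <- bp$detections[bp$detections$category == cat, ]
    att <- bp$attach[bp$attach$category == cat, ]
    m <- bp$multi[[cat]]
    dehp_n <- det$n[det$chemical == "DEHP"]
    if (length(dehp_n) == 0) dehp_n <- 0
    if (m > dehp_n) fail(cat, ": ", m, " multi products but only ", dehp_n, " DEHP detections")
    if (nrow(att) > 0) {
      if (any(att$n > m)) {
        fail(cat, ": attachment count exceeds hosting products")
      }
      for (i in seq_len(nrow(att))) {
        cell <- det$n[det$chemical == att$chemical[i]]
        reserve <- if (cat == "shoes" && att$chemical[i] %in% c("DBP", "DINP")) {
          bp$n_pair_products
        } else {
          0
        }
        if (length(cell) == 0 || att$n[i] + reserve > cell) {
          fail(cat, "/", att$chemical[i], ": more attachments than detections")
        }
      }
      if (sum(att$n) < m) fail(cat, ": a hosting product would carry no co-detection")
    } else if (m > 0) {
      fail(cat, ": hosting products but no attachments")
    }
    used <- dehp_n + sum(det$n[det$chemical != "DEHP"])
    if (used > bp$category_sizes[[cat]]) {
      fail(cat, ": more detections than products")
    }
  }
  td <- sum(bp$detections$n)
  multi_products <- sum(bp$multi) + bp$n_pair_products
  multi_detections <- sum(bp$multi) + sum(bp$attach$n) + 2 * bp$n_pair_products
  singles <- td - multi_detections
  if (singles + multi_products != bp$n_any) {
    fail("allocation implies ", singles + multi_products,
      " products with a detection, expected ", bp$n_any
    )
  }
  if (singles != bp$n_single) {
    fail("allocation implies ", singles, " single-chemical products, expected ", bp$n_single)
  }
  miss_max <- dplyr::anti_join(bp$detections, bp$maxima,
    by = c("category", "chemical")
  )
  if (nrow(miss_max) > 0) {
    fail("no maximum concentration for ", miss_max$category[1], "/", miss_max$chemical[1])
  }
  invisible(bp)
}

# Truncated lognormal draw on (lo, hi) by inverse CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a synthetic product survey
#'
#' Builds a survey matching every blueprint margin exactly. The structural
#' assignment (which product carries which chemicals) is deterministic and
#' canonical: within each category, the DEHP-hosting multi-plasticizer
#' products come first, with co-detections distributed cyclically in
#' alphabetical chemical order (so no product receives the same chemical
#' twice and each receives at least one); the non-DEHP pair products (in
#' shoes) follow; then the single-chemical products in alphabetical order;
#' the remainder carry no detection. Each (category, chemical) cell's
#' maximum concentration is assigned to exactly one product (the first in
#' canonical order); the remaining detected concentrations are drawn from
#' the blueprint's truncated lognormal strictly between 100 mg/kg and the
#' cell maximum. Non-detected measurements are emitted for every other
#' (product, chemical) pair with a missing concentration. The same seed
#' yields an identical survey.
#'
#' @param blueprint A `survey_blueprint`; checked first.
#' @param seed Integer seed for the concentration and subcategory draws.
#' @return A survey tibble (long format, 6 rows per product).
#' @export
generate_survey <- function(blueprint = default_blueprint(), seed = 1) {
  check_blueprint(blueprint)
  set.seed(seed)
  chems <- survey_chemicals()
  cats <- names(blueprint$category_sizes)

  surveys <- lapply(cats, function(cat) {
    n_prod <- blueprint$category_sizes[[cat]]
    ids <- sprintf("%s_%04d", cat, seq_len(n_prod))
    det <- blueprint$detections[blueprint$detections$category == cat, ]
    att <- blueprint$attach[blueprint$attach$category == cat, ]
    m <- if (cat %in% names(blueprint$multi)) blueprint$multi[[cat]] else 0

    # detected[i, chem] flags
    detmat <- matrix(FALSE, n_prod, length(chems), dimnames = list(NULL, chems))
    if (m > 0) {
      detmat[seq_len(m), "DEHP"] <- TRUE
      # cyclic assignment of co-detections over the m hosting products
      att_sorted <- att[order(att$chemical), ]
      k <- 0
      for (i in seq_len(nrow(att_sorted))) {
        slots <- ((k + seq_len(att_sorted$n[i]) - 1) %% m) + 1
        detmat[slots, att_sorted$chemical[i]] <- TRUE
        k <- k + att_sorted$n[i]
      }
    }
    next_free <- m + 1
    if (cat == "shoes" && blueprint$n_pair_products > 0) {
      pair_idx <- next_free + seq_len(blueprint$n_pair_products) - 1
      detmat[pair_idx, "DBP"] <- TRUE
      detmat[pair_idx, "DINP"] <- TRUE
      next_free <- next_free + blueprint$n_pair_products
    }
    # singles in alphabetical chemical order
    for (chem in sort(det$chemical)) {
      cell_n <- det$n[det$chemical == chem]
      assigned <- sum(detmat[, chem])
      n_single <- cell_n - assigned
      if (n_single < 0) {
        stop("over-assigned cell ", cat, "/", chem, call. = FALSE)
      }
      if (n_single > 0) {
        idx <- next_free + seq_len(n_single) - 1
        detmat[idx, chem] <- TRUE
        next_free <- next_free + n_single
      }
    }

    subcat <- sample(blueprint$subcategories[[cat]], n_prod, replace = TRUE)
    conc <- matrix(NA_real_, n_prod, length(chems), dimnames = list(NULL, chems))
    for (chem in sort(det$chemical)) {
      slots <- which(detmat[, chem])
      cmax <- blueprint$maxima$conc_max[
        blueprint$maxima$category == cat & blueprint$maxima$chemical == chem
      ]
      conc[slots[1], chem] <- cmax
      if (length(slots) > 1) {
        if (cmax <= INCLUSION_THRESHOLD_MG_KG) {
          stop(
            "cell ", cat, "/", chem, " has multiple detections but a maximum",
            " at the inclusion threshold",
            call. = FALSE
          )
        }
        conc[slots[-1], chem] <- rlnorm_trunc(
          length(slots) - 1, blueprint$conc_meanlog, blueprint$conc_sdlog,
          INCLUSION_THRESHOLD_MG_KG, cmax
        )
      }
    }

    tibble::tibble(
      product_id = rep(ids, each = length(chems)),
      category = cat,
      subcategory = rep(subcat, each = length(chems)),
      chemical = rep(chems, times = n_prod),
      concentration = as.vector(t(conc)),
      unit = "mg_per_kg",
      detected = as.vector(t(detmat))
    )
  })
  out <- dplyr::bind_rows(surveys)
  validate_survey(out)
  out
}

#' Validate a survey against a blueprint's margins
#'
#' Compares every blueprint constraint against the survey: total and
#' per-category product counts, per-(category, chemical) detection counts,
#' per-chemical totals, the number of products with any and with exactly
#' one detection, the DEP single-use rule, the DEHP co-occurrence rule
#' (every multi-plasticizer product contains DEHP except the stated number
#' of DBP+DINP shoes), and the per-cell maximum concentrations.
#'
#' @param survey A survey tibble.
#' @param blueprint A `survey_blueprint`.
#' @return A tibble with columns `constraint`, `expected`, `observed`,
#'   `pass`, with an attribute `"pass"` giving the overall verdict.
#' @export
validate_margins <- function(survey, blueprint = default_blueprint()) {
  validate_survey(survey)
  checks <- list()
  add <- function(constraint, expected, observed) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      constraint = constraint,
      expected = as.numeric(expected),
      observed = as.numeric(observed),
      pass = isTRUE(all.equal(as.numeric(expected), as.numeric(observed)))
    )
  }

  products <- dplyr::distinct(survey, .data$product_id, .data$category)
  add("total_products", blueprint$n_products, nrow(products))
  for (cat in names(blueprint$category_sizes)) {
    add(
      paste0("products_", cat), blueprint$category_sizes[[cat]],
      sum(products$category == cat)
    )
  }

  det <- dplyr::filter(survey, .data$detected)
  cell_counts <- dplyr::count(det, .data$category, .data$chemical)
  for (i in seq_len(nrow(blueprint$detections))) {
    row <- blueprint$detections[i, ]
    obs <- cell_counts$n[
      cell_counts$category == row$category & cell_counts$chemical == row$chemical
    ]
    add(
      paste0("detections_", row$category, "_", row$chemical), row$n,
      if (length(obs) == 0) 0 else obs
    )
  }
  chem_totals <- dplyr::count(det, .data$chemical)
  bp_chem_totals <- blueprint$detections |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  for (i in seq_len(nrow(bp_chem_totals))) {
    obs <- chem_totals$n[chem_totals$chemical == bp_chem_totals$chemical[i]]
    add(
      paste0("detections_total_", bp_chem_totals$chemical[i]),
      bp_chem_totals$n[i], if (length(obs) == 0) 0 else obs
    )
  }

  per_product <- det |>
    dplyr::group_by(.data$product_id, .data$category) |>
    dplyr::summarise(
      n_chem = dplyr::n(),
      has_dehp = any(.data$chemical == "DEHP"),
      chems = paste(sort(.data$chemical), collapse = "+"),
      .groups = "drop"
    )
  add("products_with_any_detection", blueprint$n_any, nrow(per_product))
  add(
    "products_with_single_detection", blueprint$n_single,
    sum(per_product$n_chem == 1)
  )

  dep_rows <- dplyr::filter(det, .data$chemical == "DEP")
  dep_products <- per_product[per_product$product_id %in% dep_rows$product_id, ]
  add("dep_only_in_toys", 0, sum(dep_rows$category != "toy"))
  add("dep_always_single", 0, sum(dep_products$n_chem != 1))

  multi_no_dehp <- per_product[per_product$n_chem > 1 & !per_product$has_dehp, ]
  add("multi_without_dehp", blueprint$n_pair_products, nrow(multi_no_dehp))
  add(
    "multi_without_dehp_are_dbp_dinp_shoes", blueprint$n_pair_products,
    sum(multi_no_dehp$category == "shoes" & multi_no_dehp$chems == "DBP+DINP")
  )

  cell_max <- det |>
    dplyr::group_by(.data$category, .data$chemical) |>
    dplyr::summarise(conc_max = max(.data$concentration), .groups = "drop")
  for (i in seq_len(nrow(blueprint$maxima))) {
    row <- blueprint$maxima[i, ]
    obs <- cell_max$conc_max[
      cell_max$category == row$category & cell_max$chemical == row$chemical
    ]
    add(
      paste0("conc_max_", row$category, "_", row$chemical), row$conc_max,
      if (length(obs) == 0) NA_real_ else obs
    )
  }

  out <- dplyr::bind_rows(checks)
  attr(out, "pass") <- all(out$pass)
  out
}
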