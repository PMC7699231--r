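# Monte Carlo exposure estimation: sample parameter distributions per age
# group, evaluate the ingestion and dermal dose equations per product
# category, sum across categories within each iteration, and report the
# median and 95th percentile with margins of exposure.

#' Distribution specifications for Monte Carlo sampling
#'
#' Small constructors for the parameter distributions understood by
#' [run_mc()]:
#'
#' * `dist_point(value)` degenerate (deterministic) value
#' * `dist_normal(mean, sd)` normal
#' * `dist_truncnorm(mean, sd, lower, upper)` normal truncated by inverse
#'   CDF (defaults: lower at `max(0, mean - 3*sd)`, upper `mean + 3*sd`),
#'   used for anthropometric and behavioural parameters to avoid
#'   non-physical negatives
#' * `dist_lognormal(meanlog, sdlog)` lognormal with parameters on the log
#'   scale
#'
#' @param value,mean,sd,lower,upper,meanlog,sdlog Distribution parameters
#'   in the units of the target quantity (log-scale for the lognormal).
#' @return A `dist_spec` object.
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.finite(value))
  structure(list(kind = "point", value = value), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(sd >= 0)
  structure(list(kind = "normal", mean = mean, sd = sd), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lower = max(0, mean - 3 * sd),
                           upper = mean + 3 * sd) {
  stopifnot(sd >= 0, lower < upper)
  structure(
    list(kind = "truncnorm", mean = mean, sd = sd, lower = lower, upper = upper),
    class = "dist_spec"
  )
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  stopifnot(sdlog >= 0)
  structure(
    list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog),
    class = "dist_spec"
  )
}

#' Draw from a distribution specification
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  switch(spec$kind,
    point = rep(spec$value, n),
    normal = rnorm(n, spec$mean, spec$sd),
    truncnorm = {
      if (spec$sd == 0) {
        rep(spec$mean, n)
      } else {
        plo <- stats::pnorm(spec$lower, spec$mean, spec$sd)
        phi <- stats::pnorm(spec$upper, spec$mean, spec$sd)
        qnorm(runif(n, plo, phi), spec$mean, spec$sd)
      }
    },
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}

#' Fit a concentration distribution for one (chemical, category) cell
#'
#' Fits a lognormal to all measurements of `chemical` in `category`
#' (detected values plus non-detects substituted at LOQ/2) by matching the
#' mean and standard deviation of the logs. A degenerate sample (all
#' values equal, e.g. all non-detects) yields a point mass; fewer than two
#' measurements yield an explicit `"insufficient"` marker so the cell can
#' be skipped with a log entry rather than silently dropped.
#'
#' @param survey A survey tibble; non-detects are substituted internally.
#' @param chemical Chemical abbreviation.
#' @param category Category name.
#' @param registry Chemical registry (for LOQ lookup).
#' @return A `dist_spec` (lognormal or point), or a list with
#'   `kind = "insufficient"` when fewer than two measurements exist.
#' @export
fit_concentration_distribution <- function(survey, chemical, category,
                                           registry = plasticizer_registry()) {
  sub <- substitute_nondetects(survey, registry)
  x <- sub$concentration[sub$chemical == chemical & sub$category == category]
  x <- x[!is.na(x) & x > 0]
  if (length(x) < 2) {
    return(structure(
      list(kind = "insufficient", n = length(x)),
      class = "dist_spec"
    ))
  }
  lx <- log(x)
  s <- sd(lx)
  if (s == 0) {
    return(dist_point(x[1]))
  }
  dist_lognormal(mean(lx), s)
}

#' Age group profile for Monte Carlo simulation
#'
#' Collects the per-parameter distributions for one age group: body weight
#' `BW` (kg), exposed hand surface area `SA` (cm2), mouthing contact area
#' `CA` (cm2), mouthing duration `D_mouthing` (min/h), solid-phase
#' diffusivity `D` (m2/h), and the daily activity duration `ED` (h/d) per
#' product category under the activity mapping: accessories = stay in
#' home, shoes = stay out of home, mat and toy = playing, stationery =
#' study, toilet = personal sanitation.
#'
#' @param label Age group label, e.g. `"0-2 years"`.
#' @param BW,SA,CA,D_mouthing,D `dist_spec` objects.
#' @param ED Named list of `dist_spec`, one per category in
#'   [survey_categories()].
#' @return An `age_profile` object.
#' @export
age_profile <- function(label, BW, SA, CA, D_mouthing, ED, D) {
  stopifnot(
    inherits(BW, "dist_spec"), inherits(SA, "dist_spec"),
    inherits(CA, "dist_spec"), inherits(D_mouthing, "dist_spec"),
    inherits(D, "dist_spec"),
    is.list(ED), setequal(names(ED), survey_categories())
  )
  structure(
    list(label = label, BW = BW, SA = SA, CA = CA, D_mouthing = D_mouthing,
         ED = ED, D = D),
    class = "age_profile"
  )
}

#' Default age group profiles (0-2 and 3-12 years)
#'
#' Plausible, documented placeholder distributions for the two age
#' groups. The national exposure-factor handbook values behind the
#' original assessment are not public, so these defaults are explicitly
#' non-authoritative: they encode the expected ordering (younger children
#' mouth more, weigh less, stay home longer) and realistic magnitudes,
#' and real assessments should supply handbook-derived profiles instead.
#' Anthropometric and behavioural parameters use truncated normals
#' (bounded at mean +/- 3 SD and at 0); the diffusivity is lognormal
#' around the calibrated deterministic value.
#'
#' @param factors A calibrated [exposure_factors()] set supplying the
#'   central diffusivity.
#' @return A list of two `age_profile` objects named `"0-2"` and `"3-12"`.
#' @export
default_age_profiles <- function(factors = default_exposure_factors()) {
  d_spec <- dist_lognormal(log(factors$D), log(3) / qnorm(0.95))
  list(
    "0-2" = age_profile(
      label = "0-2 years",
      BW = dist_truncnorm(9.4, 2.3),
      SA = dist_truncnorm(400, 80),
      CA = dist_truncnorm(10, 3),
      D_mouthing = dist_truncnorm(6, 3),
      ED = list(
        accessories = dist_truncnorm(16, 3, upper = 24),
        shoes = dist_truncnorm(1.5, 1),
        mat = dist_truncnorm(4, 1.5),
        toy = dist_truncnorm(4, 1.5),
        stationery = dist_truncnorm(0.5, 0.3),
        toilet = dist_truncnorm(0.5, 0.25)
      ),
      D = d_spec
    ),
    "3-12" = age_profile(
      label = "3-12 years",
      BW = dist_truncnorm(24, 8),
      SA = dist_truncnorm(700, 150),
      CA = dist_truncnorm(5, 2),
      D_mouthing = dist_truncnorm(0.8, 0.5),
      ED = list(
        accessories = dist_truncnorm(13, 2.5, upper = 24),
        shoes = dist_truncnorm(3, 1.5),
        mat = dist_truncnorm(2.5, 1),
        toy = dist_truncnorm(2.5, 1),
        stationery = dist_truncnorm(3, 1.5),
        toilet = dist_truncnorm(0.4, 0.2)
      ),
      D = d_spec
    )
  )
}

#' Degenerate (point-mass) profile from a factor set
#'
#' Builds an `age_profile` whose every distribution is a point mass at the
#' corresponding deterministic factor value, with the per-category
#' activity duration fixed at `ED_hours`. With such a profile the Monte
#' Carlo engine collapses onto the deterministic engine (the two routes
#' coincide simultaneously when `factors$use_hours == factors$Dur / 60`,
#' since a single activity duration feeds both routes per category).
#'
#' @param factors A calibrated [exposure_factors()] set.
#' @param ED_hours Activity duration for every category, h/d.
#' @param label Profile label.
#' @return An `age_profile` of point masses.
#' @export
point_profile <- function(factors, ED_hours = factors$Dur / 60,
                          label = "degenerate") {
  ed <- lapply(survey_categories(), function(x) dist_point(ED_hours))
  names(ed) <- survey_categories()
  age_profile(
    label = label,
    BW = dist_point(factors$BW),
    SA = dist_point(factors$SA_over_BW * factors$BW),
    CA = dist_point(factors$CA),
    D_mouthing = dist_point(factors$D_mouthing),
    ED = ed,
    D = dist_point(factors$D)
  )
}

# Deterministic derivation of a per-parameter child seed from the master
# seed, so the draw for one parameter is independent of how many other
# parameters exist or the order in which cells are processed.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629
}

draw_param <- function(spec, n, seed, stream) {
  set.seed(derive_seed(seed, stream))
  sample_dist(spec, n)
}

#' Monte Carlo exposure simulation
#'
#' For each age group and iteration: draw body weight, hand surface area,
#' mouthing parameters, diffusivity, per-category activity durations and
#' per-(chemical, category) article concentrations; evaluate the ingestion
#' dose (mouthing categories only, with the migration rate induced by
#' mapping each sampled concentration through the migration-rate policy)
#' and the dermal dose (hands only, all categories) per category; sum
#' across categories within the iteration; and report the median and 95th
#' percentile per route with margins of exposure. Totals are summed per
#' iteration, not per statistic. Fully reproducible: every parameter draws
#' from its own seed stream derived from the master seed.
#'
#' @param survey A survey tibble (the full survey; non-detects are
#'   substituted internally for the concentration fits).
#' @param profiles Named list of [age_profile()] objects.
#' @param registry Chemical registry.
#' @param factors A calibrated [exposure_factors()] set supplying the
#'   non-sampled parameters (T, h, a, h_sc, rho_article, ED/AT).
#' @param policy A [migration_policy()].
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Master seed.
#' @return A tibble (class `mc_result`) with one row per chemical x age
#'   group x route (`ingestion`, `dermal`, `total`): `median`, `p95`
#'   (mg/kg/d, empirical quantiles with linear interpolation), `moe_median`,
#'   `moe_p95` (the MOE at the p95 dose pairs with the p95), `n_iter`,
#'   `seed`. Cells skipped for insufficient data are recorded in the
#'   `"skipped"` attribute.
#' @export
run_mc <- function(survey, profiles = default_age_profiles(),
                   registry = plasticizer_registry(),
                   factors = default_exposure_factors(),
                   policy = migration_policy("two_level"),
                   n_iter = 10000, seed = 1) {
  stopifnot(n_iter >= 1, length(profiles) >= 1, !is.null(names(profiles)))
  validate_survey(survey)
  sub <- substitute_nondetects(survey, registry)
  cells <- dplyr::distinct(sub, .data$chemical, .data$category)
  cells <- dplyr::arrange(cells, .data$chemical, .data$category)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fits[[i]] <- fit_concentration_distribution(
      sub, cells$chemical[i], cells$category[i], registry
    )
  }
  skipped <- cells[vapply(fits, function(f) f$kind == "insufficient", logical(1)), ]
  chemicals <- sort(unique(cells$chemical))
  rfd <- setNames(registry$reference_dose, registry$abbreviation)

  results <- list()
  for (g in seq_along(profiles)) {
    prof <- profiles[[g]]
    group <- names(profiles)[g]
    stream0 <- g * 1000L
    bw <- draw_param(prof$BW, n_iter, seed, stream0 + 1)
    sa <- draw_param(prof$SA, n_iter, seed, stream0 + 2)
    ca <- draw_param(prof$CA, n_iter, seed, stream0 + 3)
    dm <- draw_param(prof$D_mouthing, n_iter, seed, stream0 + 4)
    dd <- draw_param(prof$D, n_iter, seed, stream0 + 5)
    bw <- pmax(bw, 1e-6)
    ed <- lapply(seq_along(survey_categories()), function(k) {
      pmax(draw_param(prof$ED[[survey_categories()[k]]], n_iter, seed,
        stream0 + 10 + k
      ), 0)
    })
    names(ed) <- survey_categories()

    ing <- matrix(0, n_iter, length(chemicals), dimnames = list(NULL, chemicals))
    der <- matrix(0, n_iter, length(chemicals), dimnames = list(NULL, chemicals))
    for (i in seq_len(nrow(cells))) {
      fit <- fits[[i]]
      if (fit$kind == "insufficient") next
      chem <- cells$chemical[i]
      cat_i <- cells$category[i]
      conc <- draw_param(fit, n_iter, seed, stream0 + 100 + i)
      conc <- pmin(pmax(conc, 0), 1e6) # cap at pure substance
      dur_min <- ed[[cat_i]] * 60
      spec <- get_chemical(chem, registry)
      k_p <- skin_permeability(spec$k_lip, spec$k_pol, spec$k_aq)
      t_lag <- lag_time(spec$mw, factors$h_sc)
      chi <- volatility_ratio(
        factors$h, spec$p_vap_torr, spec$mw, k_p, spec$s_w_mg_ml, factors$T
      )
      fa <- fraction_absorbed(chi, dur_min, t_lag, factors$a)
      l <- diffusion_distance(dd, dur_min)
      c_art <- article_concentration(conc, factors$rho_article)
      der[, chem] <- der[, chem] +
        c_art * (sa / bw) * l * fa * factors$ED / factors$AT
      if (cat_i %in% ingestion_categories()) {
        mr <- assign_migration_rate(conc * 1e-6, policy)
        ing[, chem] <- ing[, chem] +
          mr * ca * (dm / 60) * ed[[cat_i]] * factors$ED / (bw * factors$AT)
      }
    }
    tot <- ing + der
    for (chem in chemicals) {
      for (route in c("ingestion", "dermal", "total")) {
        x <- switch(route, ingestion = ing[, chem], dermal = der[, chem],
          total = tot[, chem]
        )
        med <- median(x)
        p95 <- quantile(x, 0.95, type = 7, names = FALSE)
        results[[length(results) + 1]] <- tibble::tibble(
          chemical = chem, age_group = group, route = route,
          median = med, p95 = p95,
          moe_median = moe(unname(rfd[chem]), med),
          moe_p95 = moe(unname(rfd[chem]), p95),
          n_iter = n_iter, seed = seed
        )
      }
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "skipped") <- skipped
  class(out) <- c("mc_result", class(out))
  out
}

#' Shape Monte Carlo results as the published summary table
#'
#' One row per chemical x age group with ingestion, dermal and total
#' median and 95th-percentile doses and the MOE of the total at each
#' statistic (the MOE at the 95th-percentile dose is the smaller one,
#' since the margin is anti-monotone in dose).
#'
#' @param mc An `mc_result` from [run_mc()].
#' @return A wide tibble with columns `chemical`, `age_group`,
#'   `ingestion_median`, `ingestion_p95`, `dermal_median`, `dermal_p95`,
#'   `total_median`, `total_p95`, `moe_median`, `moe_p95`.
#' @export
summarize_mc <- function(mc) {
  if (nrow(mc) == 0) {
    return(tibble::tibble(
      chemical = character(), age_group = character(),
      ingestion_median = numeric(), ingestion_p95 = numeric(),
      dermal_median = numeric(), dermal_p95 = numeric(),
      total_median = numeric(), total_p95 = numeric(),
      moe_median = numeric(), moe_p95 = numeric()
    ))
  }
  doses <- mc |>
    dplyr::select("chemical", "age_group", "route", "median", "p95") |>
    tidyr::pivot_wider(
      names_from = "route", values_from = c("median", "p95"),
      names_glue = "{route}_{.value}"
    )
  moes <- mc |>
    dplyr::filter(.data$route == "total") |>
    dplyr::select("chemical", "age_group",
      moe_median = "moe_median", moe_p95 = "moe_p95"
    )
  dplyr::left_join(doses, moes, by = c("chemical", "age_group")) |>
    dplyr::select(
      "chemical", "age_group",
      "ingestion_median", "ingestion_p95",
      "dermal_median", "dermal_p95",
      "total_median", "total_p95",
      "moe_median", "moe_p95"
    )
}
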