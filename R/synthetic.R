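# Seeded synthetic input generator.
#
# Emulates the statistical structure of the study inputs -- an age/sex
# stratified population, GBD-style prevalence/incidence rates per 1,000 with
# confidence bounds, per-case unit-cost decompositions (drug and supply,
# staff minutes by cadre, programme overheads), and an inflation/exchange
# series -- so the whole pipeline runs and is testable without any external
# download. Everything is reproducible from (seed, parameters).

# Allocate `total` (integer) across weights, returning integers that sum to
# `total` exactly (largest-remainder apportionment).
alloc_integer <- function(total, weights) {
  q <- weights / sum(weights) * total
  f <- floor(q)
  short <- as.integer(round(total - sum(f)))
  if (short > 0) {
    idx <- order(q - f, decreasing = TRUE)[seq_len(short)]
    f[idx] <- f[idx] + 1
  }
  f
}

#' Generate a synthetic age/sex-stratified population table
#'
#' Builds a smooth age pyramid (young-adult bulge, thinning towards 80+)
#' split into the 34 age-sex groups, for `n_years` consecutive years with a
#' constant annual growth rate. Counts are integers; the first year sums to
#' `base_total` exactly and each later year to the rounded grown total.
#'
#' @param seed Integer seed; identical seeds give identical tables.
#' @param n_years Number of calendar years (default 11, i.e. 2020-2030).
#' @param base_total Total population in the first year (> 0).
#' @param growth Annual population growth rate (default 1.2%).
#' @param start_year First calendar year (default 2020).
#' @return Data frame with columns `year`, `sex`, `age_band`, `count`
#'   (34 rows per year).
#' @examples
#' pop <- make_population(1, base_total = 1e6)
#' sum(pop$count[pop$year == 2020])  # exactly 1e6
#' @export
make_population <- function(seed, n_years = 11, base_total = 83e6,
                            growth = 0.012, start_year = 2020) {
  if (!is.numeric(base_total) || length(base_total) != 1L || base_total <= 0) {
    stop_validation("base_total must be a positive number")
  }
  if (!is_count(n_years) || n_years < 1) {
    stop_validation("n_years must be a positive integer")
  }
  set.seed(seed)
  mid <- band_midpoints()
  # young-adult bulge around age 30 over a declining base, small seeded jitter
  shape <- exp(-((mid - 30)^2) / (2 * 28^2)) + 0.35 * exp(-mid / 60)
  shape <- shape * runif(17, 0.95, 1.05)
  female_share <- pmin(0.53, 0.49 + pmax(0, mid - 60) * 0.0015 +
                         runif(17, -0.005, 0.005))
  w <- c(shape * female_share, shape * (1 - female_share))
  groups <- age_sex_groups()
  years <- start_year + seq_len(n_years) - 1L
  out <- do.call(rbind, lapply(seq_along(years), function(i) {
    total <- round(base_total * (1 + growth)^(i - 1L))
    data.frame(year = years[i], sex = groups$sex, age_band = groups$age_band,
               count = alloc_integer(total, w), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Age/sex prevalence profiles per 1,000, by disorder. Shapes follow the
# broad epidemiology: depression rises with age then plateaus and is more
# common in women; anxiety peaks in young adulthood, also female-skewed;
# bipolar is low, adult-onset, sex-neutral; epilepsy is flatter with a
# childhood bump.
epi_profile <- function(disorder, mid, sex) {
  fem <- sex == "female"
  switch(disorder,
    depression = (10 + 45 * stats::plogis((mid - 25) / 10)) *
      ifelse(fem, 1.45, 0.85),
    anxiety = (12 + 42 * exp(-((mid - 30)^2) / (2 * 22^2))) *
      ifelse(fem, 1.5, 0.85),
    bipolar = 7.5 * stats::plogis((mid - 15) / 4) * ifelse(fem, 1.0, 1.0),
    epilepsy = (6 + 2 * exp(-((mid - 10)^2) / (2 * 12^2))) *
      ifelse(fem, 0.95, 1.05),
    # unknown disorders get a generic flat adult profile
    8 * stats::plogis((mid - 18) / 6)
  )
}

#' Generate a synthetic epidemiological rate table
#'
#' Prevalence and incidence per 1,000 population for each disorder in each
#' of the 34 age-sex groups, with confidence bounds. Rates follow plausible
#' age/sex gradients (see Details) with multiplicative lognormal noise;
#' confidence half-widths are drawn between 5% and 15% of the point value,
#' so `lo <= point <= hi` holds by construction and all rates stay far below
#' 1,000.
#'
#' The generator declares its own plausibility window for the
#' population-weighted adult depression prevalence as the
#' `"plausibility"` attribute, so tests can recompute the weighted mean from
#' the emitted table and check it against what the generator intended.
#'
#' @param seed Integer seed.
#' @param disorders Non-empty character vector of disorder ids.
#' @return Data frame with columns `disorder`, `sex`, `age_band`,
#'   `prevalence_per_1000`, `prev_lo`, `prev_hi`, `incidence_per_1000`,
#'   `inc_lo`, `inc_hi`; 34 rows per disorder.
#' @export
make_epi <- function(seed, disorders = c("depression", "anxiety", "bipolar",
                                         "epilepsy")) {
  if (length(disorders) < 1L) stop_validation("disorders must be non-empty")
  set.seed(seed)
  groups <- age_sex_groups()
  mid <- band_midpoints()[match(groups$age_band, age_bands())]
  out <- do.call(rbind, lapply(disorders, function(d) {
    point <- epi_profile(d, mid, groups$sex) * exp(rnorm(nrow(groups), 0, 0.05))
    hw_lo <- runif(nrow(groups), 0.05, 0.15)
    hw_hi <- runif(nrow(groups), 0.05, 0.15)
    inc_frac <- runif(1, 0.15, 0.35)
    inc <- point * inc_frac * exp(rnorm(nrow(groups), 0, 0.05))
    ihw_lo <- runif(nrow(groups), 0.05, 0.15)
    ihw_hi <- runif(nrow(groups), 0.05, 0.15)
    data.frame(
      disorder = d, sex = groups$sex, age_band = groups$age_band,
      prevalence_per_1000 = point,
      prev_lo = point * (1 - hw_lo), prev_hi = point * (1 + hw_hi),
      incidence_per_1000 = inc,
      inc_lo = inc * (1 - ihw_lo), inc_hi = inc * (1 + ihw_hi),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  # window the generator commits to for population-weighted adult (15+)
  # depression prevalence per 1,000, given its profile and noise levels
  attr(out, "plausibility") <- list(depression_adult_prev_per_1000 = c(25, 90))
  out
}

# Cadre salary levels (IRR per minute) around which the generator jitters.
cadre_salaries <- function() {
  c(community_health_worker = 12000, general_practitioner = 30000,
    psychologist = 28000, psychiatrist = 70000, social_worker = 20000)
}

#' Generate synthetic per-case unit-cost profiles
#'
#' For each intervention, draws a per-case-year cost decomposition: a
#' commodity (drug and supply) amount and staff contact time in minutes per
#' cadre with a per-minute salary, all in integer rial. Intensive-tier
#' interventions are guaranteed to cost more per case-year than the basic
#' tier of the same disorder (severe cases referred to community mental
#' health centres use specialist time and costlier regimens).
#'
#' @param seed Integer seed.
#' @param interventions Data frame with columns `id`, `disorder`, `tier`
#'   (`"basic"` or `"intensive"`), non-empty.
#' @return Data frame (one row per component) with columns `intervention`,
#'   `component` (`"commodity"` or a cadre name), `minutes_per_case_year`,
#'   `salary_per_minute`, `amount` (IRR; for labor rows,
#'   `minutes * salary`). The declared per-case total of an intervention is
#'   the sum of its `amount` column.
#' @export
make_costs <- function(seed, interventions) {
  if (is.null(interventions) || nrow(interventions) < 1L) {
    stop_validation("interventions must be non-empty")
  }
  set.seed(seed)
  sal <- round(cadre_salaries() * runif(5, 0.9, 1.1))
  basic_total <- setNames(numeric(0), character(0))
  rows <- list()
  # draw basic tiers first so intensive tiers can be anchored above them
  ord <- order(match(interventions$tier, c("basic", "intensive")))
  for (i in ord) {
    iv <- interventions[i, ]
    if (iv$tier == "basic") {
      commodity <- round(runif(1, 0.5e6, 0.9e6))
      cad <- c("community_health_worker", "general_practitioner", "psychologist")
      minutes <- round(c(runif(1, 40, 80), runif(1, 20, 40), runif(1, 30, 60)))
    } else {
      anchor <- basic_total[iv$disorder]
      commodity <- if (is.na(anchor)) round(runif(1, 1.5e6, 3e6)) else
        round(unname(anchor) * runif(1, 0.4, 0.6))
      cad <- c("psychiatrist", "psychologist", "social_worker")
      minutes <- round(c(runif(1, 30, 60), runif(1, 60, 120), runif(1, 40, 80)))
    }
    amount <- c(commodity, minutes * sal[cad])
    total <- sum(amount)
    if (iv$tier == "intensive" && !is.na(basic_total[iv$disorder]) &&
        total <= basic_total[iv$disorder]) {
      # enforce the tier ordering by topping up the commodity component
      commodity <- commodity + ceiling(basic_total[iv$disorder] - total) + 1
      amount[1] <- commodity
    }
    if (iv$tier == "basic") basic_total[iv$disorder] <- sum(amount)
    rows[[iv$id]] <- data.frame(
      intervention = iv$id,
      component = c("commodity", cad),
      minutes_per_case_year = c(NA_real_, minutes),
      salary_per_minute = c(NA_real_, unname(sal[cad])),
      amount = amount,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[interventions$id])
  rownames(out) <- NULL
  out
}

#' Declared per-case-year cost of an intervention
#'
#' @param unit_costs Unit-cost table as returned by [make_costs()].
#' @param intervention Intervention id.
#' @return Per-case-year cost in IRR (commodity plus all labor components).
#' @export
unit_cost_per_case <- function(unit_costs, intervention) {
  rows <- unit_costs[unit_costs$intervention == intervention, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_validation("no unit-cost profile for intervention '%s'", intervention)
  }
  sum(rows$amount)
}

#' Generate synthetic economic settings
#'
#' Ten observed annual inflation rates (2010-2019 by default) drawn from a
#' high-inflation middle-income range, extrapolated over the projection
#' horizon as the geometric mean of the observed `1 + rate` factors; a
#' constant observed series therefore extrapolates to itself. Exchange rate,
#' PPP factor, and GDP per capita default to the study-setting values (see
#' [iran_defaults()]).
#'
#' @param seed Integer seed.
#' @param horizon_start,horizon_end Projection years covered by the
#'   extrapolated rates.
#' @param observed_years Years of the observed inflation series.
#' @param observed_rates Optional numeric vector of observed rates (> -1);
#'   drawn uniformly in \[0.08, 0.42\] when `NULL`.
#' @param exchange_rate_irr_per_usd,ppp_factor_intl_per_usd,gdp_per_capita_usd
#'   Positive economic factors.
#' @return List with `inflation` (data frame `year`, `rate` covering observed
#'   and horizon years), `exchange_rate_irr_per_usd`,
#'   `ppp_factor_intl_per_usd`, `gdp_per_capita_usd`.
#' @export
make_economics <- function(seed, horizon_start = 2020, horizon_end = 2030,
                           observed_years = 2010:2019, observed_rates = NULL,
                           exchange_rate_irr_per_usd =
                             iran_defaults()$exchange_rate_irr_per_usd,
                           ppp_factor_intl_per_usd =
                             iran_defaults()$ppp_factor_intl_per_usd,
                           gdp_per_capita_usd =
                             iran_defaults()$gdp_per_capita_usd) {
  set.seed(seed)
  if (is.null(observed_rates)) {
    observed_rates <- runif(length(observed_years), 0.08, 0.42)
  }
  if (length(observed_rates) != length(observed_years)) {
    stop_validation("observed_rates must match observed_years in length")
  }
  if (any(observed_rates <= -1)) stop_validation("inflation rates must exceed -1")
  if (exchange_rate_irr_per_usd <= 0 || ppp_factor_intl_per_usd <= 0 ||
      gdp_per_capita_usd <= 0) {
    stop_validation("exchange, PPP and GDP factors must be positive")
  }
  g <- expm1(mean(log1p(observed_rates)))
  horizon_years <- horizon_start:horizon_end
  list(
    inflation = data.frame(
      year = c(observed_years, horizon_years),
      rate = c(observed_rates, rep(g, length(horizon_years)))
    ),
    exchange_rate_irr_per_usd = exchange_rate_irr_per_usd,
    ppp_factor_intl_per_usd = ppp_factor_intl_per_usd,
    gdp_per_capita_usd = gdp_per_capita_usd
  )
}

# Programme overhead profile (IRR per year at base-year prices): national
# management booked once; provincial management, supervision travel and
# allowances, and training scale with the administrative-unit count.
default_program_profile <- function() {
  list(national_management = 7.0e9, provincial_management = 4.2e8,
       supervision = 1.3e8, training = 1.1e8, n_admin_units = 31)
}

#' Generate a complete synthetic input bundle
#'
#' Assembles population, epidemiology, unit costs, programme overheads,
#' economic settings, disorder disability weights, the seven-intervention
#' roster of the national plan (with the published baseline/target coverage
#' levels), the published front-loaded coverage rows (optional), and the
#' eight standard sensitivity scenarios into a validated bundle ready for
#' [project_scaleup()].
#'
#' Disability weights and per-intervention effect sizes are not published
#' for this service package, so the generator draws them from plausible
#' ranges (weights 0.1-0.7 by disorder-specific sub-ranges, effect sizes
#' 0.2-0.5) and records the drawn values in the bundle, giving
#' parameter-recovery tests a known truth.
#'
#' @param seed Integer seed controlling every random draw.
#' @param base_total First-year total population.
#' @param horizon_start,horizon_end Projection horizon (calendar years,
#'   `horizon_end > horizon_start`).
#' @param use_reference_coverage If `TRUE` (default) attach the published
#'   coverage rows as the authoritative trajectories; if `FALSE`,
#'   trajectories are interpolated from the pattern at run time.
#' @return A validated `mh_bundle` (see [load_config()] for the structure).
#' @examples
#' b <- generate_bundle(1)
#' names(b)
#' @export
generate_bundle <- function(seed, base_total = 83e6, horizon_start = 2020,
                            horizon_end = 2030,
                            use_reference_coverage = TRUE) {
  if (!is_count(seed %% 2^31)) stop_validation("seed must be an integer")
  n_years <- horizon_end - horizon_start + 1L
  if (n_years < 2L) stop_validation("horizon must span at least 2 years")

  set.seed(seed)
  dw <- c(
    depression = runif(1, 0.30, 0.50),
    anxiety = runif(1, 0.20, 0.40),
    bipolar = runif(1, 0.35, 0.55),
    epilepsy = runif(1, 0.20, 0.45)
  )
  disorders <- data.frame(
    id = names(dw), name = names(dw), disability_weight = unname(dw),
    stringsAsFactors = FALSE
  )

  cov <- iran_coverage()
  interventions <- data.frame(
    id = cov$intervention,
    disorder = cov$disorder,
    tier = cov$tier,
    eligible_fraction = c(anx_basic = 0.60, anx_intensive = 0.25,
                          dep_basic = 0.55, dep_intensive_first = 0.15,
                          dep_intensive_maint = 0.20, bip_intensive = 1.00,
                          epi_basic = 0.90)[cov$intervention],
    effect_size = runif(nrow(cov), 0.2, 0.5),
    baseline_coverage_pct = cov$y2020,
    target_coverage_pct = cov$y2030,
    pattern = "front_loaded",
    stringsAsFactors = FALSE
  )
  rownames(interventions) <- NULL

  population <- make_population(seed + 1L, n_years = n_years,
                                base_total = base_total,
                                start_year = horizon_start)
  epi <- make_epi(seed + 2L, disorders = disorders$id)
  unit_costs <- make_costs(seed + 3L, interventions)
  economics <- make_economics(seed + 4L, horizon_start = horizon_start,
                              horizon_end = horizon_end)

  coverage_table <- NULL
  if (use_reference_coverage && identical(horizon_start:horizon_end, 2020:2030)) {
    pct <- as.matrix(cov[, paste0("y", 2020:2030)])
    coverage_table <- data.frame(
      intervention = rep(cov$intervention, each = n_years),
      year = rep(2020:2030, times = nrow(cov)),
      percent = as.vector(t(pct)),
      stringsAsFactors = FALSE
    )
  }

  bundle <- structure(list(
    config = list(
      horizon_start = horizon_start, horizon_end = horizon_end,
      base_year = horizon_start, country_label = "Iran",
      currency_local = "IRR", coverage_pattern = "front_loaded"
    ),
    population = population,
    epi = epi,
    disorders = disorders,
    interventions = interventions,
    unit_costs = unit_costs,
    program = default_program_profile(),
    economics = economics,
    coverage_table = coverage_table,
    scenarios = default_scenarios()
  ), class = "mh_bundle")
  validate_bundle(bundle)
}
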