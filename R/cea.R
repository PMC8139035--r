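# Cost-effectiveness ratios, GDP-threshold classification, and the
# deterministic multi-scenario sensitivity analysis.

#' Cost per healthy life year gained
#'
#' Total cost divided by total healthy life years gained. Reporting follows
#' the planning-table convention of whole US dollars (half-up); set
#' `rounded = FALSE` to keep full precision.
#'
#' @param total_cost_usd Total cost in USD (>= 0).
#' @param total_hly Total healthy life years gained (> 0 unless the cost is
#'   also 0, in which case the ratio is defined as 0).
#' @param rounded Round half-up to whole USD (default `TRUE`).
#' @return Cost per healthy life year (USD per person-year).
#' @examples
#' cost_per_hly(1363581654, 1702755)  # 801
#' cost_per_hly(1522234357, 2103194)  # 724
#' @export
cost_per_hly <- function(total_cost_usd, total_hly, rounded = TRUE) {
  if (total_cost_usd < 0) stop_validation("total_cost_usd must be non-negative")
  if (total_cost_usd == 0) return(0)
  if (total_hly <= 0) {
    stop_validation("cost per healthy life year is undefined for %g healthy life years",
                    total_hly)
  }
  r <- total_cost_usd / total_hly
  if (rounded) round_half_up(r) else r
}

#' Classify a cost-effectiveness ratio against GDP-based thresholds
#'
#' WHO-CHOICE convention: an intervention costing less than one GDP per
#' capita per healthy life year gained is very cost-effective; between one
#' and three times GDP per capita, cost-effective; above three times, not
#' cost-effective. A ratio exactly equal to a band edge is assigned to the
#' higher (less favourable) band.
#'
#' @param ratio_usd Cost per healthy life year in USD.
#' @param gdp_per_capita_usd GDP per capita in USD (> 0).
#' @return One of `"very_cost_effective"`, `"cost_effective"`,
#'   `"not_cost_effective"`.
#' @examples
#' classify_cost_effectiveness(801, 5550)
#' @export
classify_cost_effectiveness <- function(ratio_usd, gdp_per_capita_usd) {
  if (!is.numeric(gdp_per_capita_usd) || gdp_per_capita_usd <= 0) {
    stop_validation("gdp_per_capita_usd must be positive")
  }
  if (ratio_usd < gdp_per_capita_usd) {
    "very_cost_effective"
  } else if (ratio_usd <= 3 * gdp_per_capita_usd) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }
}

#' Define a sensitivity scenario
#'
#' A scenario bundles a scale-up pattern, an epidemiological bound
#' (point estimate or a confidence-interval bound), and optional coverage
#' overrides by intervention tier. Fields not overridden are inherited from
#' the base inputs unchanged.
#'
#' @param name Scenario name.
#' @param pattern Scale-up pattern (see [coverage_interpolate()]).
#' @param epi_bound `"point"`, `"lower"` or `"upper"`.
#' @param overrides List of overrides, each a list with `tier`
#'   (`"basic"`/`"intensive"`) and one or both of `baseline_pct`,
#'   `target_pct`.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, pattern = "front_loaded",
                          epi_bound = c("point", "lower", "upper"),
                          overrides = list()) {
  if (!pattern %in% coverage_patterns()) {
    stop_validation("scenario '%s' names unknown coverage pattern '%s'",
                    name, pattern)
  }
  epi_bound <- match.arg(epi_bound)
  for (ov in overrides) {
    if (is.null(ov$tier) || !ov$tier %in% c("basic", "intensive")) {
      stop_validation("scenario '%s': override tier must be 'basic' or 'intensive'",
                      name)
    }
    for (f in c("baseline_pct", "target_pct")) {
      if (!is.null(ov[[f]])) check_scalar_prob(ov[[f]], f, 0, 100)
    }
  }
  structure(list(name = name, pattern = pattern, epi_bound = epi_bound,
                 overrides = overrides),
            class = "scenario_spec")
}

#' The eight standard sensitivity scenarios
#'
#' The published sensitivity design: the front-loaded base case; the
#' exponential and linear pattern variants; the lower and upper
#' epidemiological confidence bounds; and three coverage variants --
#' `coverage_1` raises the baseline coverage of basic interventions from 40
#' to 50%, `coverage_2` raises the intensive-tier target from 30 to 40%,
#' and `coverage_3` lowers the basic-tier target to 60%.
#'
#' @return Named list of eight [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  specs <- list(
    scenario_spec("base_front_loaded"),
    scenario_spec("exponential", pattern = "exponential"),
    scenario_spec("linear", pattern = "linear"),
    scenario_spec("epi_lower_CI", epi_bound = "lower"),
    scenario_spec("epi_upper_CI", epi_bound = "upper"),
    scenario_spec("coverage_1",
                  overrides = list(list(tier = "basic", baseline_pct = 50))),
    scenario_spec("coverage_2",
                  overrides = list(list(tier = "intensive", target_pct = 40))),
    scenario_spec("coverage_3",
                  overrides = list(list(tier = "basic", target_pct = 60)))
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Apply a scenario to a set of base inputs
#'
#' Returns a modified copy of the bundle: the epidemiology table swapped to
#' the chosen confidence bound, interventions re-pointed at the scenario's
#' pattern, and coverage endpoint overrides applied. The base scenario
#' (front-loaded pattern, point estimates, no overrides) returns the bundle
#' unchanged. When the pattern differs from the bundle's recorded base
#' pattern the published per-year coverage rows are dropped so trajectories
#' regenerate from the pattern; coverage overrides drop only the rows of
#' the overridden tier.
#'
#' @param bundle An `mh_bundle`.
#' @param spec A [scenario_spec()].
#' @return Modified `mh_bundle`.
#' @export
apply_scenario <- function(bundle, spec) {
  if (!inherits(spec, "scenario_spec")) {
    stop_validation("spec must be a scenario_spec")
  }
  if (spec$epi_bound != "point") {
    cols <- if (spec$epi_bound == "lower") c("prev_lo", "inc_lo") else
      c("prev_hi", "inc_hi")
    bundle$epi$prevalence_per_1000 <- bundle$epi[[cols[1L]]]
    bundle$epi$incidence_per_1000 <- bundle$epi[[cols[2L]]]
  }
  base_pattern <- bundle$config$coverage_pattern %||% "front_loaded"
  if (!identical(spec$pattern, base_pattern)) {
    bundle$interventions$pattern <- spec$pattern
    bundle$coverage_table <- NULL
  }
  for (ov in spec$overrides) {
    sel <- bundle$interventions$tier == ov$tier
    if (!is.null(ov$baseline_pct)) {
      bundle$interventions$baseline_coverage_pct[sel] <- ov$baseline_pct
    }
    if (!is.null(ov$target_pct)) {
      bundle$interventions$target_coverage_pct[sel] <- ov$target_pct
    }
    if (!is.null(bundle$coverage_table)) {
      drop_ids <- bundle$interventions$id[sel]
      keep <- !(bundle$coverage_table$intervention %in% drop_ids)
      bundle$coverage_table <- if (any(keep)) {
        bundle$coverage_table[keep, , drop = FALSE]
      } else NULL
    }
  }
  bundle
}

#' Run the full scenario sensitivity analysis
#'
#' Projects every scenario and assembles the sensitivity matrix: cost
#' components and totals (whole USD), per-disorder and total healthy life
#' years gained, and cost per healthy life year in USD and international
#' dollars, one column per scenario. A failure in any scenario aborts the
#' run with that scenario named.
#'
#' @param bundle An `mh_bundle`.
#' @param specs List of [scenario_spec()] objects (default: the bundle's
#'   configured scenarios, else [default_scenarios()]).
#' @return List of class `mh_sensitivity` with elements `results` (named
#'   list of `mh_projection`s) and `matrix` (data frame, one row per
#'   quantity, one column per scenario).
#' @export
run_scenarios <- function(bundle, specs = NULL) {
  specs <- specs %||% bundle$scenarios %||% default_scenarios()
  if (length(specs) == 0L) stop_validation("no scenarios to run")
  nm <- vapply(specs, `[[`, "", "name")
  results <- setNames(vector("list", length(specs)), nm)
  for (i in seq_along(specs)) {
    results[[i]] <- tryCatch(
      project_scaleup(bundle, scenario = specs[[i]]),
      error = function(e) {
        stop_validation("scenario '%s' failed: %s", nm[i], conditionMessage(e))
      }
    )
  }
  disorders <- bundle$disorders$id
  cols <- lapply(results, function(pr) {
    s <- pr$summary
    usd <- vapply(c("intervention_costs", "program_costs", "labor_costs",
                    "total_costs"),
                  function(k) round_half_up(sum(annual_usd(
                    pr$costs[[k]], pr$costs$year, pr$economics))),
                  numeric(1))
    c(usd,
      setNames(as.numeric(s$impact$by_disorder[disorders]), disorders),
      total_impact = s$total_hly,
      cost_per_hly_usd = s$cost_per_hly_usd,
      cost_per_hly_intl = s$cost_per_hly_intl)
  })
  mat <- data.frame(quantity = names(cols[[1L]]), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(cols)) mat[[nm[j]]] <- unname(cols[[j]])
  structure(list(results = results, matrix = mat), class = "mh_sensitivity")
}

#' Recompute cost-effectiveness summaries from component totals
#'
#' Given the three cost components (USD) and per-disorder healthy life
#' years of one scenario, recomputes total cost, total impact, and cost per
#' healthy life year in USD and international dollars. Used to check
#' internal consistency of published sensitivity tables, whose components
#' and totals are both printed.
#'
#' @param cost_components_usd Numeric vector of cost components (USD).
#' @param impacts_hly Numeric vector of per-disorder healthy life years.
#' @param ppp_factor_intl_per_usd PPP factor for the Intl$ ratio.
#' @return List with `total_costs`, `total_impact`, `cost_per_hly_usd`,
#'   `cost_per_hly_intl` (ratios rounded half-up to whole dollars).
#' @examples
#' cea_from_components(c(382120919, 8736258, 972724477),
#'                     c(1147236, 362192, 93802, 99525))
#' @export
cea_from_components <- function(cost_components_usd, impacts_hly,
                                ppp_factor_intl_per_usd =
                                  iran_defaults()$ppp_factor_intl_per_usd) {
  total_cost <- sum(cost_components_usd)
  total_impact <- sum(impacts_hly)
  ratio <- cost_per_hly(total_cost, total_impact, rounded = FALSE)
  list(
    total_costs = total_cost,
    total_impact = total_impact,
    cost_per_hly_usd = round_half_up(ratio),
    cost_per_hly_intl = round_half_up(ratio * ppp_factor_intl_per_usd)
  )
}

#' @export
print.mh_sensitivity <- function(x, ...) {
  cat("Scenario sensitivity analysis:", length(x$results), "scenarios\n\n")
  m <- x$matrix
  num <- m[, -1L, drop = FALSE]
  num[] <- lapply(num, function(v) formatC(v, format = "f", digits = 0,
                                           big.mark = ","))
  print(cbind(quantity = m$quantity, num), row.names = FALSE)
  invisible(x)
}
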