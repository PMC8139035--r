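#' Project the scale-up of the service package
#'
#' The central routine: given a validated input bundle (and optionally a
#' sensitivity scenario), builds the coverage trajectories, treated
#' caseloads, the three-component annual cost series, and the annual
#' healthy-life-years-gained series, and summarizes them into
#' cost-effectiveness quantities -- total cost (local currency, USD,
#' Intl$), total healthy life years gained, cost per healthy life year,
#' its GDP-threshold classification, and per-capita cost.
#'
#' Published per-year coverage rows in the bundle (`coverage_table`) are
#' authoritative where present; other interventions interpolate from their
#' baseline/target under their pattern. The projection is fully
#' deterministic: identical bundles give identical projections.
#'
#' @param bundle An `mh_bundle` from [generate_bundle()] or
#'   [load_config()].
#' @param scenario `NULL` (base inputs as-is), a [scenario_spec()], or the
#'   name of a scenario configured in the bundle.
#' @return An object of class `mh_projection`: list with `trajectories`,
#'   `caseloads`, `costs` (annual IRR series), `impact` (annual series),
#'   `economics`, `summary`, `scenario` (name or `"base"`), `horizon`.
#' @examples
#' b <- generate_bundle(1)
#' pr <- project_scaleup(b)
#' pr
#' @seealso [run_scenarios()] for the eight-scenario sensitivity analysis.
#' @export
project_scaleup <- function(bundle, scenario = NULL) {
  if (!inherits(bundle, "mh_bundle")) {
    stop_validation("bundle must be an mh_bundle (see generate_bundle, load_config)")
  }
  scenario_name <- "base"
  if (is.character(scenario)) {
    nm <- vapply(bundle$scenarios, `[[`, "", "name")
    if (!scenario %in% nm) {
      stop_validation("unknown scenario name '%s' (configured: %s)",
                      scenario, paste(nm, collapse = ", "))
    }
    scenario <- bundle$scenarios[[match(scenario, nm)]]
  }
  if (!is.null(scenario)) {
    scenario_name <- scenario$name
    bundle <- apply_scenario(bundle, scenario)
  }

  cfg <- bundle$config
  years <- cfg$horizon_start:cfg$horizon_end
  n_steps <- length(years) - 1L

  trajectories <- lapply(seq_len(nrow(bundle$interventions)), function(i) {
    iv <- bundle$interventions[i, ]
    tab <- bundle$coverage_table
    if (!is.null(tab)) {
      rows <- tab[tab$intervention == iv$id, , drop = FALSE]
      if (nrow(rows) > 0L) {
        rows <- rows[order(rows$year), ]
        if (!identical(as.integer(rows$year), as.integer(years))) {
          stop_validation("coverage table for '%s' does not cover every horizon year",
                          iv$id)
        }
        return(coverage_from_table(rows$percent, years = rows$year,
                                   intervention = iv$id))
      }
    }
    coverage_interpolate(iv$baseline_coverage_pct, iv$target_coverage_pct,
                         n_steps, pattern = iv$pattern, years = years,
                         intervention = iv$id)
  })
  names(trajectories) <- bundle$interventions$id

  caseloads <- build_caseloads(bundle$population, bundle$epi,
                               bundle$interventions, trajectories, years)
  impact <- build_impact(caseloads, bundle$disorders, bundle$interventions,
                         discount_rate = cfg$discount_rate %||% 0)
  costs <- build_costs(caseloads, bundle$unit_costs, bundle$program,
                       bundle$economics, years,
                       base_year = cfg$base_year %||% min(years))

  eco <- bundle$economics
  cost_totals_irr <- list(
    intervention_costs = sum(costs$intervention_costs),
    program_costs = sum(costs$program_costs),
    labor_costs = sum(costs$labor_costs),
    total_costs = sum(costs$total_costs)
  )
  total_usd <- sum(annual_usd(costs$total_costs, costs$year, eco))
  imp <- summarize_impact(impact)
  ratio_full <- if (total_usd == 0) {
    0
  } else if (imp$total_hly > 0) {
    cost_per_hly(total_usd, imp$total_hly, rounded = FALSE)
  } else {
    NA_real_  # flat-at-baseline runs: positive cost, no health gain
  }
  pop0 <- sum(bundle$population$count[bundle$population$year == years[1L]])

  summary <- list(
    cost_totals_irr = cost_totals_irr,
    total_cost_usd = total_usd,
    total_cost_intl = total_usd * eco$ppp_factor_intl_per_usd,
    total_hly = imp$total_hly,
    impact = imp,
    cost_per_hly_full = ratio_full,
    cost_per_hly_usd = if (is.na(ratio_full)) NA_real_ else round_half_up(ratio_full),
    cost_per_hly_intl = if (is.na(ratio_full)) NA_real_ else
      round_half_up(ratio_full * eco$ppp_factor_intl_per_usd),
    classification = if (is.na(ratio_full)) NA_character_ else
      classify_cost_effectiveness(ratio_full, eco$gdp_per_capita_usd),
    per_capita_usd = total_usd / pop0,
    gdp_per_capita_usd = eco$gdp_per_capita_usd
  )

  structure(list(
    scenario = scenario_name,
    horizon = range(years),
    trajectories = trajectories,
    caseloads = caseloads,
    costs = costs,
    impact = impact,
    economics = eco,
    disorders = bundle$disorders,
    summary = summary
  ), class = "mh_projection")
}

#' @export
print.mh_projection <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Scale-up projection [%s], %d-%d\n", x$scenario,
              x$horizon[1L], x$horizon[2L]))
  cat(sprintf("  Total cost: %s USD (%s IRR)\n",
              formatC(round_half_up(s$total_cost_usd), format = "f",
                      digits = 0, big.mark = ","),
              formatC(s$cost_totals_irr$total_costs, format = "f",
                      digits = 0, big.mark = ",")))
  cat(sprintf("  Healthy life years gained: %s\n",
              formatC(round_half_up(s$total_hly), format = "f", digits = 0,
                      big.mark = ",")))
  cat(sprintf("  Cost per healthy life year: %s USD (%s Intl$) -- %s\n",
              formatC(s$cost_per_hly_usd, format = "f", digits = 0,
                      big.mark = ","),
              formatC(s$cost_per_hly_intl, format = "f", digits = 0,
                      big.mark = ","),
              gsub("_", " ", s$classification)))
  cat(sprintf("  Per-capita cost over horizon: %.2f USD\n", s$per_capita_usd))
  invisible(x)
}

#' Summarize a projection into a serializable run report
#'
#' Assembles the annual cost table (three components plus total, in IRR and
#' whole USD), the per-year-per-disorder impact table, and the summary
#' block. Summary totals equal the column sums of the detail tables exactly
#' (integer rial for costs, stored precision for impacts).
#'
#' @param object An `mh_projection`.
#' @param ... Unused.
#' @return An object of class `mh_report` with elements `costs`, `impacts`,
#'   `summary`.
#' @export
summary.mh_projection <- function(object, ...) {
  s <- object$summary
  costs <- object$costs
  for (k in c("intervention_costs", "program_costs", "labor_costs",
              "total_costs")) {
    costs[[paste0(k, "_usd")]] <-
      round_half_up(annual_usd(costs[[k]], costs$year, object$economics))
  }
  impacts <- object$impact
  structure(list(
    scenario = object$scenario,
    costs = costs,
    impacts = impacts,
    summary = list(
      total_cost_irr = s$cost_totals_irr$total_costs,
      intervention_costs_irr = s$cost_totals_irr$intervention_costs,
      program_costs_irr = s$cost_totals_irr$program_costs,
      labor_costs_irr = s$cost_totals_irr$labor_costs,
      total_cost_usd = s$total_cost_usd,
      total_cost_intl = s$total_cost_intl,
      total_hly = s$total_hly,
      cost_per_hly_usd = s$cost_per_hly_usd,
      cost_per_hly_intl = s$cost_per_hly_intl,
      classification = s$classification,
      per_capita_usd = s$per_capita_usd,
      gdp_per_capita_usd = s$gdp_per_capita_usd,
      exchange_rate_irr_per_usd = object$economics$exchange_rate_irr_per_usd
    )
  ), class = "mh_report")
}

#' @export
print.mh_report <- function(x, ...) {
  cat(render_report_text(x), sep = "\n")
  invisible(x)
}

#' Plot a scale-up projection
#'
#' Two panels: stacked annual cost components (million USD) and annual
#' healthy life years gained by disorder.
#'
#' @param x An `mh_projection`.
#' @param ... Passed to [graphics::barplot()] for the cost panel.
#' @return `x`, invisibly.
#' @export
plot.mh_projection <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  costs_usd <- t(as.matrix(x$costs[, c("intervention_costs", "program_costs",
                                       "labor_costs")])) /
    x$economics$exchange_rate_irr_per_usd / 1e6
  colnames(costs_usd) <- x$costs$year
  cols <- hcl.colors(3, "Dark 3")
  barplot(costs_usd, col = cols, border = NA, las = 2,
          ylab = "Annual cost (million USD)",
          main = sprintf("Costs [%s]", x$scenario), ...)
  legend("topleft", fill = cols, bty = "n", cex = 0.8,
         legend = c("intervention", "programme", "labor"))

  imp <- x$impact
  wide <- do.call(cbind, lapply(split(imp$hly_gained, imp$disorder), identity))
  yrs <- sort(unique(imp$year))
  cols2 <- hcl.colors(ncol(wide), "Dark 3")
  matplot(yrs, wide, type = "l", lty = 1, lwd = 2, col = cols2,
          xlab = "Year", ylab = "Healthy life years gained",
          main = "Health impact")
  legend("topleft", col = cols2, lty = 1, lwd = 2, bty = "n", cex = 0.8,
         legend = colnames(wide))
  invisible(x)
}
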