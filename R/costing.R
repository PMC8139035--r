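# Three-component costing in integer rial, with inflation compounding and
# report-time currency conversion. Money is carried internally as integer
# minor units of the local currency so every conservation identity
# (component sums, horizon totals) holds exactly.

#' Compound an amount forward through an inflation series
#'
#' Multiplies `amount` by the product of `(1 + rate)` over the years after
#' `base_year` up to and including `target_year`. Equal years return the
#' amount unchanged.
#'
#' @param amount Amount in local currency.
#' @param base_year,target_year Calendar years, both covered by the series,
#'   with `target_year >= base_year`.
#' @param inflation_series Data frame with columns `year`, `rate`.
#' @return Inflated amount (full precision; callers round).
#' @examples
#' infl <- data.frame(year = 2020:2022, rate = 0.1)
#' inflate(100, 2020, 2022, infl)  # 121
#' @export
inflate <- function(amount, base_year, target_year, inflation_series) {
  yrs <- inflation_series$year
  if (!(base_year %in% yrs) || !(target_year %in% yrs)) {
    stop_validation("year %s outside inflation series (%s-%s)",
                    if (base_year %in% yrs) target_year else base_year,
                    min(yrs), max(yrs))
  }
  if (target_year < base_year) {
    stop_validation("target_year (%s) precedes base_year (%s)",
                    target_year, base_year)
  }
  if (target_year == base_year) return(amount)
  span <- yrs > base_year & yrs <= target_year
  amount * prod(1 + inflation_series$rate[span])
}

# Commodity (drug and supply) component of a profile, in base-year IRR.
commodity_amount <- function(profile) {
  sum(profile$amount[profile$component == "commodity"])
}

# Per-case labor component: sum of minutes x per-minute salary over cadres.
labor_amount <- function(profile) {
  lab <- profile[profile$component != "commodity", , drop = FALSE]
  if (nrow(lab) == 0L) return(0)
  sum(lab$minutes_per_case_year * lab$salary_per_minute)
}

#' Annual intervention (commodity) cost
#'
#' Treated cases times the inflated per-case drug-and-supply amount,
#' rounded half-up to integer rial.
#'
#' @param treated Treated case count for the year.
#' @param profile Unit-cost rows for one intervention (see [make_costs()]).
#' @param year Costing year.
#' @param base_year Price base year of the profile.
#' @param inflation_series Inflation series (`year`, `rate`).
#' @return Cost in integer IRR.
#' @export
intervention_cost <- function(treated, profile, year, base_year,
                              inflation_series) {
  if (any(treated < 0)) stop_validation("treated must be non-negative")
  round_half_up(treated * inflate(commodity_amount(profile), base_year, year,
                                  inflation_series))
}

#' Annual delivery-labor cost
#'
#' Treated cases times the inflated per-case staff-time amount (sum over
#' cadres of minutes times per-minute salary), rounded half-up.
#'
#' @inheritParams intervention_cost
#' @return Cost in integer IRR.
#' @export
labor_cost <- function(treated, profile, year, base_year, inflation_series) {
  if (any(treated < 0)) stop_validation("treated must be non-negative")
  round_half_up(treated * inflate(labor_amount(profile), base_year, year,
                                  inflation_series))
}

#' Annual programme overhead cost
#'
#' Management, supervision and training overheads not attributable to
#' individual cases: national management booked once, provincial
#' components scaled by the administrative-unit count, all inflated to the
#' costing year and rounded half-up.
#'
#' @param program Programme profile: list with `national_management`,
#'   `provincial_management`, `supervision`, `training` (annual IRR at
#'   base-year prices) and `n_admin_units`.
#' @param year Costing year.
#' @param base_year Price base year.
#' @param inflation_series Inflation series.
#' @param scale Administrative-unit count (defaults to the profile's).
#' @return Cost in integer IRR.
#' @export
program_cost <- function(program, year, base_year, inflation_series,
                         scale = program$n_admin_units) {
  comp <- vapply(c("national_management", "provincial_management",
                   "supervision", "training"),
                 function(k) program[[k]] %||% 0, numeric(1))
  if (any(comp < 0) || scale < 0) {
    stop_validation("programme cost components must be non-negative")
  }
  annual <- comp[["national_management"]] +
    scale * (comp[["provincial_management"]] + comp[["supervision"]] +
               comp[["training"]])
  round_half_up(inflate(annual, base_year, year, inflation_series))
}

#' Assemble the full annual cost series
#'
#' Per year: intervention (commodity) costs summed over interventions,
#' programme overheads, delivery-labor costs, and their total, all in
#' integer rial. Component rounding happens at the (intervention, year)
#' level, so the per-year total equals the component sum exactly and the
#' horizon total equals the sum of annual totals exactly.
#'
#' @param caseloads Caseload series from [build_caseloads()].
#' @param unit_costs Unit-cost table (see [make_costs()]).
#' @param program Programme profile (see [program_cost()]).
#' @param economics Economic settings (see [make_economics()]).
#' @param years Horizon years.
#' @param base_year Price base year (default: first horizon year).
#' @return Data frame with columns `year`, `intervention_costs`,
#'   `program_costs`, `labor_costs`, `total_costs` (IRR).
#' @export
build_costs <- function(caseloads, unit_costs, program, economics, years,
                        base_year = min(years)) {
  infl <- economics$inflation
  ids <- unique(caseloads$intervention)
  profiles <- lapply(setNames(ids, ids), function(id) {
    pr <- unit_costs[unit_costs$intervention == id, , drop = FALSE]
    if (nrow(pr) == 0L) {
      stop_validation("no unit-cost profile for intervention '%s'", id)
    }
    pr
  })
  out <- do.call(rbind, lapply(years, function(y) {
    cl <- caseloads[caseloads$year == y, , drop = FALSE]
    ic <- sum(vapply(ids, function(id) {
      intervention_cost(cl$treated[cl$intervention == id], profiles[[id]],
                        y, base_year, infl)
    }, numeric(1)))
    lc <- sum(vapply(ids, function(id) {
      labor_cost(cl$treated[cl$intervention == id], profiles[[id]],
                 y, base_year, infl)
    }, numeric(1)))
    pc <- program_cost(program, y, base_year, infl)
    data.frame(year = y, intervention_costs = ic, program_costs = pc,
               labor_costs = lc, total_costs = ic + pc + lc)
  }))
  rownames(out) <- NULL
  out
}

#' Convert annual local-currency amounts to USD
#'
#' Per-year conversion of an annual cost series. By default every year uses
#' the single fixed market exchange rate; if the economic settings carry an
#' `exchange_rate_series` (data frame `year`, `rate`, e.g. an extrapolated
#' depreciation path), each year converts at its own rate. With high local
#' inflation the two modes diverge substantially: a depreciating series
#' largely offsets inflation in dollar terms, a fixed rate does not.
#'
#' @param amount_irr Annual amounts in local currency (one per `years`).
#' @param years Calendar years of the amounts.
#' @param economics Economic settings (see [make_economics()]), optionally
#'   with `exchange_rate_series`.
#' @return Annual amounts in USD, full precision.
#' @export
annual_usd <- function(amount_irr, years, economics) {
  ser <- economics$exchange_rate_series
  if (is.null(ser)) {
    return(convert_currency(amount_irr, economics, "USD"))
  }
  rate <- ser$rate[match(years, ser$year)]
  if (anyNA(rate)) {
    stop_validation("exchange_rate_series does not cover year %s",
                    years[which(is.na(rate))[1L]])
  }
  if (any(rate <= 0)) stop_validation("exchange rates must be positive")
  amount_irr / rate
}

#' Convert a local-currency amount to USD or international dollars
#'
#' USD is local currency divided by the market exchange rate; international
#' (PPP-adjusted) dollars are USD times the PPP factor.
#'
#' @param amount_local Amount in local currency minor units.
#' @param economics Economic settings with positive
#'   `exchange_rate_irr_per_usd` and `ppp_factor_intl_per_usd`.
#' @param unit `"USD"` or `"IntlD"`.
#' @return Converted amount (full precision; callers round for display).
#' @examples
#' eco <- make_economics(1)
#' convert_currency(194881, eco, "USD")  # 1
#' @export
convert_currency <- function(amount_local, economics,
                             unit = c("USD", "IntlD")) {
  unit <- match.arg(unit)
  ex <- economics$exchange_rate_irr_per_usd
  ppp <- economics$ppp_factor_intl_per_usd
  if (is.null(ex) || ex <= 0 || is.null(ppp) || ppp <= 0) {
    stop_validation("exchange and PPP factors must be positive")
  }
  usd <- amount_local / ex
  switch(unit, USD = usd, IntlD = usd * ppp)
}
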