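# Reference tables from the published national projection for Iran's
# 2020-2030 socio-mental health service scale-up (the base study this
# package re-implements). These are inputs: printed coverage rows, cost and
# impact tables, and the eight-scenario sensitivity matrix. The
# effectiveness parameters behind the absolute impact levels live inside
# the original planning tool and were never published, so these tables are
# the authoritative fixture for identity checks; ab-initio runs use the
# synthetic generator instead.

#' Published coverage trajectories (front-loaded scale-up, 2020-2030)
#'
#' The seven intervention coverage rows of the published national scale-up
#' plan: basic packages start from 40% baseline coverage and reach 60-70% by
#' 2030, intensive packages start near zero and reach 30%. Rows are in
#' percent, one column per calendar year.
#'
#' @return Data frame with columns `intervention`, `disorder`, `tier`, and
#'   `y2020` ... `y2030`.
#' @examples
#' iran_coverage()[, 1:6]
#' @export
iran_coverage <- function() {
  rows <- list(
    anx_basic     = c("anxiety",    "basic",     40, 43.9, 47.5, 50.9, 54.1, 57.1, 59.9, 62.6, 65.2, 67.7, 70),
    anx_intensive = c("anxiety",    "intensive",  1, 12.6, 17.3, 20.4, 22.6, 24.4, 25.8, 27.1, 28.2, 29.1, 30),
    dep_basic     = c("depression", "basic",     40, 43.0, 46.0, 49.0, 52.0, 55.0, 58.0, 61.0, 64.0, 67.0, 70),
    dep_intensive_first = c("depression", "intensive", 1, 3.9, 6.8, 9.7, 12.6, 15.5, 18.4, 21.3, 24.2, 27.1, 30),
    dep_intensive_maint = c("depression", "intensive", 1, 3.9, 6.8, 9.7, 12.6, 15.5, 18.4, 21.3, 24.2, 27.1, 30),
    bip_intensive = c("bipolar",    "intensive",  1, 12.6, 17.3, 20.4, 22.6, 24.4, 25.8, 27.1, 28.2, 29.1, 30),
    epi_basic     = c("epilepsy",   "basic",     40, 43.9, 47.5, 50.9, 54.1, 57.1, 59.9, 62.6, 65.2, 67.7, 70)
  )
  out <- data.frame(
    intervention = names(rows),
    disorder = vapply(rows, `[`, "", 1L),
    tier = vapply(rows, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  pct <- t(vapply(rows, function(r) as.numeric(r[-(1:2)]), numeric(11)))
  colnames(pct) <- paste0("y", 2020:2030)
  rownames(out) <- NULL
  cbind(out, as.data.frame(pct, row.names = NULL))
}

#' Published annual cost table (US dollars, 2020-2030)
#'
#' Annual intervention (drug and supply), programme, and labor costs of the
#' base-case front-loaded scale-up, in whole US dollars, plus the printed
#' annual totals.
#'
#' @return Data frame with columns `year`, `intervention_costs`,
#'   `program_costs`, `labor_costs`, `total_costs` (11 rows).
#' @seealso [iran_cost_totals()] for the printed horizon totals.
#' @export
iran_cost_table <- function() {
  data.frame(
    year = 2020:2030,
    intervention_costs = c(8448265, 13488255, 18621150, 23847368, 29150836,
                           34514740, 39924870, 45361257, 50808697, 56257325,
                           61698157),
    program_costs = c(141575, 301207, 424001, 560520, 683314, 819833,
                      942627, 1051697, 1162739, 1269838, 1378908),
    labor_costs = c(31012194, 42009848, 53232422, 64666007, 76263942,
                    87984733, 99796025, 111651997, 123519471, 135378198,
                    147209639),
    total_costs = c(39602034, 55799310, 72277573, 89073895, 106098092,
                    123319306, 140663522, 158064951, 175490907, 192905361,
                    210286703)
  )
}

#' @rdname iran_cost_table
#' @return `iran_cost_totals()`: named vector of the printed horizon totals
#'   (US dollars) and the printed per-capita cost.
#' @export
iran_cost_totals <- function() {
  c(intervention_costs = 382120919, program_costs = 8736258,
    labor_costs = 972724477, total_costs = 1363581654, per_capita = 16.42)
}

#' Published annual healthy-life-years-gained table (2020-2030)
#'
#' Annual healthy life years gained (equivalently DALYs averted) by disorder
#' under the base-case scale-up, with the printed annual totals. The 2020
#' column is zero for every disorder: gains are booked only for treatment
#' above the baseline coverage, and in the first year coverage equals
#' baseline.
#'
#' @return Data frame with columns `year`, `depression`, `anxiety`,
#'   `bipolar`, `epilepsy`, `total` (11 rows).
#' @seealso [iran_impact_totals()] for the printed horizon totals.
#' @export
iran_impact_table <- function() {
  data.frame(
    year = 2020:2030,
    depression = c(0, 35873, 59717, 78750, 95490, 110979, 125688, 139854,
                   153611, 167043, 180231),
    anxiety = c(0, 8235, 13966, 19595, 25477, 31699, 38272, 45177, 52380,
                59847, 67544),
    bipolar = c(0, 4461, 6371, 7658, 8660, 9498, 10229, 10884, 11480,
                12027, 12534),
    epilepsy = c(0, 1691, 3423, 5199, 7018, 8879, 10774, 12698, 14645,
                 16610, 18588),
    total = c(0, 50260, 83477, 111202, 136645, 161055, 184963, 208613,
              232116, 255527, 278897)
  )
}

#' @rdname iran_impact_table
#' @return `iran_impact_totals()`: named vector of the printed per-disorder
#'   horizon totals and overall total (healthy life years).
#' @export
iran_impact_totals <- function() {
  c(depression = 1147236, anxiety = 362192, bipolar = 93802,
    epilepsy = 99525, total = 1702755)
}

#' Published eight-scenario sensitivity components
#'
#' Cost components (US dollars) and per-disorder healthy-life-year impacts
#' of the eight published sensitivity scenarios: the front-loaded base case,
#' two alternative scale-up patterns, the lower/upper epidemiological
#' confidence bounds, and three coverage variants. `iran_scenario_reported()`
#' returns the totals and cost-effectiveness ratios as printed, for checking
#' recomputed values against.
#'
#' @return `iran_scenario_components()`: data frame with a `quantity` column
#'   (three cost components, four disorder impacts) and one column per
#'   scenario. `iran_scenario_reported()`: same layout for the printed
#'   `total_costs`, `total_impact`, `cost_per_hly_usd`, `cost_per_hly_intl`.
#' @examples
#' iran_scenario_components()[, 1:3]
#' @export
iran_scenario_components <- function() {
  data.frame(
    quantity = c("intervention_costs", "program_costs", "labor_costs",
                 "depression", "anxiety", "bipolar", "epilepsy"),
    base_front_loaded = c(382120919, 8736258, 972724477,
                          1147236, 362192, 93802, 99525),
    exponential = c(390611079, 8736258, 994357774,
                    753131, 282307, 38658, 88300),
    linear = c(387772875, 8736258, 987228401,
               957688, 324450, 67133, 94216),
    epi_lower_CI = c(305783940, 8736258, 778324069,
                     934294, 316006, 65494, 61126),
    epi_upper_CI = c(476662810, 8736258, 1213512516,
                     1403864, 418867, 130647, 150542),
    coverage_1 = c(392627220, 8736258, 1014058490,
                   1105159, 310894, 93802, 65234),
    coverage_2 = c(448247779, 8736258, 1065250321,
                   1439832, 435672, 128165, 99525),
    coverage_3 = c(372911819, 8736258, 934160222,
                   1105371, 311346, 93802, 65716)
  )
}

#' @rdname iran_scenario_components
#' @export
iran_scenario_reported <- function() {
  data.frame(
    quantity = c("total_costs", "total_impact", "cost_per_hly_usd",
                 "cost_per_hly_intl"),
    base_front_loaded = c(1363581654, 1702755, 801, 7714),
    exponential = c(1393705112, 1162396, 1199, 11548),
    linear = c(1383737535, 1443487, 959, 9236),
    epi_lower_CI = c(1092844267, 1376920, 794, 7647),
    epi_upper_CI = c(1698911584, 2103920, 807, 7772),
    coverage_1 = c(1415421968, 1575089, 899, 8658),
    coverage_2 = c(1522234357, 2103194, 724, 6973),
    coverage_3 = c(1315808299, 1576235, 835, 8042)
  )
}

#' Reference economic settings of the study setting
#'
#' The fixed June-2020 market exchange rate (194,881 IRR per USD), the 2018
#' GDP per capita used for the cost-effectiveness threshold (5,550 USD), the
#' PPP conversion factor implied by the reported USD and Intl$ ratio pair
#' (about 9.63 Intl$ per USD), and the 2020 national population used for the
#' per-capita denominator (83 million).
#'
#' @return Named list with `exchange_rate_irr_per_usd`,
#'   `gdp_per_capita_usd`, `ppp_factor_intl_per_usd`, `population`.
#' @export
iran_defaults <- function() {
  list(
    exchange_rate_irr_per_usd = 194881,
    gdp_per_capita_usd = 5550,
    ppp_factor_intl_per_usd = 9.63,
    population = 83e6
  )
}
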