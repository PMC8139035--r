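# Cost-effectiveness ratios, threshold classification, scenario semantics,
# and the sensitivity engine.

test_that("cost per healthy life year reproduces the published ratio identities", {
  expect_identical(cost_per_hly(1363581654, 1702755), 801)
  expect_identical(cost_per_hly(1522234357, 2103194), 724)
  expect_identical(cost_per_hly(1698911584, 2103920), 807)  # 807.498 half-up
  expect_identical(cost_per_hly(0, 12345), 0)
  expect_error(cost_per_hly(100, 0), class = "mh_validation_error")
  expect_equal(cost_per_hly(1363581654, 1702755, rounded = FALSE),
               1363581654 / 1702755)
})

test_that("GDP threshold bands classify with the boundary assigned upward", {
  expect_identical(classify_cost_effectiveness(801, 5550), "very_cost_effective")
  expect_identical(classify_cost_effectiveness(5550, 5550), "cost_effective")
  expect_identical(classify_cost_effectiveness(3 * 5550, 5550), "cost_effective")
  expect_identical(classify_cost_effectiveness(20000, 5550), "not_cost_effective")
  expect_error(classify_cost_effectiveness(801, 0), class = "mh_validation_error")
  # invariance under a consistent currency change
  k <- 9.63
  expect_identical(classify_cost_effectiveness(801 * k, 5550 * k),
                   classify_cost_effectiveness(801, 5550))
})

test_that("scenario specs validate their fields", {
  expect_s3_class(scenario_spec("s", pattern = "linear"), "scenario_spec")
  expect_error(scenario_spec("s", pattern = "quadratic"),
               class = "mh_validation_error")
  expect_error(scenario_spec("s", overrides = list(list(tier = "deluxe"))),
               class = "mh_validation_error")
  expect_error(scenario_spec("s", overrides = list(
    list(tier = "basic", target_pct = 150))), class = "mh_validation_error")
  specs <- default_scenarios()
  expect_length(specs, 8)
  expect_setequal(names(specs),
                  c("base_front_loaded", "exponential", "linear",
                    "epi_lower_CI", "epi_upper_CI",
                    "coverage_1", "coverage_2", "coverage_3"))
})

test_that("applying scenarios modifies exactly what each one names", {
  b <- shared_bundle()
  specs <- default_scenarios()

  expect_identical(apply_scenario(b, specs$base_front_loaded), b)

  lo <- apply_scenario(b, specs$epi_lower_CI)
  expect_identical(lo$epi$prevalence_per_1000, b$epi$prev_lo)
  expect_identical(lo$epi$incidence_per_1000, b$epi$inc_lo)
  expect_identical(lo$interventions, b$interventions)

  hi <- apply_scenario(b, specs$epi_upper_CI)
  expect_identical(hi$epi$prevalence_per_1000, b$epi$prev_hi)

  cv2 <- apply_scenario(b, specs$coverage_2)
  intensive <- cv2$interventions$tier == "intensive"
  expect_true(all(cv2$interventions$target_coverage_pct[intensive] == 40))
  expect_identical(cv2$interventions$target_coverage_pct[!intensive],
                   b$interventions$target_coverage_pct[!intensive])
  # overridden tier loses its published rows; the other tier keeps them
  expect_false(any(cv2$coverage_table$intervention %in%
                     cv2$interventions$id[intensive]))
  expect_true(all(cv2$interventions$id[!intensive] %in%
                    cv2$coverage_table$intervention))

  cv1 <- apply_scenario(b, specs$coverage_1)
  basic <- cv1$interventions$tier == "basic"
  expect_true(all(cv1$interventions$baseline_coverage_pct[basic] == 50))

  cv3 <- apply_scenario(b, specs$coverage_3)
  expect_true(all(cv3$interventions$target_coverage_pct[
    cv3$interventions$tier == "basic"] == 60))

  ex <- apply_scenario(b, specs$exponential)
  expect_null(ex$coverage_table)
  expect_true(all(ex$interventions$pattern == "exponential"))

  expect_error(project_scaleup(b, scenario = "no_such_scenario"),
               "no_such_scenario", class = "mh_validation_error")
})

test_that("the sensitivity engine reports internally consistent columns", {
  b <- shared_bundle()
  sens <- run_scenarios(b)
  m <- sens$matrix
  expect_identical(ncol(m), 9L)  # quantity + 8 scenarios
  row_of <- function(q) unlist(m[m$quantity == q, -1])
  expect_equal(row_of("total_costs"),
               row_of("intervention_costs") + row_of("program_costs") +
                 row_of("labor_costs"),
               tolerance = 1e-9)
  expect_equal(row_of("total_impact"),
               row_of("depression") + row_of("anxiety") + row_of("bipolar") +
                 row_of("epilepsy"),
               tolerance = 1e-6)
  # each reported ratio equals cost/impact recomputed from its own column,
  # to rounding (the ratio uses full-precision totals internally)
  recomputed <- mapply(function(cost, hly) cost / hly,
                       row_of("total_costs"), row_of("total_impact"))
  expect_true(all(abs(row_of("cost_per_hly_usd") - recomputed) <= 1))
})

test_that("identical specs give identical results and failures name the scenario", {
  b <- shared_bundle()
  same <- lapply(1:3, function(i) scenario_spec(paste0("s", i)))
  sens <- run_scenarios(b, specs = same)
  expect_identical(sens$matrix$s1, sens$matrix$s2)
  expect_identical(sens$matrix$s1, sens$matrix$s3)

  broken <- shared_bundle()
  broken$unit_costs <- broken$unit_costs[
    broken$unit_costs$intervention != "anx_basic", ]
  expect_error(run_scenarios(broken, specs = same[1]),
               "s1", class = "mh_validation_error")
})

test_that("recomputing published scenario columns reproduces their ratios", {
  comp <- iran_scenario_components()
  rep <- iran_scenario_reported()
  for (sc in names(comp)[-1]) {
    got <- cea_from_components(
      comp[[sc]][comp$quantity %in% c("intervention_costs", "program_costs",
                                      "labor_costs")],
      comp[[sc]][comp$quantity %in% c("depression", "anxiety", "bipolar",
                                      "epilepsy")])
    # published component sums land within a dollar of the printed totals
    # (the source table's own rounding); the ratios agree exactly
    expect_lte(abs(got$total_costs -
                     rep[[sc]][rep$quantity == "total_costs"]), 1)
    expect_identical(got$total_impact,
                     rep[[sc]][rep$quantity == "total_impact"])
    expect_identical(got$cost_per_hly_usd,
                     rep[[sc]][rep$quantity == "cost_per_hly_usd"])
  }
})
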