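# Costing: inflation compounding, component arithmetic, conservation,
# homogeneity, currency conversion, and the component-by-component oracle.

test_that("inflation compounds over the open-closed year interval", {
  infl <- data.frame(year = 2018:2025, rate = 0.10)
  expect_identical(inflate(500, 2021, 2021, infl), 500)
  expect_equal(inflate(100, 2020, 2022, infl), 121)
  zero <- data.frame(year = 2018:2025, rate = 0)
  expect_identical(inflate(777, 2018, 2025, zero), 777)
  expect_error(inflate(100, 2020, 2030, infl), class = "mh_validation_error")
  expect_error(inflate(100, 2022, 2020, infl), class = "mh_validation_error")
})

test_that("component costs follow their unit decompositions", {
  zero <- data.frame(year = 2019:2031, rate = 0)
  prof <- data.frame(
    intervention = "x",
    component = c("commodity", "psychologist"),
    minutes_per_case_year = c(NA, 30),
    salary_per_minute = c(NA, 2000),
    amount = c(50000, 60000))
  expect_identical(intervention_cost(1000, prof, 2020, 2020, zero), 5e7)
  expect_identical(intervention_cost(0, prof, 2025, 2020, zero), 0)
  expect_identical(labor_cost(100, prof, 2020, 2020, zero), 6e6)
  no_lab <- prof[prof$component == "commodity", ]
  expect_identical(labor_cost(100, no_lab, 2020, 2020, zero), 0)

  pg <- list(national_management = 0, provincial_management = 0,
             supervision = 0, training = 0, n_admin_units = 31)
  expect_identical(program_cost(pg, 2025, 2020, zero), 0)
  pg2 <- list(national_management = 1e9, provincial_management = 1e8,
              supervision = 5e7, training = 5e7, n_admin_units = 10)
  vals <- vapply(2020:2030, function(y) program_cost(pg2, y, 2020, zero),
                 numeric(1))
  expect_true(all(vals == vals[1]))  # constant profile, zero inflation
  expect_identical(vals[1], 1e9 + 10 * 2e8)
})

test_that("cost series matches the brute-force oracle and conserves exactly", {
  b <- shared_bundle()
  years <- 2020:2030
  traj <- bundle_trajectories(b)
  cl <- build_caseloads(b$population, b$epi, b$interventions, traj, years)
  costs <- build_costs(cl, b$unit_costs, b$program, b$economics, years,
                       base_year = 2020)
  oc <- oracle_costs(b, oracle_caseloads(b, traj, years), years)
  expect_identical(costs$intervention_costs, oc$intervention_costs)
  expect_identical(costs$labor_costs, oc$labor_costs)
  expect_identical(costs$program_costs, oc$program_costs)
  expect_identical(costs$total_costs, oc$total_costs)
  # conservation: per-year totals and horizon totals are exact integer sums
  expect_identical(costs$total_costs,
                   costs$intervention_costs + costs$program_costs +
                     costs$labor_costs)
  expect_true(all(costs$total_costs == floor(costs$total_costs)))
})

test_that("costs are homogeneous in unit costs and monotone in coverage", {
  b <- shared_bundle()
  years <- 2020:2030
  traj <- bundle_trajectories(b)
  cl <- build_caseloads(b$population, b$epi, b$interventions, traj, years)
  costs <- build_costs(cl, b$unit_costs, b$program, b$economics, years)

  uc2 <- b$unit_costs
  uc2$amount <- uc2$amount * 2
  uc2$salary_per_minute <- uc2$salary_per_minute * 2
  pg2 <- b$program
  for (k in c("national_management", "provincial_management", "supervision",
              "training")) pg2[[k]] <- pg2[[k]] * 2
  doubled <- build_costs(cl, uc2, pg2, b$economics, years)
  expect_equal(doubled$intervention_costs, 2 * costs$intervention_costs)
  expect_equal(doubled$labor_costs, 2 * costs$labor_costs)
  expect_equal(doubled$total_costs, 2 * costs$total_costs)

  # pointwise-higher trajectory never yields a lower horizon total
  up <- traj
  for (id in names(up)) {
    v <- pmin(100, as.numeric(up[[id]]) + 3)
    v <- cummax(v)
    up[[id]] <- coverage_from_table(v, years = years, intervention = id)
  }
  cl_up <- build_caseloads(b$population, b$epi, b$interventions, up, years)
  costs_up <- build_costs(cl_up, b$unit_costs, b$program, b$economics, years)
  expect_gte(sum(costs_up$total_costs), sum(costs$total_costs))
})

test_that("zero caseloads leave only programme costs", {
  b <- shared_bundle()
  years <- 2020:2030
  # zero coverage needs zero baselines too for a true null run
  iv0 <- b$interventions
  iv0$baseline_coverage_pct <- 0
  cl0 <- build_caseloads(b$population, b$epi, iv0,
                         setNames(lapply(iv0$id, function(id)
                           coverage_from_table(rep(0, 11), years = years,
                                               intervention = id)), iv0$id),
                         years)
  costs0 <- build_costs(cl0, b$unit_costs, b$program, b$economics, years)
  expect_true(all(costs0$intervention_costs == 0))
  expect_true(all(costs0$labor_costs == 0))
  expect_identical(costs0$total_costs, costs0$program_costs)
})

test_that("currency conversion matches the fixed rate and round-trips", {
  eco <- make_economics(1)
  expect_identical(convert_currency(194881, eco, "USD"), 1)
  eco1 <- eco
  eco1$exchange_rate_irr_per_usd <- 1
  expect_identical(convert_currency(123.45, eco1, "USD"), 123.45)
  amount <- 987654321
  back <- convert_currency(amount, eco, "USD") * eco$exchange_rate_irr_per_usd
  expect_lt(abs(back - amount), 1)
  expect_identical(convert_currency(194881, eco, "IntlD"),
                   eco$ppp_factor_intl_per_usd)
  bad <- eco
  bad$exchange_rate_irr_per_usd <- 0
  expect_error(convert_currency(1, bad, "USD"), class = "mh_validation_error")
})

test_that("per-year exchange series mode converts each year at its own rate", {
  b <- shared_bundle()
  pr_fixed <- project_scaleup(b)
  b2 <- b
  g <- 0.2
  b2$economics$exchange_rate_series <- data.frame(
    year = 2020:2030, rate = 194881 * (1 + g)^(0:10))
  pr_ser <- project_scaleup(b2)
  # depreciation makes later (inflated) years cheaper in dollars
  expect_lt(pr_ser$summary$total_cost_usd, pr_fixed$summary$total_cost_usd)
  manual <- sum(pr_fixed$costs$total_costs /
                  (194881 * (1 + g)^(pr_fixed$costs$year - 2020)))
  expect_equal(pr_ser$summary$total_cost_usd, manual, tolerance = 1e-12)
})
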