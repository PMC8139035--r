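# Caseload accounting: products, rounding level, linearity, monotonicity,
# and agreement with the brute-force group-by-group oracle.

test_that("prevalent cases equal the group-level accumulation", {
  b <- shared_bundle()
  # single-group sanity: uniform prevalence collapses to pop * rate / 1000
  pop1 <- data.frame(year = 2020, age_sex_groups(),
                     count = c(100000, rep(0, 33)))
  epi1 <- make_epi(1, "depression")
  epi1$prevalence_per_1000 <- 50
  expect_identical(prevalent_cases(pop1, epi1, "depression", 2020), 5000)

  epi0 <- epi1
  epi0$prevalence_per_1000 <- 0
  expect_identical(prevalent_cases(pop1, epi0, "depression", 2020), 0)

  # seeded fixture vs independent per-group sum rounded once
  acc <- 0
  groups <- age_sex_groups()
  e <- b$epi[b$epi$disorder == "depression", ]
  p <- b$population[b$population$year == 2020, ]
  for (g in seq_len(34)) {
    cnt <- p$count[p$sex == groups$sex[g] & p$age_band == groups$age_band[g]]
    rate <- e$prevalence_per_1000[e$sex == groups$sex[g] &
                                    e$age_band == groups$age_band[g]]
    acc <- acc + cnt * rate / 1000
  }
  expect_identical(prevalent_cases(b$population, b$epi, "depression", 2020),
                   floor(acc + 0.5))

  # missing group is a validation error naming the disorder
  epi_miss <- e[-1, ]
  expect_error(prevalent_cases(b$population, epi_miss, "depression", 2020),
               "missing group", class = "mh_validation_error")
})

test_that("treated cases follow the eligibility-coverage product with half-up rounding", {
  expect_identical(treated_cases(10000, 1, 40), 4000)
  expect_identical(treated_cases(10000, 1, 0), 0)
  expect_identical(treated_cases(5000, 0.3, 12.6), 189)  # 5000*0.3*0.126
  expect_identical(treated_cases(101, 0.5, 99), 50)      # 49.995 rounds down
  expect_identical(treated_cases(1, 0.5, 100), 1)        # 0.5 rounds up
  expect_error(treated_cases(100, 0, 50), class = "mh_validation_error")
  expect_error(treated_cases(100, 0.5, 101), class = "mh_validation_error")
})

test_that("caseload series matches the brute-force triple-loop oracle", {
  b <- shared_bundle()
  years <- 2020:2030
  traj <- bundle_trajectories(b)
  cl <- build_caseloads(b$population, b$epi, b$interventions, traj, years)
  ocl <- oracle_caseloads(b, traj, years)
  m <- merge(cl, ocl, by = c("intervention", "year"))
  expect_equal(nrow(m), nrow(cl))
  expect_identical(m$prevalent.x, m$prevalent.y)
  expect_identical(m$treated.x, m$treated.y)
  expect_identical(m$treated_above_baseline.x, m$treated_above_baseline.y)
  # ordering invariant holds cell by cell
  expect_true(all(cl$treated <= cl$eligible))
  expect_true(all(cl$eligible <= cl$prevalent))
  expect_true(all(cl$treated_above_baseline >= 0))
})

test_that("first-year above-baseline treatment is zero; flat trajectories give zero throughout", {
  b <- shared_bundle()
  years <- 2020:2030
  cl <- build_caseloads(b$population, b$epi, b$interventions,
                        bundle_trajectories(b), years)
  expect_true(all(cl$treated_above_baseline[cl$year == 2020] == 0))

  flat <- lapply(seq_len(nrow(b$interventions)), function(i) {
    iv <- b$interventions[i, ]
    coverage_from_table(rep(iv$baseline_coverage_pct, length(years)),
                        years = years, intervention = iv$id)
  })
  names(flat) <- b$interventions$id
  cl0 <- build_caseloads(b$population, b$epi, b$interventions, flat, years)
  expect_true(all(cl0$treated_above_baseline == 0))
})

test_that("caseloads are linear in population and monotone in coverage", {
  b <- shared_bundle()
  years <- 2020:2030
  traj <- bundle_trajectories(b)

  b2 <- b
  b2$population$count <- b2$population$count * 2
  # linearity before rounding: compare unrounded accumulations
  ocl <- oracle_caseloads(b, traj, years)
  ocl2 <- oracle_caseloads(b2, traj, years)
  expect_equal(ocl2$prevalent_raw, 2 * ocl$prevalent_raw)

  # raising one year's coverage never lowers that year's treated count
  id <- "anx_basic"
  up <- traj
  v <- as.numeric(up[[id]])
  v[6:11] <- pmin(100, v[6:11] + 5)
  up[[id]] <- coverage_from_table(v, years = years, intervention = id)
  cl <- build_caseloads(b$population, b$epi, b$interventions, traj, years)
  cl_up <- build_caseloads(b$population, b$epi, b$interventions, up, years)
  expect_true(all(cl_up$treated[cl_up$intervention == id] >=
                    cl$treated[cl$intervention == id]))
})

test_that("horizon misalignment is rejected", {
  b <- shared_bundle()
  traj <- bundle_trajectories(b)
  expect_error(
    build_caseloads(b$population, b$epi, b$interventions, traj, 2020:2025),
    class = "mh_validation_error")
  expect_error(
    build_caseloads(b$population, b$epi, b$interventions,
                    traj[-1], 2020:2030),
    class = "mh_validation_error")
})
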