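# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's accounting functions: plain loops, their own half-up
# rounding, their own inflation compounding.

# one seeded bundle reused across test files (generation is cheap but not free)
shared_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- generate_bundle(42)
    b
  }
})

o_round <- function(x) floor(x + 0.5)  # independent half-up

# Brute-force caseloads: loop year x group x intervention, accumulate at
# full precision, round once per (intervention, year).
oracle_caseloads <- function(bundle, trajectories, years) {
  iv <- bundle$interventions
  out <- list()
  for (i in seq_len(nrow(iv))) {
    id <- iv$id[i]
    for (yi in seq_along(years)) {
      y <- years[yi]
      acc <- 0
      for (g in seq_len(34)) {
        grp <- age_sex_groups()[g, ]
        cnt <- bundle$population$count[
          bundle$population$year == y &
            bundle$population$sex == grp$sex &
            bundle$population$age_band == grp$age_band]
        rate <- bundle$epi$prevalence_per_1000[
          bundle$epi$disorder == iv$disorder[i] &
            bundle$epi$sex == grp$sex &
            bundle$epi$age_band == grp$age_band]
        acc <- acc + cnt * rate / 1000
      }
      prevalent <- o_round(acc)
      cov <- as.numeric(trajectories[[id]])[yi]
      treated <- o_round(prevalent * iv$eligible_fraction[i] * cov / 100)
      base_treated <- o_round(prevalent * iv$eligible_fraction[i] *
                                iv$baseline_coverage_pct[i] / 100)
      out[[length(out) + 1L]] <- data.frame(
        intervention = id, year = y, prevalent = prevalent,
        treated = treated,
        treated_above_baseline = max(0, treated - base_treated),
        prevalent_raw = acc)
    }
  }
  do.call(rbind, out)
}

# Brute-force costs: per (intervention, year) commodity and cadre-by-cadre
# labor, inflated by an explicit cumulative product.
oracle_costs <- function(bundle, ocl, years) {
  infl <- bundle$economics$inflation
  base_year <- bundle$config$base_year
  factor_to <- function(y) {
    f <- 1
    for (yy in (base_year + 1):y) {
      if (yy > y) break
      f <- f * (1 + infl$rate[infl$year == yy])
    }
    if (y == base_year) 1 else f
  }
  pg <- bundle$program
  out <- list()
  for (y in years) {
    ic <- 0; lc <- 0
    for (id in bundle$interventions$id) {
      tr <- ocl$treated[ocl$intervention == id & ocl$year == y]
      prof <- bundle$unit_costs[bundle$unit_costs$intervention == id, ]
      commodity <- sum(prof$amount[prof$component == "commodity"])
      lab <- 0
      for (r in which(prof$component != "commodity")) {
        lab <- lab + prof$minutes_per_case_year[r] * prof$salary_per_minute[r]
      }
      ic <- ic + o_round(tr * commodity * factor_to(y))
      lc <- lc + o_round(tr * lab * factor_to(y))
    }
    pc <- o_round((pg$national_management + pg$n_admin_units *
                     (pg$provincial_management + pg$supervision + pg$training)) *
                    factor_to(y))
    out[[length(out) + 1L]] <- data.frame(
      year = y, intervention_costs = ic, program_costs = pc, labor_costs = lc,
      total_costs = ic + pc + lc)
  }
  do.call(rbind, out)
}

# Brute-force impact: per intervention-year products summed into disorders.
oracle_impact <- function(bundle, ocl) {
  iv <- bundle$interventions
  dw <- setNames(bundle$disorders$disability_weight, bundle$disorders$id)
  out <- list()
  for (d in bundle$disorders$id) {
    for (y in sort(unique(ocl$year))) {
      acc <- 0
      for (i in which(iv$disorder == d)) {
        tab <- ocl$treated_above_baseline[ocl$intervention == iv$id[i] &
                                            ocl$year == y]
        acc <- acc + tab * dw[[d]] * iv$effect_size[i]
      }
      out[[length(out) + 1L]] <- data.frame(disorder = d, year = y,
                                            hly_gained = acc)
    }
  }
  do.call(rbind, out)
}

# horizon trajectories as project_scaleup builds them, for oracle input
bundle_trajectories <- function(bundle) {
  years <- bundle$config$horizon_start:bundle$config$horizon_end
  pr <- project_scaleup(bundle)
  pr$trajectories
}
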