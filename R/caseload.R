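# Treated-caseload accounting: population x prevalence x eligibility x
# coverage, with half-up rounding applied only at the (intervention, year)
# level so group-level precision is never lost.

#' Prevalent cases of a disorder in a year
#'
#' Sums `count(g) * prevalence_per_1000(g) / 1000` over all 34 age-sex
#' groups at full precision, then rounds half-up to a whole number of
#' persons. Rounding happens only here, at the disorder-year level.
#'
#' @param pop Population table (`year`, `sex`, `age_band`, `count`).
#' @param epi Epidemiology table (see [make_epi()] for columns).
#' @param disorder Disorder id present in `epi`.
#' @param year Calendar year present in `pop`.
#' @return Integer-valued count of prevalent cases.
#' @examples
#' pop <- make_population(1, base_total = 1e6)
#' epi <- make_epi(1, "epilepsy")
#' prevalent_cases(pop, epi, "epilepsy", 2020)
#' @export
prevalent_cases <- function(pop, epi, disorder, year) {
  p <- pop[pop$year == year, , drop = FALSE]
  if (nrow(p) == 0L) stop_validation("no population rows for year %s", year)
  e <- epi[epi$disorder == disorder, , drop = FALSE]
  m <- merge(p, e[, c("sex", "age_band", "prevalence_per_1000")],
             by = c("sex", "age_band"), all.x = TRUE)
  if (anyNA(m$prevalence_per_1000)) {
    miss <- m[is.na(m$prevalence_per_1000), c("sex", "age_band")]
    stop_validation("epi table for '%s' is missing group %s/%s",
                    disorder, miss$sex[1L], miss$age_band[1L])
  }
  if (nrow(m) != 34L) {
    stop_validation("expected 34 age-sex groups for year %s, found %d",
                    year, nrow(m))
  }
  round_half_up(sum(m$count * m$prevalence_per_1000 / 1000))
}

#' Treated cases given coverage
#'
#' `prevalent * eligible_fraction * coverage_pct / 100`, rounded half-up.
#' The eligible fraction is the share of prevalent cases the intervention
#' targets (e.g. moderate cases for the basic tier, severe for intensive).
#'
#' @param prevalent Prevalent case count (non-negative).
#' @param eligible_fraction Fraction in (0, 1\].
#' @param coverage_pct Coverage percentage in \[0, 100\].
#' @return Integer-valued treated case count.
#' @examples
#' treated_cases(10000, 1, 40)      # 4000
#' treated_cases(5000, 0.3, 12.6)   # 189
#' @export
treated_cases <- function(prevalent, eligible_fraction, coverage_pct) {
  if (!is.numeric(prevalent) || any(prevalent < 0)) {
    stop_validation("prevalent must be non-negative")
  }
  check_scalar_prob(eligible_fraction, "eligible_fraction", 0, 1, lo_open = TRUE)
  check_scalar_prob(coverage_pct, "coverage_pct", 0, 100)
  round_half_up(prevalent * eligible_fraction * coverage_pct / 100)
}

#' Build the full treated-caseload series
#'
#' For every intervention and horizon year: prevalent cases of its disorder,
#' eligible cases, treated cases under that year's coverage, and treated
#' cases above what baseline coverage alone would have treated (floored at
#' zero). The first horizon year has zero above-baseline treatment for
#' every intervention, since its coverage equals the baseline.
#'
#' @param pop,epi Population and epidemiology tables.
#' @param interventions Intervention roster (`id`, `disorder`,
#'   `eligible_fraction`, `baseline_coverage_pct`, ...).
#' @param trajectories Named list of [coverage_trajectory][coverage_interpolate]
#'   objects, one per intervention id, aligned on the horizon years.
#' @param years Horizon years (integer vector).
#' @return Data frame with columns `intervention`, `disorder`, `year`,
#'   `prevalent`, `eligible`, `treated`, `treated_above_baseline`.
#' @export
build_caseloads <- function(pop, epi, interventions, trajectories, years) {
  missing_traj <- setdiff(interventions$id, names(trajectories))
  if (length(missing_traj)) {
    stop_validation("no trajectory for intervention '%s'", missing_traj[1L])
  }
  for (id in interventions$id) {
    if (length(trajectories[[id]]) != length(years)) {
      stop_validation(
        "trajectory for '%s' has %d values but the horizon has %d years",
        id, length(trajectories[[id]]), length(years))
    }
  }
  # prevalent cases depend only on (disorder, year): compute once
  prev <- list()
  for (d in unique(interventions$disorder)) {
    prev[[d]] <- vapply(years, function(y) prevalent_cases(pop, epi, d, y),
                        numeric(1))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(interventions)), function(i) {
    iv <- interventions[i, ]
    cov <- as.numeric(trajectories[[iv$id]])
    pv <- prev[[iv$disorder]]
    eligible <- round_half_up(pv * iv$eligible_fraction)
    treated <- round_half_up(pv * iv$eligible_fraction * cov / 100)
    base_treated <- round_half_up(pv * iv$eligible_fraction *
                                    iv$baseline_coverage_pct / 100)
    data.frame(
      intervention = iv$id, disorder = iv$disorder, year = years,
      prevalent = pv, eligible = eligible, treated = treated,
      treated_above_baseline = pmax(0, treated - base_treated),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
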