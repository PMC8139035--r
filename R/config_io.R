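# Input schemas, validation, and serialization: a YAML master config plus
# CSV side tables (population, epi, unit_costs, economics, optional
# coverage), and report writing/reading in csv, json or text form.

#' Validate an input bundle
#'
#' Checks every structural invariant the projection relies on: a horizon of
#' at least two years; 34 age-sex groups per population year; epidemiology
#' coverage of all 34 groups for every disorder with `0 <= lo <= point <=
#' hi` and rates below 1,000; every intervention referencing a known
#' disorder, with eligible fraction in (0, 1\], effect size in \[0, 1\] and
#' `0 <= baseline <= target <= 100`; known patterns; unit-cost profiles for
#' every intervention with non-negative components; positive economic
#' factors and an inflation series covering the horizon; and monotone,
#' horizon-complete coverage rows where supplied. Validation errors name
#' the offending key. Any bundle that passes runs to completion.
#'
#' @param bundle An `mh_bundle` (or plain list with the same elements).
#' @return The bundle, invisibly, classed as `mh_bundle`.
#' @export
validate_bundle <- function(bundle) {
  cfg <- bundle$config
  if (is.null(cfg$horizon_start) || is.null(cfg$horizon_end)) {
    stop_validation("config: horizon_start and horizon_end are required")
  }
  if (cfg$horizon_end <= cfg$horizon_start) {
    stop_validation("config: horizon_end (%s) must exceed horizon_start (%s)",
                    cfg$horizon_end, cfg$horizon_start)
  }
  years <- cfg$horizon_start:cfg$horizon_end

  pop <- bundle$population
  need <- c("year", "sex", "age_band", "count")
  if (!all(need %in% names(pop))) {
    stop_validation("population: missing column(s) %s",
                    paste(setdiff(need, names(pop)), collapse = ", "))
  }
  for (y in years) {
    ny <- sum(pop$year == y)
    if (ny != 34L) {
      stop_validation("population: year %s has %d age-sex groups, expected 34",
                      y, ny)
    }
  }
  if (any(pop$count < 0)) stop_validation("population: negative counts")

  dis <- bundle$disorders
  if (is.null(dis) || nrow(dis) == 0L) stop_validation("disorders: table empty")
  if (any(dis$disability_weight <= 0 | dis$disability_weight >= 1)) {
    bad <- dis$id[dis$disability_weight <= 0 | dis$disability_weight >= 1]
    stop_validation("disorders: disability_weight for '%s' outside (0, 1)",
                    bad[1L])
  }

  epi <- bundle$epi
  groups <- age_sex_groups()
  for (d in dis$id) {
    e <- epi[epi$disorder == d, , drop = FALSE]
    if (nrow(e) != 34L) {
      stop_validation("epi: disorder '%s' has %d groups, expected 34", d, nrow(e))
    }
    key_have <- paste(e$sex, e$age_band)
    key_need <- paste(groups$sex, groups$age_band)
    if (!setequal(key_have, key_need)) {
      stop_validation("epi: disorder '%s' missing group '%s'", d,
                      setdiff(key_need, key_have)[1L])
    }
    for (trio in list(c("prev_lo", "prevalence_per_1000", "prev_hi"),
                      c("inc_lo", "incidence_per_1000", "inc_hi"))) {
      lo <- e[[trio[1L]]]; pt <- e[[trio[2L]]]; hi <- e[[trio[3L]]]
      if (any(lo < 0) || any(lo > pt + 1e-12) || any(pt > hi + 1e-12)) {
        stop_validation("epi: disorder '%s' violates 0 <= %s <= %s <= %s",
                        d, trio[1L], trio[2L], trio[3L])
      }
      if (any(hi >= 1000)) {
        stop_validation("epi: disorder '%s' has rates >= 1000 per 1000", d)
      }
    }
  }

  iv <- bundle$interventions
  if (is.null(iv) || nrow(iv) == 0L) stop_validation("interventions: table empty")
  unknown <- setdiff(iv$disorder, dis$id)
  if (length(unknown)) {
    stop_validation("interventions: unknown disorder '%s'", unknown[1L])
  }
  if (anyDuplicated(iv$id)) {
    stop_validation("interventions: duplicate id '%s'", iv$id[duplicated(iv$id)][1L])
  }
  for (i in seq_len(nrow(iv))) {
    r <- iv[i, ]
    if (!(r$eligible_fraction > 0 && r$eligible_fraction <= 1)) {
      stop_validation("interventions: '%s' eligible_fraction outside (0, 1]", r$id)
    }
    if (!(r$effect_size >= 0 && r$effect_size <= 1)) {
      stop_validation("interventions: '%s' effect_size outside [0, 1]", r$id)
    }
    if (!(r$baseline_coverage_pct >= 0 &&
          r$baseline_coverage_pct <= r$target_coverage_pct &&
          r$target_coverage_pct <= 100)) {
      stop_validation("interventions: '%s' needs 0 <= baseline <= target <= 100",
                      r$id)
    }
    if (!r$pattern %in% coverage_patterns()) {
      stop_validation("interventions: '%s' names unknown coverage pattern '%s'",
                      r$id, r$pattern)
    }
  }

  uc <- bundle$unit_costs
  no_profile <- setdiff(iv$id, unique(uc$intervention))
  if (length(no_profile)) {
    stop_validation("unit_costs: no profile for intervention '%s'",
                    no_profile[1L])
  }
  if (any(uc$amount < 0, na.rm = TRUE)) {
    stop_validation("unit_costs: negative amounts")
  }

  eco <- bundle$economics
  if (is.null(eco$inflation) || !all(years %in% eco$inflation$year)) {
    stop_validation("economics: inflation series must cover every horizon year")
  }
  if (any(eco$inflation$rate <= -1)) {
    stop_validation("economics: inflation rates must exceed -1")
  }
  if ((eco$exchange_rate_irr_per_usd %||% 0) <= 0 ||
      (eco$ppp_factor_intl_per_usd %||% 0) <= 0 ||
      (eco$gdp_per_capita_usd %||% 0) <= 0) {
    stop_validation("economics: exchange, PPP and GDP factors must be positive")
  }

  if (!is.null(bundle$coverage_table)) {
    tab <- bundle$coverage_table
    bad_iv <- setdiff(unique(tab$intervention), iv$id)
    if (length(bad_iv)) {
      stop_validation("coverage table: unknown intervention '%s'", bad_iv[1L])
    }
    for (id in unique(tab$intervention)) {
      rows <- tab[tab$intervention == id, , drop = FALSE]
      rows <- rows[order(rows$year), ]
      if (!identical(as.integer(rows$year), as.integer(years))) {
        stop_validation("coverage table: '%s' does not cover every horizon year",
                        id)
      }
      coverage_from_table(rows$percent, years = rows$year, intervention = id)
    }
  }

  for (sc in bundle$scenarios %||% list()) {
    if (!inherits(sc, "scenario_spec")) {
      stop_validation("scenarios: entries must be scenario_spec objects")
    }
  }

  if (!inherits(bundle, "mh_bundle")) class(bundle) <- "mh_bundle"
  invisible(bundle)
}

scenario_to_list <- function(sc) {
  list(name = sc$name, pattern = sc$pattern, epi_bound = sc$epi_bound,
       overrides = sc$overrides)
}

scenario_from_list <- function(x) {
  scenario_spec(x$name, pattern = x$pattern %||% "front_loaded",
                epi_bound = x$epi_bound %||% "point",
                overrides = x$overrides %||% list())
}

# write.csv keeps only ~15 significant digits; format numeric columns so
# read.csv round-trips every double bit-exactly
write_precise_csv <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_full(out[[j]])
  }
  write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' Write an input bundle to a directory
#'
#' Serializes a bundle as `config.yaml` plus the CSV side tables
#' (`population.csv`, `epi.csv`, `unit_costs.csv`, `economics.csv`, and
#' `coverage.csv` when published rows are attached). [load_config()] on the
#' written `config.yaml` reproduces the bundle.
#'
#' @param bundle A validated `mh_bundle`.
#' @param dir Output directory (created if needed).
#' @return The path to `config.yaml`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_precise_csv(bundle$population, file.path(dir, "population.csv"))
  write_precise_csv(bundle$epi, file.path(dir, "epi.csv"))
  write_precise_csv(bundle$unit_costs, file.path(dir, "unit_costs.csv"))
  eco_df <- bundle$economics$inflation
  eco_df$exchange_rate <- bundle$economics$exchange_rate_irr_per_usd
  write_precise_csv(eco_df, file.path(dir, "economics.csv"))
  paths <- list(population = "population.csv", epi = "epi.csv",
                unit_costs = "unit_costs.csv", economics = "economics.csv")
  if (!is.null(bundle$coverage_table)) {
    write_precise_csv(bundle$coverage_table, file.path(dir, "coverage.csv"))
    paths$coverage <- "coverage.csv"
  }
  cfg <- c(bundle$config, list(
    paths = paths,
    disorders = lapply(seq_len(nrow(bundle$disorders)), function(i)
      as.list(bundle$disorders[i, ])),
    interventions = lapply(seq_len(nrow(bundle$interventions)), function(i)
      as.list(bundle$interventions[i, ])),
    program = bundle$program,
    economics = list(
      exchange_rate_irr_per_usd = bundle$economics$exchange_rate_irr_per_usd,
      ppp_factor_intl_per_usd = bundle$economics$ppp_factor_intl_per_usd,
      gdp_per_capita_usd = bundle$economics$gdp_per_capita_usd
    ),
    scenarios = lapply(bundle$scenarios %||% list(), scenario_to_list)
  ))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

read_table_checked <- function(path, what) {
  if (!file.exists(path)) {
    stop_input("%s table not found at '%s'", what, path)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML master config and the CSV side tables it references
#' (resolved relative to the config file), reconstructs the input bundle,
#' and validates every cross-reference (intervention to disorder, scenario
#' to pattern, coverage rows to interventions and horizon years).
#'
#' @param path Path to a `config.yaml` written by [write_bundle()] (or
#'   hand-authored with the same schema).
#' @return A validated `mh_bundle`.
#' @examples
#' dir <- tempfile()
#' write_bundle(generate_bundle(1), dir)
#' b <- load_config(file.path(dir, "config.yaml"))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: '%s'", path)
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else
    file.path(base_dir, p)
  paths <- cfg$paths %||% list()
  for (need in c("population", "epi", "unit_costs", "economics")) {
    if (is.null(paths[[need]])) {
      stop_validation("config: paths.%s is required", need)
    }
  }

  population <- read_table_checked(resolve(paths$population), "population")
  epi <- read_table_checked(resolve(paths$epi), "epi")
  unit_costs <- read_table_checked(resolve(paths$unit_costs), "unit_costs")
  eco_df <- read_table_checked(resolve(paths$economics), "economics")
  coverage_table <- NULL
  if (!is.null(paths$coverage)) {
    coverage_table <- read_table_checked(resolve(paths$coverage), "coverage")
  }

  to_df <- function(lst, what) {
    if (is.null(lst) || length(lst) == 0L) {
      stop_validation("config: %s list is empty", what)
    }
    do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  }
  eco_cfg <- cfg$economics %||% list()
  bundle <- structure(list(
    config = list(
      horizon_start = cfg$horizon_start, horizon_end = cfg$horizon_end,
      base_year = cfg$base_year %||% cfg$horizon_start,
      country_label = cfg$country_label %||% "unknown",
      currency_local = cfg$currency_local %||% "IRR",
      coverage_pattern = cfg$coverage_pattern %||% "front_loaded",
      discount_rate = cfg$discount_rate %||% 0
    ),
    population = population,
    epi = epi,
    disorders = to_df(cfg$disorders, "disorders"),
    interventions = to_df(cfg$interventions, "interventions"),
    unit_costs = unit_costs,
    program = cfg$program %||% default_program_profile(),
    economics = list(
      inflation = data.frame(year = eco_df$year, rate = eco_df$rate),
      # optional per-year conversion mode: use the exchange_rate column of
      # economics.csv as a year-specific series instead of one fixed rate
      exchange_rate_series = if (identical(eco_cfg$exchange_mode, "series") &&
                                 !is.null(eco_df$exchange_rate)) {
        data.frame(year = eco_df$year, rate = eco_df$exchange_rate)
      },
      exchange_rate_irr_per_usd = eco_cfg$exchange_rate_irr_per_usd %||%
        eco_df$exchange_rate[1L],
      ppp_factor_intl_per_usd = eco_cfg$ppp_factor_intl_per_usd %||%
        iran_defaults()$ppp_factor_intl_per_usd,
      gdp_per_capita_usd = eco_cfg$gdp_per_capita_usd %||%
        iran_defaults()$gdp_per_capita_usd
    ),
    coverage_table = coverage_table,
    scenarios = lapply(cfg$scenarios %||% list(), scenario_from_list)
  ), class = "mh_bundle")
  validate_bundle(bundle)
}

report_to_list <- function(report) {
  list(
    scenario = report$scenario,
    costs = as.list(report$costs),
    impacts = as.list(report$impacts),
    summary = report$summary
  )
}

report_from_list <- function(x) {
  structure(list(
    scenario = x$scenario,
    costs = as.data.frame(lapply(x$costs, unlist), stringsAsFactors = FALSE),
    impacts = as.data.frame(lapply(x$impacts, unlist), stringsAsFactors = FALSE),
    summary = x$summary
  ), class = "mh_report")
}

render_report_text <- function(report) {
  s <- report$summary
  fmt <- function(x) formatC(x, format = "f", digits = 0, big.mark = ",")
  c(
    sprintf("Run report [%s]", report$scenario),
    "",
    "Costs (USD):",
    sprintf("  intervention %s | programme %s | labor %s | total %s",
            fmt(round_half_up(s$intervention_costs_irr / s$exchange_rate_irr_per_usd)),
            fmt(round_half_up(s$program_costs_irr / s$exchange_rate_irr_per_usd)),
            fmt(round_half_up(s$labor_costs_irr / s$exchange_rate_irr_per_usd)),
            fmt(round_half_up(s$total_cost_usd))),
    sprintf("Healthy life years gained: %s", fmt(round_half_up(s$total_hly))),
    sprintf("Cost per healthy life year: %s USD (%s Intl$), %s",
            fmt(s$cost_per_hly_usd), fmt(s$cost_per_hly_intl),
            gsub("_", " ", s$classification)),
    sprintf("Per-capita cost: %.2f USD (GDP per capita %s USD)",
            s$per_capita_usd, fmt(s$gdp_per_capita_usd))
  )
}

#' Write a run report
#'
#' Serializes an `mh_report` (from [summary.mh_projection()]). `json`
#' writes a single file holding all tables at full numeric precision;
#' `csv` writes a directory with `costs.csv`, `impacts.csv` and
#' `summary.csv`; `text` writes a human-readable rendering. For `json` and
#' `csv`, [read_report()] reproduces every numeric field exactly.
#'
#' @param report An `mh_report`.
#' @param path Output file (`json`, `text`) or directory (`csv`).
#' @param format `"csv"`, `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  if (!inherits(report, "mh_report")) {
    stop_validation("report must be an mh_report (see summary.mh_projection)")
  }
  if (format == "json") {
    # digits = I(17): significant digits, enough for bit-exact double round-trip
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = I(17), null = "null")
  } else if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_precise_csv(report$costs, file.path(path, "costs.csv"))
    write_precise_csv(report$impacts, file.path(path, "impacts.csv"))
    sm <- report$summary
    sm_df <- data.frame(
      key = c("scenario", names(sm)),
      value = c(report$scenario, vapply(sm, function(v)
        if (is.numeric(v)) fmt_full(v) else as.character(v), "")),
      stringsAsFactors = FALSE
    )
    write.csv(sm_df, file.path(path, "summary.csv"), row.names = FALSE,
              quote = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(render_report_text(report), con)
  }
  invisible(path)
}

#' Read a run report written by [write_report()]
#'
#' @param path The file (`json`) or directory (`csv`) written by
#'   [write_report()].
#' @param format `"json"` or `"csv"`; guessed from `path` when missing.
#' @return An `mh_report`.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "csv" else "json"
  }
  if (format == "json") {
    if (!file.exists(path)) stop_input("report not found: '%s'", path)
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    structure(list(
      scenario = x$scenario,
      costs = as.data.frame(x$costs, stringsAsFactors = FALSE),
      impacts = as.data.frame(x$impacts, stringsAsFactors = FALSE),
      summary = as.list(x$summary)
    ), class = "mh_report")
  } else if (format == "csv") {
    costs <- read.csv(file.path(path, "costs.csv"), stringsAsFactors = FALSE)
    impacts <- read.csv(file.path(path, "impacts.csv"), stringsAsFactors = FALSE)
    sm_df <- read.csv(file.path(path, "summary.csv"), stringsAsFactors = FALSE,
                      colClasses = "character")
    sm <- as.list(sm_df$value)
    names(sm) <- sm_df$key
    scenario <- sm$scenario
    sm$scenario <- NULL
    sm <- lapply(sm, function(v) {
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n)) v else n
    })
    structure(list(scenario = scenario, costs = costs, impacts = impacts,
                   summary = sm), class = "mh_report")
  } else {
    stop_input("unsupported report format '%s'", format)
  }
}
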