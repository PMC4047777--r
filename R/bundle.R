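#' Assemble a model parameter bundle
#'
#' A bundle holds every input the cost-utility model needs, fully stratified
#' by ethnicity, sex, 5-year age band, and deprivation tertile. All rates are
#' stored per person-year and converted to monthly rates inside the engine.
#'
#' @param incidence Tibble `(cancer, ethnicity, sex, age_band, deprivation,
#'   rate)`: cancer incidence, events per person-year.
#' @param excess_mortality Tibble with the same columns: excess cancer
#'   mortality (the mortality attributable to the cancer over and above
#'   background), events per person-year.
#' @param life_table A [life_table()] of background all-cause mortality.
#' @param pyld Tibble `(ethnicity, sex, age_band, value)`: prevalent years
#'   lived with disability per person-year, each in \[0, 1).
#' @param phases Tibble `(cancer, diagnosis_months, preterminal_months,
#'   terminal_months, cure_months)`: disease-phase durations in months.
#' @param disability_weights Tibble `(cancer, phase, weight)` over phases
#'   diagnosis / preterminal / terminal / remission, weights in \[0, 1).
#' @param costs List of three tibbles: `background` `(sex, age_band,
#'   annual_cost)` average annual health-system cost; `last_six_months`
#'   `(sex, age_band, cost)` total cost of the final six months of life for
#'   deaths from causes other than the cancer; `cancer_phase` `(cancer,
#'   phase, monthly_cost)` additional monthly cancer cost by phase.
#' @param deprivation_weights Tibble `(ethnicity, deprivation, weight)`:
#'   each ethnicity's population distribution over deprivation tertiles
#'   (sums to 1).
#' @param population Tibble `(ethnicity, sex, age_band, count)`: census-style
#'   population counts used for per-100,000 reporting and case weighting.
#' @param intervention List with `effect` (proportional reduction of excess
#'   mortality, default 0.20), `direct_monthly_cost` (NZ$ per month during
#'   the diagnosis/treatment phase, default 2500), and `discount_rate`
#'   (annual, default 0.03).
#' @param meta Optional list of provenance notes (seed, config).
#' @return An object of class `cea_bundle`.
#' @seealso [generate_bundle()], [validate_bundle()], [read_bundle()]
#' @export
cea_bundle <- function(incidence, excess_mortality, life_table, pyld, phases,
                       disability_weights, costs, deprivation_weights,
                       population,
                       intervention = list(
                         effect = 0.20,
                         direct_monthly_cost = 2500,
                         discount_rate = 0.03
                       ),
                       meta = list()) {
  stopifnot(
    inherits(life_table, "life_table"),
    is.list(costs),
    all(c("background", "last_six_months", "cancer_phase") %in% names(costs)),
    all(c("effect", "direct_monthly_cost", "discount_rate") %in% names(intervention))
  )
  structure(
    list(
      incidence = as_tibble(incidence),
      excess_mortality = as_tibble(excess_mortality),
      life_table = life_table,
      pyld = as_tibble(pyld),
      phases = as_tibble(phases),
      disability_weights = as_tibble(disability_weights),
      costs = lapply(costs, as_tibble),
      deprivation_weights = as_tibble(deprivation_weights),
      population = as_tibble(population),
      intervention = intervention,
      meta = meta
    ),
    class = "cea_bundle"
  )
}

#' @export
print.cea_bundle <- function(x, ...) {
  cat("<cea_bundle>\n")
  cat("  cancers:   ", paste(unique(x$incidence$cancer), collapse = ", "), "\n", sep = "")
  cat("  strata:    ", nrow(stratum_grid()), " per cancer (2 ethnicities x 2 sexes x ",
    length(age_bands()), " age bands x 3 deprivation tertiles)\n",
    sep = ""
  )
  cat("  intervention: ", sprintf(
    "%.0f%% excess-mortality reduction, $%s/month, %.1f%% discount",
    100 * x$intervention$effect,
    format(x$intervention$direct_monthly_cost, big.mark = ","),
    100 * x$intervention$discount_rate
  ), "\n", sep = "")
  if (!is.null(x$meta$seed)) cat("  seed: ", x$meta$seed, "\n", sep = "")
  invisible(x)
}

# -- validation ---------------------------------------------------------------

violation <- function(table, key, issue) {
  tibble(table = table, key = key, issue = issue)
}

#' Validate a parameter bundle
#'
#' Checks grid completeness of every stratified table, range constraints
#' (rates and costs non-negative, disability weights and pYLD in \[0, 1),
#' decline fractions in \[0, 0.04\]), phase-duration consistency (terminal
#' phase present, statistical cure time longer than the summed phases), and
#' that each ethnicity's deprivation distribution sums to 1. Never mutates
#' the bundle.
#'
#' @param bundle A [cea_bundle()].
#' @return A tibble of violations `(table, key, issue)` with class
#'   `bundle_validation`; zero rows means the bundle is valid.
#' @examples
#' b <- generate_bundle(seed = 1)
#' validate_bundle(b)
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cea_bundle"))
  v <- list()
  grid <- stratum_grid()

  for (tab in c("incidence", "excess_mortality")) {
    df <- bundle[[tab]]
    for (cx in unique(df$cancer)) {
      sub <- df[df$cancer == cx, ]
      missing <- dplyr::anti_join(grid, sub,
        by = c("ethnicity", "sex", "age_band", "deprivation")
      )
      if (nrow(missing) > 0) {
        v[[length(v) + 1]] <- violation(
          tab, paste0(cx, ": ", nrow(missing), " strata"),
          "incomplete stratum grid"
        )
      }
    }
    bad <- df[!is.finite(df$rate) | df$rate < 0, ]
    if (nrow(bad) > 0) {
      v[[length(v) + 1]] <- violation(
        tab, paste(bad$cancer[1], bad$ethnicity[1], bad$sex[1], bad$age_band[1]),
        "negative or non-finite rate"
      )
    }
  }

  lt <- bundle$life_table
  lt_grid <- tidyr::expand_grid(ethnicity = ethnicities(), sex = sexes(), age = 0:110)
  missing <- dplyr::anti_join(lt_grid, lt$rates, by = c("ethnicity", "sex", "age"))
  if (nrow(missing) > 0) {
    v[[length(v) + 1]] <- violation(
      "life_table", paste0(nrow(missing), " (ethnicity, sex, age) cells"),
      "incomplete age grid"
    )
  }
  if (any(lt$rates$rate < 0)) {
    v[[length(v) + 1]] <- violation("life_table", "rate", "negative rate")
  }
  if (any(lt$declines$annual_decline < 0 | lt$declines$annual_decline > 0.04)) {
    v[[length(v) + 1]] <- violation(
      "life_table", "annual_decline", "decline outside [0, 0.04]"
    )
  }

  pyld_grid <- tidyr::expand_grid(
    ethnicity = ethnicities(), sex = sexes(), age_band = age_bands()
  )
  missing <- dplyr::anti_join(pyld_grid, bundle$pyld, by = names(pyld_grid))
  if (nrow(missing) > 0) {
    v[[length(v) + 1]] <- violation(
      "pyld", paste0(nrow(missing), " cells"), "incomplete grid"
    )
  }
  bad <- bundle$pyld[bundle$pyld$value < 0 | bundle$pyld$value >= 1, ]
  if (nrow(bad) > 0) {
    v[[length(v) + 1]] <- violation(
      "pyld", paste(bad$ethnicity[1], bad$sex[1], bad$age_band[1]),
      "pYLD outside [0, 1)"
    )
  }

  dw <- bundle$disability_weights
  bad <- dw[dw$weight < 0 | dw$weight >= 1, ]
  if (nrow(bad) > 0) {
    for (i in seq_len(nrow(bad))) {
      v[[length(v) + 1]] <- violation(
        "disability_weights", paste(bad$cancer[i], bad$phase[i]),
        "weight outside [0, 1)"
      )
    }
  }
  need_phases <- setdiff(cancer_phases(), "cured")
  for (cx in unique(bundle$phases$cancer)) {
    have <- dw$phase[dw$cancer == cx]
    if (!all(need_phases %in% have)) {
      v[[length(v) + 1]] <- violation(
        "disability_weights", cx,
        paste0("missing phase weight(s): ", paste(setdiff(need_phases, have), collapse = ", "))
      )
    }
  }

  ph <- bundle$phases
  for (i in seq_len(nrow(ph))) {
    dur <- ph$diagnosis_months[i] + ph$preterminal_months[i] + ph$terminal_months[i]
    if (any(c(
      ph$diagnosis_months[i], ph$preterminal_months[i],
      ph$terminal_months[i], ph$cure_months[i]
    ) < 1)) {
      v[[length(v) + 1]] <- violation("phases", ph$cancer[i], "non-positive phase duration")
    }
    if (ph$cure_months[i] <= dur) {
      v[[length(v) + 1]] <- violation(
        "phases", ph$cancer[i],
        "cure time must exceed diagnosis + preterminal + terminal durations"
      )
    }
  }

  for (tab in c("background", "last_six_months")) {
    df <- bundle$costs[[tab]]
    val <- df[[setdiff(names(df), c("sex", "age_band"))[1]]]
    if (any(val < 0)) {
      v[[length(v) + 1]] <- violation(paste0("costs$", tab), "cost", "negative cost")
    }
    grid2 <- tidyr::expand_grid(sex = sexes(), age_band = age_bands())
    missing <- dplyr::anti_join(grid2, df, by = c("sex", "age_band"))
    if (nrow(missing) > 0) {
      v[[length(v) + 1]] <- violation(
        paste0("costs$", tab), paste0(nrow(missing), " cells"), "incomplete grid"
      )
    }
  }
  if (any(bundle$costs$cancer_phase$monthly_cost < 0)) {
    v[[length(v) + 1]] <- violation("costs$cancer_phase", "monthly_cost", "negative cost")
  }

  sums <- bundle$deprivation_weights |>
    dplyr::group_by(.data$ethnicity) |>
    dplyr::summarise(total = sum(.data$weight), .groups = "drop")
  for (i in seq_len(nrow(sums))) {
    if (abs(sums$total[i] - 1) > 1e-8) {
      v[[length(v) + 1]] <- violation(
        "deprivation_weights", sums$ethnicity[i],
        sprintf("weights sum to %.4f, not 1", sums$total[i])
      )
    }
  }
  if (any(bundle$deprivation_weights$weight < 0)) {
    v[[length(v) + 1]] <- violation("deprivation_weights", "weight", "negative weight")
  }

  if (any(bundle$population$count <= 0)) {
    v[[length(v) + 1]] <- violation("population", "count", "non-positive population count")
  }

  iv <- bundle$intervention
  if (iv$effect < 0 || iv$effect > 1) {
    v[[length(v) + 1]] <- violation("intervention", "effect", "effect outside [0, 1]")
  }
  if (iv$discount_rate < 0) {
    v[[length(v) + 1]] <- violation("intervention", "discount_rate", "negative discount rate")
  }

  out <- if (length(v) == 0) violation(character(), character(), character()) else bind_rows(v)
  class(out) <- c("bundle_validation", class(out))
  out
}

#' @export
print.bundle_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<bundle_validation> no violations\n")
  } else {
    cat("<bundle_validation> ", nrow(x), " violation(s)\n", sep = "")
    NextMethod()
  }
  invisible(x)
}

# -- scenario resolution ------------------------------------------------------

lookup_rate <- function(df, table_name, cancer, ethnicity, sex, age_band, deprivation) {
  hit <- df$cancer == cancer & df$ethnicity == ethnicity & df$sex == sex &
    df$age_band == age_band & df$deprivation == deprivation
  if (sum(hit) != 1L) {
    abort(paste0(
      "table '", table_name, "' has ", sum(hit), " rows for key (",
      paste(cancer, ethnicity, sex, age_band, deprivation, sep = ", "), ")"
    ))
  }
  df$rate[hit]
}

#' Resolve the effective parameters for one stratum under a scenario
#'
#' Applies the scenario's switch matrix to the bundle: where a parameter's
#' source is `reference_group`, the stratum's value is replaced by the value
#' of the matching reference-ethnicity stratum (same sex, age band, and
#' deprivation tertile) — for background mortality this substitution covers
#' the projected annual decline as well. Disability weights and the
#' prevalent-morbidity envelope are zeroed when their switches are off.
#' Incidence is always taken from the stratum's own ethnicity. Resolution of
#' a reference-ethnicity stratum is the identity under every scenario, as is
#' resolution of any stratum under full heterogeneity (Model 5).
#'
#' @param bundle A [cea_bundle()].
#' @param scenario One row of a `cea_scenario` tibble (see [scenario_spec()]).
#' @param cancer Cancer site, one of [cancer_sites()].
#' @param stratum List or one-row data frame with `ethnicity`, `sex`,
#'   `age_band`, `deprivation`.
#' @param reference_ethnicity The group whose values stand in when a switch
#'   is set to `reference_group` (default `"non_maori"`).
#' @return A list of class `effective_params` holding the per-stratum rates,
#'   weights, costs, phase schedule, projection settings, and intervention.
#' @export
resolve_effective_params <- function(bundle, scenario, cancer, stratum,
                                     reference_ethnicity = "non_maori") {
  stopifnot(inherits(bundle, "cea_bundle"), nrow(scenario) == 1L)
  stratum <- as.list(stratum)
  check_stratum(stratum)
  if (!reference_ethnicity %in% ethnicities()) {
    abort(paste0("unknown reference ethnicity: ", reference_ethnicity))
  }

  excess_eth <- if (scenario$excess_mortality_source == "reference_group") {
    reference_ethnicity
  } else {
    stratum$ethnicity
  }
  bg_eth <- if (scenario$background_mortality_source == "reference_group") {
    reference_ethnicity
  } else {
    stratum$ethnicity
  }

  incidence_rate <- lookup_rate(
    bundle$incidence, "incidence", cancer,
    stratum$ethnicity, stratum$sex, stratum$age_band, stratum$deprivation
  )
  excess_annual <- lookup_rate(
    bundle$excess_mortality, "excess_mortality", cancer,
    excess_eth, stratum$sex, stratum$age_band, stratum$deprivation
  )

  ph <- bundle$phases[bundle$phases$cancer == cancer, ]
  if (nrow(ph) != 1L) abort(paste0("table 'phases' missing cancer ", cancer))

  dw_rows <- bundle$disability_weights[bundle$disability_weights$cancer == cancer, ]
  dw <- setNames(dw_rows$weight, dw_rows$phase)
  need <- setdiff(cancer_phases(), "cured")
  if (!all(need %in% names(dw))) {
    abort(paste0("table 'disability_weights' missing phase(s) for ", cancer))
  }
  dw <- c(dw[need], cured = 0)
  if (!scenario$disability_weights_on) dw[] <- 0

  # envelope: own-ethnicity prevalent morbidity, by age band, zero when off
  pyld_rows <- bundle$pyld[
    bundle$pyld$ethnicity == stratum$ethnicity & bundle$pyld$sex == stratum$sex,
  ]
  pyld_band <- setNames(pyld_rows$value, pyld_rows$age_band)
  if (!all(age_bands() %in% names(pyld_band))) {
    abort(paste0(
      "table 'pyld' missing band(s) for (", stratum$ethnicity, ", ", stratum$sex, ")"
    ))
  }
  pyld_band <- pyld_band[age_bands()]
  if (!scenario$pyld_on) pyld_band[] <- 0

  decline <- bundle$life_table$declines$annual_decline[
    match(bg_eth, bundle$life_table$declines$ethnicity)
  ]
  if (is.na(decline)) abort(paste0("table 'life_table' missing decline for ", bg_eth))

  bg_cost <- bundle$costs$background[bundle$costs$background$sex == stratum$sex, ]
  bg_cost_band <- setNames(bg_cost$annual_cost, bg_cost$age_band)[age_bands()]
  l6 <- bundle$costs$last_six_months[bundle$costs$last_six_months$sex == stratum$sex, ]
  l6_band <- setNames(l6$cost, l6$age_band)[age_bands()]
  if (anyNA(bg_cost_band) || anyNA(l6_band)) {
    abort(paste0("cost tables missing band(s) for sex ", stratum$sex))
  }
  cp <- bundle$costs$cancer_phase[bundle$costs$cancer_phase$cancer == cancer, ]
  phase_cost <- setNames(cp$monthly_cost, cp$phase)
  if (!all(need %in% names(phase_cost))) {
    abort(paste0("table 'costs$cancer_phase' missing phase(s) for ", cancer))
  }
  phase_cost <- c(phase_cost[need], cured = 0)

  structure(
    list(
      cancer = cancer,
      stratum = stratum,
      model_id = scenario$model_id,
      incidence_rate = incidence_rate,
      excess_annual = excess_annual,
      phases = as.list(ph[, -1]),
      dw = dw,
      dw_on = isTRUE(scenario$disability_weights_on),
      pyld_band = pyld_band,
      pyld_on = isTRUE(scenario$pyld_on),
      life_table = bundle$life_table,
      bg_ethnicity = bg_eth,
      bg_decline = decline,
      bg_cost_band = bg_cost_band,
      last6_cost_band = l6_band,
      phase_cost = phase_cost,
      intervention = bundle$intervention,
      entry_year = bundle$life_table$base_year
    ),
    class = "effective_params"
  )
}

# -- disk I/O -----------------------------------------------------------------

#' Write / read a parameter bundle on disk
#'
#' Stratified tables are written as UTF-8 CSV files with a header row
#' (`incidence.csv`, `excess_mortality.csv`, `life_table.csv`, `pyld.csv`,
#' `costs_background.csv`, `costs_last_six_months.csv`,
#' `costs_cancer_phase.csv`, `population.csv`); scalar structures (phase
#' schedules, disability weights, deprivation weights, intervention,
#' projection settings) go into `settings.yaml`.
#'
#' @param bundle A [cea_bundle()].
#' @param dir Directory to write into (created if needed).
#' @return `write_bundle()`: `dir`, invisibly. `read_bundle()`: the bundle.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cea_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(dir, name), progress = FALSE)
  w(bundle$incidence, "incidence.csv")
  w(bundle$excess_mortality, "excess_mortality.csv")
  w(bundle$life_table$rates, "life_table.csv")
  w(bundle$pyld, "pyld.csv")
  w(bundle$costs$background, "costs_background.csv")
  w(bundle$costs$last_six_months, "costs_last_six_months.csv")
  w(bundle$costs$cancer_phase, "costs_cancer_phase.csv")
  w(bundle$population, "population.csv")
  settings <- list(
    phases = lapply(split(bundle$phases, bundle$phases$cancer), function(d) as.list(d[, -1])),
    disability_weights = lapply(
      split(bundle$disability_weights, bundle$disability_weights$cancer),
      function(d) as.list(setNames(d$weight, d$phase))
    ),
    deprivation_weights = lapply(
      split(bundle$deprivation_weights, bundle$deprivation_weights$ethnicity),
      function(d) as.list(setNames(d$weight, d$deprivation))
    ),
    intervention = bundle$intervention,
    projection = list(
      base_year = bundle$life_table$base_year,
      horizon_year = bundle$life_table$horizon_year,
      annual_decline = as.list(setNames(
        bundle$life_table$declines$annual_decline,
        bundle$life_table$declines$ethnicity
      ))
    ),
    meta = bundle$meta
  )
  yaml::write_yaml(settings, file.path(dir, "settings.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  need <- c(
    "incidence.csv", "excess_mortality.csv", "life_table.csv", "pyld.csv",
    "costs_background.csv", "costs_last_six_months.csv",
    "costs_cancer_phase.csv", "population.csv", "settings.yaml"
  )
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(paste0("bundle directory missing file(s): ", paste(missing, collapse = ", ")))
  }
  r <- function(name) readr::read_csv(file.path(dir, name), show_col_types = FALSE, progress = FALSE)
  s <- yaml::read_yaml(file.path(dir, "settings.yaml"))
  lt <- life_table(
    r("life_table.csv"),
    base_year = s$projection$base_year,
    horizon_year = s$projection$horizon_year,
    declines = tibble(
      ethnicity = names(s$projection$annual_decline),
      annual_decline = unlist(s$projection$annual_decline, use.names = FALSE)
    )
  )
  phases <- purrr::imap(s$phases, function(p, cx) tibble(cancer = cx, !!!p)) |> bind_rows()
  dw <- purrr::imap(s$disability_weights, function(w, cx) {
    tibble(cancer = cx, phase = names(w), weight = unlist(w, use.names = FALSE))
  }) |> bind_rows()
  depw <- purrr::imap(s$deprivation_weights, function(w, eth) {
    tibble(ethnicity = eth, deprivation = names(w), weight = unlist(w, use.names = FALSE))
  }) |> bind_rows()
  cea_bundle(
    incidence = r("incidence.csv"),
    excess_mortality = r("excess_mortality.csv"),
    life_table = lt,
    pyld = r("pyld.csv"),
    phases = phases,
    disability_weights = dw,
    costs = list(
      background = r("costs_background.csv"),
      last_six_months = r("costs_last_six_months.csv"),
      cancer_phase = r("costs_cancer_phase.csv")
    ),
    deprivation_weights = depw,
    population = r("population.csv"),
    intervention = s$intervention,
    meta = s$meta %||% list()
  )
}
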