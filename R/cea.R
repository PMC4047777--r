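#' Expected HALYs and costs over an absorption distribution
#'
#' The model is valued conditionally on the absorbing state and the month it
#' was reached; the expected value is the probability-weighted sum of the
#' valued trajectories over the full absorption distribution (cancer deaths
#' and other-cause deaths at every month, plus survival to the horizon).
#'
#' @param absorption An `absorption_dist` from [run_cohort()].
#' @param valuation A list with per-month value vectors `haly_cancer`,
#'   `haly_other`, `cost_cancer`, `cost_other` (each of length
#'   `absorption$n_months`) and scalars `haly_surv`, `cost_surv`.
#' @return One-row tibble with columns `halys` and `cost`.
#' @export
expected_value <- function(absorption, valuation) {
  stopifnot(inherits(absorption, "absorption_dist"))
  n <- absorption$n_months
  need <- c("haly_cancer", "haly_other", "cost_cancer", "cost_other")
  for (f in need) {
    if (length(valuation[[f]]) != n) {
      abort(paste0(
        "valuation coverage gap: '", f, "' has length ",
        length(valuation[[f]]), ", absorption has ", n, " months"
      ))
    }
  }
  if (is.null(valuation$haly_surv) || is.null(valuation$cost_surv)) {
    abort("valuation coverage gap: survivor outcome missing")
  }
  pc <- absorption$months$p_cancer_death
  po <- absorption$months$p_other_death
  tibble(
    halys = sum(pc * valuation$haly_cancer) + sum(po * valuation$haly_other) +
      absorption$p_alive * valuation$haly_surv,
    cost = sum(pc * valuation$cost_cancer) + sum(po * valuation$cost_other) +
      absorption$p_alive * valuation$cost_surv
  )
}

#' Case-weighted aggregation over deprivation tertiles
#'
#' Ethnic-level per-case results weight each deprivation tertile by the
#' number of cases arising in it: the ethnicity's population share of the
#' tertile times the tertile's incidence rate, normalised over tertiles. A
#' group concentrated in deprived tertiles therefore reflects
#' deprived-stratum parameters.
#'
#' @param values Tibble with a `deprivation` column and numeric value
#'   columns to aggregate.
#' @param weights Tibble `(deprivation, weight)` for one ethnicity; weights
#'   must sum to 1.
#' @param incidence Optional tibble `(deprivation, rate)`; when supplied the
#'   case weights are `weight * rate` renormalised, otherwise `weight`.
#' @return One-row tibble of weighted means of the value columns.
#' @export
aggregate_deprivation <- function(values, weights, incidence = NULL) {
  stopifnot("deprivation" %in% names(values))
  if (abs(sum(weights$weight) - 1) > 1e-8) {
    abort("deprivation weights must sum to 1")
  }
  df <- dplyr::left_join(values, weights, by = "deprivation")
  if (!is.null(incidence)) {
    df <- dplyr::left_join(df, incidence, by = "deprivation")
    df$weight <- df$weight * df$rate
    df$rate <- NULL
  }
  if (anyNA(df$weight)) abort("missing deprivation weight for some tertile")
  w <- df$weight / sum(df$weight)
  df |>
    dplyr::summarise(dplyr::across(
      dplyr::where(is.numeric) & !dplyr::any_of("weight"),
      ~ sum(.x * w)
    ))
}

#' Population-level HALY gain per 100,000
#'
#' Scales the per-case incremental gain to the population: per-case gain
#' times annual incident cases, divided by the group's census population,
#' times 100,000. Equivalently the incidence rate per 100,000 times the
#' per-case gain.
#'
#' @param per_case Incremental HALYs per case.
#' @param cases Annual incident cases in the group.
#' @param population Census population of the group (> 0).
#' @return HALYs per 100,000 population.
#' @examples
#' per_100k(1.0, 100, 1e5)
#' @export
per_100k <- function(per_case, cases, population) {
  if (any(population <= 0)) abort("population must be positive")
  per_case * cases / population * 1e5
}

#' Percent change against a reference value
#'
#' `(value - reference) / reference * 100`. A zero reference is undefined
#' and returns `NA`.
#'
#' @param value,reference Numeric vectors.
#' @return Percent change(s); `NA` where the reference is zero.
#' @examples
#' pct_change(0.81, 0.89)
#' @export
pct_change <- function(value, reference) {
  ifelse(reference == 0, NA_real_, (value - reference) / reference * 100)
}

#' Maori / non-Maori relative risk of health gain
#'
#' Simple ratio of the Maori value to the non-Maori value. A non-positive
#' denominator is undefined and returns `NA`.
#'
#' @param maori_value,non_maori_value Numeric vectors.
#' @return Ratio(s); `NA` where the denominator is not positive.
#' @examples
#' rr(1.01, 0.85)
#' @export
rr <- function(maori_value, non_maori_value) {
  ifelse(non_maori_value <= 0, NA_real_, maori_value / non_maori_value)
}

#' Incremental cost-effectiveness ratio
#'
#' Net change in costs divided by net health gain. When the health gain is
#' positive and costs increase the ratio is an ordinary ICER (`status`
#' `"ok"`); a positive gain with a cost saving yields a negative ratio
#' flagged `"dominant"`; a non-positive health gain leaves the ratio
#' undefined (`NA`, `status` `"undefined"`).
#'
#' @param incremental_cost,incremental_halys Numeric vectors.
#' @return Tibble with columns `icer` (NZ$ per HALY) and `status`.
#' @examples
#' compute_icer(4000, 0.2)
#' @export
compute_icer <- function(incremental_cost, incremental_halys) {
  n <- max(length(incremental_cost), length(incremental_halys))
  dc <- rep_len(incremental_cost, n)
  dh <- rep_len(incremental_halys, n)
  tibble(
    icer = ifelse(dh > 0, dc / dh, NA_real_),
    status = dplyr::case_when(
      dh <= 0 ~ "undefined",
      dc < 0 ~ "dominant",
      TRUE ~ "ok"
    )
  )
}

# -- pipeline internals -------------------------------------------------------

# expected baseline / intervention HALYs and costs for one stratum
stratum_cea <- function(bundle, scenario, cancer, stratum,
                        reference_ethnicity = "non_maori",
                        baseline_only = FALSE) {
  params <- resolve_effective_params(bundle, scenario, cancer, stratum,
    reference_ethnicity = reference_ethnicity
  )
  start_age <- band_midpoint(stratum$age_band)
  ad0 <- run_cohort(params, start_age, intervention_on = FALSE)
  v0 <- value_outcomes(params, ad0$n_months, start_age, intervention_on = FALSE)
  e0 <- expected_value(ad0, v0)
  out <- tibble(
    incidence_rate = params$incidence_rate,
    baseline_halys = e0$halys,
    baseline_cost = e0$cost
  )
  if (!baseline_only) {
    ad1 <- run_cohort(params, start_age, intervention_on = TRUE)
    v1 <- value_outcomes(params, ad1$n_months, start_age, intervention_on = TRUE)
    e1 <- expected_value(ad1, v1)
    out$int_halys <- e1$halys
    out$int_cost <- e1$cost
  }
  out
}

# per-stratum results for every (sex, deprivation) cell of one
# (cancer, model, ethnicity, age band), plus annual case counts
cell_strata <- function(bundle, scenario, cancer, ethnicity, band,
                        reference_ethnicity = "non_maori",
                        baseline_only = FALSE) {
  sexes_used <- if (cancer == "breast") "female" else sexes()
  combos <- tidyr::expand_grid(sex = sexes_used, deprivation = deprivation_tertiles())
  purrr::pmap(combos, function(sex, deprivation) {
    stratum <- list(
      ethnicity = ethnicity, sex = sex,
      age_band = band, deprivation = deprivation
    )
    vals <- stratum_cea(bundle, scenario, cancer, stratum,
      reference_ethnicity = reference_ethnicity, baseline_only = baseline_only
    )
    pop <- bundle$population$count[
      bundle$population$ethnicity == ethnicity &
        bundle$population$sex == sex &
        bundle$population$age_band == band
    ]
    depw <- bundle$deprivation_weights$weight[
      bundle$deprivation_weights$ethnicity == ethnicity &
        bundle$deprivation_weights$deprivation == deprivation
    ]
    dplyr::mutate(vals,
      sex = sex, deprivation = deprivation,
      cases = pop * depw * vals$incidence_rate,
      .before = 1
    )
  }) |> bind_rows()
}

# case-weighted aggregation of cell_strata() output to one reported cell
aggregate_cell <- function(strata_df) {
  w <- strata_df$cases
  if (sum(w) <= 0) w <- rep(1, nrow(strata_df))
  w <- w / sum(w)
  num <- strata_df |> dplyr::select(dplyr::where(is.numeric), -"cases")
  out <- dplyr::summarise(num, dplyr::across(dplyr::everything(), ~ sum(.x * w)))
  out$cases <- sum(strata_df$cases)
  out
}

#' Run the full scenario-by-cancer cost-effectiveness grid
#'
#' Crosses cancers, heterogeneity models, ethnicities, and age bands;
#' computes expected baseline and intervention HALYs and costs per case in
#' every (sex x deprivation) stratum; aggregates strata case-weightedly
#' (breast is modelled in women only); and derives the reporting metrics:
#' incremental HALYs and costs per case, percent change against Model 1,
#' ICERs, HALYs per 100,000 ethnic population, and Maori/non-Maori relative
#' risks per case and per 100,000.
#'
#' @param bundle A [cea_bundle()].
#' @param cancers Subset of [cancer_sites()].
#' @param models Integer vector of canonical model ids (subset of 1:5), or a
#'   `cea_scenario` tibble.
#' @param bands Age bands to report (default the three used for headline
#'   results: 50-54, 65-69, 80-84).
#' @param reference_ethnicity Reference group for `reference_group` switches.
#' @param baseline_only Skip the intervention arm (baseline HALYs/costs
#'   only); used for scenario-dominance checks.
#' @return An object of class `cea_results`: a list with `results` (the
#'   aggregated reporting table), `strata` (per-stratum values), and run
#'   metadata. Use [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], or [format_table3()] on it.
#' @examples
#' \donttest{
#' b <- generate_bundle(seed = 1)
#' res <- run_model_grid(b, cancers = "lung", bands = "65-69")
#' res$results
#' }
#' @export
run_model_grid <- function(bundle, cancers = cancer_sites(), models = 1:5,
                           bands = c("50-54", "65-69", "80-84"),
                           reference_ethnicity = "non_maori",
                           baseline_only = FALSE) {
  stopifnot(inherits(bundle, "cea_bundle"))
  scenarios <- if (inherits(models, "data.frame")) {
    models
  } else {
    canonical_scenarios() |> dplyr::filter(.data$model_id %in% models)
  }
  stopifnot(all(cancers %in% cancer_sites()), all(bands %in% age_bands()))

  pop_total <- bundle$population |>
    dplyr::group_by(.data$ethnicity) |>
    dplyr::summarise(population = sum(.data$count), .groups = "drop")

  cells <- tidyr::expand_grid(
    cancer = cancers,
    model_id = scenarios$model_id,
    ethnicity = ethnicities(),
    age_band = bands
  )
  strata_all <- list()
  rows <- purrr::pmap(cells, function(cancer, model_id, ethnicity, age_band) {
    scenario <- scenarios[scenarios$model_id == model_id, ]
    st <- cell_strata(bundle, scenario, cancer, ethnicity, age_band,
      reference_ethnicity = reference_ethnicity, baseline_only = baseline_only
    )
    strata_all[[length(strata_all) + 1]] <<- dplyr::mutate(st,
      cancer = cancer, model_id = model_id, ethnicity = ethnicity,
      age_band = age_band, .before = 1
    )
    agg <- aggregate_cell(st)
    dplyr::mutate(agg,
      cancer = cancer, model_id = model_id,
      ethnicity = ethnicity, age_band = age_band, .before = 1
    )
  }) |> bind_rows()

  res <- rows |>
    dplyr::left_join(pop_total, by = "ethnicity")
  if (!baseline_only) {
    res <- res |>
      dplyr::mutate(
        inc_haly_per_case = .data$int_halys - .data$baseline_halys,
        inc_cost_per_case = .data$int_cost - .data$baseline_cost,
        haly_per_100k = per_100k(
          .data$inc_haly_per_case, .data$cases, .data$population
        )
      )
    icer <- compute_icer(res$inc_cost_per_case, res$inc_haly_per_case)
    res$icer <- icer$icer
    res$icer_status <- icer$status
    m1 <- res |>
      dplyr::filter(.data$model_id == min(scenarios$model_id)) |>
      dplyr::select("cancer", "ethnicity", "age_band",
        m1_inc = "inc_haly_per_case"
      )
    res <- res |>
      dplyr::left_join(m1, by = c("cancer", "ethnicity", "age_band")) |>
      dplyr::mutate(pct_change_vs_model1 = pct_change(.data$inc_haly_per_case, .data$m1_inc)) |>
      dplyr::select(-"m1_inc")
    rr_tab <- res |>
      dplyr::select(
        "cancer", "model_id", "age_band", "ethnicity",
        "inc_haly_per_case", "haly_per_100k"
      ) |>
      tidyr::pivot_wider(
        names_from = "ethnicity",
        values_from = c("inc_haly_per_case", "haly_per_100k")
      ) |>
      dplyr::mutate(
        rr_per_case = rr(
          .data$inc_haly_per_case_maori, .data$inc_haly_per_case_non_maori
        ),
        rr_per_100k = rr(.data$haly_per_100k_maori, .data$haly_per_100k_non_maori)
      ) |>
      dplyr::select("cancer", "model_id", "age_band", "rr_per_case", "rr_per_100k")
    res <- dplyr::left_join(res, rr_tab, by = c("cancer", "model_id", "age_band"))
  }
  res <- dplyr::rename(res, baseline_haly_per_case = "baseline_halys") |>
    dplyr::select(-dplyr::any_of(c("int_halys", "int_cost")))

  structure(
    list(
      results = res,
      strata = bind_rows(strata_all),
      scenarios = scenarios,
      reference_ethnicity = reference_ethnicity,
      intervention = bundle$intervention,
      baseline_only = baseline_only,
      meta = bundle$meta
    ),
    class = "cea_results"
  )
}

#' Two-way sensitivity analysis over direct cost and effect size
#'
#' Recomputes the aggregated ICER for each combination of direct monthly
#' intervention cost and excess-mortality reduction, per ethnicity, for one
#' cancer, heterogeneity model, and age band. ICERs increase in the direct
#' cost at fixed effect and decrease in the effect at fixed cost; a zero
#' effect leaves the ICER undefined (flagged, not fatal).
#'
#' @param bundle A [cea_bundle()].
#' @param cancer One cancer site.
#' @param direct_costs Numeric vector of NZ$ monthly direct costs.
#' @param effects Numeric vector of proportional excess-mortality reductions
#'   in \[0, 1\].
#' @param model Canonical model id (default 5, full heterogeneity).
#' @param band Age band (default "65-69").
#' @param reference_ethnicity Reference group for scenario switches.
#' @return Tibble with one row per (ethnicity, direct_cost, effect):
#'   incremental HALYs and cost per case, `icer`, `icer_status`.
#' @export
sensitivity_grid <- function(bundle, cancer = "lung",
                             direct_costs = c(1250, 2500, 5000),
                             effects = c(0.1, 0.2, 0.4),
                             model = 5L, band = "65-69",
                             reference_ethnicity = "non_maori") {
  stopifnot(length(direct_costs) > 0, length(effects) > 0)
  if (any(effects < 0 | effects > 1)) abort("effects must lie in [0, 1]")
  scenario <- canonical_scenarios() |> dplyr::filter(.data$model_id == model)
  grid <- tidyr::expand_grid(
    ethnicity = ethnicities(), direct_cost = direct_costs, effect = effects
  )
  purrr::pmap(grid, function(ethnicity, direct_cost, effect) {
    b <- bundle
    b$intervention$effect <- effect
    b$intervention$direct_monthly_cost <- direct_cost
    st <- cell_strata(b, scenario, cancer, ethnicity, band,
      reference_ethnicity = reference_ethnicity
    )
    agg <- aggregate_cell(st)
    dh <- agg$int_halys - agg$baseline_halys
    dc <- agg$int_cost - agg$baseline_cost
    ic <- compute_icer(dc, dh)
    tibble(
      ethnicity = ethnicity, direct_cost = direct_cost, effect = effect,
      inc_haly_per_case = dh, inc_cost_per_case = dc,
      icer = ic$icer, icer_status = ic$status
    )
  }) |> bind_rows()
}
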