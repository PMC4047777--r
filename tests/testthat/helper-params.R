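# Hand-built effective parameter sets with fully controlled rates, so engine
# and valuation behaviour can be checked against closed forms.

flat_life_table <- function(annual_rate = 0.02, decline = 0) {
  life_table(
    tidyr::expand_grid(
      ethnicity = ethnicities(), sex = sexes(), age = 0:110
    ) |> dplyr::mutate(rate = annual_rate),
    base_year = 2006L, horizon_year = 2026L,
    declines = tibble::tibble(
      ethnicity = ethnicities(), annual_decline = decline
    )
  )
}

lung_dw <- c(diagnosis = 0.469, preterminal = 0.539, terminal = 0.548, remission = 0.315)

make_test_params <- function(excess_annual = 0.3,
                             bg_annual = 0.02,
                             decline = 0,
                             phases = list(
                               diagnosis_months = 5, preterminal_months = 5,
                               terminal_months = 1, cure_months = 72
                             ),
                             dw = lung_dw,
                             dw_on = TRUE,
                             pyld = 0,
                             pyld_on = FALSE,
                             bg_cost = 0,
                             last6_cost = 0,
                             phase_cost = c(
                               diagnosis = 0, preterminal = 0,
                               terminal = 0, remission = 0
                             ),
                             effect = 0.2,
                             direct_monthly_cost = 2500,
                             discount_rate = 0,
                             age_band = "65-69",
                             sex = "female",
                             ethnicity = "non_maori") {
  bands <- age_bands()
  structure(
    list(
      cancer = "lung",
      stratum = list(
        ethnicity = ethnicity, sex = sex,
        age_band = age_band, deprivation = "dep4_6"
      ),
      model_id = 5L,
      incidence_rate = 0.001,
      excess_annual = excess_annual,
      phases = phases,
      dw = c(if (dw_on) dw else setNames(rep(0, 4), names(dw)), cured = 0),
      dw_on = dw_on,
      pyld_band = setNames(rep(if (pyld_on) pyld else 0, length(bands)), bands),
      pyld_on = pyld_on,
      life_table = flat_life_table(bg_annual, decline),
      bg_ethnicity = ethnicity,
      bg_decline = decline,
      bg_cost_band = setNames(rep(bg_cost, length(bands)), bands),
      last6_cost_band = setNames(rep(last6_cost, length(bands)), bands),
      phase_cost = c(phase_cost, cured = 0),
      intervention = list(
        effect = effect,
        direct_monthly_cost = direct_monthly_cost,
        discount_rate = discount_rate
      ),
      entry_year = 2006L
    ),
    class = "effective_params"
  )
}

# cached default synthetic bundle shared across test files
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_bundle(seed = 1)
    cache
  }
})
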