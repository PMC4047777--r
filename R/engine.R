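#' Apply the intervention effect to an excess mortality rate
#'
#' The modelled treatment reduces the monthly excess mortality rate by a
#' fixed proportion: `m * (1 - effect)`. It acts in every cycle in which
#' excess mortality is non-zero, i.e. from diagnosis until statistical cure.
#'
#' @param m_excess Non-negative excess mortality rate(s).
#' @param effect Proportional reduction in \[0, 1\].
#' @return Scaled rate(s).
#' @examples
#' apply_intervention(0.05, 0.2)
#' @export
apply_intervention <- function(m_excess, effect) {
  if (length(effect) != 1L || !is.finite(effect) || effect < 0 || effect > 1) {
    abort("effect must be a single value in [0, 1]")
  }
  if (any(m_excess < 0)) abort("excess rates must be non-negative")
  m_excess * (1 - effect)
}

#' Run the monthly-cycle cohort model from diagnosis to the horizon age
#'
#' Propagates a cohort of incident cases through a three-state Markov model
#' (alive with cancer; death from cancer; death from other causes) in
#' monthly cycles from diagnosis until age 110. Each cycle combines the
#' (possibly intervention-scaled) monthly excess mortality rate — constant
#' in time since diagnosis and exactly zero after the statistical cure time
#' — with the projected background mortality rate at the attained age and
#' calendar year, splits the exit probability between the two causes
#' proportionally to the rates, and accumulates absorption mass. Probability
#' mass still alive at the horizon is reported as surviving.
#'
#' @param params An `effective_params` list from [resolve_effective_params()].
#' @param start_age Exact age in years at diagnosis (defaults to the
#'   midpoint of the stratum's age band, e.g. 52.5 for 50-54).
#' @param intervention_on Logical; scale excess mortality by
#'   `1 - params$intervention$effect`.
#' @param horizon_age Age at which follow-up stops (default 110).
#' @return An object of class `absorption_dist`: a list with `months` (a
#'   tibble of `month`, `p_cancer_death`, `p_other_death`), `p_alive`
#'   (probability of surviving to the horizon), `n_months`, `start_age`, and
#'   `intervention_on`. All probabilities sum to 1.
#' @examples
#' b <- generate_bundle(seed = 1)
#' sc <- canonical_scenarios()[5, ]
#' st <- list(
#'   ethnicity = "maori", sex = "female",
#'   age_band = "65-69", deprivation = "dep7_10"
#' )
#' p <- resolve_effective_params(b, sc, "lung", st)
#' ad <- run_cohort(p)
#' sum(ad$months$p_cancer_death) + sum(ad$months$p_other_death) + ad$p_alive
#' @export
run_cohort <- function(params, start_age = NULL, intervention_on = FALSE,
                       horizon_age = 110) {
  stopifnot(inherits(params, "effective_params"))
  if (is.null(start_age)) start_age <- band_midpoint(params$stratum$age_band)
  if (start_age >= horizon_age) abort("start_age must be below horizon_age")

  n_months <- floor((horizon_age - start_age) * 12 + 1e-9)
  month <- seq_len(n_months)
  attained_age <- floor(start_age + (month - 1) / 12)
  calendar_year <- params$entry_year + floor((month - 1) / 12)

  m_excess_ann <- params$excess_annual
  if (!is.finite(m_excess_ann)) abort("non-finite excess mortality rate")
  m_excess <- rep(m_excess_ann / 12, n_months)
  m_excess[month > params$phases$cure_months] <- 0
  if (intervention_on) {
    m_excess <- apply_intervention(m_excess, params$intervention$effect)
  }

  m_bg <- project_background_rate(
    params$life_table, attained_age, params$stratum$sex,
    params$bg_ethnicity, calendar_year,
    decline = params$bg_decline
  )
  if (any(!is.finite(m_bg))) {
    abort(paste0(
      "non-finite background rate at cycle ", which(!is.finite(m_bg))[1]
    ))
  }

  split <- competing_split(m_excess, m_bg)
  alive_before <- c(1, cumprod(split$p_survive))[seq_len(n_months)]
  p_cancer <- alive_before * split$p_cancer_death
  p_other <- alive_before * split$p_other_death
  p_alive <- prod(split$p_survive)

  structure(
    list(
      months = tibble(
        month = month,
        p_cancer_death = p_cancer,
        p_other_death = p_other
      ),
      p_alive = p_alive,
      n_months = n_months,
      start_age = start_age,
      entry_year = params$entry_year,
      intervention_on = intervention_on
    ),
    class = "absorption_dist"
  )
}

#' @export
print.absorption_dist <- function(x, ...) {
  cat(
    "<absorption_dist> ", x$n_months, " monthly cycles from age ",
    format(x$start_age), "\n",
    sprintf(
      "  P(cancer death) = %.4f, P(other death) = %.4f, P(alive at horizon) = %.4f\n",
      sum(x$months$p_cancer_death), sum(x$months$p_other_death), x$p_alive
    ),
    sep = ""
  )
  invisible(x)
}

#' @describeIn run_cohort Tidy the monthly absorption probabilities into a
#'   long tibble (one row per month and cause, plus a terminal `alive` row).
#' @param x An `absorption_dist`.
#' @param ... Unused.
#' @export
tidy.absorption_dist <- function(x, ...) {
  bind_rows(
    x$months |>
      tidyr::pivot_longer(
        c("p_cancer_death", "p_other_death"),
        names_to = "outcome", values_to = "probability"
      ) |>
      dplyr::mutate(outcome = sub("^p_", "", .data$outcome)),
    tibble(month = NA_integer_, outcome = "alive", probability = x$p_alive)
  )
}

#' Individual-level Monte-Carlo counterpart of [run_cohort()]
#'
#' Simulates `n` individuals month by month under exactly the hazards the
#' cohort engine uses, drawing each month's outcome from the same
#' competing-risk split. Used as a stochastic oracle: empirical absorption
#' frequencies converge to the cohort model's probabilities.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals.
#' @param seed Integer seed for the simulation.
#' @return A tibble with one row per individual: `outcome`
#'   (`"cancer_death"`, `"other_death"`, `"alive"`) and `month` of death
#'   (`NA` for survivors).
#' @export
simulate_individuals <- function(params, n = 10000, seed = 1,
                                 start_age = NULL, intervention_on = FALSE,
                                 horizon_age = 110) {
  stopifnot(inherits(params, "effective_params"))
  if (is.null(start_age)) start_age <- band_midpoint(params$stratum$age_band)
  ad <- run_cohort(params, start_age, intervention_on, horizon_age)
  # per-cycle conditional probabilities, identical to the engine's
  n_months <- ad$n_months
  alive_before <- c(1, 1 - cumsum(ad$months$p_cancer_death + ad$months$p_other_death))
  alive_before <- pmax(alive_before[seq_len(n_months)], 0)
  p_c_cond <- ifelse(alive_before > 0, ad$months$p_cancer_death / alive_before, 0)
  p_o_cond <- ifelse(alive_before > 0, ad$months$p_other_death / alive_before, 0)

  outcome <- rep("alive", n)
  month_of <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  for (t in seq_len(n_months)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    u <- runif(length(idx))
    dies_c <- u < p_c_cond[t]
    dies_o <- !dies_c & u < p_c_cond[t] + p_o_cond[t]
    if (any(dies_c)) {
      outcome[idx[dies_c]] <- "cancer_death"
      month_of[idx[dies_c]] <- t
      alive[idx[dies_c]] <- FALSE
    }
    if (any(dies_o)) {
      outcome[idx[dies_o]] <- "other_death"
      month_of[idx[dies_o]] <- t
      alive[idx[dies_o]] <- FALSE
    }
  }
  tibble(outcome = outcome, month = month_of)
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}
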