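#' Background-mortality life table with projected decline
#'
#' Wraps single-year all-cause mortality rates (age 0-110 by sex and
#' ethnicity) together with the projection settings used to carry them
#' forward in calendar time: a base calendar year, an annual proportional
#' decline per ethnicity, and a horizon year after which rates are frozen.
#' Defaults follow historical improvement in life expectancy: declines of
#' 2.25\%/yr (Maori) and 1.75\%/yr (non-Maori) applied up to 2026.
#'
#' @param rates Tibble with columns `ethnicity`, `sex`, `age` (integer
#'   0-110), `rate` (annual all-cause mortality, events per person-year).
#' @param base_year Calendar year the rates describe (default 2006, the
#'   cohort entry year).
#' @param horizon_year Last calendar year the decline is applied (default
#'   2026); later years reuse the horizon-year rate.
#' @param declines Tibble with columns `ethnicity`, `annual_decline`
#'   (fraction per year, each in \[0, 0.04\]).
#' @return An object of class `life_table`.
#' @export
life_table <- function(rates,
                       base_year = 2006L,
                       horizon_year = 2026L,
                       declines = tibble(
                         ethnicity = c("maori", "non_maori"),
                         annual_decline = c(0.0225, 0.0175)
                       )) {
  stopifnot(
    all(c("ethnicity", "sex", "age", "rate") %in% names(rates)),
    all(c("ethnicity", "annual_decline") %in% names(declines)),
    horizon_year >= base_year
  )
  if (any(rates$rate < 0)) abort("life_table rates must be non-negative")
  if (any(rates$age < 0 | rates$age > 110)) abort("life_table ages must lie in 0-110")
  if (any(declines$annual_decline < 0 | declines$annual_decline > 0.04)) {
    abort("annual declines must lie in [0, 0.04]")
  }
  structure(
    list(
      rates = as_tibble(rates),
      base_year = as.integer(base_year),
      horizon_year = as.integer(horizon_year),
      declines = as_tibble(declines)
    ),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ", nrow(x$rates), " rates; base year ", x$base_year,
    "; decline to ", x$horizon_year, ": ",
    paste(sprintf("%s %.2f%%/yr", x$declines$ethnicity, 100 * x$declines$annual_decline),
      collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' Project a background mortality rate and convert it to a monthly rate
#'
#' The annual rate for (age, sex, ethnicity) is scaled by
#' `(1 - decline)^(years since base)`, with elapsed years capped at the
#' projection horizon, then divided by 12 to a monthly rate. Vectorised over
#' `age` and `calendar_year` (recycled together).
#'
#' @param lt A [life_table()].
#' @param age Integer attained age(s), 0-110.
#' @param sex,ethnicity Single stratum labels.
#' @param calendar_year Attained calendar year(s), `>= lt$base_year`.
#' @param decline Optional override of the annual decline fraction (used
#'   when a scenario substitutes the reference group's projection).
#' @return Monthly mortality rate(s), events per person-month.
#' @examples
#' lt <- life_table(tidyr::expand_grid(
#'   ethnicity = ethnicities(), sex = sexes(), age = 0:110
#' ) |> dplyr::mutate(rate = 0.012))
#' project_background_rate(lt, 70, "female", "non_maori", 2008)
#' @export
project_background_rate <- function(lt, age, sex, ethnicity, calendar_year,
                                    decline = NULL) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age > 110)) abort("age beyond the life-table maximum of 110")
  if (any(age < 0)) abort("age must be non-negative")
  if (any(calendar_year < lt$base_year)) {
    abort("calendar_year precedes the life-table base year")
  }
  if (is.null(decline)) {
    decline <- lt$declines$annual_decline[match(ethnicity, lt$declines$ethnicity)]
    if (is.na(decline)) abort(paste0("no decline configured for ethnicity ", ethnicity))
  }
  sub <- lt$rates[lt$rates$ethnicity == ethnicity & lt$rates$sex == sex, ]
  if (nrow(sub) == 0L) {
    abort(paste0("life table has no rows for ", ethnicity, "/", sex))
  }
  annual <- sub$rate[match(as.integer(age), sub$age)]
  if (anyNA(annual)) {
    abort(paste0(
      "life table missing age(s) ",
      paste(unique(age[is.na(annual)]), collapse = ", "),
      " for ", ethnicity, "/", sex
    ))
  }
  elapsed <- pmin(calendar_year, lt$horizon_year) - lt$base_year
  annual * (1 - decline)^elapsed / 12
}

#' Convert a monthly rate to a monthly probability
#'
#' Standard actuarial identity under a constant hazard within the cycle:
#' `p = 1 - exp(-m)`. Strictly increasing in `m`, in \[0, 1).
#'
#' @param m Non-negative monthly rate(s).
#' @return Monthly probability(ies).
#' @examples
#' rate_to_prob(0.01)
#' @export
rate_to_prob <- function(m) {
  if (any(m < 0)) abort("rates must be non-negative")
  1 - exp(-m)
}

#' Split one cycle's exit probability between competing causes
#'
#' With constant cancer and background hazards acting together over one
#' cycle, the total exit probability is `1 - exp(-(m_c + m_b))` and is
#' allocated to the two causes proportionally to their rates (standard
#' cause-deletion). Vectorised; the three outputs sum to 1 in every row.
#'
#' @param m_cancer,m_background Non-negative monthly rates.
#' @return Tibble with columns `p_cancer_death`, `p_other_death`, `p_survive`.
#' @examples
#' competing_split(0.02, 0.01)
#' @export
competing_split <- function(m_cancer, m_background) {
  if (any(m_cancer < 0) || any(m_background < 0)) {
    abort("rates must be non-negative")
  }
  n <- max(length(m_cancer), length(m_background))
  m_cancer <- rep_len(m_cancer, n)
  m_background <- rep_len(m_background, n)
  m_tot <- m_cancer + m_background
  p_exit <- 1 - exp(-m_tot)
  share <- ifelse(m_tot > 0, m_cancer / m_tot, 0)
  tibble(
    p_cancer_death = p_exit * share,
    p_other_death = p_exit * (1 - share),
    p_survive = 1 - p_exit
  )
}
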