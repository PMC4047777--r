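#' Socio-demographic stratification constants
#'
#' The model stratifies every rate table by ethnicity (Maori / non-Maori),
#' sex, 5-year age band at diagnosis (45-49 through 90-94), and small-area
#' deprivation tertile (NZDep-style groups 1-3, 4-6, 7-10). These helpers
#' expose the canonical levels and the full stratum grid.
#'
#' @return Character vectors of levels, or for [stratum_grid()] a tibble with
#'   one row per stratum (ethnicity x sex x age_band x deprivation).
#' @examples
#' age_bands()
#' nrow(stratum_grid())  # 2 * 2 * 10 * 3 = 120
#' @name strata
NULL

#' @rdname strata
#' @export
ethnicities <- function() c("maori", "non_maori")

#' @rdname strata
#' @export
sexes <- function() c("female", "male")

#' @rdname strata
#' @export
age_bands <- function() {
  lo <- seq(45L, 90L, by = 5L)
  sprintf("%d-%d", lo, lo + 4L)
}

#' @rdname strata
#' @export
deprivation_tertiles <- function() c("dep1_3", "dep4_6", "dep7_10")

#' @rdname strata
#' @export
stratum_grid <- function() {
  tidyr::expand_grid(
    ethnicity = ethnicities(),
    sex = sexes(),
    age_band = age_bands(),
    deprivation = deprivation_tertiles()
  )
}

#' Age-band arithmetic
#'
#' `band_midpoint()` returns the midpoint age of a 5-year band (52.5 for
#' "50-54"); cohorts enter the model at this age. `band_for_age()` maps an
#' attained age to the band used for age-banded lookups (prevalent morbidity,
#' background costs); ages beyond the oldest band reuse the oldest band and
#' ages below the youngest reuse the youngest, so lookups are defined over
#' the whole life course of a cohort followed to age 110.
#'
#' @param band Character vector of band labels such as "65-69".
#' @param age Numeric vector of attained ages in years.
#' @return `band_midpoint()`: numeric midpoints; `band_for_age()`: band labels.
#' @examples
#' band_midpoint("50-54")
#' band_for_age(c(44, 67, 103))
#' @export
band_midpoint <- function(band) {
  stopifnot(all(band %in% age_bands()))
  lo <- as.numeric(sub("-.*", "", band))
  lo + 2.5
}

#' @rdname band_midpoint
#' @export
band_for_age <- function(age) {
  stopifnot(is.numeric(age), all(is.finite(age)))
  lo <- pmin(pmax(floor(age / 5) * 5, 45), 90)
  sprintf("%d-%d", lo, lo + 4)
}

#' @rdname strata
#' @export
cancer_sites <- function() c("lung", "breast", "colon")

#' @rdname strata
#' @export
cancer_phases <- function() c("diagnosis", "remission", "preterminal", "terminal", "cured")

check_stratum <- function(stratum) {
  need <- c("ethnicity", "sex", "age_band", "deprivation")
  if (!all(need %in% names(stratum))) {
    abort(paste0("stratum must supply fields: ", paste(need, collapse = ", ")))
  }
  if (!stratum$ethnicity %in% ethnicities()) abort(paste0("unknown ethnicity: ", stratum$ethnicity))
  if (!stratum$sex %in% sexes()) abort(paste0("unknown sex: ", stratum$sex))
  if (!stratum$age_band %in% age_bands()) abort(paste0("unknown age_band: ", stratum$age_band))
  if (!stratum$deprivation %in% deprivation_tertiles()) {
    abort(paste0("unknown deprivation tertile: ", stratum$deprivation))
  }
  invisible(stratum)
}
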