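#' Construct a heterogeneity scenario
#'
#' A scenario decides, for each class of input parameter, whether the model
#' uses group-specific (ethnic-specific) values or substitutes the reference
#' group's values, and whether morbidity adjustments are applied at all.
#' Cancer incidence is always ethnic-specific: it determines who the cases
#' are, not how a case is valued.
#'
#' @param model_id Integer scenario label (1-5 for the canonical ladder).
#' @param excess_mortality_source `"reference_group"` or `"ethnic_specific"`:
#'   where each stratum's excess cancer mortality rate comes from.
#' @param disability_weights_on Logical; apply cancer-phase disability
#'   weights when valuing health, or count raw life years.
#' @param background_mortality_source `"reference_group"` or
#'   `"ethnic_specific"`: source of all-cause background mortality, including
#'   its projected annual decline.
#' @param pyld_on Logical; cap health gain by the background-morbidity
#'   envelope (1 - pYLD), using ethnic-specific prevalent morbidity.
#' @return A one-row tibble of class `cea_scenario`.
#' @seealso [canonical_scenarios()]
#' @export
scenario_spec <- function(model_id,
                          excess_mortality_source = c("ethnic_specific", "reference_group"),
                          disability_weights_on = TRUE,
                          background_mortality_source = c("ethnic_specific", "reference_group"),
                          pyld_on = TRUE) {
  excess_mortality_source <- match.arg(excess_mortality_source)
  background_mortality_source <- match.arg(background_mortality_source)
  stopifnot(is.logical(disability_weights_on), is.logical(pyld_on))
  out <- tibble(
    model_id = as.integer(model_id),
    incidence_source = "ethnic_specific",
    excess_mortality_source = excess_mortality_source,
    disability_weights_on = disability_weights_on,
    background_mortality_source = background_mortality_source,
    pyld_on = pyld_on
  )
  class(out) <- c("cea_scenario", class(out))
  out
}

#' The canonical five-model heterogeneity ladder
#'
#' Each successive model adds one layer of ethnic heterogeneity on top of
#' ethnic-specific incidence:
#' \describe{
#'   \item{Model 1}{Excess cancer mortality set to the reference (non-Maori)
#'     level for both groups; disability weights off; background mortality at
#'     the reference level (including its 1.75\%/yr projected decline);
#'     prevalent-morbidity envelope off.}
#'   \item{Model 2}{Adds ethnic-specific excess mortality (cancer survival).}
#'   \item{Model 3}{Adds cancer-phase disability weights.}
#'   \item{Model 4}{Adds ethnic-specific background mortality and its
#'     ethnic-specific projected decline.}
#'   \item{Model 5}{Adds the ethnic-specific background-morbidity envelope
#'     (prevalent years lived with disability): full heterogeneity.}
#' }
#'
#' @return A five-row `cea_scenario` tibble, one row per model.
#' @examples
#' canonical_scenarios()
#' @export
canonical_scenarios <- function() {
  out <- bind_rows(
    scenario_spec(1L, "reference_group", FALSE, "reference_group", FALSE),
    scenario_spec(2L, "ethnic_specific", FALSE, "reference_group", FALSE),
    scenario_spec(3L, "ethnic_specific", TRUE, "reference_group", FALSE),
    scenario_spec(4L, "ethnic_specific", TRUE, "ethnic_specific", FALSE),
    scenario_spec(5L, "ethnic_specific", TRUE, "ethnic_specific", TRUE)
  )
  class(out) <- c("cea_scenario", class(out))
  out
}
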