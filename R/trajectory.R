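#' Retrospectively construct a disease-phase trajectory
#'
#' Given the absorbing outcome and the month it was reached, lays out the
#' monthly disease phases from diagnosis onward. For a cancer death the
#' phases are anchored at the end of life: the final `terminal_months` are
#' terminal, the `preterminal_months` before them pre-terminal, the first
#' `diagnosis_months` are diagnosis/treatment, and any months in between are
#' remission. When death comes too early to fit every phase, end-anchored
#' precedence applies: terminal first, then pre-terminal, then a truncated
#' diagnosis phase. Deaths from other causes and survivors follow the
#' non-terminal sequence — diagnosis, remission until the statistical cure
#' time, cured thereafter — and other-cause deaths flag their final six
#' months (`last6`), which carry end-of-life costs instead of average
#' background costs.
#'
#' @param outcome `"cancer_death"`, `"other_death"`, or `"survivor"`.
#' @param death_month Month of death since diagnosis (1-based); omitted for
#'   survivors.
#' @param schedule One row of a phase table, or a list with
#'   `diagnosis_months`, `preterminal_months`, `terminal_months`,
#'   `cure_months`.
#' @param total_months Months from diagnosis to the model horizon.
#' @param start_age Optional exact age at diagnosis; when given, each slot
#'   carries its attained age (needed for age-banded morbidity and costs).
#' @return A tibble of class `cea_trajectory` with columns `month`, `phase`,
#'   `last6`, `attained_age`, and attribute `outcome`.
#' @examples
#' sched <- list(
#'   diagnosis_months = 5, preterminal_months = 5,
#'   terminal_months = 1, cure_months = 72
#' )
#' build_trajectory("cancer_death", 11, sched, 120)
#' @export
build_trajectory <- function(outcome = c("cancer_death", "other_death", "survivor"),
                             death_month = NULL, schedule, total_months,
                             start_age = NULL) {
  outcome <- match.arg(outcome)
  schedule <- as.list(schedule)
  d <- schedule$diagnosis_months
  p <- schedule$preterminal_months
  tau <- schedule$terminal_months
  cure <- schedule$cure_months
  stopifnot(d >= 1, p >= 1, tau >= 1, cure > d + p + tau)

  if (outcome == "survivor") {
    if (!is.null(death_month)) abort("survivors have no death_month")
    t_end <- total_months
  } else {
    if (is.null(death_month) || death_month < 1) {
      abort("death_month must be >= 1 for deaths")
    }
    if (death_month > total_months) {
      abort("death_month exceeds total_months")
    }
    t_end <- death_month
  }

  month <- seq_len(t_end)
  if (outcome == "cancer_death") {
    n_term <- min(tau, t_end)
    n_pre <- min(p, t_end - n_term)
    n_diag <- min(d, t_end - n_term - n_pre)
    phase <- rep("remission", t_end)
    if (n_diag > 0) phase[seq_len(n_diag)] <- "diagnosis"
    if (n_pre > 0) phase[(t_end - n_term - n_pre + 1):(t_end - n_term)] <- "preterminal"
    phase[(t_end - n_term + 1):t_end] <- "terminal"
    last6 <- rep(FALSE, t_end)
  } else {
    phase <- dplyr::case_when(
      month <= min(d, t_end) ~ "diagnosis",
      month <= cure ~ "remission",
      TRUE ~ "cured"
    )
    last6 <- if (outcome == "other_death") month > t_end - 6 else rep(FALSE, t_end)
  }

  attained_age <- if (is.null(start_age)) rep(NA_real_, t_end) else start_age + (month - 1) / 12
  out <- tibble(month = month, phase = phase, last6 = last6, attained_age = attained_age)
  attr(out, "outcome") <- outcome
  class(out) <- c("cea_trajectory", class(out))
  out
}

#' Monthly discount factor
#'
#' Values are attributed at the end of each month and discounted with the
#' annual rate compounded monthly through the 1/12 exponent:
#' `(1 + r)^(-t/12)`.
#'
#' @param t Month(s) since diagnosis, `>= 1`.
#' @param annual_rate Annual discount rate, `>= 0` (default 0.03).
#' @return Discount factor(s) in (0, 1\].
#' @examples
#' discount_factor(12, 0.03) # 1 / 1.03
#' @export
discount_factor <- function(t, annual_rate = 0.03) {
  stopifnot(all(t >= 1), annual_rate >= 0)
  (1 + annual_rate)^(-t / 12)
}

#' Health weight of one month in a given disease phase
#'
#' Combines the cancer-phase disability weight with the background-morbidity
#' envelope multiplicatively on the health scale:
#' `(1 - dw) * (1 - pYLD)` per year of life, so the cancer's morbidity
#' scales the health that background comorbidity leaves available. The cured
#' phase carries no cancer disability (`dw = 0`); either component can be
#' switched off, in which case it contributes a factor of 1.
#'
#' @param phase Phase label(s) from [cancer_phases()].
#' @param dw_set Named numeric vector of disability weights for phases
#'   `diagnosis`, `preterminal`, `terminal`, `remission` (each in \[0, 1)).
#' @param pyld Prevalent-morbidity fraction(s) in \[0, 1).
#' @param dw_on,pyld_on Logical switches for the two components.
#' @return Health weight(s) per life-year, in \[0, 1\].
#' @examples
#' haly_weight("cured", c(
#'   diagnosis = 0.469, preterminal = 0.539,
#'   terminal = 0.548, remission = 0.315
#' ), pyld = 0.224)
#' @export
haly_weight <- function(phase, dw_set, pyld = 0, dw_on = TRUE, pyld_on = TRUE) {
  dw_set <- c(dw_set[setdiff(cancer_phases(), "cured")], cured = 0)
  if (anyNA(dw_set)) abort("dw_set must name diagnosis, preterminal, terminal, remission")
  if (any(dw_set < 0 | dw_set >= 1)) abort("disability weights must lie in [0, 1)")
  if (any(pyld < 0 | pyld >= 1)) abort("pYLD must lie in [0, 1)")
  bad <- setdiff(unique(phase), cancer_phases())
  if (length(bad) > 0) abort(paste0("unknown phase(s): ", paste(bad, collapse = ", ")))
  dw <- unname(dw_set[phase])
  (1 - dw * as.numeric(dw_on)) * (1 - pyld * as.numeric(pyld_on))
}

#' Value a trajectory in discounted HALYs
#'
#' Sums `haly_weight / 12 * discount_factor` over the trajectory's months.
#' The prevalent-morbidity fraction is looked up at each month's attained
#' age band. For deaths from other causes the terminal-phase disability
#' weight can be applied to the final month of life
#' (`other_death_terminal_dw`, default `TRUE`), representing increased
#' end-of-life morbidity.
#'
#' @param traj A [build_trajectory()] result.
#' @param dw_set Named disability weights (see [haly_weight()]).
#' @param pyld_band Named vector of pYLD by age band, or a single number
#'   applied to all months; ignored when `pyld_on = FALSE`.
#' @param dw_on,pyld_on Morbidity switches.
#' @param discount_rate Annual discount rate.
#' @param other_death_terminal_dw Apply the terminal disability weight to
#'   the final month of an other-cause death.
#' @return Discounted HALYs (scalar).
#' @export
value_halys <- function(traj, dw_set, pyld_band = 0, dw_on = TRUE,
                        pyld_on = FALSE, discount_rate = 0,
                        other_death_terminal_dw = TRUE) {
  stopifnot(inherits(traj, "cea_trajectory"))
  if (nrow(traj) == 0) return(0)
  pyld <- lookup_by_band(pyld_band, traj$attained_age, "pYLD", needed = pyld_on)
  w <- haly_weight(traj$phase, dw_set, pyld, dw_on, pyld_on)
  if (other_death_terminal_dw && dw_on &&
    identical(attr(traj, "outcome"), "other_death")) {
    last <- nrow(traj)
    w[last] <- haly_weight("terminal", dw_set, pyld[min(last, length(pyld))], dw_on, pyld_on)
  }
  sum(w / 12 * discount_factor(traj$month, discount_rate))
}

#' Value a trajectory in discounted health-system costs
#'
#' Each month accrues the phase-specific cancer cost (zero once cured), plus
#' one twelfth of the average annual background cost at the attained age
#' band — replaced by one sixth of the last-six-months-of-life cost in
#' months flagged `last6` — plus the intervention's direct monthly cost
#' during the diagnosis/treatment phase when the intervention is on. All
#' components are discounted at the monthly factor.
#'
#' @inheritParams value_halys
#' @param bg_cost_band Named annual background cost by age band, or scalar.
#' @param last6_cost_band Named total last-six-months cost by age band, or
#'   scalar.
#' @param phase_cost Named monthly cancer cost for phases `diagnosis`,
#'   `preterminal`, `terminal`, `remission` (cured is always 0).
#' @param intervention_on Logical; add `direct_monthly_cost` in diagnosis
#'   months.
#' @param direct_monthly_cost Direct intervention cost, NZ$ per month.
#' @return Discounted cost in NZ$ (scalar).
#' @export
value_costs <- function(traj, bg_cost_band = 0, last6_cost_band = 0,
                        phase_cost = c(
                          diagnosis = 0, preterminal = 0,
                          terminal = 0, remission = 0
                        ),
                        intervention_on = FALSE, direct_monthly_cost = 0,
                        discount_rate = 0) {
  stopifnot(inherits(traj, "cea_trajectory"))
  if (nrow(traj) == 0) return(0)
  phase_cost <- c(phase_cost[setdiff(cancer_phases(), "cured")], cured = 0)
  if (anyNA(phase_cost)) {
    abort("phase_cost must name diagnosis, preterminal, terminal, remission")
  }
  bg <- lookup_by_band(bg_cost_band, traj$attained_age, "background cost")
  l6 <- lookup_by_band(last6_cost_band, traj$attained_age, "last-six-months cost")
  monthly <- unname(phase_cost[traj$phase]) +
    ifelse(traj$last6, l6 / 6, bg / 12) +
    (traj$phase == "diagnosis") * as.numeric(intervention_on) * direct_monthly_cost
  sum(monthly * discount_factor(traj$month, discount_rate))
}

# look up a per-band value for each month's attained age; scalars recycle
lookup_by_band <- function(band_vec, attained_age, what, needed = TRUE) {
  if (length(band_vec) == 1L && is.null(names(band_vec))) {
    return(rep(unname(band_vec), length(attained_age)))
  }
  if (anyNA(attained_age)) {
    if (!needed) return(rep(0, length(attained_age)))
    abort(paste0(
      "trajectory lacks attained ages; build it with start_age to use age-banded ", what
    ))
  }
  out <- unname(band_vec[band_for_age(attained_age)])
  if (anyNA(out)) abort(paste0(what, " table missing an age band"))
  out
}

# -- vectorised valuation of every absorbing outcome --------------------------
#
# The cohort pipeline needs the value of a cancer death and an other-cause
# death at every possible month, plus the survivor value. Prefix sums over
# the discounted month weights make each death month O(1), so a whole cohort
# is valued in O(T). Must agree exactly with build_trajectory() +
# value_halys()/value_costs(); a test enforces this.
value_outcomes <- function(params, n_months, start_age,
                           intervention_on = FALSE,
                           other_death_terminal_dw = TRUE) {
  stopifnot(inherits(params, "effective_params"))
  d <- params$phases$diagnosis_months
  p <- params$phases$preterminal_months
  tau <- params$phases$terminal_months
  cure <- params$phases$cure_months
  r <- params$intervention$discount_rate
  direct <- if (intervention_on) params$intervention$direct_monthly_cost else 0

  month <- seq_len(n_months)
  disc <- discount_factor(month, r)
  age <- start_age + (month - 1) / 12
  band <- band_for_age(age)
  pyld_m <- unname(params$pyld_band[band]) # already zeroed when the envelope is off
  q <- 1 - pyld_m

  A <- 1 - params$dw # named per-phase health factors (dw zeroed when off)
  B <- q * disc / 12
  S <- c(0, cumsum(B)) # S[t + 1] = sum of B over months 1..t
  at <- function(t) S[pmax(t, 0) + 1]

  bgc <- unname(params$bg_cost_band[band]) / 12 * disc
  l6c <- unname(params$last6_cost_band[band]) / 6 * disc
  Sd <- c(0, cumsum(disc))
  Sbg <- c(0, cumsum(bgc))
  Sl6 <- c(0, cumsum(l6c))
  dat <- function(t) Sd[pmax(t, 0) + 1]
  bgat <- function(t) Sbg[pmax(t, 0) + 1]
  l6at <- function(t) Sl6[pmax(t, 0) + 1]
  cp <- params$phase_cost

  t <- month
  # cancer deaths: end-anchored phase blocks
  n_term <- pmin(tau, t)
  n_pre <- pmin(p, t - n_term)
  n_diag <- pmin(d, t - n_term - n_pre)
  rem_end <- t - n_term - n_pre # remission occupies n_diag+1 .. rem_end (empty when truncated)
  haly_cancer <- A[["diagnosis"]] * at(n_diag) +
    A[["remission"]] * (at(rem_end) - at(n_diag)) +
    A[["preterminal"]] * (at(t - n_term) - at(rem_end)) +
    A[["terminal"]] * (at(t) - at(t - n_term))
  cost_cancer <- cp[["diagnosis"]] * dat(n_diag) +
    cp[["remission"]] * (dat(rem_end) - dat(n_diag)) +
    cp[["preterminal"]] * (dat(t - n_term) - dat(rem_end)) +
    cp[["terminal"]] * (dat(t) - dat(t - n_term)) +
    bgat(t) +
    direct * dat(n_diag)

  # other-cause deaths and survivors: diagnosis / remission / cured sequence
  ph_s <- dplyr::case_when(
    month <= d ~ "diagnosis",
    month <= cure ~ "remission",
    TRUE ~ "cured"
  )
  As <- unname(A[ph_s])
  Hs <- c(0, cumsum(As * B))
  haly_other <- Hs[t + 1]
  if (other_death_terminal_dw && params$dw_on) {
    haly_other <- haly_other + (A[["terminal"]] - As[t]) * B[t]
  }
  haly_surv <- Hs[n_months + 1]

  cps <- unname(cp[ph_s])
  Cs <- c(0, cumsum(cps * disc))
  cost_other <- Cs[t + 1] +
    bgat(t - 6) + (l6at(t) - l6at(t - 6)) + # final six months at end-of-life cost
    direct * dat(pmin(d, t))
  cost_surv <- Cs[n_months + 1] + bgat(n_months) + direct * dat(pmin(d, n_months))

  list(
    haly_cancer = haly_cancer, haly_other = haly_other, haly_surv = haly_surv,
    cost_cancer = cost_cancer, cost_other = cost_other, cost_surv = cost_surv
  )
}
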