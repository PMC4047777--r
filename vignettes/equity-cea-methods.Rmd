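---
title: "Methods: equity-aware Markov cost-utility modelling with equicea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity-aware Markov cost-utility modelling with equicea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicea)
library(dplyr)
```

## The problem

Cost-utility analyses routinely report a single expected gain per treated
case, yet the inputs behind that number — disease incidence, survival,
background mortality, comorbidity, costs — differ systematically between
population subgroups. `equicea` models a stylised cancer treatment (a
proportional reduction in excess cancer mortality) for two ethnic groups
(Māori and non-Māori, in a New Zealand-like setting) and makes the effect of
each layer of between-group heterogeneity explicit, so an analyst can see
exactly which parameter choices drive apparent differences in
cost-effectiveness between groups.

## Model structure

The core is a three-state Markov cohort model with a monthly cycle: alive
with cancer, death from the cancer, and death from other causes (both
absorbing). A cohort of incident cases enters at diagnosis, at the midpoint
age of its 5-year age band, and is followed until age 110. Each cycle
combines two hazards:

* the **excess mortality rate** attributable to the cancer, constant in time
  since diagnosis and exactly zero after the cancer's *statistical cure
  time* (72, 240, and 96 months for lung, breast, and colon cancer). The
  within-period hazard is held constant because the inputs are summary
  excess rates without a stated time-shape; the hazard sits behind a single
  interface in `run_cohort()` so a declining shape could be substituted.
* the **background all-cause mortality rate** at the attained single year of
  age and attained calendar year, taken from a life table projected forward
  with ethnicity-specific annual proportional declines (2.25 %/yr Māori,
  1.75 %/yr non-Māori) up to 2026 and frozen thereafter. We project by the
  cohort's *attained* calendar year (entry year 2006 plus elapsed months),
  not the diagnosis year; this is an assumption the inputs do not decide.

Annual rates are divided by 12 to monthly rates (rates are additive; the
engine works on the rate scale throughout). Within a cycle the two constant
hazards give a total exit probability $1 - e^{-(m_c + m_b)}$, allocated to
the causes in proportion to their rates — the standard cause-deletion split
(`competing_split()`). No half-cycle correction is applied: at a monthly
cycle length the correction is an order of magnitude below the reporting
precision, and it would complicate the retrospective valuation below.

The engine's output is an *absorption distribution*: for every month since
diagnosis, the probability of dying of the cancer and of other causes in
that month, plus the probability of being alive at the horizon. These sum to
one by construction (tested to 1e-10 over random parameter draws).

## Valuing outcomes: retrospective trajectories

Health and cost consequences are attached to each absorbing outcome by
retrospectively laying out the disease-phase sequence
(`build_trajectory()`):

* **cancer deaths** are end-anchored: the final month(s) are terminal, the
  pre-terminal phase sits before them, the diagnosis/treatment phase
  occupies the first months, and remission fills the gap. If death comes too
  early to fit every phase, the terminal phase takes precedence, then
  pre-terminal, then a truncated diagnosis phase.
* **other-cause deaths and survivors** pass through diagnosis, remission
  until the statistical cure time, then a cured phase. Other-cause deaths
  flag their final six months, which carry end-of-life costs instead of
  average background costs, and (configurably, on by default) the
  terminal-phase disability weight in the final month, representing the
  increased morbidity of dying that the average background weight misses.

A month of life in phase $p$ at attained age $a$ is worth

$$w = \frac{(1 - d_p)\,(1 - \mathrm{pYLD}_a)}{12}$$

HALYs, where $d_p$ is the phase's disability weight (zero once cured) and
$\mathrm{pYLD}_a$ the prevalent background morbidity of the person's
ethnicity, sex, and attained age band. The two components combine
**multiplicatively**: the prevalent-morbidity envelope defines the maximum
health a life-year can yield (e.g. $1 - 0.224 = 0.776$ for a pYLD of
0.224), and the cancer weight scales what remains. This is the key
modelling choice that a subtractive combination would get wrong near the
ends of the scale; it guarantees weights stay in $[0, 1]$ and that turning
either component on can only reduce HALYs (a tested dominance property).
Ages beyond the oldest band reuse the oldest band's pYLD and costs.

Costs accrue per month: the phase-specific cancer cost (zero once cured),
one twelfth of the average annual background health-system cost at the
attained age band (replaced by one sixth of the last-six-months cost in
flagged months), and the intervention's direct cost ($2,500/month by
default) during the diagnosis phase when the intervention arm is on. Both
HALYs and costs are discounted at 3 %/yr, attributed at month end with the
monthly factor $(1+r)^{-t/12}$.

The pipeline values every possible death month in one vectorised pass using
prefix sums over the discounted month weights (`value_outcomes()`), which
is algebraically identical to building and valuing each trajectory — a test
enforces exact agreement between the two routes — and makes a whole cohort
O(T) instead of O(T²).

## The intervention and reported metrics

The modelled treatment multiplies the monthly excess mortality rate by
$1 - \text{effect}$ (default effect 0.20) in **every** cycle with non-zero
excess mortality, i.e. from diagnosis to statistical cure; the effect is
defined on the excess rate itself, without restriction to the treatment
phase. Reported per reporting cell (cancer × model × ethnicity × age band):

* baseline and incremental expected HALYs per case,
* percent change of the incremental gain against Model 1,
* incremental cost per case and the ICER (incremental cost / incremental
  HALYs; flagged *dominant* when costs fall, *undefined* when the gain is
  non-positive),
* HALYs per 100,000 ethnic population — the per-case gain times annual
  incident cases divided by the group's total population × 100,000, so it is
  driven by incidence as well as per-case gain,
* Māori/non-Māori relative risks of gain, per case and per 100,000.

Strata are aggregated case-weightedly: within a cell, each (sex ×
deprivation) stratum contributes in proportion to its annual incident cases
(population share × deprivation distribution × incidence rate). Breast
cancer is modelled in women only. Rounding (HALYs 2 dp, percents 1 dp, RRs
2 dp, ICERs to the nearest 100) happens only in `format_table3()`; all
internal computation is at full precision.

## The heterogeneity ladder

`canonical_scenarios()` defines five models. Model 1 keeps only incidence
ethnic-specific — excess mortality and background mortality are set to the
reference group's values (including the reference group's projected
decline), and both morbidity adjustments are off. Models 2–5 add, one layer
at a time: ethnic-specific excess mortality, disability weights,
ethnic-specific background mortality (with its own decline), and the
ethnic-specific prevalent-morbidity envelope. The reference group defaults
to non-Māori but is configurable (`reference_ethnicity`), since
standard-population analyses may want a different standard. Substitution is
by matched stratum: a Māori stratum under a reference switch takes the
value of the non-Māori stratum with the same sex, age band, and deprivation
tertile. Resolution never alters reference-group strata, and under Model 5
it is the identity.

Two consequences are built into the arithmetic and tested: adding
disability weights or the envelope can only lower baseline HALYs (Model 3 ≤
Model 2, Model 5 ≤ Model 4, every cell), and giving the
higher-mortality group its own background mortality lowers its baseline
HALYs (Model 4 ≤ Model 3 for Māori whenever Māori background mortality
dominates, as the synthetic generator guarantees).

## The synthetic parameter generator

No registry inputs ship with the package; `generate_bundle()` emulates
their structure so the full pipeline is exercisable. Defaults (all stated
in `synthetic_config()` and chosen once):

* **Incidence** ratios Māori/non-Māori of 3.0 (lung), 1.17 (breast), 0.6
  (colon) at every matched stratum, on log-linear age curves anchored at age
  65–69 (non-Māori bases 0.0012, 0.0030, 0.0015 per person-year).
* **Excess mortality** ratios 1.5, 1.7, 1.35 on bases 0.45, 0.035, 0.090
  per year. The bases matter qualitatively: lung sits in a low-survival
  regime and breast/colon in high-survival regimes, which is what produces
  the characteristic reversal — a group with higher excess mortality gains
  *less* per case from a proportional rate reduction in a low-survival
  cancer but *more* in high-survival cancers. This reversal is an emergent
  property of the hazard arithmetic, not hard-coded, and is asserted on the
  default bundle in the acceptance tests.
* **Background mortality** is Gompertz (log-linear in age,
  $\log m = -10.5 + 0.097\,a$ for non-Māori women), with a Māori ratio of
  1.8 and male ratio 1.45, so Māori rates dominate at every age.
* **pYLD** is anchored at the value 0.224 for non-Māori women aged 70–74,
  rises 0.0052 per year of age, and is shifted up for men (+0.02) and Māori
  (+0.08) — higher at every age for Māori, non-decreasing in age.
* **Deprivation distributions** (Māori 0.15/0.25/0.60, non-Māori
  0.40/0.35/0.25 across NZDep tertiles 1–3/4–6/7–10) are assumptions: the
  real distributions are not published at this granularity. A 1.15/1.00/0.90
  deprivation gradient multiplies incidence and excess mortality.
* **Costs**: background annual costs grow log-linearly with age from $1,500;
  last-six-months costs start at $30,000 and decline slightly with age;
  per-phase cancer costs are in the thousands per month with the terminal
  phase most expensive.
* **Noise**: non-Māori stratum rates carry 2 % log-normal jitter; Māori
  rates are the matched non-Māori rate times the ethnic ratio with 0.3 %
  jitter, so embedded ratios are reproduced to a fraction of a percent and
  differ across seeds. Population counts are expected (real-valued) counts;
  rounding them would perturb sex shares and break exact symmetry
  diagnostics.

What the generator does **not** emulate: correlation between deprivation
and background mortality (the life table is not deprivation-stratified, by
design, matching the input interface), stage-at-diagnosis structure,
time-varying excess hazards, and any calibration to actual NZ statistics.
Passing tests on synthetic bundles therefore demonstrate the *mechanics*
and the qualitative comparative statics, not numerical agreement with any
published national analysis.

## Numerical and validation choices

* Rates, not probabilities, are the internal currency; conversion
  $p = 1 - e^{-m}$ happens once per cycle. Degenerate inputs (zero rates)
  give exact results (`p_alive = 1`), and both-zero competing rates split
  as (0, 0, 1).
* Problem sizes: a cohort entering at 52.5 runs 690 monthly cycles; the
  full reporting grid (3 cancers × 5 models × 2 ethnicities × 3 age bands,
  both arms, all sex/deprivation strata) is ~900 cohort runs and takes a
  few seconds. The scenario-dominance sweep uses 50 seeded bundles with
  baseline-only runs of Models 2–5.
* The engine is validated three ways: closed forms (cumulative cancer
  mortality $1 - e^{-mT}$ when background mortality is zero, to 1e-9), a
  fine-time-step two-hazard integration oracle for the cycle split (to
  1e-6), and an individual-level microsimulation of 100,000 people under
  identical hazards. For the microsimulation we compare cumulative
  cause-specific absorption at checkpoint horizons, survival at the
  horizon, and the expected-HALY mean, each within 3 standard errors.
  Checking every month × cause bin at 3 SE would fail by sheer multiplicity
  (~1,400 simultaneous comparisons) for a perfectly correct engine, so the
  checkpoint design keeps the stated tolerance while controlling the
  comparison count; a per-month check at a simultaneous level would be the
  alternative.
* Expected-value aggregation is validated against multinomial resampling
  of the absorption distribution (stochastic oracle, 3 SE).

## Known limitations

* Expected values only: no probabilistic sensitivity analysis; parameter
  uncertainty is out of scope (two-way deterministic sensitivity over
  direct cost and effect size is provided instead).
* The constant-in-time excess hazard and the single cure threshold are
  simplifications; real relative-survival curves decline with time since
  diagnosis.
* The morbidity adjustment for other-cause decedents (terminal weight in
  the final month) is a modelling convention — the inputs specify that
  end-of-life morbidity rises but not by how much; it is switchable.
* Per-100,000 results use the group's total population as denominator with
  age-band-specific cases, so they mix the band's incidence with the
  group's age structure — appropriate for population-priority comparisons,
  not for band-specific rates.
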