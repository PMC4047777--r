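lung_sched <- list(
  diagnosis_months = 5, preterminal_months = 5,
  terminal_months = 1, cure_months = 72
)

test_that("cancer-death trajectories are end-anchored", {
  # death at month 11 fits the full schedule: 5 diagnosis, 5 pre-terminal,
  # 1 terminal, no remission
  tr <- build_trajectory("cancer_death", 11, lung_sched, 120)
  expect_equal(tr$phase, c(rep("diagnosis", 5), rep("preterminal", 5), "terminal"))

  # later death inserts remission between diagnosis and pre-terminal
  tr2 <- build_trajectory("cancer_death", 20, lung_sched, 120)
  expect_equal(
    tr2$phase,
    c(rep("diagnosis", 5), rep("remission", 9), rep("preterminal", 5), "terminal")
  )

  # early death: terminal first, then pre-terminal, diagnosis squeezed out
  tr3 <- build_trajectory("cancer_death", 3, lung_sched, 120)
  expect_equal(tr3$phase, c("preterminal", "preterminal", "terminal"))

  # death at month 8: truncated diagnosis at the start
  tr4 <- build_trajectory("cancer_death", 8, lung_sched, 120)
  expect_equal(tr4$phase, c(rep("diagnosis", 2), rep("preterminal", 5), "terminal"))

  expect_error(build_trajectory("cancer_death", 130, lung_sched, 120), "total_months")
})

test_that("survivors pass through diagnosis, remission, and statistical cure", {
  tr <- build_trajectory("survivor", schedule = lung_sched, total_months = 100)
  expect_equal(tr$phase[1:5], rep("diagnosis", 5))
  expect_equal(unique(tr$phase[6:72]), "remission")
  expect_equal(unique(tr$phase[73:100]), "cured")
  expect_false(any(tr$last6))

  # other-cause deaths share the sequence but flag their final six months
  tr2 <- build_trajectory("other_death", 80, lung_sched, 100)
  expect_equal(which(tr2$last6), 75:80)
  expect_equal(unique(tr2$phase[73:80]), "cured")
  tr3 <- build_trajectory("other_death", 4, lung_sched, 100)
  expect_true(all(tr3$last6))
  expect_equal(tr3$phase, c(rep("diagnosis", 4)))
})

test_that("discounting compounds the annual rate monthly", {
  expect_equal(discount_factor(1:40, 0), rep(1, 40))
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-10)
  expect_equal(discount_factor(12, 0.03), 0.97087, tolerance = 1e-5)
  f <- discount_factor(1:120, 0.03)
  expect_true(all(diff(f) < 0))
})

test_that("health weights combine disability and the morbidity envelope multiplicatively", {
  # cured survivor year under the envelope alone
  expect_equal(haly_weight("cured", lung_dw, pyld = 0.224), 0.776)
  # both switches off: full health
  expect_equal(haly_weight("terminal", lung_dw, 0.3, dw_on = FALSE, pyld_on = FALSE), 1)
  # diagnosis-phase weight with the envelope off
  expect_equal(haly_weight("diagnosis", lung_dw, pyld_on = FALSE), 0.531)
  # multiplicative combination
  expect_equal(
    haly_weight("diagnosis", lung_dw, 0.2),
    (1 - 0.469) * (1 - 0.2)
  )
  expect_error(
    haly_weight("diagnosis", replace(lung_dw, "diagnosis", 1.2), 0),
    "\\[0, 1\\)"
  )
})

test_that("trajectory HALY valuation matches hand sums", {
  # a year lived in full health, undiscounted, is one HALY
  tr <- build_trajectory("survivor", schedule = lung_sched, total_months = 12)
  expect_equal(
    value_halys(tr, lung_dw, dw_on = FALSE, pyld_on = FALSE, discount_rate = 0),
    1.0
  )
  # lung cancer death at month 11 with phase weights on:
  # (5 x 0.531 + 5 x 0.461 + 1 x 0.452) / 12
  tr2 <- build_trajectory("cancer_death", 11, lung_sched, 120)
  expect_equal(
    value_halys(tr2, lung_dw, dw_on = TRUE, pyld_on = FALSE, discount_rate = 0),
    (5 * 0.531 + 5 * 0.461 + 1 * 0.452) / 12,
    tolerance = 1e-4
  )
  # discounting strictly reduces value
  expect_lt(
    value_halys(tr2, lung_dw, discount_rate = 0.03),
    value_halys(tr2, lung_dw, discount_rate = 0)
  )
})

test_that("morbidity adjustments never increase HALYs and valuation is additive", {
  set.seed(42)
  for (i in 1:20) {
    t_end <- sample(3:200, 1)
    outcome <- sample(c("cancer_death", "other_death"), 1)
    tr <- build_trajectory(outcome, t_end, lung_sched, 240)
    v_off <- value_halys(tr, lung_dw, dw_on = FALSE, pyld_on = FALSE)
    v_dw <- value_halys(tr, lung_dw, dw_on = TRUE, pyld_on = FALSE)
    v_py <- value_halys(tr, lung_dw, pyld_band = 0.2, dw_on = FALSE, pyld_on = TRUE)
    expect_lte(v_dw, v_off)
    expect_lte(v_py, v_off)
    expect_gte(v_dw, 0)
    # never more than lived months / 12
    expect_lte(v_off, t_end / 12 + 1e-12)
  }
  # additivity over disjoint month ranges (survivor split at the cure point)
  tr <- build_trajectory("survivor", schedule = lung_sched, total_months = 100)
  v_all <- value_halys(tr, lung_dw, discount_rate = 0.03)
  v_a <- value_halys(tr[1:72, ], lung_dw, discount_rate = 0.03)
  v_b <- value_halys(tr[73:100, ], lung_dw, discount_rate = 0.03)
  expect_equal(v_all, v_a + v_b, tolerance = 1e-12)
})

test_that("cost valuation accrues phase, background, end-of-life, and direct costs", {
  # zero cost tables, intervention on: 5 diagnosis months x $2,500
  tr <- build_trajectory("survivor", schedule = lung_sched, total_months = 100)
  expect_equal(
    value_costs(tr, intervention_on = TRUE, direct_monthly_cost = 2500),
    5 * 2500
  )
  expect_equal(value_costs(tr, intervention_on = FALSE, direct_monthly_cost = 2500), 0)

  # background cost accrues per month lived; last-six-months substitution
  tr2 <- build_trajectory("other_death", 50, lung_sched, 100)
  got <- value_costs(tr2, bg_cost_band = 1200, last6_cost_band = 30000)
  expect_equal(got, 44 * 1200 / 12 + 6 * 30000 / 6)

  # phase costs weight the months spent in each phase
  pc <- c(diagnosis = 1000, preterminal = 500, terminal = 2000, remission = 10)
  tr3 <- build_trajectory("cancer_death", 11, lung_sched, 120)
  expect_equal(
    value_costs(tr3, phase_cost = pc),
    5 * 1000 + 5 * 500 + 1 * 2000
  )

  # a survivor living longer accrues more background cost
  tr_short <- build_trajectory("survivor", schedule = lung_sched, total_months = 60)
  tr_long <- build_trajectory("survivor", schedule = lung_sched, total_months = 90)
  expect_gt(
    value_costs(tr_long, bg_cost_band = 1200),
    value_costs(tr_short, bg_cost_band = 1200)
  )
})

test_that("the vectorised all-outcome valuation agrees with per-trajectory valuation", {
  bands <- age_bands()
  p <- make_test_params(
    excess_annual = 0.3, bg_annual = 0.02,
    pyld = 0.25, pyld_on = TRUE,
    bg_cost = 1500, last6_cost = 28000,
    phase_cost = c(diagnosis = 4000, preterminal = 2000, terminal = 8000, remission = 150),
    discount_rate = 0.03
  )
  # age-varying tables to exercise the band lookups
  p$pyld_band <- setNames(seq(0.1, 0.4, length.out = length(bands)), bands)
  p$bg_cost_band <- setNames(seq(1000, 9000, length.out = length(bands)), bands)
  p$last6_cost_band <- setNames(seq(30000, 24000, length.out = length(bands)), bands)

  start_age <- 67.5
  n_months <- 300
  vo <- value_outcomes(p, n_months, start_age, intervention_on = TRUE)

  for (t in c(1, 2, 3, 5, 8, 11, 12, 40, 73, 150, 300)) {
    tr_c <- build_trajectory("cancer_death", t, p$phases, n_months, start_age)
    tr_o <- build_trajectory("other_death", t, p$phases, n_months, start_age)
    expect_equal(
      vo$haly_cancer[t],
      value_halys(tr_c, p$dw,
        pyld_band = p$pyld_band, dw_on = TRUE, pyld_on = TRUE,
        discount_rate = 0.03
      ),
      tolerance = 1e-12, info = paste("cancer HALY, t =", t)
    )
    expect_equal(
      vo$haly_other[t],
      value_halys(tr_o, p$dw,
        pyld_band = p$pyld_band, dw_on = TRUE, pyld_on = TRUE,
        discount_rate = 0.03
      ),
      tolerance = 1e-12, info = paste("other HALY, t =", t)
    )
    expect_equal(
      vo$cost_cancer[t],
      value_costs(tr_c, p$bg_cost_band, p$last6_cost_band, p$phase_cost,
        intervention_on = TRUE, direct_monthly_cost = 2500, discount_rate = 0.03
      ),
      tolerance = 1e-9, info = paste("cancer cost, t =", t)
    )
    expect_equal(
      vo$cost_other[t],
      value_costs(tr_o, p$bg_cost_band, p$last6_cost_band, p$phase_cost,
        intervention_on = TRUE, direct_monthly_cost = 2500, discount_rate = 0.03
      ),
      tolerance = 1e-9, info = paste("other cost, t =", t)
    )
  }
  tr_s <- build_trajectory("survivor", schedule = p$phases, total_months = n_months, start_age = start_age)
  expect_equal(
    vo$haly_surv,
    value_halys(tr_s, p$dw,
      pyld_band = p$pyld_band, dw_on = TRUE, pyld_on = TRUE,
      discount_rate = 0.03
    ),
    tolerance = 1e-12
  )
  expect_equal(
    vo$cost_surv,
    value_costs(tr_s, p$bg_cost_band, p$last6_cost_band, p$phase_cost,
      intervention_on = TRUE, direct_monthly_cost = 2500, discount_rate = 0.03
    ),
    tolerance = 1e-9
  )
})
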