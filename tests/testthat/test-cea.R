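test_that("expected values are probability-weighted sums over outcomes", {
  p <- make_test_params(excess_annual = 0.3, bg_annual = 0.03)
  ad <- run_cohort(p)
  vo <- value_outcomes(p, ad$n_months, 67.5)

  # point mass on one outcome returns that outcome's value
  ad1 <- ad
  ad1$months$p_cancer_death[] <- 0
  ad1$months$p_other_death[] <- 0
  ad1$months$p_cancer_death[24] <- 1
  ad1$p_alive <- 0
  expect_equal(expected_value(ad1, vo)$halys, vo$haly_cancer[24])

  # two outcomes at probability 1/2 each average
  ad2 <- ad1
  ad2$months$p_cancer_death[24] <- 0.5
  ad2$months$p_other_death[100] <- 0.5
  expect_equal(
    expected_value(ad2, vo)$halys,
    (vo$haly_cancer[24] + vo$haly_other[100]) / 2
  )

  # a coverage gap is an error
  vo_bad <- vo
  vo_bad$haly_cancer <- vo_bad$haly_cancer[-1]
  expect_error(expected_value(ad, vo_bad), "coverage gap")

  # stochastic oracle: multinomial resampling of the absorption distribution
  probs <- c(ad$months$p_cancer_death, ad$months$p_other_death, ad$p_alive)
  vals <- c(vo$haly_cancer, vo$haly_other, vo$haly_surv)
  set.seed(11)
  n <- 200000
  draws <- as.vector(rmultinom(1, n, probs))
  mc_mean <- sum(draws * vals) / n
  mc_se <- sqrt((sum(probs * vals^2) - sum(probs * vals)^2) / n)
  expect_lt(abs(expected_value(ad, vo)$halys - mc_mean), 3 * mc_se)
})

test_that("deprivation aggregation weights cases by share and incidence", {
  vals <- tibble::tibble(
    deprivation = deprivation_tertiles(),
    halys = c(1.0, 0.9, 0.8)
  )
  w <- tibble::tibble(deprivation = deprivation_tertiles(), weight = c(0.2, 0.3, 0.5))
  inc <- tibble::tibble(deprivation = deprivation_tertiles(), rate = c(0.001, 0.002, 0.004))

  # identical values are unchanged
  same <- dplyr::mutate(vals, halys = 0.7)
  expect_equal(aggregate_deprivation(same, w, inc)$halys, 0.7)

  # degenerate weight picks out one tertile
  w1 <- tibble::tibble(deprivation = deprivation_tertiles(), weight = c(0, 1, 0))
  expect_equal(aggregate_deprivation(vals, w1)$halys, 0.9)

  # hand-computed case-weighted mean
  cw <- w$weight * inc$rate
  cw <- cw / sum(cw)
  expect_equal(
    aggregate_deprivation(vals, w, inc)$halys,
    sum(vals$halys * cw),
    tolerance = 1e-12
  )
  expect_error(
    aggregate_deprivation(vals, dplyr::mutate(w, weight = weight * 0.9)),
    "sum to 1"
  )
})

test_that("per-100k scaling is the incidence rate times the per-case gain", {
  expect_equal(per_100k(1.0, 100, 1e5), 100)
  expect_equal(per_100k(0.5, 0, 1e5), 0)
  # algebraic identity: per-case x (cases / pop x 1e5)
  per_case <- 0.37
  cases <- 412
  pop <- 3.2e6
  expect_equal(
    per_100k(per_case, cases, pop),
    per_case * (cases / pop * 1e5),
    tolerance = 1e-12
  )
  expect_error(per_100k(1, 10, 0), "positive")
})

test_that("percent change and relative risk recover reported derived cells", {
  expect_equal(round(pct_change(0.81, 0.89), 1), -9.0)
  expect_equal(round(pct_change(0.96, 0.75), 1), 28.0)
  expect_equal(pct_change(0.5, 0.5), 0)
  expect_true(is.na(pct_change(1, 0)))

  expect_equal(round(rr(1.01, 0.85), 2), 1.19)
  expect_equal(round(rr(114, 159), 2), 0.72)
  expect_equal(rr(0.4, 0.4), 1)
  expect_true(is.na(rr(1, 0)))
})

test_that("ICERs are ratios with dominance flags", {
  out <- compute_icer(4000, 0.2)
  expect_equal(out$icer, 20000)
  expect_equal(out$status, "ok")
  out2 <- compute_icer(1000, 0)
  expect_true(is.na(out2$icer))
  expect_equal(out2$status, "undefined")
  out3 <- compute_icer(-1000, 0.5)
  expect_equal(out3$icer, -2000)
  expect_equal(out3$status, "dominant")
})

test_that("equal deprivation distributions equalise Model 1 per-case values", {
  cfg <- synthetic_config(
    jitter_sd = 0, ratio_jitter_sd = 0,
    dep_weights = list(
      maori = c(dep1_3 = 1 / 3, dep4_6 = 1 / 3, dep7_10 = 1 / 3),
      non_maori = c(dep1_3 = 1 / 3, dep4_6 = 1 / 3, dep7_10 = 1 / 3)
    )
  )
  b <- generate_bundle(seed = 3, config = cfg)
  res <- run_model_grid(b, cancers = "lung", models = 1L, bands = "65-69")
  r <- res$results
  expect_equal(
    r$baseline_haly_per_case[r$ethnicity == "maori"],
    r$baseline_haly_per_case[r$ethnicity == "non_maori"],
    tolerance = 1e-9
  )
  expect_equal(
    r$inc_haly_per_case[r$ethnicity == "maori"],
    r$inc_haly_per_case[r$ethnicity == "non_maori"],
    tolerance = 1e-9
  )
})

test_that("the model grid carries the per-100k identity and scenario dominance", {
  b <- default_bundle()
  res <- run_model_grid(b, cancers = "lung", bands = c("65-69", "80-84"))
  r <- res$results

  # exact identity: per-100k equals incidence per 100k times per-case gain
  expect_equal(
    r$haly_per_100k,
    r$inc_haly_per_case * r$cases / r$population * 1e5,
    tolerance = 1e-12
  )
  # under Model 1 the per-100k RR is the incidence-rate ratio scaled by the
  # (deprivation-driven) per-case ratio
  m1 <- r[r$model_id == 1, ]
  by_band <- split(m1, m1$age_band)
  for (bb in by_band) {
    inc_rr <- (bb$cases[bb$ethnicity == "maori"] / bb$population[bb$ethnicity == "maori"]) /
      (bb$cases[bb$ethnicity == "non_maori"] / bb$population[bb$ethnicity == "non_maori"])
    expect_equal(
      bb$rr_per_100k[1],
      inc_rr * bb$rr_per_case[1],
      tolerance = 1e-9
    )
  }

  # adding disability weights can only lower baseline HALYs (Model 3 vs 2)
  wide <- tidyr::pivot_wider(
    r[, c("model_id", "ethnicity", "age_band", "baseline_haly_per_case")],
    names_from = "model_id", values_from = "baseline_haly_per_case",
    names_prefix = "m"
  )
  expect_true(all(wide$m3 <= wide$m2 + 1e-12))
  expect_true(all(wide$m5 <= wide$m4 + 1e-12))

  # incremental gains are non-negative under a beneficial intervention
  expect_true(all(r$inc_haly_per_case >= 0))
  # percent change of Model 1 against itself is zero
  expect_equal(r$pct_change_vs_model1[r$model_id == 1], rep(0, 4))
})

test_that("sensitivity grids are monotone in cost and effect", {
  b <- default_bundle()
  sens <- sensitivity_grid(b,
    cancer = "lung",
    direct_costs = c(1250, 2500, 5000),
    effects = c(0, 0.2, 0.4), model = 5L, band = "65-69"
  )
  expect_equal(nrow(sens), 2 * 9)
  # zero effect: undefined ICER, flagged not fatal
  expect_true(all(sens$icer_status[sens$effect == 0] == "undefined"))
  ok <- sens[sens$effect > 0, ]
  for (eth in ethnicities()) {
    for (e in unique(ok$effect)) {
      icers <- ok$icer[ok$ethnicity == eth & ok$effect == e][order(ok$direct_cost[ok$ethnicity == eth & ok$effect == e])]
      expect_true(all(diff(icers) > 0)) # dearer intervention, higher ICER
    }
    for (d in unique(ok$direct_cost)) {
      icers <- ok$icer[ok$ethnicity == eth & ok$direct_cost == d][order(ok$effect[ok$ethnicity == eth & ok$direct_cost == d])]
      expect_true(all(diff(icers) < 0)) # stronger effect, lower ICER
    }
  }

  # doubling the direct cost doubles the intervention-cost component when
  # all other costs are zero
  cfg0 <- synthetic_config(
    bg_cost_base = 0, last6_cost_base = 0, last6_cost_slope = 0,
    phase_cost = list(
      lung = c(diagnosis = 0, preterminal = 0, terminal = 0, remission = 0),
      breast = c(diagnosis = 0, preterminal = 0, terminal = 0, remission = 0),
      colon = c(diagnosis = 0, preterminal = 0, terminal = 0, remission = 0)
    )
  )
  b0 <- generate_bundle(seed = 5, config = cfg0)
  s0 <- sensitivity_grid(b0,
    cancer = "lung", direct_costs = c(2500, 5000),
    effects = 0.2, model = 5L, band = "65-69"
  )
  for (eth in ethnicities()) {
    cc <- s0[s0$ethnicity == eth, ]
    expect_equal(
      cc$inc_cost_per_case[cc$direct_cost == 5000],
      2 * cc$inc_cost_per_case[cc$direct_cost == 2500],
      tolerance = 1e-9
    )
  }
})
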