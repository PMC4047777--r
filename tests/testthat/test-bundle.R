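test_that("a generated bundle validates cleanly and violations are caught", {
  b <- default_bundle()
  expect_s3_class(validate_bundle(b), "bundle_validation")
  expect_equal(nrow(validate_bundle(b)), 0L)

  # out-of-range disability weight is reported with its phase
  b2 <- b
  b2$disability_weights$weight[
    b2$disability_weights$cancer == "lung" &
      b2$disability_weights$phase == "terminal"
  ] <- 1.2
  v <- validate_bundle(b2)
  expect_true(any(v$table == "disability_weights" & grepl("terminal", v$key)))

  # deprivation weights that do not sum to 1
  b3 <- b
  b3$deprivation_weights$weight[1] <- b3$deprivation_weights$weight[1] - 0.1
  v3 <- validate_bundle(b3)
  expect_true(any(v3$table == "deprivation_weights"))

  # incomplete stratum grid
  b4 <- b
  b4$incidence <- b4$incidence[-1, ]
  v4 <- validate_bundle(b4)
  expect_true(any(v4$table == "incidence" & v4$issue == "incomplete stratum grid"))
})

test_that("reference-group switches substitute the matching non-Maori values", {
  b <- default_bundle()
  sc <- canonical_scenarios()
  st_m <- list(
    ethnicity = "maori", sex = "female",
    age_band = "65-69", deprivation = "dep7_10"
  )
  st_nm <- st_m
  st_nm$ethnicity <- "non_maori"

  p1_m <- resolve_effective_params(b, sc[1, ], "lung", st_m)
  p1_nm <- resolve_effective_params(b, sc[1, ], "lung", st_nm)
  # Model 1: Maori stratum carries the matching non-Maori excess mortality
  expect_equal(p1_m$excess_annual, p1_nm$excess_annual)
  # ... and the non-Maori background mortality including its decline
  expect_equal(p1_m$bg_ethnicity, "non_maori")
  expect_equal(p1_m$bg_decline, 0.0175)
  # morbidity switched off entirely
  expect_true(all(p1_m$dw == 0))
  expect_true(all(p1_m$pyld_band == 0))
  # incidence stays ethnic-specific
  expect_false(isTRUE(all.equal(p1_m$incidence_rate, p1_nm$incidence_rate)))

  # Model 2: ethnic-specific survival but still the reference decline
  p2_m <- resolve_effective_params(b, sc[2, ], "lung", st_m)
  expect_equal(p2_m$bg_decline, 0.0175)
  expect_gt(p2_m$excess_annual, p1_m$excess_annual)

  # Model 4: own background mortality and own (faster) decline
  p4_m <- resolve_effective_params(b, sc[4, ], "lung", st_m)
  expect_equal(p4_m$bg_ethnicity, "maori")
  expect_equal(p4_m$bg_decline, 0.0225)
})

test_that("Model 5 resolution is the identity and resolution is deterministic", {
  b <- default_bundle()
  sc5 <- canonical_scenarios()[5, ]
  st <- list(
    ethnicity = "maori", sex = "male",
    age_band = "50-54", deprivation = "dep1_3"
  )
  p <- resolve_effective_params(b, sc5, "colon", st)
  expect_identical(
    p$excess_annual,
    b$excess_mortality$rate[
      b$excess_mortality$cancer == "colon" &
        b$excess_mortality$ethnicity == "maori" &
        b$excess_mortality$sex == "male" &
        b$excess_mortality$age_band == "50-54" &
        b$excess_mortality$deprivation == "dep1_3"
    ]
  )
  expect_identical(
    unname(p$dw[c("diagnosis", "preterminal", "terminal", "remission")]),
    b$disability_weights$weight[b$disability_weights$cancer == "colon"][
      match(
        c("diagnosis", "preterminal", "terminal", "remission"),
        b$disability_weights$phase[b$disability_weights$cancer == "colon"]
      )
    ]
  )
  expect_identical(
    unname(p$pyld_band),
    b$pyld$value[b$pyld$ethnicity == "maori" & b$pyld$sex == "male"][
      match(age_bands(), b$pyld$age_band[b$pyld$ethnicity == "maori" & b$pyld$sex == "male"])
    ]
  )
  # deterministic: resolving twice gives identical output
  expect_identical(p, resolve_effective_params(b, sc5, "colon", st))
})

test_that("non-Maori strata resolve identically under every scenario", {
  b <- default_bundle()
  sc <- canonical_scenarios()
  st <- list(
    ethnicity = "non_maori", sex = "female",
    age_band = "80-84", deprivation = "dep4_6"
  )
  p5 <- resolve_effective_params(b, sc[5, ], "lung", st)
  for (i in 1:4) {
    pi <- resolve_effective_params(b, sc[i, ], "lung", st)
    expect_equal(pi$excess_annual, p5$excess_annual)
    expect_equal(pi$bg_ethnicity, p5$bg_ethnicity)
    expect_equal(pi$bg_decline, p5$bg_decline)
  }
})

test_that("a missing stratum raises an error naming the table and key", {
  b <- default_bundle()
  b$excess_mortality <- b$excess_mortality |>
    dplyr::filter(!(
      cancer == "lung" & ethnicity == "maori" &
        sex == "female" & age_band == "65-69" &
        deprivation == "dep7_10"
    ))
  st <- list(
    ethnicity = "maori", sex = "female",
    age_band = "65-69", deprivation = "dep7_10"
  )
  expect_error(
    resolve_effective_params(b, canonical_scenarios()[5, ], "lung", st),
    "excess_mortality.*maori.*65-69"
  )
})

test_that("bundles round-trip through disk", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(nrow(validate_bundle(b2)), 0L)
  expect_equal(b2$incidence$rate, b$incidence$rate, tolerance = 1e-12)
  expect_equal(b2$life_table$declines, b$life_table$declines)
  expect_equal(b2$intervention$effect, b$intervention$effect)
  expect_equal(
    dplyr::arrange(b2$phases, cancer),
    dplyr::arrange(b$phases, cancer),
    ignore_attr = TRUE
  )
  expect_error(read_bundle(withr::local_tempdir()), "missing file")
})
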