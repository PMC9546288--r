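test_that("fractional reductions match the worked-example fluxes", {
  expect_equal(round(fraction_flux_reduction(1.3e-2, 4.6e-5), 3), 0.996)
  expect_equal(fraction_volume_reduction(1.6, 0.2), 0.875)
  expect_equal(fraction_volume_reduction(2.0, 0.5), 0.75)
  expect_equal(fraction_flux_reduction(3, 3), 0)
  expect_equal(fraction_flux_reduction(3, 0), 1)
  expect_equal(fraction_flux_reduction(0, 0), 0)  # convention
  expect_error(fraction_flux_reduction(1, 2), "exceeds")
  expect_error(fraction_volume_reduction(-1, 0), ">= 0")
})

test_that("the dilution equation reproduces the worked example within rounding", {
  pec <- pec_unmitigated(1.3e-2, 1.6, 1.3, 19.9)
  # printed inputs are rounded; the printed result is 1.61 ug/L
  expect_equal(pec, 1.61, tolerance = 0.05)
  # independent arithmetic oracle with n = 10
  oracle <- 1000 * (1.3e-2 / 10 * 0.208) /
    (0.2 / 24 + 0.1 * 1.3 / 24 + 1.6 / 10)
  expect_equal(pec, oracle, tolerance = 1e-12)
  expect_equal(pec_unmitigated(0, 1.6, 1.3, 19.9), 0)
  # runoff-dominated limit: PEC -> 1000 * fa * RFLX / RUNF
  big <- pec_unmitigated(1.3e-2, 1e6, 1.3, 19.9)
  expect_equal(big, 1000 * 0.208 * 1.3e-2 / 1e6, tolerance = 1e-4)
  expect_error(pec_unmitigated(1e-2, 0, 0, 19.9, scenario_config(basf = 0)),
               "denominator")
})

test_that("the catchment correction reproduces the downstream worked value", {
  fr <- fraction_flux_reduction(1.3e-2, 4.6e-5)
  fv <- fraction_volume_reduction(1.6, 0.2)
  # chained from the printed PEC 1.61: paper-internal value 6.82e-3
  expect_equal(pec_mitigated(1.61, fr, fv), 6.82e-3, tolerance = 0.15)
  expect_equal(pec_mitigated(2.5, 0, 0), 2.5)   # no-mitigation identity
  expect_equal(pec_mitigated(2.5, 1, 0.5), 0)   # total mass removal
  expect_error(pec_mitigated(1, 0.5, 1, scenario_config(fa = 1)), "< 1")
  expect_error(pec_mitigated(1, 1.2, 0.5), "0, 1")
})

test_that("equal mass and water reduction over a fully treated catchment leaves PEC unchanged", {
  cfg <- scenario_config(fa = 1)
  withr::with_seed(2, {
    for (f in runif(20, 0, 0.99)) {
      expect_equal(pec_mitigated(1.7, f, f, cfg), 1.7, tolerance = 1e-12)
    }
  })
})

test_that("mitigated PEC decreases in fr and increases in fv", {
  frs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pec_mitigated(rep(2, length(frs)), frs, 0.5)) <= 0))
  fvs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pec_mitigated(rep(2, length(fvs)), 0.5, fvs)) >= 0))
})

test_that("day-wise series application matches a brute-force evaluation", {
  nomiti <- tibble::tibble(
    date = as.Date("1984-05-01") + c(0, 3, 5, 9),
    rflx_mg_m2_d = c(2.2e-2, 0, 1.3e-2, 4e-3),
    runf_L_m2_d = c(2.5, 0, 1.6, 0.8),
    infl_L_m2_d = c(1.3, 1.3, 1.3, 1.3),
    precip_mm = c(28, 1, 19.9, 9)
  )
  miti <- nomiti
  miti$rflx_mg_m2_d <- c(5e-4, 0, 4.6e-5, 3.9e-3)
  miti$runf_L_m2_d <- c(0.9, 0, 0.2, 0.75)
  ser <- pec_mitigation(nomiti, miti)
  expect_s3_class(ser, "pec_series")
  # brute-force day-wise oracle over the runoff days
  for (i in c(1, 3, 4)) {
    fr <- (nomiti$rflx_mg_m2_d[i] - miti$rflx_mg_m2_d[i]) / nomiti$rflx_mg_m2_d[i]
    fv <- (nomiti$runf_L_m2_d[i] - miti$runf_L_m2_d[i]) / nomiti$runf_L_m2_d[i]
    n <- min(24, ceiling(nomiti$precip_mm[i] / 2))
    pec <- 1000 * (nomiti$rflx_mg_m2_d[i] / n * 0.208) /
      (0.2 / 24 + 0.1 * 1.3 / 24 + nomiti$runf_L_m2_d[i] / n)
    expect_equal(ser$pec_nomiti_ug_l[ser$date == nomiti$date[i]], pec)
    expect_equal(ser$pec_mitigated_ug_l[ser$date == nomiti$date[i]],
                 pec * (1 - fr) / (1 - 0.208 * fv))
  }
  # dry day carries zero from this pathway
  expect_equal(ser$pec_nomiti_ug_l[2], 0)
  # the mitigated maximum may fall on a different day than the unmitigated one
  mx <- pec_max(ser)
  expect_equal(mx$date_nomiti, nomiti$date[1])
  expect_equal(mx$date, nomiti$date[4])  # barely-reduced flux day wins
  expect_gt(mx$pec_nomiti_ug_l, mx$pec_mitigated_ug_l)
})

test_that("a series without runoff days signals an empty maximum", {
  dry <- tibble::tibble(date = as.Date("1984-05-01") + 0:1,
                        rflx_mg_m2_d = 0, runf_L_m2_d = 0,
                        infl_L_m2_d = 1.3, precip_mm = c(1, 0.5))
  ser <- pec_mitigation(dry, dry)
  expect_equal(nrow(pec_max(ser)), 0)
  # single runoff day: that day is the maximum
  one <- dry
  one$runf_L_m2_d[1] <- 1
  one$rflx_mg_m2_d[1] <- 1e-3
  ser1 <- pec_mitigation(one, dry)
  expect_equal(pec_max(ser1)$date, one$date[1])
})

test_that("scenario constants are validated", {
  expect_error(scenario_config(fa = 0), "0, 1")
  expect_error(scenario_config(basf = -1), ">= 0")
  expect_error(scenario_config(raindr = 1.5), "0, 1")
  cfg <- scenario_config()
  expect_equal(c(cfg$fa, cfg$basf, cfg$raindr), c(0.208, 0.2, 0.1))
})
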