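test_that("miscarriage correction rounds once per factor age group", {
  sus <- make_counts(c(23912, 59488, 41319, 9335))
  corr <- apply_miscarriage(sus)
  cells <- tibble::as_tibble(corr)
  expect_equal(cells$count[match(miscarriage_bands, cells$age_band)],
               c(75060, 35121, 7001))
  expect_equal(counts_total(corr), 117182)

  supp <- make_counts(c(669, 6696, 11181, 2210))
  corr_supp <- apply_miscarriage(supp)
  cells <- tibble::as_tibble(corr_supp)
  # 7,365 * 0.9 = 6,628.5 rounds up only when the under-30 group is
  # aggregated before rounding
  expect_equal(cells$count[match(miscarriage_bands, cells$age_band)],
               c(6629, 9504, 1658))
  expect_equal(counts_total(corr_supp), 17791)
})

test_that("unit factors are the identity and corrections are monotone in each factor", {
  tab <- make_counts(c(100, 200, 300, 400))
  ident <- apply_miscarriage(tab, miscarriage_factors(
    c("10-19" = 1, "20-29" = 1, "30-39" = 1, "40-49" = 1)))
  expect_equal(counts_total(ident), counts_total(tab))
  withr::with_seed(31, {
    for (i in 1:5) {
      f1 <- stats::runif(3, 0.3, 0.9)
      f2 <- pmin(f1 + 0.05, 1)
      mk <- function(f) miscarriage_factors(
        c("10-19" = f[1], "20-29" = f[1], "30-39" = f[2], "40-49" = f[3]))
      lo <- apply_miscarriage(tab, mk(f1))
      hi <- apply_miscarriage(tab, mk(f2))
      expect_true(all(tibble::as_tibble(lo)$count <=
                        tibble::as_tibble(hi)$count))
      expect_true(all(tibble::as_tibble(lo)$count <=
                        c(300, 300, 400)))
    }
  })
})

test_that("misconfigured miscarriage factors fail loudly", {
  tab <- make_counts(c(1, 2, 3, 4))
  expect_error(apply_miscarriage(tab, c("10-29" = 0.9, "30-39" = 0.85)),
               "40-49")
  expect_error(miscarriage_factors(c("10-29" = 0, "30-39" = 0.85,
                                     "40-49" = 0.75)),
               "\\(0, 1\\]")
  expect_error(apply_miscarriage(tab, miscarriage_factors(
    c("10-19" = 0.8, "20-29" = 0.9, "30-39" = 0.85, "40-49" = 0.75))),
    "single value")
})

test_that("survey-age restriction counts public ages directly and splits the private 15-19 band", {
  ans_fine <- counts_table(tibble::tibble(
    region = "R1", age_band = c("15-19", "20-24", "25-29", "30-34", "35-39"),
    count = c(100, 50, 50, 40, 40)))
  sus <- dplyr::bind_rows(
    sus_record(age = 17, diag1 = "O03"),   # below survey ages
    sus_record(age = 18, diag1 = "O03"),
    sus_record(age = 35, diag1 = "O05"),
    sus_record(age = 45, diag1 = "O05"),   # above survey ages
    sus_record(age = 25, diag1 = "Z349"))  # not an abortion admission
  out <- restrict_to_survey_ages(sus, ans_fine, share_18_19 = 0)
  # ANS: 0.9 * (0 + 100) + 0.85 * 80 = 158
  expect_equal(out$hosp_supp_18_39, 158)
  expect_equal(out$hosp_sus_18_39, round_half_up(0.9 * 1 + 0.85 * 1))
  full_share <- restrict_to_survey_ages(sus, ans_fine, share_18_19 = 1)
  expect_equal(full_share$hosp_supp_18_39, 158 + 90)
  # share irrelevant when the 15-19 band is empty
  no_teen <- counts_table(tibble::tibble(
    region = "R1", age_band = c("20-24", "25-29"), count = c(10, 10)))
  expect_equal(restrict_to_survey_ages(sus, no_teen, share_18_19 = 1),
               restrict_to_survey_ages(sus, no_teen, share_18_19 = 0))
  coarse <- make_counts(c(1, 2, 3, 4))
  expect_error(restrict_to_survey_ages(sus, coarse), "fine")
})

test_that("scenario engine reproduces the pooled, sector and constrained factors", {
  hosp <- list(sus = 103623, supp = 15963)
  pooled <- run_scenario(scenario_spec("pooled"), hosp$sus, hosp$supp)
  expect_equal(pooled$factor_total, 4.2)

  sector <- run_scenario(scenario_spec("sector"), hosp$sus, hosp$supp)
  expect_equal(sector$est_sus, 371208)
  expect_equal(sector$est_supp, 128803)
  expect_equal(sector$factor_sus, 3.6)
  expect_equal(sector$factor_supp, 8.1)

  half <- run_scenario(scenario_spec("constrained", freq_ratio = 0.5),
                       hosp$sus, hosp$supp)
  expect_equal(round_half_up(100 * half$freq_sus, 2), 1.56)
  expect_equal(half$factor_supp, 4.7)
  expect_equal(half$est_sus + half$est_supp, 503000)
})

test_that("constrained calibration with ratio 1 collapses to the sector mode at the implied frequency", {
  spec_k1 <- scenario_spec("constrained", freq_ratio = 1)
  f <- 503000 / (spec_k1$pop_sus + spec_k1$pop_supp)
  spec_sector <- scenario_spec("sector", freq_sus = f, freq_supp = f)
  a <- run_scenario(spec_k1, 103623, 15963)
  b <- run_scenario(spec_sector, 103623, 15963)
  expect_equal(a$factor_sus, b$factor_sus)
  expect_equal(a$factor_supp, b$factor_supp)
  expect_equal(a$est_sus, b$est_sus)
})

test_that("the pooled factor lies between the sector factors of any same-input scenario", {
  withr::with_seed(41, {
    for (i in 1:8) {
      hs <- sample(50000:150000, 1)
      hp <- sample(5000:30000, 1)
      pooled <- run_scenario(scenario_spec("pooled"), hs, hp)
      for (k in c(0.5, 0.75, 0.9, 1)) {
        sc <- run_scenario(scenario_spec("constrained", freq_ratio = k),
                           hs, hp)
        expect_gte(pooled$factor_total, min(sc$factor_sus, sc$factor_supp))
        expect_lte(pooled$factor_total, max(sc$factor_sus, sc$factor_supp))
      }
    }
  })
})

test_that("zero hospitalizations against a nonzero estimate is an undefined factor", {
  expect_error(run_scenario(scenario_spec("sector"), 0, 15963),
               "undefined correction factor")
  pooled_zero <- expect_error(
    run_scenario(scenario_spec("pooled"), 0, 0), "undefined")
})

test_that("the canonical scenario suite matches the published factor columns", {
  st <- scenario_suite(hosp_sus_18_39 = 103623, hosp_supp_18_39 = 15963)
  expect_equal(nrow(st), 5)
  expect_equal(st$factor_sus, c(NA, 3.6, 4.1, 3.9, 3.7))
  expect_equal(st$factor_supp, c(NA, 8.1, 4.7, 6.5, 7.5))
  expect_equal(st$factor_total, c(4.2, NA, NA, NA, NA))
  one <- scenario_suite(list(scenario_spec("pooled")), 103623, 15963)
  expect_equal(nrow(one), 1)
})
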