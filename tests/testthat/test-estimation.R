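test_that("the estimation equation scales corrected counts by the factor and its bounds", {
  sus <- estimate_abortions(117182, 4)
  expect_equal(unname(sus), c(468728, 351546, 585910))
  supp <- estimate_abortions(17791, 5)
  expect_equal(unname(supp), c(88955, 71164, 106746))
  expect_equal(unname(estimate_abortions(1000, 0, 0, 0)), c(0, 0, 0))
  expect_error(estimate_abortions(100, 2, 3, 4))
})

test_that("sector denominators split by band coverage and add back to the total", {
  m <- brazil_margins_2015()
  pop <- sector_denominators(m$population)
  expect_equal(unname(pop), c(63868953, 16450369, 47418584))
  births <- sector_denominators(m$births)
  expect_equal(unname(births), c(3017203, 796198, 2221005))
  zero <- sector_denominators(m$population,
                              c("10-19" = 0, "20-29" = 0, "30-39" = 0,
                                "40-49" = 0))
  expect_equal(zero[["supp"]], 0)
  expect_equal(zero[["sus"]], zero[["total"]])
  expect_error(sector_denominators(m$population, c("10-19" = 0.18)),
               "20-29")
})

test_that("rates and ratios divide by the right denominator and refuse zero", {
  expect_equal(abortion_rate(557683, 63868953), 8.7)
  expect_equal(abortion_rate(468728, 47418584), 9.9)
  expect_equal(abortion_rate(0, 1000), 0)
  expect_equal(abortion_ratio(557683, 3017203), 18.5)
  expect_equal(abortion_ratio(468728, 2221005), 21.1)
  expect_equal(abortion_ratio(88955, 796198), 11.2)
  expect_error(abortion_rate(1, 0), "population")
  expect_error(abortion_ratio(1, 0), "live births")
})

test_that("sector estimates are additive and bounds widen monotonically with the factor range", {
  pop <- c(total = 1e6, supp = 3e5, sus = 7e5)
  births <- c(total = 5e4, supp = 2e4, sus = 3e4)
  res <- estimate_result(1000, 400, 900, 350, pop = pop, births = births)
  tot <- res[res$sector == "total", ]
  sus <- res[res$sector == "sus", ]
  supp <- res[res$sector == "supp", ]
  expect_equal(tot$abortions, sus$abortions + supp$abortions)
  expect_equal(tot$abortions_ll, sus$abortions_ll + supp$abortions_ll)
  expect_equal(tot$abortions_ul, sus$abortions_ul + supp$abortions_ul)
  expect_true(all(res$abortions_ll <= res$abortions &
                    res$abortions <= res$abortions_ul))
  expect_true(all(res$rate_ll <= res$rate & res$rate <= res$rate_ul))

  wider <- estimate_result(1000, 400, 900, 350,
                           factors = list(sus = c(4, 2, 6),
                                          supp = c(5, 3, 7)),
                           pop = pop, births = births)
  expect_lte(wider$abortions_ll[1], res$abortions_ll[1])
  expect_gte(wider$abortions_ul[1], res$abortions_ul[1])
  expect_lte(wider$rate_ll[3], res$rate_ll[3])
  expect_gte(wider$rate_ul[3], res$rate_ul[3])
})

test_that("estimation is linear in the corrected counts before rounding", {
  a <- estimate_abortions(12345, 4)
  b <- estimate_abortions(3 * 12345, 4)
  expect_equal(unname(b), 3 * unname(a))
})

test_that("the full pipeline on synthetic microdata equals the fixture-margin computation", {
  res <- full_dataset()$result
  m <- brazil_margins_2015()

  # selection aggregates equal the configured margins cell for cell
  expect_equal(counts_total(res$selection$sus), counts_total(m$sus))
  expect_equal(band_totals <- counts_margins(res$selection$ans)$by_band,
               counts_margins(m$ans_total)$by_band)

  # and the estimates equal what the margins give directly
  corr_sus <- counts_total(apply_miscarriage(aggregate_regions(m$sus)))
  corr_supp <- counts_total(apply_miscarriage(m$ans_total))
  direct <- estimate_result(
    counts_total(m$sus), counts_total(m$ans_total), corr_sus, corr_supp,
    pop = sector_denominators(m$population),
    births = sector_denominators(m$births))
  expect_equal(res$estimates, direct)
  expect_equal(res$log$n_unlinkable, 0)
})

test_that("a broken input path aborts with the failing stage named", {
  paths <- full_dataset()$paths
  bad <- paths
  bad$ans_det <- "nonexistent.csv"
  expect_error(suppressMessages(full_pipeline(run_config(paths = bad))),
               "read_ans_det")
})
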