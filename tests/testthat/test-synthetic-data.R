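test_that("exact-mode public microdata hit the margins cell for cell, decoys never selected", {
  spec <- small_margin_spec()
  sus <- generate_sus(spec, seed = 2)
  sel <- select_sus(sus)
  expect_equal(tibble::as_tibble(sel)[c("region", "age_band", "count")],
               tibble::as_tibble(spec$sus_margins)[c("region", "age_band",
                                                     "count")],
               ignore_attr = TRUE)
  # decoys exist but are invisible to selection
  expect_gt(nrow(sus), counts_total(spec$sus_margins))
  no_decoys <- generate_sus(small_margin_spec(decoys_per_region = 0),
                            seed = 2)
  expect_equal(tibble::as_tibble(select_sus(no_decoys)),
               tibble::as_tibble(sel))
})

test_that("zero margins generate only decoys and select to zero", {
  spec <- small_margin_spec()
  zero <- margin_spec(
    sus_margins = make_counts(rep(0, 4)),
    ans_margins_icd = spec$ans_margins_icd,
    ans_margins_total = spec$ans_margins_total,
    population = spec$population, beneficiaries = spec$beneficiaries,
    births = spec$births)
  sus <- generate_sus(zero, seed = 4)
  expect_gt(nrow(sus), 0)
  expect_equal(counts_total(select_sus(sus)), 0)
})

test_that("seeded generation is reproducible and exact-mode aggregates are seed-invariant", {
  spec <- small_margin_spec()
  expect_identical(generate_sus(spec, seed = 10), generate_sus(spec, seed = 10))
  a <- generate_ans(spec, seed = 10)
  b <- generate_ans(spec, seed = 10)
  expect_identical(a, b)
  s1 <- select_sus(generate_sus(spec, seed = 1))
  s2 <- select_sus(generate_sus(spec, seed = 99))
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
})

test_that("private events reproduce both margin tables through linkage and dedup", {
  spec <- small_margin_spec()
  ans <- generate_ans(spec, seed = 5)
  ev <- link_ans(ans$cons, ans$det)
  icd_only <- coarsen_counts(select_ans(ev, selection_rule(mode = "icd_only"),
                                        "fine"))
  both <- coarsen_counts(select_ans(ev, selection_rule(), "fine"))
  expect_equal(tibble::as_tibble(icd_only)[c("region", "age_band", "count")],
               tibble::as_tibble(spec$ans_margins_icd)[c("region", "age_band",
                                                         "count")],
               ignore_attr = TRUE)
  expect_equal(tibble::as_tibble(both)[c("region", "age_band", "count")],
               tibble::as_tibble(spec$ans_margins_total)[c("region",
                                                           "age_band",
                                                           "count")],
               ignore_attr = TRUE)
})

test_that("margins where ICD-only exceeds the ICD-or-procedure table are rejected", {
  spec <- small_margin_spec()
  expect_error(margin_spec(
    sus_margins = spec$sus_margins,
    ans_margins_icd = spec$ans_margins_total,
    ans_margins_total = spec$ans_margins_icd,
    population = spec$population, beneficiaries = spec$beneficiaries,
    births = spec$births), "inconsistent margins")
})

test_that("multinomial mode is noisy per draw but centred on the margins", {
  spec <- small_margin_spec(noise_mode = "multinomial")
  totals <- t(vapply(1:200, function(s) {
    tibble::as_tibble(select_sus(generate_sus(spec, seed = s)))$count
  }, numeric(8)))
  expected <- tibble::as_tibble(spec$sus_margins)$count
  expect_true(any(totals[1, ] != totals[2, ]))
  expect_equal(sum(totals[1, ]), sum(expected))  # total is conserved
  expect_true(all(abs(colMeans(totals) - expected) <=
                    pmax(0.01 * sum(expected) / 8, 1.5)))
})

test_that("generated panels are deterministic and honour degenerate configurations", {
  panels <- generate_panels(margin_spec())
  cov <- compute_coverage(panels$beneficiaries, panels$population)
  expect_equal(round_half_up(100 * cov$overall, 2), 25.88)
  expect_equal(unname(sector_denominators(panels$population)),
               c(63868953, 16450369, 47418584))

  one <- small_margin_spec()
  one$population <- make_counts(rep(1000, 4), regions = "R9",
                                kind = "population")
  one$beneficiaries <- make_counts(rep(250, 4), regions = "R9",
                                   kind = "beneficiaries")
  cov1 <- compute_coverage(one$beneficiaries, one$population)
  expect_equal(cov1$overall, 0.25)
})
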