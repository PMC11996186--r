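test_that("public-sector selection applies the inclusion rule in any diagnosis field", {
  records <- dplyr::bind_rows(
    sus_record(age = 24, diag3 = "O062"),          # counted, band 20-29
    sus_record(age = 24, diag1 = "O001"),          # excluded category only
    sus_record(age = 24, diag1 = "Z349"),          # non-obstetric
    sus_record(age = 55, diag1 = "O03"),           # age out of range
    sus_record(age = 24, diag1 = "O03", year = 2014),  # wrong year
    sus_record(age = 12, diag5 = "O08"))           # counted, band 10-19
  tab <- select_sus(records, selection_rule(), year = 2015)
  expect_equal(counts_total(tab), 2)
  cells <- tibble::as_tibble(tab)
  expect_equal(cells$count[cells$age_band == "20-29"], 1)
  expect_equal(cells$count[cells$age_band == "10-19"], 1)
  expect_equal(counts_total(select_sus(records[0, ], selection_rule())), 0)
})

test_that("a public record with both an abortion and an excluded code is counted by default", {
  records <- sus_record(age = 24, diag1 = "O03", diag2 = "O00")
  expect_equal(counts_total(select_sus(records)), 1)
  strict <- selection_rule(sus_apply_exclusion = TRUE)
  expect_equal(counts_total(select_sus(records, strict)), 0)
})

test_that("linkage yields one event per id with any-field flag semantics", {
  cons <- dplyr::bind_rows(
    cons_record("E1", icd1 = "O03"),
    cons_record("E2", icd2 = "O01"),
    cons_record("E3"))
  det <- dplyr::bind_rows(
    det_record("E1", "31309062"),
    det_record("E2", "31303013"),
    det_record("E3", "31309020"),
    det_record("E9", "31309020"),
    det_record("E9", "31309062"))
  ev <- link_ans(cons, det)
  expect_equal(nrow(ev), 4)
  e1 <- ev[ev$event_id == "E1", ]
  expect_true(e1$has_abortion_icd && e1$has_abortion_procedure)
  expect_true(ev$has_excluded_icd[ev$event_id == "E2"])
  # detail-only event: retained, unknown stratum, reported
  expect_equal(attr(ev, "n_unlinkable"), 1)
  expect_true(is.na(ev$region[ev$event_id == "E9"]))
  expect_true(ev$has_abortion_procedure[ev$event_id == "E9"])
})

test_that("counting modes: procedure-only events appear only in icd_or_procedure; exclusion always wins", {
  cons <- dplyr::bind_rows(
    cons_record("E1", icd1 = "O03"),                  # icd only
    cons_record("E2"),                                # procedure only
    cons_record("E3", icd1 = "O03"),                  # icd + procedure
    cons_record("E4", icd1 = "O01"),                  # excluded + procedure
    cons_record("E5", icd1 = "O03", icd3 = "O00"))    # abortion + excluded
  det <- dplyr::bind_rows(det_record("E2"), det_record("E3"),
                          det_record("E4"))
  ev <- link_ans(cons, det)
  icd_only <- select_ans(ev, selection_rule(mode = "icd_only"))
  both <- select_ans(ev, selection_rule(mode = "icd_or_procedure"))
  expect_equal(counts_total(icd_only), 2)   # E1, E3
  expect_equal(counts_total(both), 3)       # E1, E2, E3
  empty <- select_ans(ev[0, ], selection_rule())
  expect_equal(counts_total(empty), 0)
})

test_that("icd_or_procedure dominates icd_only cellwise and detail duplication is idempotent", {
  withr::with_seed(9, {
    for (i in 1:5) {
      spec <- small_margin_spec(seed_counts = i)
      ans <- generate_ans(spec, seed = i)
      ev <- link_ans(ans$cons, ans$det)
      icd_only <- select_ans(ev, selection_rule(mode = "icd_only"))
      both <- select_ans(ev, selection_rule(mode = "icd_or_procedure"))
      j <- dplyr::left_join(
        dplyr::rename(tibble::as_tibble(both), both = "count"),
        dplyr::rename(tibble::as_tibble(icd_only), icd = "count"),
        by = c("region", "age_band"))
      j$icd[is.na(j$icd)] <- 0
      expect_true(all(j$both >= j$icd))

      # duplicating every detail row must not change any count
      ev_dup <- link_ans(ans$cons, dplyr::bind_rows(ans$det, ans$det))
      both_dup <- select_ans(ev_dup, selection_rule(mode = "icd_or_procedure"))
      expect_equal(tibble::as_tibble(both_dup), tibble::as_tibble(both))
    }
  })
})

test_that("adding an excluded diagnosis to any event can only decrease counts", {
  spec <- small_margin_spec()
  ans <- generate_ans(spec, seed = 3)
  base <- counts_total(select_ans(link_ans(ans$cons, ans$det),
                                  selection_rule()))
  poisoned <- ans$cons
  poisoned$icd4[seq(1, nrow(poisoned), by = 3)] <- "O021"
  after <- counts_total(select_ans(link_ans(poisoned, ans$det),
                                   selection_rule()))
  expect_lt(after, base)
})

test_that("the ICD-and/or-procedure to ICD-only ratio matches summed-count division", {
  m <- brazil_margins_2015()
  r <- icd_procedure_ratio(m$ans_total, m$ans_icd)
  expect_equal(r$total, 2.1)
  expect_equal(r$by_band$ratio[match(coarse_bands, r$by_band$age_band)],
               c(2.1, 2.0, 2.2, 2.2))
  zero <- make_counts(rep(0, 4))
  expect_true(all(is.na(icd_procedure_ratio(zero, zero)$cells$ratio)))
  # one-decimal division of printed cells
  expect_equal(counts_ratio(make_counts(c(4290, 0, 0, 0)),
                            make_counts(c(669, 0, 0, 0)))$total, 6.4)
})
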