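# Builders for small, fully controlled inputs, plus a lazily generated
# full-scale synthetic dataset shared by the end-to-end tests.

sus_record <- function(region = "R1", age = 25, diag1 = "", diag2 = "",
                       diag3 = "", diag4 = "", diag5 = "", year = 2015) {
  tibble::tibble(region = region, age = age, diag1 = diag1, diag2 = diag2,
                 diag3 = diag3, diag4 = diag4, diag5 = diag5, year = year)
}

cons_record <- function(event_id, region = "R1", age_band = "20-24",
                        icd1 = NA_character_, icd2 = NA_character_,
                        icd3 = NA_character_, icd4 = NA_character_,
                        year = 2015) {
  tibble::tibble(event_id = event_id, region = region, age_band = age_band,
                 icd1 = icd1, icd2 = icd2, icd3 = icd3, icd4 = icd4,
                 year = year)
}

det_record <- function(event_id, procedure_code = "31309062") {
  tibble::tibble(event_id = event_id, procedure_code = procedure_code)
}

make_counts <- function(counts, regions = "R1", bands = coarse_bands,
                        kind = "counts") {
  counts_table(tidyr::expand_grid(region = regions, age_band = bands) |>
                 dplyr::mutate(count = counts),
               kind = kind)
}

# A two-region margin spec small enough for property-style loops.
small_margin_spec <- function(..., seed_counts = 11) {
  set.seed(seed_counts)
  regions <- c("R1", "R2")
  sus <- make_counts(sample(5:40, 8, replace = TRUE), regions)
  tot <- make_counts(sample(10:30, 8, replace = TRUE), regions)
  icd <- counts_table(dplyr::mutate(tibble::as_tibble(tot),
                                    count = floor(count / 2)))
  pop <- make_counts(rep(10000, 8), regions, kind = "population")
  ben <- make_counts(rep(2500, 8), regions, kind = "beneficiaries")
  births <- make_counts(rep(400, 8), regions, kind = "live_births")
  margin_spec(sus_margins = sus, ans_margins_icd = icd,
              ans_margins_total = tot, population = pop,
              beneficiaries = ben, births = births, ...)
}

# Full-scale synthetic 2015 dataset, generated once per test run.
full_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "aicm-full-synth")
      paths <- write_synthetic_dataset(margin_spec(), dir, seed = 20150101)
      cache <<- list(paths = paths,
                     result = suppressMessages(
                       full_pipeline(run_config(paths = paths))))
    }
    cache
  }
})
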