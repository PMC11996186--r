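#' Specify the margins a synthetic dataset must reproduce
#'
#' The generator emits record-level microdata (public-sector admissions,
#' private-insurance consolidated and detail rows, denominator panels)
#' whose aggregates match configured region-by-band margins, so every
#' pipeline stage can be exercised end-to-end without access to the source
#' data systems. The defaults are the packaged 2015 national margins
#' ([brazil_margins_2015()]), together with the within-band allocations
#' that reproduce the published survey-age (18-39) sector totals:
#'
#' * `sus_share_18_19`: share of 10-19 public admissions at ages 18-19
#'   (default 16,625 / 23,912, the allocation consistent with the published
#'   18-39 public-sector total).
#' * `fine_band_split`: share of each decade's private events falling in
#'   the *older* 5-year band (default 0.5 except 10-19, where 641 / 669
#'   reproduces the published private 18-39 total under the 75% rule).
#'
#' In `"exact"` mode generated aggregates equal the margins cell for cell;
#' in `"multinomial"` mode cell totals are drawn from a multinomial with
#' the margins as expected proportions, emulating sampling noise.
#'
#' @param sus_margins,ans_margins_icd,ans_margins_total Coarse-band
#'   [counts_table()]s; the ICD-only margins must not exceed the
#'   ICD-and/or-procedure margins in any cell.
#' @param population,beneficiaries,births Panel `counts_table`s.
#' @param sus_share_18_19,fine_band_split Within-band allocations, above.
#' @param icd_missing_rate Proportion of *non-abortion* decoy events whose
#'   ICD fields are all unreported (default 0.238, the observed unreported
#'   rate in obstetric claims). Among abortion events the missing share is
#'   fully determined by the two margin tables and is not a free parameter.
#' @param dedup_overlap Share of ICD-identified private events that also
#'   carry an abortion procedure row, exercising event deduplication.
#' @param decoys_per_region Non-qualifying records injected per region into
#'   each source (excluded O00-O02 diagnoses, non-obstetric codes,
#'   out-of-range ages, wrong years); selection output must be invariant to
#'   them.
#' @param noise_mode `"exact"` or `"multinomial"`.
#' @return A `margin_spec` list.
#' @export
margin_spec <- function(sus_margins = NULL, ans_margins_icd = NULL,
                        ans_margins_total = NULL, population = NULL,
                        beneficiaries = NULL, births = NULL,
                        sus_share_18_19 = 16625 / 23912,
                        fine_band_split = c("10-19" = 641 / 669,
                                            "20-29" = 0.5, "30-39" = 0.5,
                                            "40-49" = 0.5),
                        icd_missing_rate = 0.238, dedup_overlap = 0.5,
                        decoys_per_region = 8,
                        noise_mode = c("exact", "multinomial")) {
  noise_mode <- match.arg(noise_mode)
  defaults <- brazil_margins_2015()
  spec <- list(
    sus_margins = sus_margins %||% defaults$sus,
    ans_margins_icd = ans_margins_icd %||% defaults$ans_icd,
    ans_margins_total = ans_margins_total %||% defaults$ans_total,
    population = population %||% defaults$population,
    beneficiaries = beneficiaries %||% defaults$beneficiaries,
    births = births %||% defaults$births,
    sus_share_18_19 = sus_share_18_19,
    fine_band_split = fine_band_split,
    icd_missing_rate = icd_missing_rate,
    dedup_overlap = dedup_overlap,
    decoys_per_region = decoys_per_region,
    noise_mode = noise_mode)
  stopifnot(spec$sus_share_18_19 >= 0, spec$sus_share_18_19 <= 1,
            all(spec$fine_band_split >= 0), all(spec$fine_band_split <= 1),
            spec$icd_missing_rate >= 0, spec$icd_missing_rate <= 1)
  chk <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(spec$ans_margins_icd), icd = "count"),
    dplyr::rename(tibble::as_tibble(spec$ans_margins_total), tot = "count"),
    by = c("region", "age_band"))
  chk[is.na(chk)] <- 0
  if (any(chk$icd > chk$tot)) {
    stop("inconsistent margins: ICD-only exceeds ICD-and/or-procedure in ",
         "at least one cell", call. = FALSE)
  }
  structure(spec, class = "margin_spec")
}

# Integer allocation of share * n across cells by largest remainder, so the
# grand total equals round_half_up(share * sum(n)) exactly.
allocate_share <- function(n, share) {
  target <- round_half_up(share * sum(n))
  base <- floor(share * n)
  rem <- target - sum(base)
  if (rem > 0) {
    frac <- share * n - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  base
}

maybe_multinomial <- function(counts, noise_mode) {
  if (noise_mode == "exact" || sum(counts) == 0) return(counts)
  n <- sum(counts)
  as.vector(stats::rmultinom(1, n, prob = counts / n))
}

abortion_icd_codes <- function(n) {
  cat <- sample(sprintf("O%02d", 3:8), n, replace = TRUE)
  sub <- sample(c("", as.character(0:9)), n, replace = TRUE)
  paste0(cat, sub)
}

sample_ages <- function(band, n) {
  lo <- as.integer(substr(band, 1, 2))
  hi <- as.integer(substr(band, 4, 5))
  sample(lo:hi, n, replace = TRUE)
}

#' Generate public-sector admission microdata matching margins
#'
#' Emits one qualifying record per margin unit (exact mode): the age is
#' drawn within the band — with the 18-19 share of the 10-19 band allocated
#' exactly across regions — and an abortion ICD-10 code is placed in one of
#' the five diagnosis fields at random. Decoy records (excluded O00-O02
#' codes, non-obstetric codes, out-of-range ages, wrong years) are appended
#' and must never be selected.
#'
#' @param spec A [margin_spec()].
#' @param seed Integer seed; runs are bit-reproducible given the seed.
#' @param year Year stamped on qualifying records.
#' @return A `sus_admissions` tibble (see [data_io]).
#' @export
generate_sus <- function(spec = margin_spec(), seed = 1, year = 2015) {
  stopifnot(inherits(spec, "margin_spec"))
  withr::with_seed(seed, {
    m <- tibble::as_tibble(spec$sus_margins)
    m$count <- maybe_multinomial(m$count, spec$noise_mode)
    teen <- m$age_band == "10-19"
    n18 <- integer(nrow(m))
    n18[teen] <- allocate_share(m$count[teen], spec$sus_share_18_19)
    rows <- lapply(seq_len(nrow(m)), function(i) {
      n <- m$count[i]
      if (n == 0) return(NULL)
      age <- if (teen[i]) {
        c(sample(18:19, n18[i], replace = TRUE),
          sample(10:17, n - n18[i], replace = TRUE))
      } else {
        sample_ages(m$age_band[i], n)
      }
      tibble::tibble(region = m$region[i], age = age)
    })
    rec <- dplyr::bind_rows(rows)
    if (nrow(rec) == 0) {
      rec <- tibble::tibble(region = character(0), age = integer(0))
    }
    n <- nrow(rec)
    diags <- matrix("", nrow = n, ncol = 5)
    slot <- sample.int(5, n, replace = TRUE)
    diags[cbind(seq_len(n), slot)] <- abortion_icd_codes(n)
    rec <- tibble::tibble(region = rec$region, age = rec$age,
                          diag1 = diags[, 1], diag2 = diags[, 2],
                          diag3 = diags[, 3], diag4 = diags[, 4],
                          diag5 = diags[, 5], year = year)
    dplyr::bind_rows(rec, sus_decoys(spec, year))
  })
}

sus_decoys <- function(spec, year) {
  regions <- unique(spec$sus_margins$region)
  k <- spec$decoys_per_region
  if (k == 0 || length(regions) == 0) return(NULL)
  one <- function(region) {
    n <- k
    kind <- sample(c("excluded", "nonobstetric", "age", "year"), n,
                   replace = TRUE)
    age <- sample(15:45, n, replace = TRUE)
    age[kind == "age"] <- sample(c(5:9, 50:60), sum(kind == "age"),
                                 replace = TRUE)
    yr <- rep(year, n)
    yr[kind == "year"] <- year - 1
    code <- character(n)
    code[kind == "excluded"] <- paste0(
      sample(sprintf("O%02d", 0:2), sum(kind == "excluded"), replace = TRUE),
      sample(0:9, sum(kind == "excluded"), replace = TRUE))
    code[kind == "nonobstetric"] <- sample(
      c("Z349", "A09", "N939", "K359"), sum(kind == "nonobstetric"),
      replace = TRUE)
    code[kind %in% c("age", "year")] <- abortion_icd_codes(
      sum(kind %in% c("age", "year")))
    tibble::tibble(region = region, age = age, diag1 = code, diag2 = "",
                   diag3 = "", diag4 = "", diag5 = "", year = yr)
  }
  dplyr::bind_rows(lapply(regions, one))
}

spread_to_fine <- function(margins, split) {
  m <- tibble::as_tibble(margins)
  fine_of <- list("10-19" = c("10-14", "15-19"),
                  "20-29" = c("20-24", "25-29"),
                  "30-39" = c("30-34", "35-39"),
                  "40-49" = c("40-44", "45-49"))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    band <- m$age_band[i]
    older <- allocate_share(m$count[i], split[[band]])
    tibble::tibble(region = m$region[i], age_band = fine_of[[band]],
                   count = c(m$count[i] - older, older))
  })
  dplyr::bind_rows(rows)
}

#' Generate private-insurance consolidated and detail rows matching margins
#'
#' Builds care events of three kinds so that [select_ans()] reproduces both
#' margin tables after [link_ans()] deduplication: ICD-identified events (a
#' `dedup_overlap` share of which also carries an abortion procedure row,
#' so linkage must not double count them), procedure-only events whose four
#' ICD fields are all unreported, and decoys — excluded-diagnosis events
#' (O00-O02, possibly with an abortion procedure) and non-obstetric events,
#' a `icd_missing_rate` share of which also has unreported ICDs.
#'
#' @inheritParams generate_sus
#' @return A list with tibbles `cons` (`ans_cons` schema) and `det`
#'   (`ans_det` schema).
#' @export
generate_ans <- function(spec = margin_spec(), seed = 1, year = 2015) {
  stopifnot(inherits(spec, "margin_spec"))
  withr::with_seed(seed, {
    icd_fine <- spread_to_fine(spec$ans_margins_icd, spec$fine_band_split)
    tot_fine <- spread_to_fine(spec$ans_margins_total, spec$fine_band_split)
    j <- dplyr::full_join(dplyr::rename(icd_fine, icd = "count"),
                          dplyr::rename(tot_fine, tot = "count"),
                          by = c("region", "age_band"))
    j[is.na(j)] <- 0
    j$icd <- pmin(j$icd, j$tot)
    if (spec$noise_mode == "multinomial") {
      j$icd <- maybe_multinomial(j$icd, "multinomial")
      j$tot <- j$icd + maybe_multinomial(j$tot - j$icd, "multinomial")
    }
    cons <- list()
    det <- list()
    next_id <- 0L
    new_ids <- function(n) {
      ids <- sprintf("E%07d", next_id + seq_len(n))
      next_id <<- next_id + n
      ids
    }
    cons_row <- function(ids, region, band, icd) {
      n <- length(ids)
      icds <- matrix(NA_character_, nrow = n, ncol = 4)
      if (!all(is.na(icd))) {
        slot <- sample.int(4, n, replace = TRUE)
        icds[cbind(seq_len(n), slot)] <- icd
      }
      tibble::tibble(event_id = ids, region = region, age_band = band,
                     icd1 = icds[, 1], icd2 = icds[, 2], icd3 = icds[, 3],
                     icd4 = icds[, 4], year = year)
    }
    det_row <- function(ids) {
      tibble::tibble(event_id = ids,
                     procedure_code = sample(c("31309020", "31303013",
                                               "31309062"),
                                             length(ids), replace = TRUE))
    }
    for (i in seq_len(nrow(j))) {
      n_icd <- j$icd[i]
      n_proc <- j$tot[i] - j$icd[i]
      if (n_icd > 0) {
        ids <- new_ids(n_icd)
        cons[[length(cons) + 1]] <- cons_row(ids, j$region[i], j$age_band[i],
                                             abortion_icd_codes(n_icd))
        n_overlap <- round_half_up(spec$dedup_overlap * n_icd)
        if (n_overlap > 0) {
          det[[length(det) + 1]] <- det_row(ids[seq_len(n_overlap)])
        }
      }
      if (n_proc > 0) {
        ids <- new_ids(n_proc)
        cons[[length(cons) + 1]] <- cons_row(ids, j$region[i], j$age_band[i],
                                             rep(NA_character_, n_proc))
        det[[length(det) + 1]] <- det_row(ids)
      }
    }
    dec <- ans_decoys(spec, unique(j$region), year, new_ids)
    cons <- dplyr::bind_rows(c(cons, list(dec$cons)))
    det <- dplyr::bind_rows(c(det, list(dec$det)))
    list(cons = cons, det = det)
  })
}

ans_decoys <- function(spec, regions, year, new_ids) {
  k <- spec$decoys_per_region
  if (k == 0 || length(regions) == 0) {
    return(list(cons = NULL, det = NULL))
  }
  cons <- list()
  det <- list()
  for (region in regions) {
    # excluded diagnoses, half of them with an abortion procedure attached:
    # the exclusion must dominate the procedure flag
    n_excl <- ceiling(k / 2)
    ids <- new_ids(n_excl)
    icds <- matrix(NA_character_, nrow = n_excl, ncol = 4)
    icds[, 1] <- paste0(sample(sprintf("O%02d", 0:2), n_excl, replace = TRUE),
                        sample(0:9, n_excl, replace = TRUE))
    cons[[length(cons) + 1]] <- tibble::tibble(
      event_id = ids, region = region,
      age_band = sample(fine_bands, n_excl, replace = TRUE),
      icd1 = icds[, 1], icd2 = icds[, 2], icd3 = icds[, 3], icd4 = icds[, 4],
      year = year)
    with_proc <- ids[seq_len(ceiling(n_excl / 2))]
    det[[length(det) + 1]] <- tibble::tibble(
      event_id = with_proc,
      procedure_code = sample(c("31309020", "31309062"), length(with_proc),
                              replace = TRUE))
    # non-obstetric events; icd_missing_rate of them with all-null ICDs
    n_other <- k - n_excl
    if (n_other > 0) {
      ids <- new_ids(n_other)
      n_miss <- round_half_up(spec$icd_missing_rate * n_other)
      code <- c(rep(NA_character_, n_miss),
                sample(c("Z349", "K359", "N939"), n_other - n_miss,
                       replace = TRUE))
      cons[[length(cons) + 1]] <- tibble::tibble(
        event_id = ids, region = region,
        age_band = sample(fine_bands, n_other, replace = TRUE),
        icd1 = code, icd2 = NA_character_, icd3 = NA_character_,
        icd4 = NA_character_, year = year)
      det[[length(det) + 1]] <- tibble::tibble(
        event_id = ids,
        procedure_code = sample(c("40304361", "31602096"), n_other,
                                replace = TRUE))
    }
  }
  list(cons = dplyr::bind_rows(cons), det = dplyr::bind_rows(det))
}

#' Generate denominator panels consistent with the configured margins
#'
#' The population, beneficiary and live-birth panels are deterministic
#' copies of the margin tables (they are published aggregates, not
#' microdata); the function exists so a synthetic dataset is emitted as one
#' coherent bundle and so degenerate configurations (single region, zero
#' beneficiaries) can be constructed for testing.
#'
#' @param spec A [margin_spec()].
#' @return Named list of panel `counts_table`s
#'   (`population`, `beneficiaries`, `births`).
#' @export
generate_panels <- function(spec = margin_spec()) {
  stopifnot(inherits(spec, "margin_spec"))
  list(population = spec$population, beneficiaries = spec$beneficiaries,
       births = spec$births)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the five CSV schemas of [data_io] into `dir` and returns a `paths`
#' list ready for [run_config()].
#'
#' @inheritParams generate_sus
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`sus`, `ans_cons`, `ans_det`,
#'   `population`, `beneficiaries`, `births`), invisibly.
#' @export
write_synthetic_dataset <- function(spec = margin_spec(), dir, seed = 1,
                                    year = 2015) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sus <- generate_sus(spec, seed = seed, year = year)
  ans <- generate_ans(spec, seed = seed + 1, year = year)
  panels <- generate_panels(spec)
  paths <- list(sus = file.path(dir, "sus_admissions.csv"),
                ans_cons = file.path(dir, "ans_cons.csv"),
                ans_det = file.path(dir, "ans_det.csv"),
                population = file.path(dir, "population.csv"),
                beneficiaries = file.path(dir, "beneficiaries.csv"),
                births = file.path(dir, "births.csv"))
  readr::write_csv(sus, paths$sus)
  readr::write_csv(ans$cons, paths$ans_cons, na = "")
  readr::write_csv(ans$det, paths$ans_det)
  write_counts_table(panels$population, paths$population)
  write_counts_table(panels$beneficiaries, paths$beneficiaries)
  write_counts_table(panels$births, paths$births)
  invisible(paths)
}
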