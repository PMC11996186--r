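#' Age-specific miscarriage correction factors
#'
#' Part of the hospitalized abortion caseload is spontaneous, not induced.
#' Prospective cohorts place the probability of clinically recognized
#' miscarriage higher after age 30, so the share of admissions retained as
#' induced-abortion complications decreases with age: 0.90 below 30 years,
#' 0.85 at 30-39, 0.75 at 40-49.
#'
#' @param factors Named numeric vector mapping each coarse band to a factor
#'   in `(0, 1]`.
#' @return A validated named vector.
#' @export
miscarriage_factors <- function(factors = c("10-19" = 0.90, "20-29" = 0.90,
                                            "30-39" = 0.85, "40-49" = 0.75)) {
  stopifnot(is.numeric(factors), !is.null(names(factors)))
  if (any(factors <= 0 | factors > 1)) {
    stop("miscarriage factors must lie in (0, 1]", call. = FALSE)
  }
  factors
}

#' Remove the miscarriage share from a hospitalization table
#'
#' The factors are defined on the age groups of the miscarriage-risk
#' gradient — under 30, 30-39, 40-49 — so a coarse-band input is first
#' aggregated onto those groups (10-19 and 20-29 merge into 10-29), then
#' each cell is multiplied by its group's factor and rounded half-up to an
#' integer; totals are sums of rounded cells, matching the published
#' tables. Applied separately to the public and private sectors because
#' their age profiles differ.
#'
#' @param counts A [counts_table()] on coarse (10-year) bands or already on
#'   the miscarriage groups (`"10-29"`, `"30-39"`, `"40-49"`).
#' @param factors A [miscarriage_factors()] vector covering every band
#'   present; a missing band is a configuration error. When keyed by
#'   decade, 10-19 and 20-29 must share a value (the method defines a
#'   single under-30 factor).
#' @param rounding `"half_up"` (default) or `"none"`.
#' @return A `counts_table` on the miscarriage groups.
#' @export
apply_miscarriage <- function(counts, factors = miscarriage_factors(),
                              rounding = c("half_up", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(counts, "counts_table"))
  gran <- attr(counts, "granularity")
  if (gran == "fine") {
    stop("apply_miscarriage expects coarse (10-year) bands; see coarsen_counts()",
         call. = FALSE)
  }
  out <- tibble::as_tibble(counts)
  if (gran == "coarse") {
    out$age_band <- ifelse(out$age_band %in% c("10-19", "20-29"), "10-29",
                           out$age_band)
    out <- dplyr::summarise(dplyr::group_by(out, .data$region,
                                            .data$age_band),
                            count = sum(.data$count), .groups = "drop")
  }
  f <- normalize_miscarriage_factors(factors)
  missing_bands <- setdiff(unique(out$age_band), names(f))
  if (length(missing_bands) > 0) {
    stop("no miscarriage factor configured for band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  out$count <- apply_rounding(out$count * f[out$age_band], 0, rounding)
  counts_table(out, kind = paste0(attr(counts, "kind"), "_corrected"))
}

# Accept factors keyed by decade bands or by miscarriage groups; return
# them keyed by miscarriage groups.
normalize_miscarriage_factors <- function(factors) {
  if (all(miscarriage_bands %in% names(factors))) {
    return(factors[miscarriage_bands])
  }
  if (all(c("10-19", "20-29") %in% names(factors))) {
    if (factors[["10-19"]] != factors[["20-29"]]) {
      stop("the under-30 miscarriage factor must be a single value: ",
           "10-19 and 20-29 differ", call. = FALSE)
    }
    return(c("10-29" = factors[["20-29"]], factors[c("30-39", "40-49")]))
  }
  factors
}

#' Miscarriage-corrected hospitalizations restricted to survey ages (18-39)
#'
#' The external survey total covers women aged 18-39 only, so the
#' calibration of the non-hospitalization factor compares it against
#' hospitalizations in that age range. Public-sector microdata carry exact
#' ages, so 18-39 is counted directly. The private claims data only carry
#' 5-year bands; the 18-19 contribution is taken as `share_18_19` of the
#' 15-19 band (default 0.75 — within 15-19, the frequency of abortion rises
#' steeply with age, so 18-19 year olds account for well over their
#' population share of admissions). Miscarriage factors 0.90 (18-29) and
#' 0.85 (30-39) are applied and each sector total is rounded half-up once.
#'
#' @param sus_records Validated `sus_admissions` tibble with integer ages.
#' @param ans_fine_counts Fine-band `counts_table` of private abortion
#'   events (from `select_ans(..., granularity = "fine")`).
#' @param factors A [miscarriage_factors()] vector (coarse bands).
#' @param share_18_19 Proportion of 15-19 private admissions attributed to
#'   ages 18-19, in `[0, 1]`.
#' @param year,rule Passed to the public-sector selection.
#' @return Named list `hosp_sus_18_39`, `hosp_supp_18_39`.
#' @export
restrict_to_survey_ages <- function(sus_records, ans_fine_counts,
                                    factors = miscarriage_factors(),
                                    share_18_19 = 0.75, year = 2015,
                                    rule = selection_rule()) {
  stopifnot(share_18_19 >= 0, share_18_19 <= 1)
  if (!inherits(ans_fine_counts, "counts_table") ||
      attr(ans_fine_counts, "granularity") != "fine") {
    stop(paste("restrict_to_survey_ages needs fine (5-year) private-sector",
               "bands; rerun select_ans with granularity = 'fine'"),
         call. = FALSE)
  }
  keep <- sus_records$year == year & sus_records$age >= 10 &
    sus_records$age <= 49
  sus <- sus_records[keep, , drop = FALSE]
  cats <- diag_category_matrix(sus, paste0("diag", 1:5))
  has_incl <- rowSums(matrix(cats %in% rule$include_categories,
                             nrow = nrow(sus))) > 0
  age <- sus$age[has_incl]
  hosp_sus <- round_half_up(
    factors[["20-29"]] * sum(age >= 18 & age <= 29) +
      factors[["30-39"]] * sum(age >= 30 & age <= 39))

  bt <- band_totals(ans_fine_counts)
  get <- function(b) if (b %in% names(bt)) bt[[b]] else 0
  n_18_29 <- share_18_19 * get("15-19") + get("20-24") + get("25-29")
  n_30_39 <- get("30-34") + get("35-39")
  hosp_supp <- round_half_up(factors[["20-29"]] * n_18_29 +
                               factors[["30-39"]] * n_30_39)
  list(hosp_sus_18_39 = hosp_sus, hosp_supp_18_39 = hosp_supp)
}

#' Specify one calibration scenario for the non-hospitalization factor
#'
#' The non-hospitalization correction factor scales hospitalized
#' complications up to all induced abortions. It is calibrated against an
#' external survey total of women reporting an abortion in the year
#' (503,000 for 2015), under one of three modes:
#'
#' * `"pooled"` — one factor for all women: survey total divided by total
#'   18-39 hospitalizations.
#' * `"sector"` — each sector's abortions are its population times an
#'   annual abortion frequency (`freq_sus`, `freq_supp`); a factor per
#'   sector.
#' * `"constrained"` — the private frequency is a fixed fraction
#'   `freq_ratio` of the public one, and the public frequency is solved so
#'   the sector abortions sum to the survey total.
#'
#' @param mode One of `"pooled"`, `"sector"`, `"constrained"`.
#' @param pna_total Survey count of women reporting an abortion (default
#'   503,000).
#' @param pop_sus,pop_supp Women aged 18-39 relying on the public sector /
#'   covered by private insurance. Defaults are back-solved from the
#'   published sector abortion estimates at the survey frequency 1.35%.
#' @param freq_sus,freq_supp Annual abortion frequencies (proportions in
#'   `(0, 1)`), sector mode only; default 1.35% in both sectors.
#' @param freq_ratio `freq_supp / freq_sus`, constrained mode only.
#' @param label Optional scenario name.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(mode = c("pooled", "sector", "constrained"),
                          pna_total = 503000,
                          pop_sus = 27496889, pop_supp = 9540963,
                          freq_sus = 0.0135, freq_supp = 0.0135,
                          freq_ratio = NULL, label = NULL) {
  mode <- match.arg(mode)
  stopifnot(pna_total > 0, pop_sus > 0, pop_supp > 0)
  if (mode == "sector") {
    stopifnot(freq_sus > 0, freq_sus < 1, freq_supp > 0, freq_supp < 1)
  }
  if (mode == "constrained") {
    if (is.null(freq_ratio) || freq_ratio <= 0) {
      stop("constrained mode needs a positive freq_ratio", call. = FALSE)
    }
  }
  structure(list(mode = mode, pna_total = pna_total, pop_sus = pop_sus,
                 pop_supp = pop_supp, freq_sus = freq_sus,
                 freq_supp = freq_supp, freq_ratio = freq_ratio,
                 label = label %||% mode),
            class = "scenario_spec")
}

#' Derive correction factors for one scenario
#'
#' Each factor is estimated abortions divided by the corresponding
#' miscarriage-corrected 18-39 hospitalizations, reported to 1 decimal;
#' estimated abortions are integers. In constrained mode the public
#' frequency solves `pop_sus * f + pop_supp * freq_ratio * f = pna_total`
#' and the private estimate is the remainder of the survey total, so the
#' two sectors always add up to it exactly.
#'
#' @param spec A [scenario_spec()].
#' @param hosp_sus_18_39,hosp_supp_18_39 Miscarriage-corrected 18-39
#'   hospitalizations per sector (see [restrict_to_survey_ages()]).
#' @return A one-row tibble with the scenario's estimated abortions,
#'   hospitalizations, frequencies and factors (`NA` where the scenario
#'   does not define a value).
#' @export
run_scenario <- function(spec, hosp_sus_18_39, hosp_supp_18_39) {
  stopifnot(inherits(spec, "scenario_spec"))
  hosp_total <- hosp_sus_18_39 + hosp_supp_18_39
  div <- function(num, den) {
    if (den <= 0) {
      if (num > 0) {
        stop("undefined correction factor: zero hospitalizations against a ",
             "nonzero abortion estimate", call. = FALSE)
      }
      return(NA_real_)
    }
    round_half_up(num / den, 1)
  }
  res <- tibble::tibble(
    scenario = spec$label, est_sus = NA_real_, est_supp = NA_real_,
    hosp_sus = hosp_sus_18_39, hosp_supp = hosp_supp_18_39,
    freq_sus = NA_real_, freq_supp = NA_real_,
    factor_sus = NA_real_, factor_supp = NA_real_, factor_total = NA_real_)
  if (spec$mode == "pooled") {
    res$factor_total <- div(spec$pna_total, hosp_total)
    return(res)
  }
  if (spec$mode == "sector") {
    f_sus <- spec$freq_sus
    f_supp <- spec$freq_supp
    est_sus <- round_half_up(spec$pop_sus * f_sus)
    est_supp <- round_half_up(spec$pop_supp * f_supp)
  } else {
    f_sus <- spec$pna_total / (spec$pop_sus + spec$freq_ratio * spec$pop_supp)
    f_supp <- spec$freq_ratio * f_sus
    est_sus <- round_half_up(spec$pop_sus * f_sus)
    est_supp <- spec$pna_total - est_sus
  }
  res$est_sus <- est_sus
  res$est_supp <- est_supp
  res$freq_sus <- f_sus
  res$freq_supp <- f_supp
  res$factor_sus <- div(est_sus, hosp_sus_18_39)
  res$factor_supp <- div(est_supp, hosp_supp_18_39)
  res
}

#' The five canonical calibration scenarios
#'
#' Scenario 1 pools both sectors; scenario 2 applies the survey frequency
#' (1.35%) to each sector's population; scenarios 3a-3c assume the private
#' frequency is 50%, 75% and 90% of the public one, solving the public
#' frequency against the survey total.
#'
#' @param pna_total,pop_sus,pop_supp See [scenario_spec()].
#' @param freq_pna Survey annual abortion frequency, default 1.35%.
#' @return A list of [scenario_spec()]s.
#' @export
canonical_scenarios <- function(pna_total = 503000, pop_sus = 27496889,
                                pop_supp = 9540963, freq_pna = 0.0135) {
  list(
    scenario_spec("pooled", pna_total, pop_sus, pop_supp, label = "1"),
    scenario_spec("sector", pna_total, pop_sus, pop_supp,
                  freq_sus = freq_pna, freq_supp = freq_pna, label = "2"),
    scenario_spec("constrained", pna_total, pop_sus, pop_supp,
                  freq_ratio = 0.50, label = "3a"),
    scenario_spec("constrained", pna_total, pop_sus, pop_supp,
                  freq_ratio = 0.75, label = "3b"),
    scenario_spec("constrained", pna_total, pop_sus, pop_supp,
                  freq_ratio = 0.90, label = "3c")
  )
}

#' Run a list of scenarios and stack the results
#'
#' @param specs List of [scenario_spec()]s (default [canonical_scenarios()]).
#' @inheritParams run_scenario
#' @return A tibble, one row per scenario.
#' @export
scenario_suite <- function(specs = canonical_scenarios(),
                           hosp_sus_18_39, hosp_supp_18_39) {
  dplyr::bind_rows(lapply(specs, run_scenario,
                          hosp_sus_18_39 = hosp_sus_18_39,
                          hosp_supp_18_39 = hosp_supp_18_39))
}
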