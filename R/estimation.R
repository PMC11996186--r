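#' Estimate induced abortions for one sector with sensitivity bounds
#'
#' Point estimate: miscarriage-corrected hospitalizations times the
#' non-hospitalization correction factor. The lower and upper limits move
#' the factor down and up (by one unit under the defaults: public sector
#' 4 with range 3-5, private sector 5 with range 4-6), the conventional way
#' of expressing the uncertainty of the calibrated factor.
#'
#' @param hosp_corrected Miscarriage-corrected hospitalizations, ages 10-49.
#' @param factor Point correction factor.
#' @param factor_ll,factor_ul Bounding factors; default `factor` minus/plus 1.
#' @return Named numeric vector `point`, `ll`, `ul`.
#' @examples
#' estimate_abortions(117182, 4)  # 468728 (351546 / 585910)
#' @export
estimate_abortions <- function(hosp_corrected, factor,
                               factor_ll = factor - 1,
                               factor_ul = factor + 1) {
  stopifnot(hosp_corrected >= 0, factor_ll <= factor, factor <= factor_ul)
  c(point = hosp_corrected * factor,
    ll = hosp_corrected * factor_ll,
    ul = hosp_corrected * factor_ul)
}

#' Split a national denominator panel into sector denominators
#'
#' The private-sector share of a denominator (female population 10-49, or
#' live births by maternal age) is the coverage-weighted sum over age
#' bands, rounded half-up once; the public-sector share is the remainder,
#' so the two sectors always add to the national total exactly.
#'
#' @param panel A panel `counts_table` (population or live births) on
#'   coarse bands.
#' @param band_coverage Named insurance-coverage proportions per coarse
#'   band; defaults to the published 2015 values 18% / 26% / 32% / 27%.
#' @return Named numeric vector `total`, `supp`, `sus`.
#' @export
sector_denominators <- function(panel,
                                band_coverage = c("10-19" = 0.18,
                                                  "20-29" = 0.26,
                                                  "30-39" = 0.32,
                                                  "40-49" = 0.27)) {
  stopifnot(inherits(panel, "counts_table"),
            all(band_coverage >= 0), all(band_coverage <= 1))
  bt <- band_totals(panel)
  missing_bands <- setdiff(names(bt), names(band_coverage))
  if (length(missing_bands) > 0) {
    stop("no coverage configured for band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  total <- sum(bt)
  supp <- round_half_up(sum(band_coverage[names(bt)] * bt))
  c(total = total, supp = supp, sus = total - supp)
}

#' Induced abortion rate per 1,000 women of reproductive age
#'
#' @param abortions Estimated abortions (scalar or vector, e.g. point/LL/UL).
#' @param population Female population aged 10-49; must be positive.
#' @param digits Half-up rounding decimals (default 1, as published).
#' @return Rate(s) per 1,000 women.
#' @export
abortion_rate <- function(abortions, population, digits = 1) {
  if (any(population <= 0)) {
    stop("abortion rate undefined: population must be positive",
         call. = FALSE)
  }
  round_half_up(abortions / population * 1000, digits)
}

#' Induced abortion ratio per 100 live births
#'
#' @param abortions Estimated abortions (scalar or vector).
#' @param live_births Live births; must be positive.
#' @param digits Half-up rounding decimals (default 1).
#' @return Ratio(s) per 100 live births.
#' @export
abortion_ratio <- function(abortions, live_births, digits = 1) {
  if (any(live_births <= 0)) {
    stop("abortion ratio undefined: live births must be positive",
         call. = FALSE)
  }
  round_half_up(abortions / live_births * 100, digits)
}

sector_result_row <- function(sector, hosp, hosp_corrected, factor,
                              factor_ll, factor_ul, ab, population,
                              births) {
  tibble::tibble(
    sector = sector,
    hospitalizations = hosp,
    hosp_corrected = hosp_corrected,
    factor = factor, factor_ll = factor_ll, factor_ul = factor_ul,
    abortions = ab[["point"]],
    abortions_ll = ab[["ll"]], abortions_ul = ab[["ul"]],
    population = population, live_births = births,
    rate = abortion_rate(ab[["point"]], population),
    rate_ll = abortion_rate(ab[["ll"]], population),
    rate_ul = abortion_rate(ab[["ul"]], population),
    ratio = abortion_ratio(ab[["point"]], births),
    ratio_ll = abortion_ratio(ab[["ll"]], births),
    ratio_ul = abortion_ratio(ab[["ul"]], births))
}

#' Abortion estimates, rates and ratios per sector and total
#'
#' Combines corrected hospitalization totals, correction factors with
#' ranges, and sector denominators into the final indicator table: one row
#' per sector plus a total row whose abortion numbers (point, LL, UL) are
#' the exact sums of the sector rows.
#'
#' @param hosp_sus,hosp_supp Selected hospitalizations (10-49) per sector.
#' @param corr_sus,corr_supp Miscarriage-corrected hospitalizations.
#' @param factors List with `sus = c(point, ll, ul)` and `supp = likewise`;
#'   default `list(sus = c(4, 3, 5), supp = c(5, 4, 6))`.
#' @param pop,births Named vectors from [sector_denominators()].
#' @return A tibble with rows `sus`, `supp`, `total`.
#' @export
estimate_result <- function(hosp_sus, hosp_supp, corr_sus, corr_supp,
                            factors = list(sus = c(4, 3, 5),
                                           supp = c(5, 4, 6)),
                            pop, births) {
  ab_sus <- estimate_abortions(corr_sus, factors$sus[1], factors$sus[2],
                               factors$sus[3])
  ab_supp <- estimate_abortions(corr_supp, factors$supp[1], factors$supp[2],
                                factors$supp[3])
  ab_tot <- ab_sus + ab_supp
  dplyr::bind_rows(
    sector_result_row("sus", hosp_sus, corr_sus, factors$sus[1],
                      factors$sus[2], factors$sus[3], ab_sus,
                      pop[["sus"]], births[["sus"]]),
    sector_result_row("supp", hosp_supp, corr_supp, factors$supp[1],
                      factors$supp[2], factors$supp[3], ab_supp,
                      pop[["supp"]], births[["supp"]]),
    sector_result_row("total", hosp_sus + hosp_supp, corr_sus + corr_supp,
                      NA_real_, NA_real_, NA_real_, ab_tot,
                      pop[["total"]], births[["total"]]))
}

#' Run the whole estimation pipeline from a configuration
#'
#' Executes, in order: case selection in the public and private microdata,
#' miscarriage correction per sector, (optionally) the scenario suite
#' calibrating the non-hospitalization factor, the estimation equation with
#' bounds, and the rate/ratio indicators. Any stage failure aborts with the
#' stage name.
#'
#' @param config A configuration list from [run_config()] or
#'   [read_run_config()].
#' @return A list: `estimates` (the indicator tibble), `scenarios` (tibble
#'   or `NULL`), `selection` (the per-sector counts tables), `coverage`,
#'   and `log` (parameters of the run).
#' @export
full_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  rule <- config$rule %||% selection_rule()
  factors <- config$miscarriage_factors %||% miscarriage_factors()

  sus_records <- stage("read_sus",
                       read_table_file(config$paths$sus, "sus_admissions"))
  ans_cons <- stage("read_ans_cons",
                    read_table_file(config$paths$ans_cons, "ans_cons"))
  ans_det <- stage("read_ans_det",
                   read_table_file(config$paths$ans_det, "ans_det"))
  population <- stage("read_population",
                      read_table_file(config$paths$population, "panel",
                                      kind = "population"))
  beneficiaries <- stage("read_beneficiaries",
                         read_table_file(config$paths$beneficiaries, "panel",
                                         kind = "beneficiaries"))
  births <- stage("read_births",
                  read_table_file(config$paths$births, "panel",
                                  kind = "live_births"))

  sus_counts <- stage("select_sus",
                      select_sus(sus_records, rule, config$year,
                                 config$age_range))
  events <- stage("link_ans", link_ans(ans_cons, ans_det, rule))
  ans_fine <- stage("select_ans", select_ans(events, rule, "fine"))
  ans_counts <- coarsen_counts(ans_fine)

  # the headline run is national: correct summed counts, not region cells
  sus_corr_in <- if (isTRUE(config$aggregate_regions %||% TRUE)) {
    aggregate_regions(sus_counts)
  } else {
    sus_counts
  }
  ans_corr_in <- if (isTRUE(config$aggregate_regions %||% TRUE)) {
    aggregate_regions(ans_counts)
  } else {
    ans_counts
  }
  corr_sus <- stage("miscarriage",
                    apply_miscarriage(sus_corr_in, factors, config$rounding))
  corr_supp <- stage("miscarriage",
                     apply_miscarriage(ans_corr_in, factors, config$rounding))

  cov <- stage("coverage", compute_coverage(beneficiaries, population))

  scenarios <- NULL
  if (isTRUE(config$run_scenarios)) {
    surv <- stage("survey_ages",
                  restrict_to_survey_ages(sus_records, ans_fine, factors,
                                          config$share_18_19, config$year,
                                          rule))
    scenarios <- stage("scenarios",
                       scenario_suite(config$scenarios %||%
                                        canonical_scenarios(),
                                      surv$hosp_sus_18_39,
                                      surv$hosp_supp_18_39))
  }

  pop_split <- stage("denominators",
                     sector_denominators(population, config$band_coverage))
  births_split <- stage("denominators",
                        sector_denominators(births, config$band_coverage))

  estimates <- stage("estimation",
                     estimate_result(counts_total(sus_counts),
                                     counts_total(ans_counts),
                                     counts_total(corr_sus),
                                     counts_total(corr_supp),
                                     config$factors, pop_split, births_split))
  list(estimates = estimates, scenarios = scenarios,
       selection = list(sus = sus_counts, ans = ans_counts,
                        ans_fine = ans_fine),
       coverage = cov,
       log = list(year = config$year, age_range = config$age_range,
                  rounding = config$rounding,
                  share_18_19 = config$share_18_19,
                  factors = config$factors,
                  miscarriage_factors = factors,
                  band_coverage = config$band_coverage,
                  n_unlinkable = attr(events, "n_unlinkable")))
}
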