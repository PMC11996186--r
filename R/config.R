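#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline in one validated list. The
#' defaults reproduce the published 2015 national run: year 2015, ages
#' 10-49, half-up rounding at each printed intermediate, miscarriage
#' factors 0.90/0.90/0.85/0.75, non-hospitalization factors 4 (range 3-5,
#' public) and 5 (range 4-6, private), coverage-by-band denominator split
#' 18/26/32/27%, and a 75% share of 15-19 private admissions at ages 18-19.
#'
#' @param paths Named list of input CSV paths: `sus`, `ans_cons`, `ans_det`,
#'   `population`, `beneficiaries`, `births`.
#' @param year Calendar year of the run.
#' @param age_range Inclusive age limits for case selection.
#' @param rounding `"half_up"` (table-compatible) or `"none"` (exact).
#' @param share_18_19 See [restrict_to_survey_ages()].
#' @param band_coverage See [sector_denominators()].
#' @param factors Non-hospitalization factors per sector,
#'   `list(sus = c(point, ll, ul), supp = c(point, ll, ul))`.
#' @param miscarriage_factors See [miscarriage_factors()].
#' @param rule A [selection_rule()].
#' @param aggregate_regions Collapse regions before the miscarriage
#'   correction (the national, published computation; default `TRUE`).
#'   With `FALSE`, corrections round region by region.
#' @param run_scenarios Run the calibration scenario suite as part of
#'   [full_pipeline()]?
#' @param scenarios Optional list of [scenario_spec()]s (defaults to
#'   [canonical_scenarios()]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(paths = list(), year = 2015, age_range = c(10, 49),
                       rounding = c("half_up", "none"), share_18_19 = 0.75,
                       band_coverage = c("10-19" = 0.18, "20-29" = 0.26,
                                         "30-39" = 0.32, "40-49" = 0.27),
                       factors = list(sus = c(4, 3, 5), supp = c(5, 4, 6)),
                       miscarriage_factors = NULL, rule = NULL,
                       aggregate_regions = TRUE,
                       run_scenarios = TRUE, scenarios = NULL) {
  rounding <- match.arg(rounding)
  stopifnot(is.list(paths), length(age_range) == 2,
            age_range[1] <= age_range[2],
            share_18_19 >= 0, share_18_19 <= 1,
            all(band_coverage >= 0), all(band_coverage <= 1))
  for (s in c("sus", "supp")) {
    f <- factors[[s]]
    if (!is.numeric(f) || length(f) != 3 || f[2] > f[1] || f[1] > f[3]) {
      stop(sprintf("factors$%s must be c(point, ll, ul) with ll <= point <= ul",
                   s), call. = FALSE)
    }
  }
  structure(list(paths = paths, year = as.integer(year),
                 age_range = age_range, rounding = rounding,
                 share_18_19 = share_18_19, band_coverage = band_coverage,
                 factors = factors,
                 miscarriage_factors = miscarriage_factors, rule = rule,
                 aggregate_regions = aggregate_regions,
                 run_scenarios = run_scenarios, scenarios = scenarios),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; `paths` entries
#' are resolved relative to the YAML file's directory. Unknown keys are an
#' error, so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("paths", "year", "age_range", "rounding", "share_18_19",
             "band_coverage", "factors", "miscarriage_factors",
             "aggregate_regions", "run_scenarios")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  paths <- lapply(raw$paths %||% list(), function(p) {
    if (file.exists(p)) p else file.path(base, p)
  })
  args <- list(paths = paths)
  if (!is.null(raw$year)) args$year <- raw$year
  if (!is.null(raw$age_range)) args$age_range <- unlist(raw$age_range)
  if (!is.null(raw$rounding)) args$rounding <- raw$rounding
  if (!is.null(raw$share_18_19)) args$share_18_19 <- raw$share_18_19
  if (!is.null(raw$band_coverage)) {
    args$band_coverage <- unlist(raw$band_coverage)
  }
  if (!is.null(raw$factors)) {
    args$factors <- lapply(raw$factors, unlist)
  }
  if (!is.null(raw$miscarriage_factors)) {
    args$miscarriage_factors <-
      miscarriage_factors(unlist(raw$miscarriage_factors))
  }
  if (!is.null(raw$aggregate_regions)) {
    args$aggregate_regions <- raw$aggregate_regions
  }
  if (!is.null(raw$run_scenarios)) args$run_scenarios <- raw$run_scenarios
  do.call(run_config, args)
}
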