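#' Packaged national margins for Brazil, 2015
#'
#' The package ships the cleanly legible national aggregates of the 2015
#' Brazilian run as plain-CSV fixtures: public-sector (SIH/SUS) abortion
#' admissions by state and decade band; private-insurance (ANS) abortion
#' events by decade band, both the ICD-only and the ICD-and/or-procedure
#' selections; female population and insurance beneficiaries by decade band;
#' and a births-by-maternal-age panel. The births panel is synthetic: only
#' the sector totals of live births are published, so the by-band panel was
#' back-solved to be consistent with them under the published
#' coverage-by-band split (hence the `_synthetic` filename).
#'
#' @return `brazil_margins_2015()`: a named list of [counts_table()]s
#'   (`sus`, `ans_icd`, `ans_total`, `population`, `beneficiaries`,
#'   `births`).
#' @export
brazil_margins_2015 <- function() {
  rd <- function(file, kind) {
    suppressMessages(read_table_file(aicm_extdata(file), "counts",
                                     kind = kind))
  }
  list(
    sus = rd("sih_abortion_margins_2015.csv", "sus_admissions"),
    ans_icd = rd("ans_abortion_margins_icd_2015.csv", "ans_icd_only"),
    ans_total = rd("ans_abortion_margins_total_2015.csv",
                   "ans_icd_or_procedure"),
    population = rd("population_2015.csv", "population"),
    beneficiaries = rd("beneficiaries_2015.csv", "beneficiaries"),
    births = rd("births_by_age_2015_synthetic.csv", "live_births")
  )
}

#' Path to a packaged fixture file
#' @param file File name under the package's `extdata/` directory.
#' @return Absolute path.
#' @export
aicm_extdata <- function(file = "") {
  path <- system.file("extdata", file, package = "aicm", mustWork = FALSE)
  if (path == "") {
    stop("fixture not found in installed package: ", file, call. = FALSE)
  }
  path
}
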