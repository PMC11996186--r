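#' Ratio of ICD-and/or-procedure to ICD-only selections
#'
#' Quantifies how much the procedure codes add on top of the (underreported)
#' ICD-10 diagnosis in the private-insurance data; 1 decimal, as published.
#'
#' @param table_both `counts_table` from the `"icd_or_procedure"` selection.
#' @param table_icd `counts_table` from the `"icd_only"` selection.
#' @inherit counts_ratio return
#' @export
icd_procedure_ratio <- function(table_both, table_icd) {
  counts_ratio(table_both, table_icd, digits = 1)
}

#' Health-insurance coverage by region and age band
#'
#' Cellwise beneficiaries / population. National per-band and overall
#' proportions come from summed numerators and denominators, never from
#' averaging percentages. When several monthly beneficiary snapshots are
#' supplied, take their cellwise median first (see [median_panel()]).
#'
#' @param beneficiaries,population Panel `counts_table`s on the same index.
#' @return A list: `cells` tibble with `coverage` in `[0, 1]`, `by_band`
#'   national coverage per band, and scalar `overall`.
#' @export
compute_coverage <- function(beneficiaries, population) {
  stopifnot(inherits(beneficiaries, "counts_table"),
            inherits(population, "counts_table"))
  j <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(beneficiaries), beneficiaries = "count"),
    dplyr::rename(tibble::as_tibble(population), population = "count"),
    by = c("region", "age_band"))
  j$beneficiaries[is.na(j$beneficiaries)] <- 0
  j$population[is.na(j$population)] <- 0
  bad <- j$population == 0 & j$beneficiaries > 0
  if (any(bad)) {
    stop("beneficiaries exceed population (population 0) in stratum: ",
         paste(j$region[bad], j$age_band[bad], sep = "/", collapse = ", "),
         call. = FALSE)
  }
  if (any(j$beneficiaries > j$population)) {
    stop("beneficiaries exceed population in at least one stratum",
         call. = FALSE)
  }
  j$coverage <- ifelse(j$population > 0, j$beneficiaries / j$population, 0)
  nb <- dplyr::summarise(dplyr::group_by(j, .data$age_band),
                         beneficiaries = sum(.data$beneficiaries),
                         population = sum(.data$population), .groups = "drop")
  nb$coverage <- nb$beneficiaries / nb$population
  list(cells = j, by_band = nb,
       overall = sum(j$beneficiaries) / sum(j$population))
}

#' Cellwise median of monthly panel snapshots
#'
#' Beneficiary counts are published monthly; the coverage denominator uses
#' the median of the available snapshots (with a single snapshot the value
#' is used directly).
#'
#' @param panels A list of panel `counts_table`s on the same index.
#' @return A `counts_table` of cellwise medians.
#' @export
median_panel <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1)
  if (length(panels) == 1) return(panels[[1]])
  long <- dplyr::bind_rows(lapply(panels, tibble::as_tibble))
  med <- dplyr::summarise(dplyr::group_by(long, .data$region, .data$age_band),
                          count = stats::median(.data$count),
                          .groups = "drop")
  counts_table(med, kind = attr(panels[[1]], "kind"))
}

#' Legacy coverage-factor estimate of private-sector hospitalizations
#'
#' Before claims data were available, private-sector abortion
#' hospitalizations were estimated by scaling public-sector counts by
#' insurance coverage, stratum by stratum. Reproduced here for comparison
#' against the reported claims counts.
#'
#' @param sus_counts Public-sector admissions `counts_table`.
#' @param coverage Output of [compute_coverage()] on the same index.
#' @param rounding `"half_up"` rounds each cell to an integer before any
#'   summation (the table-compatible mode); `"none"` keeps full precision.
#' @return A `counts_table` of estimated private-sector admissions.
#' @export
legacy_private_estimate <- function(sus_counts, coverage,
                                    rounding = c("half_up", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(sus_counts, "counts_table"))
  cov <- coverage$cells[c("region", "age_band", "coverage")]
  j <- dplyr::left_join(tibble::as_tibble(sus_counts), cov,
                        by = c("region", "age_band"))
  if (anyNA(j$coverage)) {
    stop("coverage missing for stratum: ",
         paste(j$region[is.na(j$coverage)], j$age_band[is.na(j$coverage)],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  j$count <- apply_rounding(j$count * j$coverage, 0, rounding)
  counts_table(j[c("region", "age_band", "count")],
               kind = "legacy_private_estimate")
}

#' Ratio of coverage-estimated to reported private-sector admissions
#'
#' @param estimated `counts_table` from [legacy_private_estimate()].
#' @param reported `counts_table` of reported claims admissions.
#' @inherit counts_ratio return
#' @export
estimated_reported_ratio <- function(estimated, reported) {
  counts_ratio(estimated, reported, digits = 2)
}
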