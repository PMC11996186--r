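#' Case-selection rule for abortion hospitalizations
#'
#' Abortion-outcome admissions are identified by the ICD-10 categories
#' O03-O08 in any diagnosis field. O00-O02 (ectopic pregnancy, molar
#' pregnancy, abnormal products of conception) are not induced-abortion
#' outcomes: they are never included, and in the private-insurance selection
#' any event carrying one is excluded outright. Because insurers
#' underreport the ICD-10, private events can alternatively be detected by
#' post-abortion procedures: manual vacuum aspiration (31309020 after
#' abortion, 31303013) and curettage after abortion (31309062).
#'
#' @param include_categories ICD-10 categories that identify an abortion
#'   admission (default `"O03"`-`"O08"`).
#' @param exclude_categories Categories that disqualify an event
#'   (default `"O00"`-`"O02"`).
#' @param procedure_codes Abortion-related procedure codes, compared as
#'   exact 8-digit strings after trimming whitespace.
#' @param mode `"icd_only"` counts events identified by diagnosis alone;
#'   `"icd_or_procedure"` also counts events identified by procedure.
#' @param sus_apply_exclusion If `TRUE`, the public-sector selection also
#'   drops records carrying an excluded category. The default `FALSE`
#'   mirrors the published procedure, which states the exclusion only for
#'   the private-insurance selection.
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(include_categories = sprintf("O%02d", 3:8),
                           exclude_categories = sprintf("O%02d", 0:2),
                           procedure_codes = c("31309020", "31303013",
                                               "31309062"),
                           mode = c("icd_or_procedure", "icd_only"),
                           sus_apply_exclusion = FALSE) {
  mode <- match.arg(mode)
  include_categories <- toupper(include_categories)
  exclude_categories <- toupper(exclude_categories)
  if (length(intersect(include_categories, exclude_categories)) > 0) {
    stop("include and exclude ICD category sets must be disjoint",
         call. = FALSE)
  }
  structure(list(include_categories = include_categories,
                 exclude_categories = exclude_categories,
                 procedure_codes = trimws(procedure_codes),
                 mode = mode,
                 sus_apply_exclusion = sus_apply_exclusion),
            class = "selection_rule")
}

diag_category_matrix <- function(df, cols) {
  vapply(cols, function(col) icd_category(df[[col]]), character(nrow(df)))
}

#' Select abortion hospitalizations in public-sector admission records
#'
#' A record is counted if its year matches, the woman's age is within
#' `age_range`, and at least one of the five diagnosis fields carries an
#' included ICD-10 category. The unit is the hospitalization (one AIH
#' record), as in the source system.
#'
#' @param records Validated `sus_admissions` tibble (see [read_table_file()]).
#' @param rule A [selection_rule()].
#' @param year Calendar year to keep.
#' @param age_range Inclusive age limits, default `c(10, 49)`.
#' @return A [counts_table()] of selected admissions by region and coarse
#'   age band; empty input gives an all-zero table.
#' @export
select_sus <- function(records, rule = selection_rule(), year = 2015,
                       age_range = c(10, 49)) {
  stopifnot(inherits(rule, "selection_rule"), length(age_range) == 2)
  keep <- records$year == year &
    records$age >= age_range[1] & records$age <= age_range[2]
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) {
    return(empty_counts(character(0)))
  }
  cats <- diag_category_matrix(records, paste0("diag", 1:5))
  has_incl <- rowSums(matrix(cats %in% rule$include_categories,
                             nrow = nrow(records))) > 0
  sel <- has_incl
  if (isTRUE(rule$sus_apply_exclusion)) {
    has_excl <- rowSums(matrix(cats %in% rule$exclude_categories,
                               nrow = nrow(records))) > 0
    sel <- sel & !has_excl
  }
  records <- records[sel, , drop = FALSE]
  tab <- tibble::tibble(region = records$region,
                        age_band = age_to_band(records$age, "coarse"),
                        count = 1)
  if (nrow(tab) == 0) return(empty_counts(character(0)))
  counts_table(tab, kind = "sus_admissions")
}

empty_counts <- function(regions, granularity = "coarse") {
  bands <- if (granularity == "coarse") coarse_bands else fine_bands
  if (length(regions) == 0) regions <- "none"
  counts_table(tidyr::expand_grid(region = regions, age_band = bands,
                                  count = 0),
               kind = "empty")
}

#' Link consolidated and detail private-insurance records into care events
#'
#' Consolidated (diagnosis) and detail (procedure) rows are joined on the
#' care-event identifier so that a woman with both an abortion ICD-10 and an
#' abortion procedure is counted once. Detail rows whose event never appears
#' in the consolidated table have no region or age band; they are retained
#' with both set to `NA`, flagged, and reported in the `n_unlinkable`
#' attribute — downstream tabulations exclude them.
#'
#' @param cons Validated `ans_cons` tibble.
#' @param det Validated `ans_det` tibble.
#' @param rule A [selection_rule()].
#' @return One row per distinct `event_id` with logical flags
#'   `has_abortion_icd`, `has_excluded_icd`, `has_abortion_procedure`, plus
#'   `region` and fine `age_band`; attribute `n_unlinkable` counts
#'   detail-only events.
#' @export
link_ans <- function(cons, det, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"))
  cats <- if (nrow(cons) > 0) {
    diag_category_matrix(cons, paste0("icd", 1:4))
  } else {
    matrix(character(0), nrow = 0, ncol = 4)
  }
  in_set <- function(m, set) {
    rowSums(matrix(!is.na(m) & m %in% set, nrow = nrow(m))) > 0
  }
  cons_flags <- tibble::tibble(
    event_id = cons$event_id,
    region = cons$region,
    age_band = cons$age_band,
    has_abortion_icd = in_set(cats, rule$include_categories),
    has_excluded_icd = in_set(cats, rule$exclude_categories)
  )
  # several CONS rows may share an event: any-field semantics over the event
  cons_ev <- dplyr::summarise(
    dplyr::group_by(cons_flags, .data$event_id),
    region = dplyr::first(.data$region),
    age_band = dplyr::first(.data$age_band),
    has_abortion_icd = any(.data$has_abortion_icd),
    has_excluded_icd = any(.data$has_excluded_icd),
    .groups = "drop"
  )
  det_ev <- dplyr::summarise(
    dplyr::group_by(det, .data$event_id),
    has_abortion_procedure = any(trimws(.data$procedure_code) %in%
                                   rule$procedure_codes),
    .groups = "drop"
  )
  events <- dplyr::full_join(cons_ev, det_ev, by = "event_id")
  events$has_abortion_icd[is.na(events$has_abortion_icd)] <- FALSE
  events$has_excluded_icd[is.na(events$has_excluded_icd)] <- FALSE
  events$has_abortion_procedure[is.na(events$has_abortion_procedure)] <- FALSE
  n_unlinkable <- sum(is.na(events$region))
  if (n_unlinkable > 0) {
    message(sprintf(
      "link_ans: %d detail-only event(s) without a consolidated record; %s",
      n_unlinkable, "kept with unknown stratum, excluded from tabulations"))
  }
  structure(events, n_unlinkable = n_unlinkable)
}

#' Count abortion care events by region and age band
#'
#' In `"icd_only"` mode an event is counted if it carries an abortion
#' ICD-10; in `"icd_or_procedure"` mode, if it carries an abortion ICD-10 or
#' an abortion procedure. Either way an event with an excluded category
#' (O00-O02) is never counted. Events with an unknown stratum (detail-only)
#' are excluded.
#'
#' @param events Output of [link_ans()].
#' @param rule A [selection_rule()]; its `mode` selects the counting rule.
#' @param granularity Band granularity of the returned table: `"coarse"`
#'   (default, the published layout) or `"fine"` (needed for the
#'   survey-age restriction of the calibration step).
#' @return A [counts_table()]; empty input gives an all-zero table.
#' @export
select_ans <- function(events, rule = selection_rule(),
                       granularity = c("coarse", "fine")) {
  stopifnot(inherits(rule, "selection_rule"))
  granularity <- match.arg(granularity)
  eligible <- !events$has_excluded_icd & !is.na(events$region)
  counted <- if (rule$mode == "icd_only") {
    eligible & events$has_abortion_icd
  } else {
    eligible & (events$has_abortion_icd | events$has_abortion_procedure)
  }
  events <- events[counted, , drop = FALSE]
  if (nrow(events) == 0) return(empty_counts(character(0), granularity))
  band <- if (granularity == "coarse") {
    fine_to_coarse(events$age_band)
  } else {
    events$age_band
  }
  counts_table(tibble::tibble(region = events$region, age_band = band,
                              count = 1),
               kind = paste0("ans_", rule$mode))
}

#' Cellwise ratio of two counts tables
#'
#' Used both for the ICD-and/or-procedure vs ICD-only comparison and for the
#' estimated vs reported comparison of the legacy coverage estimator.
#' National (per-band and overall) ratios are computed from summed counts,
#' never by averaging cell ratios. Cells with a zero denominator are
#' undefined (`NA`), mirroring the "-" cells of the published tables —
#' they are data, not errors.
#'
#' @param numerator,denominator `counts_table`s on the same index.
#' @param digits Decimals for half-up rounding of the ratios (default 1).
#' @return A list: `cells` (tibble with `ratio`), `by_band` and `total`
#'   national ratios.
#' @export
counts_ratio <- function(numerator, denominator, digits = 1) {
  stopifnot(inherits(numerator, "counts_table"),
            inherits(denominator, "counts_table"))
  j <- dplyr::full_join(
    dplyr::rename(tibble::as_tibble(numerator), num = "count"),
    dplyr::rename(tibble::as_tibble(denominator), den = "count"),
    by = c("region", "age_band"))
  j$num[is.na(j$num)] <- 0
  j$den[is.na(j$den)] <- 0
  j$ratio <- ifelse(j$den > 0, round_half_up(j$num / j$den, digits), NA_real_)
  nb <- dplyr::summarise(dplyr::group_by(j, .data$age_band),
                         num = sum(.data$num), den = sum(.data$den),
                         .groups = "drop")
  nb$ratio <- ifelse(nb$den > 0, round_half_up(nb$num / nb$den, digits),
                     NA_real_)
  total <- if (sum(j$den) > 0) {
    round_half_up(sum(j$num) / sum(j$den), digits)
  } else {
    NA_real_
  }
  list(cells = j, by_band = nb, total = total)
}
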