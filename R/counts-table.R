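#' Region-by-age-band count tables
#'
#' The universal aggregate of the pipeline: a tibble with columns `region`,
#' `age_band` and `count`, one row per stratum, carrying its band
#' granularity as an attribute. Every selection, panel and estimate table is
#' one of these, so margins, aggregation and round-trips are defined once.
#'
#' @param x A data frame with columns `region`, `age_band`, `count` (or a
#'   named equivalent passed through `...`).
#' @param kind Optional label ("counts", "population", "beneficiaries",
#'   "live_births") recorded as an attribute.
#' @return A tibble of class `counts_table`.
#' @export
counts_table <- function(x, kind = "counts") {
  stopifnot(is.data.frame(x))
  need <- c("region", "age_band", "count")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("counts table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[need]
  x$region <- as.character(x$region)
  x$age_band <- as.character(x$age_band)
  x$count <- as.numeric(x$count)
  if (anyNA(x$count) || any(x$count < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  gran <- band_granularity(x$age_band)
  x <- dplyr::summarise(dplyr::group_by(x, .data$region, .data$age_band),
                        count = sum(.data$count), .groups = "drop")
  x <- dplyr::arrange(x, .data$region,
                      match(.data$age_band, band_levels(gran)))
  structure(x, class = c("counts_table", class(x)),
            granularity = gran, kind = kind)
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("<counts_table: %s, %s bands, total %s>\n",
              attr(x, "kind"), attr(x, "granularity"),
              format(counts_total(x), big.mark = ",")))
  NextMethod()
}

#' Grand total of a counts table
#' @param x A `counts_table`.
#' @return A single number, the sum over all strata.
#' @export
counts_total <- function(x) sum(x$count)

#' Row, column and grand margins of a counts table
#'
#' @param x A `counts_table`.
#' @return A list with tibbles `by_region`, `by_band` and scalar `total`;
#'   the grand total always equals the sum of the cells.
#' @export
counts_margins <- function(x) {
  list(
    by_region = dplyr::summarise(dplyr::group_by(x, .data$region),
                                 count = sum(.data$count), .groups = "drop"),
    by_band = dplyr::summarise(dplyr::group_by(x, .data$age_band),
                               count = sum(.data$count), .groups = "drop"),
    total = counts_total(x)
  )
}

#' Aggregate a fine-band counts table onto coarse (decade) bands
#'
#' Totals are preserved exactly: fine bands nest inside coarse bands.
#'
#' @param x A `counts_table` on fine or coarse bands.
#' @return A `counts_table` on coarse bands.
#' @export
coarsen_counts <- function(x) {
  stopifnot(inherits(x, "counts_table"))
  if (attr(x, "granularity") == "coarse") return(x)
  y <- dplyr::mutate(tibble::as_tibble(x),
                     age_band = fine_to_coarse(.data$age_band))
  counts_table(y, kind = attr(x, "kind"))
}

#' Collapse all regions of a counts table into one stratum per band
#'
#' The headline estimates are national: corrections and factors are applied
#' to summed counts, not region by region (rounding region cells first
#' would give slightly different totals).
#'
#' @param x A `counts_table`.
#' @param label Region label of the collapsed table.
#' @return A `counts_table` with a single region.
#' @export
aggregate_regions <- function(x, label = "all") {
  stopifnot(inherits(x, "counts_table"))
  y <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(x),
                                        .data$age_band),
                        count = sum(.data$count), .groups = "drop")
  y$region <- label
  counts_table(y, kind = attr(x, "kind"))
}

#' Named national vector of a counts table, one entry per band
#' @noRd
band_totals <- function(x) {
  m <- counts_margins(x)$by_band
  stats::setNames(m$count, m$age_band)
}

#' Write a counts table to CSV
#'
#' Plain UTF-8 CSV with columns `region`, `age_band`, `count`; re-reading
#' with [read_table_file()] (schema `"panel"` or `"counts"`) reproduces the
#' cells exactly.
#'
#' @param x A `counts_table`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x)[c("region", "age_band", "count")],
                   path)
  invisible(path)
}
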