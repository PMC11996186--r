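#' Reading and validating the tabular inputs
#'
#' All inputs are UTF-8 CSV with a header. A small schema registry maps the
#' source-specific column layouts onto the pipeline's domain types, so real
#' administrative exports can be adapted by renaming columns alone:
#'
#' * `sus_admissions`: `region, age, diag1..diag5, year` — one public-sector
#'   hospitalization (AIH) with up to five ICD-10 diagnosis fields (principal,
#'   secondary, death, associated, notification); empty string = field unused.
#' * `ans_cons`: `event_id, region, age_band, icd1..icd4, year` — one
#'   consolidated private-insurance care event with up to four ICD-10 fields.
#'   Insurers are not required to report the ICD-10, so a missing code is an
#'   explicit `NA`, distinct from an empty string.
#' * `ans_det`: `event_id, procedure_code` — one procedure row per event.
#' * `panel` / `counts`: `region, age_band, count` — region-by-band totals
#'   (population, beneficiaries, live births, or any aggregated counts).
#'
#' @name data_io
NULL

schema_registry <- list(
  sus_admissions = c("region", "age", "diag1", "diag2", "diag3", "diag4",
                     "diag5", "year"),
  ans_cons = c("event_id", "region", "age_band", "icd1", "icd2", "icd3",
               "icd4", "year"),
  ans_det = c("event_id", "procedure_code"),
  panel = c("region", "age_band", "count"),
  counts = c("region", "age_band", "count")
)

icd_pattern <- "^[A-Za-z][0-9]{2}[0-9]*$"

#' Extract the 3-character ICD-10 category of a code
#'
#' Case selection operates on 3-character ICD-10 categories (e.g. the
#' abortion-outcome block O03-O08), so subcoded records such as "O034" or
#' "O03.4" must match their category.
#'
#' @param code Character vector of ICD-10 codes; dots are ignored.
#' @return Uppercased 3-character categories; e.g. `"O034"` becomes `"O03"`.
#'   Codes shorter than 3 characters are an error.
#' @examples
#' icd_category(c("O034", "o06"))  # "O03" "O06"
#' @export
icd_category <- function(code) {
  stopifnot(is.character(code))
  code <- gsub(".", "", code, fixed = TRUE)
  bad <- !is.na(code) & nchar(code) > 0 & nchar(code) < 3
  if (any(bad)) {
    stop("invalid ICD-10 code(s), shorter than a 3-character category: ",
         paste(unique(code[bad]), collapse = ", "), call. = FALSE)
  }
  out <- toupper(substr(code, 1, 3))
  out[!is.na(code) & code == ""] <- ""
  out
}

check_schema <- function(df, schema_kind, path) {
  expected <- schema_registry[[schema_kind]]
  if (is.null(expected)) {
    stop("unknown schema kind: ", schema_kind, call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: header does not match schema '%s'; missing column(s): %s",
                 path, schema_kind, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df[expected]
}

validate_or_abort <- function(problems, path) {
  if (length(problems) > 0) {
    stop(sprintf("%s: %d invalid record(s):\n%s", path, length(problems),
                 paste(utils::head(problems, 10), collapse = "\n")),
         call. = FALSE)
  }
}

#' Read one of the pipeline's tabular inputs
#'
#' @param path Path to a CSV file.
#' @param schema_kind One of `"sus_admissions"`, `"ans_cons"`, `"ans_det"`,
#'   `"panel"`, `"counts"` (see [data_io]).
#' @param kind For panel schemas, the panel kind recorded on the result
#'   (`"population"`, `"beneficiaries"`, `"live_births"`, or `"counts"`).
#' @return Validated typed records as a tibble; panel/counts schemas return a
#'   [counts_table()]. Any unparseable age, band or code aborts the run with
#'   a record-level error list naming the offending rows.
#' @export
read_table_file <- function(path, schema_kind, kind = schema_kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  df <- check_schema(df, schema_kind, path)
  out <- switch(
    schema_kind,
    sus_admissions = validate_sus(df, path),
    ans_cons = validate_ans_cons(df, path),
    ans_det = validate_ans_det(df, path),
    panel = ,
    counts = {
      df$count <- suppressWarnings(as.numeric(df$count))
      bad <- which(is.na(df$count) | df$count < 0)
      validate_or_abort(
        sprintf("row %d: count is missing, non-numeric or negative", bad),
        path)
      counts_table(df, kind = kind)
    }
  )
  message(sprintf("read %s: %d rows [%s]", path, nrow(out), schema_kind))
  out
}

validate_sus <- function(df, path) {
  problems <- character()
  age <- suppressWarnings(as.integer(df$age))
  bad_age <- which(is.na(age) | age < 0 | age > 120)
  problems <- c(problems,
                sprintf("row %d: age '%s' is not an integer in [0, 120]",
                        bad_age, df$age[bad_age]))
  year <- suppressWarnings(as.integer(df$year))
  problems <- c(problems,
                sprintf("row %d: year '%s' is not an integer",
                        which(is.na(year)), df$year[is.na(year)]))
  for (col in paste0("diag", 1:5)) {
    v <- df[[col]]
    v[is.na(v)] <- ""
    v <- gsub(".", "", trimws(v), fixed = TRUE)
    bad <- which(v != "" & !grepl(icd_pattern, v))
    problems <- c(problems,
                  sprintf("row %d: %s '%s' is not a valid ICD-10 code",
                          bad, col, v[bad]))
    df[[col]] <- toupper(v)
  }
  validate_or_abort(problems, path)
  tibble::tibble(region = df$region, age = age,
                 diag1 = df$diag1, diag2 = df$diag2, diag3 = df$diag3,
                 diag4 = df$diag4, diag5 = df$diag5, year = year)
}

validate_ans_cons <- function(df, path) {
  problems <- character()
  bad_id <- which(is.na(df$event_id) | df$event_id == "")
  problems <- c(problems, sprintf("row %d: empty event_id", bad_id))
  bad_band <- which(!(df$age_band %in% fine_bands))
  problems <- c(problems,
                sprintf("row %d: age_band '%s' is not a 5-year band",
                        bad_band, df$age_band[bad_band]))
  year <- suppressWarnings(as.integer(df$year))
  problems <- c(problems,
                sprintf("row %d: year '%s' is not an integer",
                        which(is.na(year)), df$year[is.na(year)]))
  for (col in paste0("icd", 1:4)) {
    v <- gsub(".", "", trimws(df[[col]]), fixed = TRUE)
    # NA = insurer did not report an ICD; distinct from "" (field unused)
    bad <- which(!is.na(v) & v != "" & !grepl(icd_pattern, v))
    problems <- c(problems,
                  sprintf("row %d: %s '%s' is not a valid ICD-10 code",
                          bad, col, v[bad]))
    df[[col]] <- toupper(v)
  }
  validate_or_abort(problems, path)
  tibble::tibble(event_id = df$event_id, region = df$region,
                 age_band = df$age_band,
                 icd1 = df$icd1, icd2 = df$icd2, icd3 = df$icd3,
                 icd4 = df$icd4, year = year)
}

validate_ans_det <- function(df, path) {
  problems <- character()
  bad_id <- which(is.na(df$event_id) | df$event_id == "")
  problems <- c(problems, sprintf("row %d: empty event_id", bad_id))
  code <- trimws(df$procedure_code)
  bad <- which(is.na(code) | !grepl("^[0-9]+$", code))
  problems <- c(problems,
                sprintf("row %d: procedure_code '%s' is not numeric",
                        bad, df$procedure_code[bad]))
  validate_or_abort(problems, path)
  tibble::tibble(event_id = df$event_id, procedure_code = code)
}
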