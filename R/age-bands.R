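#' Age bands used throughout the pipeline
#'
#' All tables in the pipeline are indexed by region and a five-year ("fine")
#' or ten-year ("coarse") age band covering women of reproductive age
#' (10-49 years). Fine bands nest exactly inside coarse bands, so aggregating
#' a fine-band table by decade always preserves totals.
#'
#' @format Character vectors of band labels, ordered by age.
#' @name age_bands
NULL

#' @rdname age_bands
#' @export
fine_bands <- c("10-14", "15-19", "20-24", "25-29",
                "30-34", "35-39", "40-44", "45-49")

#' @rdname age_bands
#' @export
coarse_bands <- c("10-19", "20-29", "30-39", "40-49")

#' @rdname age_bands
#' @export
miscarriage_bands <- c("10-29", "30-39", "40-49")

#' Map an integer age to its five- or ten-year band
#'
#' @param age Integer vector of ages in completed years.
#' @param granularity `"coarse"` (10-year bands, the default) or `"fine"`
#'   (5-year bands).
#' @return Character vector of band labels; `NA` for ages outside 10-49.
#' @examples
#' age_to_band(24)           # "20-29"
#' age_to_band(24, "fine")   # "20-24"
#' @export
age_to_band <- function(age, granularity = c("coarse", "fine")) {
  granularity <- match.arg(granularity)
  stopifnot(is.numeric(age))
  width <- if (granularity == "coarse") 10L else 5L
  bands <- if (granularity == "coarse") coarse_bands else fine_bands
  lo <- (as.integer(age) - 10L) %/% width
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= 10 & age <= 49
  out[ok] <- bands[lo[ok] + 1L]
  out
}

#' Map a fine band label onto its enclosing coarse band
#'
#' @param band Character vector of fine (or already-coarse) band labels.
#' @return Character vector of coarse band labels.
#' @export
fine_to_coarse <- function(band) {
  lut <- c(
    "10-14" = "10-19", "15-19" = "10-19",
    "20-24" = "20-29", "25-29" = "20-29",
    "30-34" = "30-39", "35-39" = "30-39",
    "40-44" = "40-49", "45-49" = "40-49",
    stats::setNames(coarse_bands, coarse_bands)
  )
  unknown <- setdiff(unique(band[!is.na(band)]), names(lut))
  if (length(unknown) > 0) {
    stop("unknown age band label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(lut[band])
}

band_granularity <- function(bands) {
  bands <- unique(bands[!is.na(bands)])
  if (all(bands %in% coarse_bands)) return("coarse")
  if (all(bands %in% fine_bands)) return("fine")
  if (all(bands %in% miscarriage_bands)) return("miscarriage")
  stop("age bands mix granularities or contain unknown labels",
       call. = FALSE)
}

band_levels <- function(granularity) {
  switch(granularity, coarse = coarse_bands, fine = fine_bands,
         miscarriage = miscarriage_bands)
}
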