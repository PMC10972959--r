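# Internal helpers shared across modules.

#' Normalize a free-text drug or indication name
#'
#' Upper-cases, folds runs of whitespace and punctuation to a single space,
#' and trims. FAERS drug names carry dosage/form suffixes
#' ("ZEPZELCA 4MG VIAL"), so cohort matching is substring-based on this
#' normalized form.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[[:punct:][:space:]]+", " ", x)
  trimws(x)
}

# Parse YYYYMMDD integers/strings to Date; partial (YYYY, YYYYMM) and
# malformed values give NA. Day-resolution arithmetic must use this.
parse_ymd <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
  }
  out
}

# TRUE where the string is a calendar-valid YYYYMMDD date.
is_full_date <- function(x) {
  !is.na(parse_ymd(x))
}

# Extract the 4-digit year from a (possibly partial) YYYYMMDD value.
# Works for YYYY, YYYYMM and YYYYMMDD; NA otherwise.
date_year <- function(x) {
  x <- trimws(as.character(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(substr(x[ok], 1L, 4L))
  out
}

# Convert age to years given FAERS age unit codes. Unknown units -> NA.
age_in_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(unit)))
  out <- rep(NA_real_, length(age))
  yr <- unit %in% c("YR", "YEAR", "YEARS", "")
  out[yr] <- age[yr]
  out[unit %in% c("MON", "MONTH", "MONTHS")] <- age[unit %in% c("MON", "MONTH", "MONTHS")] / 12
  out[unit %in% c("DY", "DAY", "DAYS")] <- age[unit %in% c("DY", "DAY", "DAYS")] / 365.25
  out[unit %in% c("DEC")] <- age[unit %in% c("DEC")] * 10
  out[unit %in% c("WK", "WEEK", "WEEKS")] <- age[unit %in% c("WK", "WEEK", "WEEKS")] * 7 / 365.25
  out
}

# Sentinel SOC for preferred terms absent from the event dictionary.
SENTINEL_SOC <- "Unmapped terms"

`%||%` <- function(a, b) if (is.null(a)) b else a

# round() in R does banker's rounding; reports use conventional
# half-up rounding so printed percentages match hand arithmetic.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
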