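#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr arrange bind_rows count desc distinct filter full_join
#'   group_by inner_join left_join mutate n pull rename row_number select
#'   semi_join slice summarise ungroup anti_join first
#' @importFrom tibble tibble as_tibble
#' @importFrom tidyr replace_na
#' @importFrom rlang .data %||% abort warn
#' @importFrom stats median rbinom rgeom rnorm rpois runif setNames uniroot
#' @importFrom utils head
NULL

# Valid category sets used across the package
.sex_levels <- c("male", "female", "unknown")
.role_levels <- c("suspect", "concomitant", "interacting")
.outcome_levels <- c("recovered", "recovering", "not_recovered", "fatal", "unknown")
.region_levels <- c("americas", "europe", "asia", "oceania", "africa", "unknown")
.age_levels <- c("<18", "18-44", "45-64", ">=65", "any")

#' Normalize a free-text drug name
#'
#' Lowercases, strips punctuation, and collapses whitespace so that FAERS-style
#' free-text drug names ("BRIUMVI.", "briumvi ") compare equal.
#'
#' @param x character vector of drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name(c("BRIUMVI.", " Ublituximab "))
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Resolve drug names through a synonym table
#'
#' @param x character vector of (raw or normalized) drug names.
#' @param synonyms two-column data frame (`alias`, `canonical`) mapping brand to
#'   generic names, or `NULL` for no mapping. Both sides are normalized before
#'   matching.
#' @return character vector of canonical normalized names.
#' @export
resolve_drug_name <- function(x, synonyms = NULL) {
  x <- normalize_drug_name(x)
  if (is.null(synonyms) || nrow(synonyms) == 0L) {
    return(x)
  }
  stopifnot(all(c("alias", "canonical") %in% names(synonyms)))
  alias <- normalize_drug_name(synonyms$alias)
  canonical <- normalize_drug_name(synonyms$canonical)
  hit <- match(x, alias)
  x[!is.na(hit)] <- canonical[hit[!is.na(hit)]]
  x
}

#' Round half away from zero
#'
#' Presentation rounding used by the TSV writers (base `round()` is
#' half-to-even); applied only at serialization, never to internal values.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a number to 2 decimals, half-up, "" for NA
fmt2 <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.2f", round_half_up(x, 2)))
  out
}

# Parse dates: full ISO-8601, plus FAERS partial dates YYYY / YYYYMM resolved
# to the first day of the period. Returns Date (NA for unparseable) and warns
# once per call listing the offending values.
parse_report_date <- function(x, warn_label = "date") {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "unknown")] <- NA_character_
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  ym8 <- !is.na(x) & grepl("^\\d{8}$", x)
  out[ym8] <- as.Date(x[ym8], format = "%Y%m%d")
  ym6 <- !is.na(x) & grepl("^\\d{6}$", x)
  out[ym6] <- as.Date(paste0(x[ym6], "01"), format = "%Y%m%d")
  y4 <- !is.na(x) & grepl("^\\d{4}$", x)
  out[y4] <- as.Date(paste0(x[y4], "0101"), format = "%Y%m%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "%d unparseable %s value(s) set to unknown (e.g. %s)",
      sum(bad), warn_label, paste(head(unique(x[bad]), 3), collapse = ", ")
    ))
  }
  out
}

# Convert ages to years given a unit code: yr (years), mon (months), dec (decades)
age_to_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- tolower(trimws(as.character(unit)))
  unit[is.na(unit) | unit == ""] <- "yr"
  mult <- c(yr = 1, mon = 1 / 12, dec = 10)[unit]
  mult[is.na(mult)] <- 1
  age * unname(mult)
}

#' Assign an age in years to the screening age bins
#'
#' Bins follow the stratified-analysis grouping: `<18`, `18-44`, `45-64`,
#' `>=65`, with inclusive boundaries (44.9 falls in `18-44`).
#'
#' @param age_years numeric vector; `NA` means unknown.
#' @return character vector of bin labels (`NA` preserved).
#' @export
age_bin <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "<18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 45] <- "18-44"
  out[!is.na(age_years) & age_years >= 45 & age_years < 65] <- "45-64"
  out[!is.na(age_years) & age_years >= 65] <- ">=65"
  out
}
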