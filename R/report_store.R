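#' Construct a spontaneous-report store
#'
#' A `report_store` is the package's container for a deduplicatable set of
#' spontaneous case reports, held in a FAERS-like relational layout: one
#' demographics row per report plus child tables of drug entries and reaction
#' entries, joined on (`report_id`, `case_version`).
#'
#' @param reports tibble with columns `report_id` (character),
#'   `case_version` (integer >= 1), `receipt_date` (Date), `sex`
#'   (`male`/`female`/`unknown`), `age_years` (numeric, `NA` = unknown),
#'   `region`, `serious` (logical), and optionally `weight` (positive numeric,
#'   default 1; used by aggregated pseudo-records from [replay_counts()]).
#' @param drugs tibble with columns `report_id`, `case_version`, `drug_name`,
#'   `role` (`suspect`/`concomitant`/`interacting`), `therapy_start` (Date,
#'   `NA` = unknown).
#' @param reactions tibble with columns `report_id`, `case_version`, `pt`,
#'   `onset_date` (Date, `NA` = unknown), `outcome`.
#' @param provenance free-text source label.
#' @return an object of class `report_store`.
#' @export
report_store <- function(reports, drugs, reactions, provenance = "unspecified") {
  reports <- as_tibble(reports)
  drugs <- as_tibble(drugs)
  reactions <- as_tibble(reactions)
  if (!"weight" %in% names(reports)) reports$weight <- 1
  reports$case_version <- as.integer(reports$case_version)
  drugs$case_version <- as.integer(drugs$case_version)
  reactions$case_version <- as.integer(reactions$case_version)
  if (!"drug_norm" %in% names(drugs)) {
    drugs$drug_norm <- normalize_drug_name(drugs$drug_name)
  }
  store <- structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         provenance = provenance),
    class = "report_store"
  )
  validate_report_store(store)
}

validate_report_store <- function(store) {
  r <- store$reports
  req <- c("report_id", "case_version", "receipt_date", "sex", "age_years",
           "region", "serious", "weight")
  missing_col <- setdiff(req, names(r))
  if (length(missing_col)) {
    abort(sprintf("reports table missing column(s): %s",
                  paste(missing_col, collapse = ", ")))
  }
  if (!all(r$sex %in% .sex_levels)) {
    abort("sex must be one of male/female/unknown")
  }
  known_age <- r$age_years[!is.na(r$age_years)]
  if (any(known_age < 0 | known_age > 120)) {
    abort("age_years, when known, must lie in [0, 120]")
  }
  if (any(r$weight <= 0)) abort("report weights must be positive")
  if (!all(store$drugs$role %in% .role_levels)) {
    abort("drug role must be one of suspect/concomitant/interacting")
  }
  if (any(!nzchar(store$drugs$drug_name))) abort("drug_name must be non-empty")
  if (any(!nzchar(store$reactions$pt))) abort("pt must be non-empty")
  key <- paste(r$report_id, r$case_version)
  if (anyDuplicated(key)) abort("duplicate (report_id, case_version) in reports")
  # every report must carry at least one drug and one reaction
  dkey <- unique(paste(store$drugs$report_id, store$drugs$case_version))
  rkey <- unique(paste(store$reactions$report_id, store$reactions$case_version))
  if (!all(key %in% dkey)) abort("every report needs at least one drug entry")
  if (!all(key %in% rkey)) abort("every report needs at least one reaction entry")
  store
}

#' @export
print.report_store <- function(x, ...) {
  cat(sprintf(
    "<report_store> %d reports (%s weighted), %d drug entries, %d reaction entries\n",
    nrow(x$reports), format(sum(x$reports$weight), big.mark = ","),
    nrow(x$drugs), nrow(x$reactions)
  ))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' Number of reports in a store
#' @param store a [report_store()].
#' @param weighted if `TRUE`, sum report weights instead of counting rows.
#' @return numeric count.
#' @export
n_reports <- function(store, weighted = FALSE) {
  if (weighted) sum(store$reports$weight) else nrow(store$reports)
}

flat_csv_columns <- c(
  "report_id", "case_version", "receipt_date", "sex", "age_years", "age_unit",
  "region", "serious", "drug_name", "drug_role", "therapy_start", "pt",
  "onset_date", "outcome"
)

#' Read spontaneous case reports
#'
#' Reads a case-report table into a [report_store()]. Two dialects are
#' supported: `flat_csv` (one row per report-drug-reaction combination, the
#' package's own interchange format) and `faers_ascii` (the quarterly FAERS
#' `$`-delimited DEMO/DRUG/REAC/THER/OUTC layout).
#'
#' Records with missing sex, age, region, or dates receive the explicit
#' `unknown` value (`NA` for numeric/date fields); they are never dropped.
#' Unparseable dates raise a record-level warning and become unknown.
#'
#' @param path for `flat_csv`, a CSV file; for `faers_ascii`, a directory
#'   containing `$`-delimited tables whose names start with `demo`, `drug`,
#'   `reac` (and optionally `ther`, `outc`).
#' @param dialect `"flat_csv"` or `"faers_ascii"`.
#' @return a [report_store()].
#' @export
read_reports <- function(path, dialect = c("flat_csv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat_csv") read_flat_csv(path) else read_faers_ascii(path)
}

read_flat_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- setdiff(flat_csv_columns, c("age_unit", "therapy_start", "onset_date",
                                          "outcome", "age_years", "region"))
  missing_col <- setdiff(required, names(raw))
  if (length(missing_col)) {
    abort(sprintf("flat_csv input missing mandatory column(s): %s",
                  paste(missing_col, collapse = ", ")))
  }
  for (opt in setdiff(flat_csv_columns, names(raw))) raw[[opt]] <- NA_character_
  if (nrow(raw) == 0L) {
    return(empty_store(provenance = path))
  }
  raw$case_version <- as.integer(raw$case_version)
  raw$case_version[is.na(raw$case_version)] <- 1L
  raw$sex <- ifelse(is.na(raw$sex) | !(raw$sex %in% .sex_levels), "unknown", raw$sex)
  raw$region <- ifelse(is.na(raw$region) | !(raw$region %in% .region_levels),
                       "unknown", raw$region)
  raw$outcome <- ifelse(is.na(raw$outcome) | !(raw$outcome %in% .outcome_levels),
                        "unknown", raw$outcome)
  raw$serious <- tolower(trimws(raw$serious)) %in% c("true", "t", "1", "yes", "y")
  reports <- raw |>
    mutate(age_years = age_to_years(.data$age_years, .data$age_unit),
           receipt_date = parse_report_date(.data$receipt_date, "receipt_date"),
           weight = if ("weight" %in% names(raw))
             replace_na(suppressWarnings(as.numeric(raw$weight)), 1) else 1) |>
    distinct(.data$report_id, .data$case_version, .keep_all = TRUE) |>
    select("report_id", "case_version", "receipt_date", "sex", "age_years",
           "region", "serious", "weight")
  drugs <- raw |>
    mutate(therapy_start = parse_report_date(.data$therapy_start, "therapy_start")) |>
    distinct(.data$report_id, .data$case_version, .data$drug_name,
             role = .data$drug_role, .data$therapy_start) |>
    filter(!is.na(.data$drug_name))
  drugs$role[is.na(drugs$role) | !(drugs$role %in% .role_levels)] <- "suspect"
  reactions <- raw |>
    mutate(onset_date = parse_report_date(.data$onset_date, "onset_date")) |>
    distinct(.data$report_id, .data$case_version, .data$pt, .data$onset_date,
             .data$outcome) |>
    filter(!is.na(.data$pt))
  report_store(reports, drugs, reactions, provenance = path)
}

empty_store <- function(provenance = "empty") {
  structure(
    list(
      reports = tibble(report_id = character(), case_version = integer(),
                       receipt_date = as.Date(character()), sex = character(),
                       age_years = numeric(), region = character(),
                       serious = logical(), weight = numeric()),
      drugs = tibble(report_id = character(), case_version = integer(),
                     drug_name = character(), role = character(),
                     therapy_start = as.Date(character()),
                     drug_norm = character()),
      reactions = tibble(report_id = character(), case_version = integer(),
                         pt = character(), onset_date = as.Date(character()),
                         outcome = character()),
      provenance = provenance
    ),
    class = "report_store"
  )
}

# FAERS quarterly ASCII layout: '$'-delimited tables joined on primaryid.
# Tolerates unknown extra columns; missing optional tables (THER/OUTC) are fine.
read_faers_ascii <- function(path) {
  if (!dir.exists(path)) abort(sprintf("directory not found: %s", path))
  find_tab <- function(prefix) {
    f <- list.files(path, pattern = paste0("^", prefix), ignore.case = TRUE,
                    full.names = TRUE)
    if (!length(f)) return(NULL)
    tab <- readr::read_delim(f[1], delim = "$", progress = FALSE, trim_ws = TRUE,
                             col_types = readr::cols(.default = readr::col_character()))
    names(tab) <- tolower(names(tab))
    tab
  }
  demo <- find_tab("demo")
  drug <- find_tab("drug")
  reac <- find_tab("reac")
  for (nm in c("demo", "drug", "reac")) {
    if (is.null(get(nm))) abort(sprintf("faers_ascii input missing mandatory table: %s", nm))
  }
  if (!"primaryid" %in% names(demo)) abort("faers_ascii DEMO missing mandatory column: primaryid")
  ther <- find_tab("ther")
  outc <- find_tab("outc")

  col_or_na <- function(tab, nm) if (nm %in% names(tab)) tab[[nm]] else NA_character_
  sex <- tolower(col_or_na(demo, "sex"))
  sex <- ifelse(sex %in% c("m"), "male", ifelse(sex %in% c("f"), "female", "unknown"))
  age_cod <- tolower(col_or_na(demo, "age_cod"))
  unit <- ifelse(age_cod %in% c("yr", "mon", "dec"), age_cod, "yr")
  region_of <- function(country) {
    country <- toupper(trimws(country))
    americas <- c("US", "USA", "CA", "BR", "MX", "AR")
    europe <- c("GB", "DE", "FR", "IT", "ES", "NL", "SE", "CH", "PL")
    asia <- c("JP", "CN", "KR", "IN")
    oceania <- c("AU", "NZ")
    africa <- c("ZA", "NG", "EG")
    ifelse(country %in% americas, "americas",
      ifelse(country %in% europe, "europe",
        ifelse(country %in% asia, "asia",
          ifelse(country %in% oceania, "oceania",
            ifelse(country %in% africa, "africa", "unknown")))))
  }
  serious <- rep(FALSE, nrow(demo))
  if (!is.null(outc) && "primaryid" %in% names(outc)) {
    serious <- demo$primaryid %in% outc$primaryid
  }
  reports <- tibble(
    report_id = col_or_na(demo, "caseid") %||% demo$primaryid,
    case_version = suppressWarnings(as.integer(col_or_na(demo, "caseversion"))),
    primaryid = demo$primaryid,
    receipt_date = parse_report_date(col_or_na(demo, "fda_dt"), "fda_dt"),
    sex = sex,
    age_years = age_to_years(col_or_na(demo, "age"), unit),
    region = region_of(col_or_na(demo, "occr_country")),
    serious = serious,
    weight = 1
  )
  reports$report_id[is.na(reports$report_id)] <- reports$primaryid[is.na(reports$report_id)]
  reports$case_version[is.na(reports$case_version)] <- 1L
  reports$age_years[!is.na(reports$age_years) &
                      (reports$age_years < 0 | reports$age_years > 120)] <- NA_real_

  role_map <- c(PS = "suspect", SS = "suspect", C = "concomitant", I = "interacting")
  drugs <- tibble(
    primaryid = drug$primaryid,
    drug_name = col_or_na(drug, "drugname"),
    role = unname(role_map[toupper(col_or_na(drug, "role_cod"))]),
    therapy_start = as.Date(NA)
  )
  drugs$role[is.na(drugs$role)] <- "suspect"
  if (!is.null(ther) && all(c("primaryid", "start_dt") %in% names(ther))) {
    ther_start <- ther |>
      mutate(start = parse_report_date(.data$start_dt, "ther start_dt")) |>
      group_by(.data$primaryid) |>
      summarise(therapy_start = suppressWarnings(min(.data$start, na.rm = TRUE)),
                .groups = "drop")
    ther_start$therapy_start[is.infinite(as.numeric(ther_start$therapy_start))] <- as.Date(NA)
    drugs <- drugs |> select(-"therapy_start") |>
      left_join(ther_start, by = "primaryid")
  }
  reactions <- tibble(
    primaryid = reac$primaryid,
    pt = col_or_na(reac, "pt"),
    onset_date = parse_report_date(col_or_na(reac, "event_dt"), "event_dt"),
    outcome = "unknown"
  )
  idmap <- reports |> select("primaryid", "report_id", "case_version")
  drugs <- drugs |> inner_join(idmap, by = "primaryid") |>
    distinct(.data$report_id, .data$case_version, .data$drug_name, .data$role,
             .data$therapy_start) |>
    filter(!is.na(.data$drug_name))
  reactions <- reactions |> inner_join(idmap, by = "primaryid") |>
    distinct(.data$report_id, .data$case_version, .data$pt, .data$onset_date,
             .data$outcome) |>
    filter(!is.na(.data$pt))
  reports <- reports |> select(-"primaryid") |>
    distinct(.data$report_id, .data$case_version, .keep_all = TRUE)
  keep <- reports$report_id %in% drugs$report_id &
    reports$report_id %in% reactions$report_id
  report_store(reports[keep, ], drugs, reactions, provenance = path)
}

#' Write a report store as a flat CSV
#'
#' Emits one row per (report, drug, reaction) combination; [read_reports()]
#' with `dialect = "flat_csv"` round-trips the store field-for-field.
#'
#' @param store a [report_store()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(store, path) {
  rows <- store$reports |>
    inner_join(store$drugs, by = c("report_id", "case_version"),
               relationship = "many-to-many") |>
    inner_join(store$reactions, by = c("report_id", "case_version"),
               relationship = "many-to-many") |>
    mutate(age_unit = "yr", drug_role = .data$role,
           serious = ifelse(.data$serious, "true", "false")) |>
    select(dplyr::all_of(flat_csv_columns), "weight") |>
    arrange(.data$report_id, .data$case_version, .data$drug_name, .data$pt)
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Deduplicate a report store
#'
#' Applies the FAERS-standard two-step rule: (i) among rows sharing a
#' `report_id`, keep only the highest `case_version` (ties broken by latest
#' `receipt_date`); (ii) collapse reports with distinct ids but identical
#' content 5-tuple (sex, age, drug-name set, PT set, receipt date) to one,
#' keeping the lexicographically smallest `report_id`. Idempotent; never
#' increases the report count.
#'
#' @param store a [report_store()].
#' @return a deduplicated [report_store()]; the number of reports removed by
#'   each rule is recorded in `attr(, "dedup_log")`.
#' @export
deduplicate <- function(store) {
  r <- store$reports
  n0 <- nrow(r)
  if (n0 == 0L) return(store)
  # rule (i): latest case_version per report_id, ties by receipt_date
  keep1 <- r |>
    arrange(.data$report_id, desc(.data$case_version), desc(.data$receipt_date)) |>
    distinct(.data$report_id, .keep_all = TRUE)
  # rule (ii): exact-content collapse
  drug_sets <- store$drugs |>
    semi_join(keep1, by = c("report_id", "case_version")) |>
    group_by(.data$report_id) |>
    summarise(drug_set = paste(sort(unique(.data$drug_norm)), collapse = "|"),
              .groups = "drop")
  pt_sets <- store$reactions |>
    semi_join(keep1, by = c("report_id", "case_version")) |>
    group_by(.data$report_id) |>
    summarise(pt_set = paste(sort(unique(.data$pt)), collapse = "|"),
              .groups = "drop")
  keyed <- keep1 |>
    left_join(drug_sets, by = "report_id") |>
    left_join(pt_sets, by = "report_id") |>
    mutate(content_key = paste(.data$sex, .data$age_years, .data$drug_set,
                               .data$pt_set, .data$receipt_date, sep = "\r"))
  keep2 <- keyed |>
    arrange(.data$content_key, .data$report_id) |>
    distinct(.data$content_key, .keep_all = TRUE) |>
    select(-"drug_set", -"pt_set", -"content_key")
  out <- structure(
    list(
      reports = keep2 |> arrange(.data$report_id),
      drugs = store$drugs |> semi_join(keep2, by = c("report_id", "case_version")),
      reactions = store$reactions |> semi_join(keep2, by = c("report_id", "case_version")),
      provenance = store$provenance
    ),
    class = "report_store"
  )
  attr(out, "dedup_log") <- c(
    input = n0,
    removed_version = n0 - nrow(keep1),
    removed_content = nrow(keep1) - nrow(keep2),
    output = nrow(keep2)
  )
  out
}

#' Select the reports mentioning a drug
#'
#' Name matching is case-insensitive after normalization and runs through an
#' optional synonym table (brand and generic names).
#'
#' @param store a [report_store()].
#' @param drug target drug name.
#' @param roles drug roles that qualify (default: all three).
#' @param synonyms optional synonym table, see [resolve_drug_name()].
#' @return a [report_store()] restricted to the matching reports.
#' @export
select_drug_reports <- function(store, drug,
                                roles = .role_levels, synonyms = NULL) {
  stopifnot(nzchar(drug))
  ids <- exposed_report_ids(store, drug, roles = roles, synonyms = synonyms)
  subset_store(store, ids)
}

# report_ids of reports containing `drug` with a qualifying role
exposed_report_ids <- function(store, drug, roles = .role_levels, synonyms = NULL) {
  target <- resolve_drug_name(drug, synonyms)
  d <- store$drugs
  hit <- resolve_drug_name(d$drug_norm, synonyms) == target & d$role %in% roles
  unique(d$report_id[hit])
}

subset_store <- function(store, report_ids) {
  structure(
    list(
      reports = store$reports |> filter(.data$report_id %in% report_ids),
      drugs = store$drugs |> filter(.data$report_id %in% report_ids),
      reactions = store$reactions |> filter(.data$report_id %in% report_ids),
      provenance = store$provenance
    ),
    class = "report_store"
  )
}

#' Read a PT-to-SOC mapping
#'
#' The MedDRA hierarchy is user-supplied as a two-column CSV (`pt`, `soc`);
#' each preferred term must map to exactly one primary system organ class.
#'
#' @param path CSV file with columns `pt` and `soc`.
#' @return named character vector mapping PT to SOC.
#' @export
read_pt2soc <- function(path) {
  tab <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("pt", "soc") %in% names(tab))) {
    abort("pt2soc mapping must have columns: pt, soc")
  }
  as_hierarchy(tab)
}

#' Build a PT-to-SOC hierarchy from a data frame or named vector
#'
#' @param x two-column data frame (`pt`, `soc`) or named character vector.
#' @return named character vector (names = PT, values = SOC).
#' @export
as_hierarchy <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    h <- x
  } else {
    x <- as_tibble(x)
    h <- setNames(as.character(x$soc), as.character(x$pt))
  }
  if (anyDuplicated(names(h))) {
    dup <- unique(names(h)[duplicated(names(h))])
    if (any(tapply(h, names(h), function(v) length(unique(v))) > 1)) {
      abort(sprintf("PT(s) mapped to more than one SOC: %s",
                    paste(head(dup, 5), collapse = ", ")))
    }
    h <- h[!duplicated(names(h))]
  }
  h
}

# map PTs through the hierarchy, erroring on unmapped PTs
map_soc <- function(pts, hierarchy) {
  soc <- unname(hierarchy[pts])
  if (anyNA(soc)) {
    missing_pt <- sort(unique(pts[is.na(soc)]))
    abort(sprintf("PT(s) missing from the PT-to-SOC hierarchy: %s",
                  paste(head(missing_pt, 10), collapse = ", ")))
  }
  soc
}

#' Read a label-listedness PT set
#' @param path text file or CSV with one PT per line (column `pt` if a header
#'   is present).
#' @return character vector of listed PTs.
#' @export
read_label_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(lines[1]) == "pt") lines <- lines[-1]
  unique(lines)
}
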