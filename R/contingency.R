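#' Define an analysis stratum
#'
#' @param sex `"male"`, `"female"`, `"unknown"`, or `"any"`.
#' @param age one of `"<18"`, `"18-44"`, `"45-64"`, `">=65"`, `"any"`
#'   (boundaries inclusive: `[18, 44]`, `[45, 64]`, `[65, Inf)`).
#' @param label display label; derived from the filters when omitted.
#' @return an object of class `stratum`.
#' @export
stratum <- function(sex = "any", age = "any", label = NULL) {
  stopifnot(sex %in% c("male", "female", "unknown", "any"), age %in% .age_levels)
  if (is.null(label)) {
    label <- if (sex == "any" && age == "any") "overall"
             else paste0(if (sex != "any") paste0("sex=", sex) else "",
                         if (sex != "any" && age != "any") "," else "",
                         if (age != "any") paste0("age=", age) else "")
  }
  structure(list(sex = sex, age = age, label = label), class = "stratum")
}

# Restrict a store to a stratum. Reports with unknown sex/age are excluded
# from the corresponding stratified screens but retained when the filter is
# "any" (mirroring "after excluding reports with unspecified data").
filter_stratum <- function(store, stratum) {
  r <- store$reports
  keep <- rep(TRUE, nrow(r))
  if (stratum$sex != "any") keep <- keep & r$sex == stratum$sex
  if (stratum$age != "any") {
    keep <- keep & !is.na(r$age_years) & age_bin(r$age_years) == stratum$age
  }
  subset_store(store, r$report_id[keep])
}

# One (report, PT) event record per distinct PT within a report, carrying the
# report weight. Duplicate reaction rows for the same PT count once.
event_records <- function(store) {
  store$reactions |>
    distinct(.data$report_id, .data$pt) |>
    inner_join(store$reports |> select("report_id", "weight"), by = "report_id")
}

new_contingency_table <- function(a, b, c, d, exposure = "", event = "",
                                  stratum_label = "overall", unit = "record") {
  structure(
    list(a = a, b = b, c = c, d = d, n = a + b + c + d,
         exposure = exposure, event = event, stratum = stratum_label,
         unit = unit, degenerate = (a + b + c + d) <= 0),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s vs %s [%s, unit=%s]%s\n",
              x$exposure, x$event, x$stratum, x$unit,
              if (x$degenerate) " DEGENERATE" else ""))
  cat(sprintf("  a=%s b=%s c=%s d=%s (N=%s)\n",
              format(x$a, big.mark = ","), format(x$b, big.mark = ","),
              format(x$c, big.mark = ","), format(x$d, big.mark = ","),
              format(x$n, big.mark = ",")))
  invisible(x)
}

#' Build the 2x2 disproportionality table for one drug-event pair
#'
#' Cell definitions follow the standard fourfold table: `a` = target-exposure
#' records with the target event, `b` = its records with other events, `c` and
#' `d` the same for all other exposures. With `unit = "record"` (default) the
#' counting unit is one (report, PT) event record — a report with several
#' distinct PTs contributes one record per PT — so `a + b` equals the
#' exposure's total event records. With `unit = "report"` a report contributes
#' at most one count per cell.
#'
#' @param store a deduplicated [report_store()].
#' @param exposure target drug name, or a [combination_exposure()].
#' @param event a PT (default) or a SOC name when `event_level = "soc"`.
#' @param hierarchy PT-to-SOC mapping ([as_hierarchy()]); required for
#'   `event_level = "soc"`.
#' @param stratum a [stratum()] restricting the table.
#' @param unit `"record"` or `"report"`.
#' @param event_level `"pt"` or `"soc"`.
#' @param roles drug roles qualifying a report as exposed.
#' @param synonyms optional drug synonym table.
#' @return a `contingency_table` with cells `a`, `b`, `c`, `d`; an empty
#'   stratum yields a table of zeros flagged `degenerate`.
#' @export
build_table <- function(store, exposure, event, hierarchy = NULL,
                        stratum = pvscreen::stratum(), unit = c("record", "report"),
                        event_level = c("pt", "soc"), roles = .role_levels,
                        synonyms = NULL) {
  unit <- match.arg(unit)
  event_level <- match.arg(event_level)
  st <- filter_stratum(store, stratum)
  exposed <- exposure_ids(st, exposure, roles, synonyms)
  ev <- event_records(st)
  if (event_level == "soc") {
    if (is.null(hierarchy)) abort("SOC-level events require a hierarchy")
    ev$match <- map_soc(ev$pt, hierarchy) == event
  } else {
    ev$match <- ev$pt == event
  }
  ev$exposed <- ev$report_id %in% exposed
  if (unit == "report") {
    ev <- ev |>
      group_by(.data$report_id, .data$exposed, .data$weight) |>
      summarise(has_event = any(.data$match), has_other = any(!.data$match),
                .groups = "drop")
    a <- sum(ev$weight[ev$exposed & ev$has_event])
    b <- sum(ev$weight[ev$exposed & ev$has_other])
    c_ <- sum(ev$weight[!ev$exposed & ev$has_event])
    d <- sum(ev$weight[!ev$exposed & ev$has_other])
  } else {
    a <- sum(ev$weight[ev$exposed & ev$match])
    b <- sum(ev$weight[ev$exposed & !ev$match])
    c_ <- sum(ev$weight[!ev$exposed & ev$match])
    d <- sum(ev$weight[!ev$exposed & !ev$match])
  }
  new_contingency_table(a, b, c_, d,
                        exposure = exposure_label(exposure), event = event,
                        stratum_label = stratum$label, unit = unit)
}

# resolve an exposure descriptor (drug name or combination) to report ids
exposure_ids <- function(store, exposure, roles = .role_levels, synonyms = NULL) {
  if (inherits(exposure, "combination_exposure")) {
    base <- exposed_report_ids(store, exposure$base_drug, roles, synonyms)
    partner <- exposed_report_ids(store, exposure$partner_drug,
                                  roles = .role_levels, synonyms = synonyms)
    intersect(base, partner)
  } else {
    exposed_report_ids(store, exposure, roles, synonyms)
  }
}

exposure_label <- function(exposure) {
  if (inherits(exposure, "combination_exposure")) {
    paste0(exposure$base_drug, " + ", exposure$partner_drug)
  } else {
    as.character(exposure)
  }
}

#' Build 2x2 tables for every observed PT of an exposure
#'
#' All tables share the same margins within the stratum: `a + b` is the
#' exposure's total event records and `c + d` the comparator's.
#'
#' @inheritParams build_table
#' @param min_a minimum `a` (case count) a PT needs to be returned; the
#'   conventional screening floor is 3.
#' @return tibble with columns `pt`, `a`, `b`, `c`, `d`, sorted by `a`
#'   descending then `pt` ascending.
#' @export
build_all_pt_tables <- function(store, exposure, stratum = pvscreen::stratum(),
                                min_a = 3, unit = c("record", "report"),
                                roles = .role_levels, synonyms = NULL) {
  unit <- match.arg(unit)
  stopifnot(min_a >= 0)
  st <- filter_stratum(store, stratum)
  exposed <- exposure_ids(st, exposure, roles, synonyms)
  ev <- event_records(st)
  ev$exposed <- ev$report_id %in% exposed
  # unit=report and unit=record coincide per PT (a report holds each PT once);
  # margins differ only through b and d, which unit=report caps per report.
  counts <- ev |>
    group_by(.data$pt) |>
    summarise(a = sum(.data$weight[.data$exposed]),
              c = sum(.data$weight[!.data$exposed]), .groups = "drop")
  if (unit == "record") {
    ab_total <- sum(ev$weight[ev$exposed])
    cd_total <- sum(ev$weight[!ev$exposed])
    counts <- counts |>
      mutate(b = ab_total - .data$a, d = cd_total - .data$c)
  } else {
    per_report <- ev |> group_by(.data$report_id) |> mutate(npt = n()) |> ungroup()
    # b: exposed reports having at least one other PT
    other_w_exp <- sum(unique(per_report[per_report$exposed, c("report_id", "weight")])$weight)
    counts$b <- vapply(counts$pt, function(p) {
      rr <- per_report[per_report$exposed, ]
      sum(unique(rr[!(rr$report_id %in% rr$report_id[rr$pt == p & rr$npt == 1]),
                    c("report_id", "weight")])$weight)
    }, numeric(1))
    counts$d <- vapply(counts$pt, function(p) {
      rr <- per_report[!per_report$exposed, ]
      sum(unique(rr[!(rr$report_id %in% rr$report_id[rr$pt == p & rr$npt == 1]),
                    c("report_id", "weight")])$weight)
    }, numeric(1))
  }
  counts |>
    filter(.data$a >= min_a) |>
    select("pt", "a", "b", "c", "d") |>
    arrange(desc(.data$a), .data$pt)
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Given the case count `a`, the exposure's total event records `a + b`, the
#' printed ROR point estimate, and the printed chi-square, the comparator
#' cells are identified: the ROR fixes the ratio `d/c` and the chi-square —
#' strictly monotone in the comparator scale — fixes `c` itself, solved
#' numerically. Used to replay published signal-table rows whose raw
#' databases are not available.
#'
#' @param a case count for the drug-event pair.
#' @param ab_total the exposure's total event records (`a + b`).
#' @param ror printed ROR point estimate.
#' @param chi2 printed chi-square statistic.
#' @return a `contingency_table` (cells `c`, `d` continuous; round before
#'   replaying as reports).
#' @export
reconstruct_table <- function(a, ab_total, ror, chi2) {
  stopifnot(a > 0, ab_total > a, ror > 0, chi2 > 0)
  b <- ab_total - a
  k <- ror * b / a # d = k * c
  chi2_of <- function(cc) {
    d <- k * cc
    n <- a + b + cc + d
    (a * d - b * cc)^2 * n / ((a + b) * (a + cc) * (cc + d) * (b + d))
  }
  sol <- uniroot(function(lc) chi2_of(exp(lc)) - chi2,
                 lower = log(1e-6), upper = log(1e12), tol = 1e-13)
  c_ <- exp(sol$root)
  new_contingency_table(a, b, c_, k * c_, exposure = "reconstructed",
                        event = "reconstructed")
}
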