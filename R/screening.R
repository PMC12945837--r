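#' Screen every PT of an exposure for disproportionality signals
#'
#' Builds all PT-level 2x2 tables with `a >= min_a`, computes the five
#' statistics and their flags, and marks a PT a "positive signal" when the
#' combined rule of the threshold configuration holds (default: both the ROR
#' and the PRR criteria). Rows are ranked by ROR point estimate (ties: `a`
#' descending, PT ascending), mirroring the published signal tables.
#'
#' @param store a deduplicated [report_store()].
#' @param exposure target drug name or a [combination_exposure()].
#' @param hierarchy PT-to-SOC mapping ([as_hierarchy()]); every screened PT
#'   must be mapped, unmapped PTs are an error.
#' @param thresholds a [threshold_config()].
#' @param priors a [bcpnn_priors()].
#' @param stratum a [stratum()].
#' @param label optional character vector of label-listed PTs; when supplied,
#'   rows gain a `label_listed` flag (see [flag_unlisted()]).
#' @param unit counting unit, `"record"` (default) or `"report"`.
#' @param roles drug roles qualifying a report as exposed.
#' @param synonyms optional drug synonym table.
#' @return an object of class `screen_result`: `rows` (tibble of per-PT
#'   metrics and flags), `meta` (exposure, stratum, thresholds, counts,
#'   number of distinct SOCs among positive signals, number of PTs tested).
#' @export
screen_pt <- function(store, exposure, hierarchy,
                      thresholds = threshold_config(),
                      priors = bcpnn_priors(), stratum = pvscreen::stratum(),
                      label = NULL, unit = "record",
                      roles = .role_levels, synonyms = NULL) {
  tabs <- build_all_pt_tables(store, exposure, stratum = stratum,
                              min_a = thresholds$min_a, unit = unit,
                              roles = roles, synonyms = synonyms)
  if (nrow(tabs) == 0L) {
    rows <- dispro_engine(numeric(0), numeric(0), numeric(0), numeric(0))
    rows <- add_flags(rows, thresholds)
    rows$pt <- character(0)
    rows$soc <- character(0)
  } else {
    rows <- dispro_engine(tabs$a, tabs$b, tabs$c, tabs$d, z = thresholds$z,
                          priors = priors, continuity = thresholds$continuity)
    rows <- add_flags(rows, thresholds)
    rows$pt <- tabs$pt
    rows$soc <- map_soc(tabs$pt, hierarchy)
  }
  rows <- rows |>
    select("soc", "pt", dplyr::everything()) |>
    arrange(desc(!is.na(.data$ror)), desc(.data$ror), desc(.data$a), .data$pt)
  rows$label_listed <- if (is.null(label)) NA else rows$pt %in% label
  res <- structure(
    list(
      rows = rows,
      meta = list(
        exposure = exposure_label(exposure),
        stratum = stratum$label,
        unit = unit,
        thresholds = thresholds,
        priors = priors,
        source = store$provenance,
        n_pt_tested = nrow(rows),
        n_positive = sum(rows$positive),
        n_soc_positive = length(unique(rows$soc[rows$positive])),
        degenerate = nrow(rows) == 0L
      )
    ),
    class = "screen_result"
  )
  res
}

#' @export
print.screen_result <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<screen_result> %s [%s, unit=%s]%s\n", m$exposure, m$stratum,
              m$unit, if (isTRUE(m$degenerate)) " DEGENERATE" else ""))
  cat(sprintf("  %d PTs tested, %d positive signals across %d SOCs (rule: %s)\n",
              m$n_pt_tested, m$n_positive, m$n_soc_positive, m$thresholds$rule))
  print(head(x$rows |> select("soc", "pt", "a", "ror", "ror_lo", "ror_hi",
                              "prr", "chi2", "ic", "ic_minus_2sd", "ebgm",
                              "ebgm_lo", "positive"), 10))
  invisible(x)
}

#' Multi-method concordance of a screen
#'
#' For every non-empty subset of the five methods, the number of PTs flagged
#' by exactly that subset and by at least that subset. The "detected by all
#' five together" count of published concordance statements is the
#' `at_least` entry for the full subset.
#'
#' @param result a [screen_pt()] result.
#' @return tibble with columns `methods` (e.g. `"ror+prr"`), `size`,
#'   `n_exactly`, `n_at_least`.
#' @export
concordance <- function(result) {
  rows <- result$rows
  methods <- c("ror", "prr", "mhra", "bcpnn", "ebgm")
  flags <- as.matrix(rows[paste0("flag_", methods)])
  colnames(flags) <- methods
  subsets <- lapply(seq_len(2^5 - 1), function(k) methods[bitwAnd(k, 2^(0:4)) > 0])
  out <- lapply(subsets, function(s) {
    in_s <- flags[, s, drop = FALSE]
    out_s <- flags[, setdiff(methods, s), drop = FALSE]
    all_in <- if (nrow(flags)) rowSums(in_s) == length(s) else logical(0)
    none_out <- if (ncol(out_s)) rowSums(out_s) == 0 else rep(TRUE, nrow(flags))
    tibble(methods = paste(s, collapse = "+"), size = length(s),
           n_exactly = sum(all_in & none_out), n_at_least = sum(all_in))
  })
  bind_rows(out) |> arrange(.data$size, .data$methods)
}

#' Flag positive signals absent from the product label
#'
#' @param result a [screen_pt()] result.
#' @param label character vector of label-listed PTs ([read_label_list()]).
#' @return the `screen_result` with `label_listed` filled in and a per-SOC
#'   summary of unlisted positive signals in `meta$unlisted_by_soc`.
#' @export
flag_unlisted <- function(result, label) {
  if (is.null(label) || !length(label)) abort("a non-empty label list is required")
  result$rows$label_listed <- result$rows$pt %in% label
  pos <- result$rows |> filter(.data$positive)
  result$meta$unlisted_by_soc <- pos |>
    group_by(.data$soc) |>
    summarise(n_positive = n(), n_unlisted = sum(!.data$label_listed),
              .groups = "drop") |>
    arrange(desc(.data$n_unlisted), .data$soc)
  result$meta$n_unlisted <- sum(!pos$label_listed)
  result
}

#' Per-SOC event-record counts and proportions for an exposure
#'
#' Counts every event record of the exposure (no `min_a` floor) and rolls
#' them up to system organ classes; proportions sum to one.
#'
#' @inheritParams screen_pt
#' @return tibble with `soc`, `records`, `proportion`, sorted by records
#'   descending.
#' @export
soc_rollup <- function(store, exposure, hierarchy,
                       stratum = pvscreen::stratum(), roles = .role_levels,
                       synonyms = NULL) {
  st <- filter_stratum(store, stratum)
  exposed <- exposure_ids(st, exposure, roles, synonyms)
  ev <- event_records(st) |> filter(.data$report_id %in% exposed)
  if (nrow(ev) == 0L) {
    return(tibble(soc = character(), records = numeric(), proportion = numeric()))
  }
  ev$soc <- map_soc(ev$pt, hierarchy)
  ev |>
    group_by(.data$soc) |>
    summarise(records = sum(.data$weight), .groups = "drop") |>
    mutate(proportion = .data$records / sum(.data$records)) |>
    arrange(desc(.data$records), .data$soc)
}

#' Write a screen result as a signal-table TSV
#'
#' Columns mirror the published signal tables: `soc`, `pt`, `case_reports`,
#' `ror_ci` (as `"354.61 (322.53, 389.89)"`), `prr_ci`, `chi_square`,
#' `ic_ic025`, `ebgm_ebgm05`, per-method flags, `positive`, `label_listed`.
#' Numbers are presentation-rounded half-up to 2 decimals; internal precision
#' is untouched.
#'
#' @param result a [screen_pt()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(result, path) {
  r <- result$rows
  out <- tibble(
    soc = r$soc,
    pt = r$pt,
    case_reports = r$a,
    ror_ci = sprintf("%s (%s, %s)", fmt2(r$ror), fmt2(r$ror_lo), fmt2(r$ror_hi)),
    prr_ci = sprintf("%s (%s, %s)", fmt2(r$prr), fmt2(r$prr_lo), fmt2(r$prr_hi)),
    chi_square = fmt2(r$chi2),
    ic_ic025 = sprintf("%s (%s)", fmt2(r$ic), fmt2(r$ic_minus_2sd)),
    ebgm_ebgm05 = sprintf("%s (%s)", fmt2(r$ebgm), fmt2(r$ebgm_lo)),
    flag_ror = r$flag_ror, flag_prr = r$flag_prr, flag_mhra = r$flag_mhra,
    flag_bcpnn = r$flag_bcpnn, flag_ebgm = r$flag_ebgm,
    positive = r$positive,
    label_listed = r$label_listed
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
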