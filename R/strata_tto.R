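#' Default sex and age strata
#'
#' The stratification used by the published sex/age subgroup screens: male,
#' female, and the age groups `18-44`, `45-64`, `>=65` (plus `<18`).
#'
#' @param by `"sex"`, `"age"`, or `"both"` (all strata of either kind).
#' @return list of [stratum()] objects.
#' @export
default_strata <- function(by = c("both", "sex", "age")) {
  by <- match.arg(by)
  sex <- list(stratum(sex = "male"), stratum(sex = "female"))
  age <- list(stratum(age = "<18"), stratum(age = "18-44"),
              stratum(age = "45-64"), stratum(age = ">=65"))
  switch(by, sex = sex, age = age, both = c(sex, age))
}

#' Sex- and age-stratified disproportionality screens
#'
#' Runs [screen_pt()] once per stratum, restricting both the exposure and the
#' comparator counts to the stratum before table construction. Reports with
#' unknown sex (or age) are excluded from the corresponding strata but remain
#' in any unstratified screen.
#'
#' @inheritParams screen_pt
#' @param strata list of [stratum()] objects (default [default_strata()]).
#' @return an object of class `stratified_screen`: `screens` (named list of
#'   `screen_result`), and `comparison` (per-PT table of the positive flag in
#'   each stratum, for spotting stratum-specific signals).
#' @export
stratified_screen <- function(store, exposure, hierarchy,
                              thresholds = threshold_config(),
                              priors = bcpnn_priors(),
                              strata = default_strata(), label = NULL,
                              unit = "record", roles = .role_levels,
                              synonyms = NULL) {
  stopifnot(length(strata) >= 1)
  screens <- lapply(strata, function(st) {
    screen_pt(store, exposure, hierarchy, thresholds = thresholds,
              priors = priors, stratum = st, label = label, unit = unit,
              roles = roles, synonyms = synonyms)
  })
  names(screens) <- vapply(strata, function(st) st$label, character(1))
  per_stratum <- lapply(names(screens), function(nm) {
    rows <- screens[[nm]]$rows
    if (nrow(rows) == 0L) {
      return(tibble(pt = character(), stratum = character(), positive = logical()))
    }
    tibble(pt = rows$pt, stratum = nm, positive = rows$positive)
  })
  comparison <- bind_rows(per_stratum)
  comparison <- if (nrow(comparison)) {
    tidyr::pivot_wider(comparison, names_from = "stratum",
                       values_from = "positive", values_fill = FALSE) |>
      arrange(.data$pt)
  } else {
    tibble(pt = character())
  }
  structure(list(screens = screens, comparison = comparison),
            class = "stratified_screen")
}

#' @export
print.stratified_screen <- function(x, ...) {
  cat(sprintf("<stratified_screen> %d strata: %s\n", length(x$screens),
              paste(names(x$screens), collapse = ", ")))
  for (nm in names(x$screens)) {
    m <- x$screens[[nm]]$meta
    cat(sprintf("  %-14s %4d PTs tested, %3d positive%s\n", nm, m$n_pt_tested,
                m$n_positive, if (isTRUE(m$degenerate)) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Sex-contrast table for an exposure's own reports
#'
#' Secondary view of the sex disparity: for each PT, a 2x2 of female vs male
#' reports *within* the exposure's reports (a = female with PT, b = female
#' other PTs, c = male with PT, d = male other PTs), pushed through the same
#' ROR machinery. A ROR above 1 means female-predominant reporting of the PT
#' relative to the drug's other events.
#'
#' @inheritParams screen_pt
#' @param min_a minimum female case count for a PT to be tabulated.
#' @return tibble of per-PT metrics (ROR scale = female vs male).
#' @export
sex_contrast <- function(store, exposure, min_a = 3, roles = .role_levels,
                         synonyms = NULL) {
  sub <- select_drug_reports(store, exposure, roles = roles, synonyms = synonyms)
  ev <- event_records(sub) |>
    inner_join(sub$reports |> select("report_id", "sex"), by = "report_id") |>
    filter(.data$sex %in% c("male", "female"))
  if (nrow(ev) == 0L) {
    return(tibble(pt = character(), a = numeric(), b = numeric(),
                  c = numeric(), d = numeric()))
  }
  tot <- ev |> group_by(.data$sex) |> summarise(w = sum(.data$weight), .groups = "drop")
  tot_f <- sum(tot$w[tot$sex == "female"])
  tot_m <- sum(tot$w[tot$sex == "male"])
  counts <- ev |>
    group_by(.data$pt) |>
    summarise(a = sum(.data$weight[.data$sex == "female"]),
              c = sum(.data$weight[.data$sex == "male"]), .groups = "drop") |>
    mutate(b = tot_f - .data$a, d = tot_m - .data$c) |>
    filter(.data$a >= min_a)
  m <- dispro_engine(counts$a, counts$b, counts$c, counts$d)
  m$pt <- counts$pt
  m |> select("pt", dplyr::everything()) |>
    arrange(desc(!is.na(.data$ror)), desc(.data$ror), .data$pt)
}

tto_bins <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")

assign_tto_bin <- function(days) {
  cut(days, breaks = c(-0.5, 30.5, 60.5, 90.5, 180.5, 360.5, Inf),
      labels = tto_bins)
}

#' Time-to-onset records for an exposure
#'
#' Days from the exposure's first (earliest) therapy start to each matching
#' reaction's onset. Missing either date propagates as unknown — never
#' imputed. Negative differences are implausible and excluded (but counted).
#'
#' @inheritParams screen_pt
#' @param event a PT, or `"all"` for every reaction.
#' @return tibble with `report_id`, `pt`, `days` (`NA` = unknown), `sex`,
#'   plus attribute `n_negative` (excluded implausible records).
#' @export
tto_records <- function(store, exposure, event = "all",
                        roles = .role_levels, synonyms = NULL) {
  sub <- select_drug_reports(store, exposure, roles = roles, synonyms = synonyms)
  target <- resolve_drug_name(exposure, synonyms)
  starts <- sub$drugs |>
    filter(resolve_drug_name(.data$drug_norm, synonyms) == target,
           .data$role %in% roles) |>
    group_by(.data$report_id) |>
    summarise(start = if (all(is.na(.data$therapy_start))) as.Date(NA)
              else min(.data$therapy_start, na.rm = TRUE), .groups = "drop")
  reac <- sub$reactions |> distinct(.data$report_id, .data$pt, .data$onset_date)
  if (event != "all") reac <- reac |> filter(.data$pt == event)
  rec <- reac |>
    left_join(starts, by = "report_id") |>
    left_join(sub$reports |> select("report_id", "sex"), by = "report_id") |>
    mutate(days = as.integer(.data$onset_date - .data$start))
  n_neg <- sum(!is.na(rec$days) & rec$days < 0)
  rec <- rec |> filter(is.na(.data$days) | .data$days >= 0) |>
    select("report_id", "pt", "days", "sex")
  attr(rec, "n_negative") <- n_neg
  rec
}

#' Time-to-onset summary
#'
#' Bins the known onset delays into the conventional intervals 0-30, 31-60,
#' 61-90, 91-180, 181-360, and >360 days, reports the median delay (lower
#' median for even counts), the unknown fraction, and per-sex empirical
#' cumulative onset curves among known-delay records.
#'
#' @inheritParams tto_records
#' @return an object of class `tto_summary`: `bins` (counts and proportions
#'   among known), `median_days` (`NA` when no delay is known),
#'   `unknown_fraction`, `n_known`, `n_negative_excluded`, and `curves`
#'   (per-sex tibble of `days`, `cum_prop`).
#' @export
tto_summary <- function(store, exposure, event = "all",
                        roles = .role_levels, synonyms = NULL) {
  rec <- tto_records(store, exposure, event = event, roles = roles,
                     synonyms = synonyms)
  known <- rec$days[!is.na(rec$days)]
  bins <- tibble(bin = factor(tto_bins, levels = tto_bins)) |>
    left_join(tibble(bin = assign_tto_bin(known)) |> count(.data$bin),
              by = "bin") |>
    mutate(n = replace_na(.data$n, 0L),
           proportion = if (length(known)) .data$n / length(known) else 0)
  med <- if (length(known)) sort(known)[floor((length(known) + 1) / 2)] else NA_integer_
  known_by_sex <- rec |>
    filter(!is.na(.data$days), .data$sex %in% c("male", "female"))
  curves <- if (nrow(known_by_sex) == 0L) {
    tibble(sex = character(), days = integer(), cum_prop = numeric())
  } else {
    known_by_sex |>
      group_by(.data$sex) |>
      arrange(.data$days, .by_group = TRUE) |>
      mutate(cum_prop = row_number() / n()) |>
      ungroup() |>
      group_by(.data$sex, .data$days) |>
      summarise(cum_prop = max(.data$cum_prop), .groups = "drop") |>
      arrange(.data$sex, .data$days)
  }
  structure(
    list(bins = bins, median_days = med,
         unknown_fraction = if (nrow(rec)) mean(is.na(rec$days)) else NA_real_,
         n_known = length(known), n_records = nrow(rec),
         n_negative_excluded = attr(rec, "n_negative"), curves = curves),
    class = "tto_summary"
  )
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("<tto_summary> %d records, %.1f%% unknown timing, median %s days\n",
              x$n_records, 100 * x$unknown_fraction,
              ifelse(is.na(x$median_days), "undefined", x$median_days)))
  print(x$bins)
  invisible(x)
}

#' Write a time-to-onset summary as TSV
#'
#' @param x a [tto_summary()].
#' @param path output TSV path; the per-sex cumulative curves go to
#'   `<path base>_curves.tsv`.
#' @return `path`, invisibly.
#' @export
write_tto_tsv <- function(x, path) {
  bins <- x$bins |>
    mutate(median_days = x$median_days,
           unknown_fraction = x$unknown_fraction)
  readr::write_tsv(bins, path, progress = FALSE)
  curve_path <- sub("(\\.[^.]*)?$", "_curves.tsv", path)
  readr::write_tsv(x$curves, curve_path, progress = FALSE)
  invisible(path)
}
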